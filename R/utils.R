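#' @keywords internal
"_PACKAGE"

# Canonical labels used throughout: the seven resting-state subnetworks and
# the three study groups.
SUBNETWORK_LEVELS <- c("visual", "somatomotor", "dorsal attention",
                       "salience/ventral attention", "limbic",
                       "frontoparietal control", "default mode")
GROUP_LEVELS <- c("HC", "MDDNSI", "MDDSI")

#' Canonical subnetwork labels
#'
#' The seven resting-state functional subnetworks used to aggregate nodal
#' entropy: visual, somatomotor, dorsal attention, salience/ventral
#' attention, limbic, frontoparietal control and default mode.
#'
#' @return Character vector of the seven labels, in canonical order.
#' @export
subnetwork_levels <- function() SUBNETWORK_LEVELS

#' Study group labels
#'
#' @return Character vector `c("HC", "MDDNSI", "MDDSI")`: healthy controls,
#'   patients without suicidal ideation, patients with suicidal ideation.
#' @export
group_levels <- function() GROUP_LEVELS

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

stop_if_not_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(as.numeric(x))
}

#' Upper-triangle edge index
#'
#' Enumerates the region pairs (m, n), m < n, in row-major upper-triangle
#' order: (1,2), (1,3), ..., (1,N), (2,3), .... All edge-level quantities in
#' the package follow this ordering.
#'
#' @param n_regions Number of regions N.
#' @return Integer matrix with E = N(N-1)/2 rows and columns `m`, `n`.
#' @export
edge_index <- function(n_regions) {
  n_regions <- stop_if_not_count(n_regions, "n_regions", min = 2L)
  m <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  n <- unlist(lapply(seq_len(n_regions - 1L),
                     function(i) seq.int(i + 1L, n_regions)),
              use.names = FALSE)
  cbind(m = m, n = n)
}

# Shannon entropy of a probability vector, normalized to [0, 1] by log2(k).
# k = 1 collapses to 0 by convention (a single community carries no overlap).
normalized_entropy <- function(p, k) {
  if (any(p < -1e-12)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("probability vector does not sum to 1", call. = FALSE)
  if (k < 2) return(0)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  h / log2(k)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score recovery of planted edge communities.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions up to
#'   relabeling, ~0 = chance agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Derive a stream of child seeds from one master seed.  Offsets keep every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% .Machine$integer.max)
}

# Hash of an R object for reproducibility stamps: serialize deterministically
# to JSON, md5 the bytes.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}
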