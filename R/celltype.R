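CELLTYPE_LEVELS <- c("astrocytes", "endothelial cells", "microglia",
                     "excitatory neurons", "inhibitory neurons",
                     "oligodendrocytes 1", "oligodendrocytes 2")

#' Canonical cell-class labels
#'
#' @return The seven cell classes used for gene-set overlap testing.
#' @export
celltype_levels <- function() CELLTYPE_LEVELS

#' Build synthetic cell-type gene sets
#'
#' Draws disjoint gene sets of the requested sizes from a background gene
#' universe, for use when no curated cell-class annotation is supplied.
#'
#' @param background Character vector of gene ids (the universe).
#' @param sizes Integer vector of set sizes, one per cell class (recycled
#'   to 7).
#' @param seed Integer seed.
#' @return Named list of 7 character vectors with attribute `background`.
#' @export
make_celltype_sets <- function(background, sizes = 20L, seed = 1L) {
  background <- unique(as.character(background))
  sizes <- rep_len(as.integer(sizes), length(CELLTYPE_LEVELS))
  if (sum(sizes) > length(background))
    stop("requested set sizes exceed the background")
  set.seed(as.integer(seed))
  pool <- sample(background)
  sets <- vector("list", length(sizes))
  offset <- 0L
  for (i in seq_along(sizes)) {
    sets[[i]] <- pool[(offset + 1L):(offset + sizes[i])]
    offset <- offset + sizes[i]
  }
  names(sets) <- CELLTYPE_LEVELS
  attr(sets, "background") <- background
  sets
}

#' Permutation test of gene-list overlap with cell-type sets
#'
#' For each cell-type gene set, counts the overlap with the query gene list
#' and compares it to the null distribution of overlaps obtained by drawing
#' random gene lists of the same size from the background universe.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`, BH-corrected across the
#' cell types.
#'
#' @param gene_list Character vector of query genes (e.g. the PLS1- set);
#'   must be a subset of the background.
#' @param sets Named list of cell-type gene sets (see
#'   [make_celltype_sets()]).
#' @param background Character vector of all genes; defaults to
#'   `attr(sets, "background")`.
#' @param n_perm Number of random draws (default 10000).
#' @param seed Integer seed.
#' @return Data frame with `celltype`, `set_size`, `overlap`, `p_raw`,
#'   `p_fdr`.
#' @export
celltype_overlap_test <- function(gene_list, sets, background = NULL,
                                  n_perm = 10000L, seed = 1L) {
  if (is.null(background)) background <- attr(sets, "background")
  if (is.null(background) || !length(background))
    stop("empty background gene universe")
  background <- unique(as.character(background))
  gene_list <- unique(as.character(gene_list))
  if (!all(gene_list %in% background))
    stop("gene list contains genes outside the background")
  bad <- names(sets)[!vapply(sets, function(s) all(s %in% background),
                             logical(1))]
  if (length(bad))
    stop(sprintf("cell-type set(s) outside the background: %s",
                 paste(bad, collapse = ", ")))
  m <- length(gene_list)
  observed <- vapply(sets, function(s) length(intersect(gene_list, s)),
                     integer(1))
  set.seed(as.integer(seed))
  exceed <- integer(length(sets))
  in_set <- lapply(sets, function(s) background %in% s)
  for (i in seq_len(n_perm)) {
    draw <- sample.int(length(background), m)
    for (j in seq_along(sets)) {
      ov <- sum(in_set[[j]][draw])
      if (ov >= observed[j]) exceed[j] <- exceed[j] + 1L
    }
  }
  p_raw <- (1 + exceed) / (1 + n_perm)
  data.frame(celltype = names(sets),
             set_size = vapply(sets, length, integer(1)),
             overlap = observed, p_raw = p_raw, p_fdr = bh_fdr(p_raw),
             row.names = NULL, stringsAsFactors = FALSE)
}
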