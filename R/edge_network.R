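#' Z-score regional time series
#'
#' Standardizes each region's signal to mean 0 and population standard
#' deviation 1 (divide-by-T convention). Under this convention the time
#' average of an edge time series equals the Pearson correlation of the two
#' regions exactly, which downstream code relies on.
#'
#' @param ts Region-by-time numeric matrix.
#' @return Matrix of the same shape, rows standardized.
#' @export
zscore_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 2L) stop("need at least 2 time points")
  if (anyNA(ts)) stop("time series contain missing values")
  mu <- rowMeans(ts)
  centered <- ts - mu
  sigma <- sqrt(rowMeans(centered^2))  # population sd
  bad <- which(sigma == 0)
  if (length(bad)) {
    nm <- rownames(ts)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(sprintf("constant (zero-variance) region(s): %s",
                 paste(nm, collapse = ", ")))
  }
  centered / sigma
}

#' Edge time series (co-fluctuation) from z-scored signals
#'
#' For every region pair (m, n), m < n, the edge time series is the
#' element-wise product of the two z-scored signals,
#' \eqn{e_{mn}(t) = z_m(t) z_n(t)} — the instantaneous co-fluctuation of the
#' pair. Its time average is the Pearson correlation of the pair.
#'
#' @param z Region-by-time matrix of z-scored signals (see
#'   [zscore_timeseries()]).
#' @return List with `values` (an `E x T` matrix, E = N(N-1)/2, rows in
#'   upper-triangle row-major order) and `edge_index` (see [edge_index()]).
#' @export
compute_edge_time_series <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 regions")
  pairs <- edge_index(nrow(z))
  ets <- z[pairs[, "m"], , drop = FALSE] * z[pairs[, "n"], , drop = FALSE]
  rn <- rownames(z)
  if (!is.null(rn))
    rownames(ets) <- paste(rn[pairs[, "m"]], rn[pairs[, "n"]], sep = "--")
  list(values = ets, edge_index = pairs)
}

# k-means++ seeding: spread initial centers by sampling proportional to
# squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2L:k) {
      probs <- d2 / sum(d2)
      if (!all(is.finite(probs)) || sum(d2) == 0)
        probs <- rep(1 / n, n)
      pick <- sample.int(n, 1L, prob = probs)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(x[pick, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' Cluster edge time series into edge communities
#'
#' K-means (Euclidean distance over the time dimension, k-means++
#' initialization, Lloyd iterations) applied to the raw edge time series.
#' The clustering is repeated `n_restarts` times with independently derived
#' seeds and the run with the lowest within-community sum of squares is
#' selected; ties go to the lowest restart index. All restart SSE values are
#' returned so the min-selection protocol can be audited.
#'
#' @param ets Edge time series, as returned by [compute_edge_time_series()],
#'   or a bare `E x T` matrix.
#' @param k Number of edge communities (default 10).
#' @param n_restarts Number of random restarts (default 25).
#' @param seed Integer seed; restart seeds are derived deterministically.
#' @param iter_max Maximum Lloyd iterations per run.
#' @return List of class `edge_communities`: `labels` (integer in 1..k per
#'   edge), `k`, `sse` (selected run's within-community sum of squares),
#'   `restart_sse` (all runs), `selected_restart`.
#' @export
cluster_edges <- function(ets, k = 10L, n_restarts = 25L, seed = 1L,
                          iter_max = 300L) {
  x <- if (is.list(ets)) ets$values else as.matrix(ets)
  if (!nrow(x)) stop("empty edge time series")
  k <- stop_if_not_count(k, "k")
  n_restarts <- stop_if_not_count(n_restarts, "n_restarts")
  if (k > nrow(x)) stop("k exceeds the number of edges")
  if (k == 1L) {
    center <- colMeans(x)
    sse <- sum((x - matrix(center, nrow(x), ncol(x), byrow = TRUE))^2)
    return(structure(list(labels = rep(1L, nrow(x)), k = 1L, sse = sse,
                          restart_sse = sse, selected_restart = 1L,
                          centers = matrix(center, 1L)),
                     class = "edge_communities"))
  }
  best <- NULL
  restart_sse <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"))
    restart_sse[r] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss)
      best <- c(fit[c("cluster", "tot.withinss", "centers")],
                list(restart = r))
  }
  structure(list(labels = as.integer(best$cluster), k = as.integer(k),
                 sse = best$tot.withinss, restart_sse = restart_sse,
                 selected_restart = best$restart,
                 centers = unname(best$centers)),
            class = "edge_communities")
}

#' Region-level community participation profile
#'
#' For each region m, the fraction of its N-1 incident edges assigned to
#' each edge community s:
#' \deqn{P_{ms} = \frac{1}{N-1} \sum_{n \ne m} \delta(g_{mn}, s).}
#' Rows are probability vectors (sum to 1).
#'
#' @param labels An `edge_communities` object (or integer label vector).
#' @param n_regions Number of regions N whose upper triangle the labels
#'   cover.
#' @param k Number of communities (taken from `labels` if available).
#' @return `N x k` matrix of frequencies.
#' @export
community_profile <- function(labels, n_regions, k = NULL) {
  if (inherits(labels, "edge_communities")) {
    if (is.null(k)) k <- labels$k
    labels <- labels$labels
  }
  labels <- as.integer(labels)
  if (is.null(k)) k <- max(labels)
  if (any(labels < 1L | labels > k))
    stop("labels outside 1..k")
  n_regions <- stop_if_not_count(n_regions, "n_regions", 2L)
  pairs <- edge_index(n_regions)
  if (nrow(pairs) != length(labels))
    stop("label vector does not cover the upper triangle for n_regions")
  P <- matrix(0, n_regions, k)
  for (e in seq_along(labels)) {
    s <- labels[e]
    P[pairs[e, 1L], s] <- P[pairs[e, 1L], s] + 1
    P[pairs[e, 2L], s] <- P[pairs[e, 2L], s] + 1
  }
  P / (n_regions - 1L)
}

#' Normalized nodal entropy of community profiles
#'
#' Shannon entropy of each region's community participation profile,
#' normalized by `log2(k)` so that values lie in \[0, 1\]:
#' \deqn{E_u = -\sum_s P_{us} \log_2 P_{us} / \log_2 k,}
#' with \eqn{0 \log 0 = 0}. A region whose incident edges all share one
#' community scores 0 (functionally integrated); a region spread evenly
#' over all k communities scores 1 (maximal overlap).
#'
#' @param profile `N x k` matrix of community frequencies (rows sum to 1).
#' @param k Normalization community count (defaults to `ncol(profile)`).
#' @return Numeric vector of length N with values in \[0, 1\].
#' @export
nodal_entropy <- function(profile, k = ncol(profile)) {
  profile <- as.matrix(profile)
  apply(profile, 1, normalized_entropy, k = k)
}

#' Global and subnetwork entropy
#'
#' Global entropy is the mean nodal entropy over all regions; each
#' subnetwork entropy is the mean over that subnetwork's member regions.
#'
#' @param entropy Numeric vector of nodal entropies.
#' @param subnetworks Factor (or character) assigning each region to one of
#'   the 7 canonical subnetworks.
#' @return Named numeric vector: `global` followed by the 7 subnetworks.
#' @export
aggregate_entropy <- function(entropy, subnetworks) {
  if (length(entropy) != length(subnetworks))
    stop("entropy and subnetwork assignment differ in length")
  subnetworks <- factor(subnetworks, levels = SUBNETWORK_LEVELS)
  if (anyNA(subnetworks)) stop("unknown subnetwork label")
  counts <- table(subnetworks)
  if (any(counts == 0))
    stop(sprintf("empty subnetwork(s): %s",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  means <- tapply(entropy, subnetworks, mean)
  c(global = mean(entropy), means)
}

#' Fit the edge-centric entropy model to one subject
#'
#' The full per-subject pipeline: z-score the regional BOLD signals,
#' compute the edge time series (pairwise instantaneous co-fluctuations),
#' cluster edges into k communities by restarted K-means, build each
#' region's community participation profile and its normalized nodal
#' entropy, and aggregate to global and subnetwork entropy.
#'
#' @param ts Region-by-time numeric matrix (rows = regions).
#' @param k Number of edge communities (default 10).
#' @param n_restarts K-means restarts (default 25).
#' @param seed Integer seed for the clustering restarts.
#' @param subnetworks Optional region-to-subnetwork assignment; when
#'   supplied the result includes global and subnetwork entropy.
#' @param communities Optional precomputed `edge_communities` object (used
#'   by group-level clustering); skips the K-means step.
#' @return Object of class `edge_entropy` with elements `entropy` (per
#'   region), `profile`, `communities`, `k`, `aggregate` (if subnetworks
#'   given), `region_ids`, `subject_id`.
#' @examples
#' x <- matrix(rnorm(20 * 60), 20, 60)
#' fit <- edge_entropy(x, k = 4, n_restarts = 5, seed = 1)
#' summary(fit)
#' @export
edge_entropy <- function(ts, k = 10L, n_restarts = 25L, seed = 1L,
                         subnetworks = NULL, communities = NULL) {
  ts <- as.matrix(ts)
  z <- zscore_timeseries(ts)
  ets <- compute_edge_time_series(z)
  if (is.null(communities))
    communities <- cluster_edges(ets, k = k, n_restarts = n_restarts,
                                 seed = seed)
  profile <- community_profile(communities, n_regions = nrow(ts))
  entropy <- nodal_entropy(profile, k = communities$k)
  names(entropy) <- rownames(ts)
  agg <- if (!is.null(subnetworks)) aggregate_entropy(entropy, subnetworks)
  structure(list(entropy = entropy, profile = profile,
                 communities = communities, k = communities$k,
                 aggregate = agg, region_ids = rownames(ts),
                 subject_id = attr(ts, "subject_id")),
            class = "edge_entropy")
}

#' @export
print.edge_entropy <- function(x, ...) {
  cat(sprintf("Edge-centric entropy fit: %d regions, %d edge communities\n",
              length(x$entropy), x$k))
  cat(sprintf("  K-means SSE %.4g (restart %d of %d)\n", x$communities$sse,
              x$communities$selected_restart,
              length(x$communities$restart_sse)))
  cat(sprintf("  nodal entropy: min %.3f, median %.3f, max %.3f\n",
              min(x$entropy), stats::median(x$entropy), max(x$entropy)))
  if (!is.null(x$aggregate)) {
    cat("  global/subnetwork entropy:\n")
    print(round(x$aggregate, 4))
  }
  invisible(x)
}

#' @export
summary.edge_entropy <- function(object, ...) {
  out <- list(n_regions = length(object$entropy), k = object$k,
              entropy_summary = summary(object$entropy),
              community_sizes = tabulate(object$communities$labels,
                                         object$k),
              sse = object$communities$sse)
  class(out) <- "summary.edge_entropy"
  out
}

#' @export
print.summary.edge_entropy <- function(x, ...) {
  cat(sprintf("Edge-centric entropy fit (%d regions, k = %d)\n",
              x$n_regions, x$k))
  cat("Nodal entropy:\n"); print(x$entropy_summary)
  cat("Edges per community:\n"); print(x$community_sizes)
  cat(sprintf("Within-community SSE: %.4g\n", x$sse))
  invisible(x)
}

#' @export
coef.edge_entropy <- function(object, ...) object$entropy

#' @export
plot.edge_entropy <- function(x, ...) {
  graphics::barplot(sort(x$entropy), las = 2, cex.names = 0.5,
                    ylab = "normalized nodal entropy",
                    main = "Nodal entropy by region", ...)
  invisible(x)
}

#' Residualize features on covariates
#'
#' Ordinary least squares of each feature column on an intercept plus the
#' covariates, across subjects; returns residuals with the fitted intercept
#' added back (so feature means are preserved when covariates carry no
#' signal). Residuals are orthogonal to every covariate.
#'
#' @param features Subjects-by-features numeric matrix.
#' @param covariates Subjects-by-p data frame or matrix (factors allowed).
#' @return Matrix of the same shape as `features`.
#' @export
residualize_covariates <- function(features, covariates) {
  features <- as.matrix(features)
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(mm) != nrow(features))
    stop("features and covariates differ in subject count")
  if (nrow(mm) < ncol(mm) + 2L)
    stop("need at least p + 2 subjects to residualize p covariates")
  # center the covariate columns so the fitted intercept is the feature mean
  mm[, -1L] <- sweep(mm[, -1L, drop = FALSE], 2L,
                     colMeans(mm[, -1L, drop = FALSE]))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    keep <- qr_mm$pivot[seq_len(qr_mm$rank)]
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)), keep)]
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(mm, features)
  res <- as.matrix(fit$residuals)
  intercepts <- fit$coefficients["(Intercept)", ]
  out <- sweep(res, 2L, -intercepts)
  dimnames(out) <- dimnames(features)
  out
}
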