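# Standardize gene columns; error on constant genes, naming them.
standardize_expression <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds < 1e-12)
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(sprintf("constant expression column(s): %s",
                 paste(utils::head(nm, 5), collapse = ", ")))
  }
  sweep(sweep(X, 2, mu), 2, sds, "/")
}

# Explained response variance of the first PLS component, given a
# pre-standardized predictor matrix.  Used heavily by the permutation test.
pls1_explained_variance <- function(Xs, y) {
  yc <- y - mean(y)
  w <- crossprod(Xs, yc)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-14) return(0)
  t1 <- Xs %*% (w / nw)
  stats::cor(t1, yc)[1]^2
}

#' Partial least squares regression of expression on a brain map
#'
#' NIPALS PLS with X and y deflation, univariate response. Gene columns are
#' standardized internally (center, unit variance) and the response is
#' centered. The first component (PLS1) is oriented so that its region
#' scores correlate non-negatively with the response; weights and scores
#' are flipped together, so the fit is unchanged. For the study design the
#' predictors are regional gene expression and the response is the
#' MDDSI-minus-MDDNSI nodal entropy t map.
#'
#' Extraction stops early if the residual cross-covariance vanishes (e.g. a
#' noise-free response); remaining components then explain zero variance.
#'
#' @param X Region-by-gene matrix (gene ids as column names).
#' @param y Numeric response per region, or a `tstat_map`.
#' @param n_components Number of components to extract (default 15).
#' @return Object of class `ecn_pls`: `scores` (regions x components),
#'   `weights` (genes x components), `loadings`, `q` (response loadings),
#'   `explained_variance` (fraction of response variance per component),
#'   `explained_cov` (per-component squared covariance, normalized to sum
#'   to 1 over extracted components), `n_components`,
#'   `n_extracted`, `gene_ids`, `y`.
#' @export
fit_pls <- function(X, y, n_components = 15L) {
  if (inherits(y, "tstat_map")) y <- y$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y disagree on region count")
  n_components <- stop_if_not_count(n_components, "n_components")
  if (nrow(X) < n_components + 2L)
    stop("need at least n_components + 2 regions")
  gene_ids <- colnames(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(X)))
  Xs <- standardize_expression(X)
  yc <- y - mean(y)
  ss_y <- sum(yc^2)
  if (ss_y == 0) stop("constant response map")

  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  evar <- numeric(n_components)
  ecov <- numeric(n_components)
  Xa <- Xs; ya <- yc
  extracted <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(p)) break
    w <- w / nw
    t_a <- as.numeric(Xa %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-20) break
    p_a <- as.numeric(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    evar[a] <- q_a^2 * tt / ss_y
    ecov[a] <- (sum(t_a * yc))^2
    extracted <- a
  }
  if (extracted && sum(ecov) > 0) ecov <- ecov / sum(ecov)
  # orient PLS1 so its scores correlate non-negatively with the response
  if (extracted && stats::cor(Tm[, 1L], yc) < 0) {
    W[, 1L] <- -W[, 1L]; Tm[, 1L] <- -Tm[, 1L]
    P[, 1L] <- -P[, 1L]; q[1L] <- -q[1L]
  }
  rownames(W) <- rownames(P) <- gene_ids
  structure(list(scores = Tm, weights = W, loadings = P, q = q,
                 explained_variance = evar, explained_cov = ecov,
                 n_components = n_components, n_extracted = extracted,
                 gene_ids = gene_ids, y = y),
            class = "ecn_pls")
}

#' @export
print.ecn_pls <- function(x, ...) {
  cat(sprintf("PLS regression: %d regions, %d genes, %d/%d components extracted\n",
              length(x$y), length(x$gene_ids), x$n_extracted,
              x$n_components))
  cat(sprintf("  PLS1 explains %.1f%% of response variance (%.1f%% of captured covariance)\n",
              100 * x$explained_variance[1L], 100 * x$explained_cov[1L]))
  cat(sprintf("  PLS1 score vs response correlation: %.3f\n",
              stats::cor(x$scores[, 1L], x$y)))
  invisible(x)
}

#' Empirical variogram of a brain map
#'
#' Mean of half squared differences, binned by inter-region distance using
#' equal-count bins restricted to the shorter half of all distances (the
#' range that carries the spatial autocorrelation signal).
#'
#' @param y Numeric map.
#' @param distance Symmetric distance matrix with zero diagonal.
#' @param n_bins Number of distance bins.
#' @return Data frame with `h` (bin center) and `gamma`.
#' @export
empirical_variogram <- function(y, distance, n_bins = 15L) {
  d <- distance[upper.tri(distance)]
  g <- 0.5 * (outer(y, y, "-")^2)[upper.tri(distance)]
  keep <- d <= stats::quantile(d, 0.6)
  d <- d[keep]; g <- g[keep]
  br <- stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1L))
  br[1L] <- -Inf
  bin <- cut(d, unique(br), labels = FALSE)
  data.frame(h = tapply(d, bin, mean), gamma = tapply(g, bin, mean))
}

#' Variogram-matched surrogate brain maps
#'
#' Generates randomized maps that preserve the spatial autocorrelation of
#' the input: each surrogate starts from a random permutation of the map,
#' is smoothed with an exponential distance kernel at several candidate
#' length scales, and the scale plus smooth/noise mixture best reproducing
#' the empirical variogram of the original map (non-negative least squares
#' on binned variograms) is kept. Used as the spatial null for the PLS
#' permutation test.
#'
#' @param y Numeric map.
#' @param distance Symmetric distance matrix, zero diagonal.
#' @param n_surrogates Number of surrogate maps.
#' @param seed Integer seed.
#' @param n_bins Variogram bins.
#' @param scales Candidate kernel length scales (defaults to distance
#'   quantiles).
#' @return List with `surrogates` (`n_surrogates x N` matrix), `fit_sse`
#'   (per surrogate, variogram sum of squared errors of the realized map
#'   against the original's variogram, normalized by the squared mean
#'   variogram level) and `tolerance` (their maximum — the fitting
#'   tolerance the generator achieved).
#' @export
variogram_surrogates <- function(y, distance, n_surrogates = 100L,
                                 seed = 1L, n_bins = 15L, scales = NULL) {
  check_distance(distance, length(y))
  set.seed(as.integer(seed))
  pos <- distance[upper.tri(distance)]
  if (is.null(scales))
    scales <- stats::quantile(pos, c(0.05, 0.1, 0.2, 0.35, 0.5))
  vg_obs <- empirical_variogram(y, distance, n_bins)
  denom <- mean(vg_obs$gamma)^2
  kernels <- lapply(scales, function(s) {
    K <- exp(-distance / s)
    K / rowSums(K)
  })
  n <- length(y)
  out <- matrix(0, n_surrogates, n)
  sse <- numeric(n_surrogates)
  for (i in seq_len(n_surrogates)) {
    yp <- sample(y)
    best <- NULL
    for (K in kernels) {
      ys <- as.numeric(K %*% yp)
      ys <- (ys - mean(ys)) / stats::sd(ys) * stats::sd(y)
      vg_s <- empirical_variogram(ys, distance, n_bins)
      # gamma_obs ~ beta * gamma_smooth + alpha (white-noise nugget)
      fit <- stats::lm.fit(cbind(1, vg_s$gamma), vg_obs$gamma)
      alpha <- max(0, fit$coefficients[1L])
      beta <- max(0, fit$coefficients[2L])
      err <- sum((alpha + beta * vg_s$gamma - vg_obs$gamma)^2)
      if (is.null(best) || err < best$err)
        best <- list(ys = ys, alpha = alpha, beta = beta, err = err)
    }
    surr <- sqrt(best$beta) * (best$ys - mean(best$ys)) +
      sqrt(best$alpha) * stats::rnorm(n) + mean(y)
    out[i, ] <- surr
    vg_r <- empirical_variogram(surr, distance, n_bins)
    sse[i] <- sum((vg_r$gamma - vg_obs$gamma)^2) / denom
  }
  list(surrogates = out, fit_sse = sse, tolerance = max(sse))
}

check_distance <- function(distance, n) {
  distance <- as.matrix(distance)
  if (nrow(distance) != n || ncol(distance) != n)
    stop("distance matrix shape does not match the map")
  if (any(abs(diag(distance)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  if (max(abs(distance - t(distance))) > 1e-8)
    stop("distance matrix must be symmetric")
  invisible(distance)
}

#' Permutation test for the first PLS component
#'
#' Tests whether PLS1's explained response variance exceeds what spatially
#' structured noise produces. When a distance matrix is supplied the null
#' maps are variogram-matched surrogates of the response (preserving its
#' spatial autocorrelation); otherwise plain permutations of the response
#' are used. The p value is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param X Region-by-gene matrix.
#' @param y Response map (or `tstat_map`).
#' @param n_perm Number of null maps (default 1000).
#' @param distance Optional symmetric distance matrix with zero diagonal.
#' @param seed Integer seed.
#' @return List with `p`, `observed` (PLS1 explained response variance),
#'   `null` (vector of null statistics), `method`, and `surrogate_fit`
#'   (variogram fit record, spatial method only).
#' @export
permutation_test_pls <- function(X, y, n_perm = 1000L, distance = NULL,
                                 seed = 1L) {
  if (inherits(y, "tstat_map")) y <- y$values
  y <- as.numeric(y)
  Xs <- standardize_expression(X)
  observed <- pls1_explained_variance(Xs, y)
  surrogate_fit <- NULL
  if (is.null(distance)) {
    set.seed(as.integer(seed))
    null_stats <- vapply(seq_len(n_perm), function(i)
      pls1_explained_variance(Xs, sample(y)), numeric(1))
    method <- "permutation"
  } else {
    sg <- variogram_surrogates(y, distance, n_surrogates = n_perm,
                               seed = seed)
    null_stats <- vapply(seq_len(n_perm), function(i)
      pls1_explained_variance(Xs, sg$surrogates[i, ]), numeric(1))
    surrogate_fit <- sg[c("fit_sse", "tolerance")]
    method <- "variogram-matched surrogates"
  }
  list(p = (1 + sum(null_stats >= observed)) / (1 + n_perm),
       observed = observed, null = null_stats, method = method,
       surrogate_fit = surrogate_fit)
}

#' Bootstrap Z scores for PLS1 gene weights
#'
#' Resamples regions with replacement, refits the first PLS component,
#' aligns each bootstrap weight vector's sign to the original (sign of
#' their inner product) and returns `Z = original weight / bootstrap
#' standard deviation` per gene — the corrected weight used to rank genes.
#'
#' @param X Region-by-gene matrix.
#' @param y Response map (or `tstat_map`).
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return List with `z` (named per gene), `weights` (original PLS1
#'   weights), `boot_sd`, `n_degenerate` (resamples discarded and redrawn
#'   because they were constant in the response or a gene).
#' @export
bootstrap_gene_weights <- function(X, y, n_boot = 1000L, seed = 1L) {
  if (inherits(y, "tstat_map")) y <- y$values
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 regions for the bootstrap")
  fit <- fit_pls(X, y, n_components = 1L)
  w0 <- fit$weights[, 1L]
  set.seed(as.integer(seed))
  boot_w <- matrix(0, length(w0), n_boot)
  n_degenerate <- 0L
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    Xb <- X[idx, , drop = FALSE]
    sds <- apply(Xb, 2, stats::sd)
    if (stats::sd(yb) < 1e-12 || any(sds < 1e-12)) {
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 10L * n_boot)
        stop("bootstrap resamples persistently degenerate")
      next
    }
    Xbs <- sweep(sweep(Xb, 2, colMeans(Xb)), 2, sds, "/")
    w <- crossprod(Xbs, yb - mean(yb))
    w <- w / sqrt(sum(w^2))
    if (sum(w * w0) < 0) w <- -w
    boot_w[, b] <- w
    b <- b + 1L
  }
  sd_b <- apply(boot_w, 1, stats::sd)
  z <- ifelse(sd_b > 0, w0 / sd_b, 0)
  names(z) <- names(w0)
  list(z = z, weights = w0, boot_sd = sd_b, n_degenerate = n_degenerate)
}

#' Split genes into PLS1+ and PLS1- sets by bootstrap Z
#'
#' Two-sided normal p values from the bootstrap Z scores, BH-FDR at
#' `alpha`; significant genes are split by Z sign into the positively and
#' negatively weighted sets, each ranked by |Z|.
#'
#' @param z Named numeric vector of bootstrap Z scores.
#' @param alpha FDR level (default 0.05).
#' @return List with `pls1_pos`, `pls1_neg` (character vectors, ranked by
#'   |Z|) and `table` (gene, z, p_raw, p_fdr, set).
#' @export
select_gene_sets <- function(z, alpha = 0.05) {
  if (any(!is.finite(z))) stop("Z scores must be finite")
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_fdr <- bh_fdr(p_raw)
  nm <- names(z)
  if (is.null(nm)) nm <- paste0("g", seq_along(z))
  set <- ifelse(p_fdr < alpha & z > 0, "PLS1+",
                ifelse(p_fdr < alpha & z < 0, "PLS1-", "ns"))
  tab <- data.frame(gene = nm, z = z, p_raw = p_raw, p_fdr = p_fdr,
                    set = set, stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$z)), ]
  rownames(tab) <- NULL
  list(pls1_pos = tab$gene[tab$set == "PLS1+"],
       pls1_neg = tab$gene[tab$set == "PLS1-"],
       table = tab)
}
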