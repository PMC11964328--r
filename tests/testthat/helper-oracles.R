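# Independent brute-force oracles used across the suite.  These are written
# from the definitions and must stay independent of the package internals.

# Step-up FDR adjustment computed literally from the definition.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Exact two-sided Mann-Whitney p by full enumeration of the U statistic's
# null distribution over all assignments of ranks (tie-free data).
bf_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  all_u <- apply(utils::combn(na + nb, na), 2, function(idx) {
    sum(seq_len(na + nb)[idx]) - na * (na + 1) / 2
  })
  mu <- na * nb / 2
  min(1, mean(abs(all_u - mu) >= abs(u_obs - mu)))
}

# Kruskal-Wallis H from the rank formula with tie correction.
bf_kw_h <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Normalized Shannon entropy of a probability vector.
bf_entropy <- function(p, k) {
  p <- p[p > 0]
  if (k < 2) return(0)
  -sum(p * log2(p)) / log2(k)
}

# Two well-separated co-fluctuation patterns with additive noise: an edge
# time-series matrix with a planted two-community structure.
make_two_pattern_ets <- function(n_per = 30, n_time = 80, sep = 4,
                                 noise = 1, seed = 1) {
  set.seed(seed)
  p1 <- c(rep(sep, n_time / 2), rep(0, n_time / 2))
  p2 <- c(rep(0, n_time / 2), rep(sep, n_time / 2))
  values <- rbind(
    matrix(rep(p1, each = n_per), n_per) +
      matrix(rnorm(n_per * n_time, sd = noise), n_per),
    matrix(rep(p2, each = n_per), n_per) +
      matrix(rnorm(n_per * n_time, sd = noise), n_per))
  list(values = values, truth = rep(1:2, each = n_per))
}

# Reduced-scale synthetic configuration used where the full study scale is
# unnecessary.
small_cfg <- function(seed = 1, n_regions = 30, n_time = 200,
                      group_sizes = c(6, 6, 6), ...) {
  synth_config(n_regions = n_regions, n_time = n_time,
               group_sizes = group_sizes, seed = seed, ...)
}

# Hand-built entropy table with known group structure, for exercising the
# staged statistics without the expensive clustering step.
make_entropy_table <- function(n_per_group = 12, n_regions = 21,
                               effect = 0, target = "dorsal.attention",
                               seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_group
  group <- factor(rep(c("HC", "MDDNSI", "MDDSI"), each = n_per_group),
                  levels = c("HC", "MDDNSI", "MDDSI"))
  subnets <- synthetic_subnetworks(n_regions)
  nodal <- matrix(runif(n * n_regions, 0.3, 0.7), n, n_regions)
  subnet_cols <- make.names(subnetwork_levels())
  target_regions <- which(subnet_cols[as.integer(subnets)] == target)
  nodal[group == "MDDSI", target_regions] <-
    nodal[group == "MDDSI", target_regions] + effect
  colnames(nodal) <- sprintf("R%03d", seq_len(n_regions))
  agg <- t(apply(nodal, 1, aggregate_entropy, subnetworks = subnets))
  colnames(agg) <- c("global", subnet_cols)
  nodal_cols <- paste0("nodal_", colnames(nodal))
  colnames(nodal) <- nodal_cols
  df <- data.frame(subject_id = sprintf("S%03d", 1:n), group = group,
                   cognitive_score = rnorm(n, 40, 8))
  out <- cbind(df, as.data.frame(agg), as.data.frame(nodal))
  structure(out, class = c("entropy_table", "data.frame"),
            subnetworks = subnets, k = 10L,
            nodal_columns = nodal_cols, subnetwork_columns = subnet_cols,
            covariate_mode = "off")
}

# Standardized orthogonal design: columns are exactly mean-zero,
# unit-variance and mutually orthogonal, so the cross-covariance with any
# single column is concentrated on that column alone.
orthogonal_expression <- function(n_regions = 50, n_genes = 20, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_regions * n_genes), n_regions)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))
  X <- sweep(Q, 2, apply(Q, 2, sd), "/")
  X <- sweep(X, 2, colMeans(X))       # re-center (numerically tiny shift)
  colnames(X) <- sprintf("g%04d", seq_len(n_genes))
  X
}
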