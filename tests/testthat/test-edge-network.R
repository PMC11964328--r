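test_that("z-scoring uses the population convention", {
  expect_equal(zscore_timeseries(matrix(c(1, -1), 1)), matrix(c(1, -1), 1))
  z <- zscore_timeseries(matrix(c(0, 1, 2), 1))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  m <- matrix(c(5, 5, 5, 1, 2, 3), 2, byrow = TRUE,
              dimnames = list(c("R1", "R2"), NULL))
  expect_error(zscore_timeseries(m), "R1")
})

test_that("edge time series are pairwise products in row-major order", {
  z <- rbind(c(-1, 1), c(1, -1))
  ets <- compute_edge_time_series(z)
  expect_equal(as.numeric(ets$values), c(-1, -1))
  expect_equal(mean(ets$values[1, ]), cor(z[1, ], z[2, ]))
  z2 <- zscore_timeseries(matrix(rnorm(8), 2))
  e2 <- compute_edge_time_series(rbind(z2[1, ], z2[1, ]))
  expect_equal(as.numeric(e2$values), z2[1, ]^2)
  expect_identical(nrow(edge_index(200)), 19900L)
  expect_identical(edge_index(4)[1:3, "n"], c(2L, 3L, 4L))
})

test_that("time-mean of every edge series equals the Pearson correlation", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(20 * 100), 20)
    ets <- compute_edge_time_series(zscore_timeseries(x))
    r <- cor(t(x))
    expect_lt(max(abs(rowMeans(ets$values) -
                        r[ets$edge_index])), 1e-10)
  }
})

test_that("cluster_edges selects the minimum-SSE restart", {
  ets <- make_two_pattern_ets(n_per = 20, seed = 3)
  cl <- cluster_edges(ets$values, k = 4, n_restarts = 10, seed = 2)
  expect_length(cl$restart_sse, 10)
  expect_equal(cl$sse, min(cl$restart_sse))
  expect_identical(cl$selected_restart,
                   which(cl$restart_sse == min(cl$restart_sse))[1])
  expect_true(all(cl$labels %in% 1:4))
})

test_that("k = 1 clustering returns the total sum of squares", {
  x <- matrix(rnorm(30), 6, 5)
  cl <- cluster_edges(x, k = 1)
  expect_identical(cl$labels, rep(1L, 6))
  expect_equal(cl$sse, sum(scale(x, scale = FALSE)^2))
  expect_error(cluster_edges(x, k = 10), "exceeds")
})

test_that("planted two-pattern edges are recovered exactly", {
  ets <- make_two_pattern_ets(n_per = 30, sep = 4, seed = 5)
  cl <- cluster_edges(ets$values, k = 2, n_restarts = 5, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels, ets$truth), 1)
})

test_that("community profiles count incident edge labels", {
  # 4 regions, edges (1,2)(1,3)(1,4)(2,3)(2,4)(3,4) labeled A A B A B B
  labels <- c(1L, 1L, 2L, 1L, 2L, 2L)
  P <- community_profile(labels, n_regions = 4, k = 2)
  expect_equal(P[1, ], c(2 / 3, 1 / 3))
  expect_equal(P[4, ], c(0, 1))
  expect_equal(rowSums(P), rep(1, 4))
  P1 <- community_profile(rep(1L, 6), n_regions = 4, k = 1)
  expect_true(all(P1 == 1))
  expect_error(community_profile(labels[-1], 4, 2), "upper triangle")
  expect_error(community_profile(c(labels[-1], 5L), 4, 2), "1..k")
})

test_that("nodal entropy matches closed forms and stays in [0,1]", {
  expect_equal(nodal_entropy(matrix(c(1, 0, 0), 1), k = 3), 0)
  expect_equal(nodal_entropy(matrix(rep(0.1, 10), 1), k = 10), 1)
  p <- matrix(c(2 / 3, 1 / 3, rep(0, 8)), 1)
  expect_lt(abs(nodal_entropy(p, k = 10) - 0.27643), 1e-5)
  expect_error(nodal_entropy(matrix(c(0.5, 0.1), 1), 2), "sum to 1")
  set.seed(1)
  P <- community_profile(sample(1:6, choose(12, 2), replace = TRUE), 12, 6)
  e <- nodal_entropy(P)
  expect_true(all(e >= 0 & e <= 1))
})

test_that("community relabeling permutes profiles and preserves entropy", {
  set.seed(2)
  labels <- sample(1:5, choose(10, 2), replace = TRUE)
  perm <- sample(5)
  P1 <- community_profile(labels, 10, 5)
  P2 <- community_profile(perm[labels], 10, 5)
  expect_equal(P2[, perm], P1)
  expect_equal(nodal_entropy(P1), nodal_entropy(P2))
})

test_that("aggregation means are exact and errors name empty subnetworks", {
  subnets <- synthetic_subnetworks(14)
  agg <- aggregate_entropy(rep(0.5, 14), subnets)
  expect_equal(unname(agg), rep(0.5, 8))
  two <- factor(c("visual", "visual"), levels = subnetwork_levels())
  expect_error(aggregate_entropy(c(0, 1), two), "somatomotor")
  set.seed(3)
  e <- runif(14)
  agg <- aggregate_entropy(e, subnets)
  w <- table(subnets) / 14
  expect_equal(unname(agg["global"]), sum(agg[-1] * w))
})

test_that("residualization is an exact OLS projection", {
  set.seed(4)
  n <- 40
  cov <- data.frame(sex = factor(sample(c("F", "M"), n, TRUE)),
                    age = rnorm(n, 24, 4), education = rnorm(n, 14, 2))
  f_indep <- rnorm(n)
  f_dep <- 2 * cov$age
  res <- residualize_covariates(cbind(a = f_indep, b = f_dep), cov)
  # exact fit: residual component orthogonal to age, constant up to fp noise
  expect_lt(sd(res[, "b"]), 1e-10)
  expect_lt(abs(sum((res[, "b"] - mean(res[, "b"])) *
                      (cov$age - mean(cov$age)))), 1e-8)
  expect_lt(max(abs(crossprod(res - rep(colMeans(res), each = n),
                              cov$age))), 1e-6)
  # feature means preserved via the returned intercept
  expect_equal(mean(res[, "a"]), mean(f_indep), tolerance = 1e-8)
  expect_error(residualize_covariates(cbind(f_indep),
                                      data.frame(c1 = rep(1, n))),
               "collinear")
})

test_that("edge_entropy composes the pipeline end to end", {
  cfg <- small_cfg(seed = 6, n_regions = 20, n_time = 120)
  sim <- simulate_bold(cfg, subject_seed = 2)
  fit <- edge_entropy(sim$ts, k = 5, n_restarts = 4, seed = 9,
                      subnetworks = synthetic_subnetworks(20))
  expect_s3_class(fit, "edge_entropy")
  expect_length(fit$entropy, 20)
  expect_true(all(fit$entropy >= 0 & fit$entropy <= 1))
  expect_named(fit$aggregate,
               c("global", subnetwork_levels()), ignore.order = FALSE)
  expect_equal(unname(fit$aggregate["global"]), mean(fit$entropy))
  expect_identical(fit$entropy,
                   edge_entropy(sim$ts, k = 5, n_restarts = 4,
                                seed = 9)$entropy)
  expect_output(print(fit), "edge communities")
  expect_output(print(summary(fit)), "Within-community SSE")
})

test_that("cohort_entropy assembles subject rows with exact aggregates", {
  cfg <- small_cfg(seed = 8, n_regions = 21, n_time = 80,
                   group_sizes = c(3, 3, 3))
  cohort <- simulate_cohort(cfg)
  tab <- cohort_entropy(cohort, k = 4, n_restarts = 3, seed = 1,
                        covariate_mode = "off")
  expect_s3_class(tab, "entropy_table")
  expect_identical(nrow(tab), 9L)
  nodal <- entropy_features(tab, "nodal")
  subnets <- attr(tab, "subnetworks")
  expect_equal(tab$global, unname(rowMeans(nodal)), tolerance = 1e-12)
  agg <- t(apply(nodal, 1, aggregate_entropy, subnetworks = subnets))
  expect_equal(unname(as.matrix(tab[attr(tab, "subnetwork_columns")])),
               unname(agg[, -1]), tolerance = 1e-12)
  # covariate residualization leaves features orthogonal to age
  tab2 <- cohort_entropy(cohort, k = 4, n_restarts = 3, seed = 1,
                         covariate_mode = "features")
  expect_lt(abs(cor(tab2$global, cohort$manifest$age)), 1e-8)
})

test_that("group clustering scope yields subject-specific labels", {
  cfg <- small_cfg(seed = 12, n_regions = 15, n_time = 60,
                   group_sizes = c(2, 2, 2))
  cohort <- simulate_cohort(cfg)
  tab <- cohort_entropy(cohort, k = 3, n_restarts = 3, seed = 2,
                        scope = "group", covariate_mode = "off")
  nodal <- entropy_features(tab, "nodal")
  expect_gt(sd(nodal[, 1]), 0)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
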