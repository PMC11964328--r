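test_that("PLS1 weights are collinear with the cross-covariance direction", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(40 * 60), 40)
    y <- rnorm(40)
    fit <- fit_pls(X, y, n_components = 3)
    Xs <- scale(X)
    w_ref <- crossprod(Xs, y - mean(y))
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    cosine <- abs(sum(fit$weights[, 1] * w_ref))
    expect_gt(cosine, 0.999)
  }
})

test_that("a perfect single predictor saturates component 1", {
  X <- orthogonal_expression(50, 20, seed = 2)
  y <- X[, 7]
  fit <- fit_pls(X, y, n_components = 15)
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-8)
  expect_identical(unname(which.max(abs(fit$weights[, 1]))), 7L)
  expect_lte(fit$n_extracted, 2)  # residual response vanishes
})

test_that("the PLS1 orientation rule fixes the reporting sign", {
  set.seed(3)
  X <- matrix(rnorm(30 * 15), 30)
  y <- rnorm(30)
  f1 <- fit_pls(X, y, 4); f2 <- fit_pls(X, -y, 4)
  expect_gte(cor(f1$scores[, 1], y), 0)
  expect_gte(cor(f2$scores[, 1], -y), 0)
  expect_equal(f1$weights[, 1], -f2$weights[, 1], tolerance = 1e-10)
  expect_equal(f1$explained_variance, f2$explained_variance,
               tolerance = 1e-10)
  expect_error(fit_pls(cbind(X, 0), y, 4), "constant")
  expect_error(fit_pls(X, y, 40), "n_components")
})

test_that("permutation p attains its lower bound for a strong signal", {
  set.seed(4)
  X <- matrix(rnorm(40 * 30), 40)
  y <- X[, 1] + 0.05 * rnorm(40)
  pt <- permutation_test_pls(X, y, n_perm = 99, seed = 1)
  expect_equal(pt$p, 1 / 100)
  expect_length(pt$null, 99)
  # the observed statistic is invariant under region relabeling
  perm <- sample(40)
  pt2 <- permutation_test_pls(X[perm, ], y[perm], n_perm = 9, seed = 1)
  expect_equal(pt2$observed, pt$observed, tolerance = 1e-12)
})

test_that("variogram surrogates preserve spatial structure", {
  ex <- simulate_expression(60, 30, integer(0), rnorm(60), seed = 7)
  y <- ex$expression[, 3]
  sg <- variogram_surrogates(y, ex$distance, n_surrogates = 30, seed = 1)
  expect_identical(dim(sg$surrogates), c(30L, 60L))
  expect_true(all(sg$fit_sse <= sg$tolerance))
  g0 <- empirical_variogram(y, ex$distance)$gamma
  set.seed(2)
  perm_sse <- vapply(1:30, function(i) {
    sum((empirical_variogram(sample(y), ex$distance)$gamma - g0)^2) /
      mean(g0)^2
  }, numeric(1))
  expect_lt(median(sg$fit_sse), median(perm_sse))
  expect_error(variogram_surrogates(y, ex$distance[-1, -1]), "shape")
  bad <- ex$distance; bad[1, 1] <- 1
  expect_error(variogram_surrogates(y, bad), "zero diagonal")
})

test_that("bootstrap Z flags planted signal genes", {
  target <- rnorm(50)
  ex <- simulate_expression(50, 120, 1:6, target, seed = 5)
  boot <- bootstrap_gene_weights(ex$expression, target, n_boot = 300,
                                 seed = 2)
  z <- abs(boot$z)
  expect_gt(min(z[1:6]), quantile(z[-(1:6)], 0.95))
  boot_neg <- bootstrap_gene_weights(ex$expression, -target, n_boot = 300,
                                     seed = 2)
  expect_equal(abs(boot_neg$z), z, tolerance = 1e-10)
  expect_identical(boot$n_degenerate, 0L)
  expect_error(bootstrap_gene_weights(ex$expression[1:5, ], target[1:5]),
               "10 regions")
})

test_that("gene set selection splits significant Z by sign", {
  z0 <- stats::setNames(rep(0, 20), paste0("g", 1:20))
  sel0 <- select_gene_sets(z0)
  expect_length(sel0$pls1_pos, 0)
  expect_length(sel0$pls1_neg, 0)
  z <- stats::setNames(c(rep(10, 5), rep(-10, 5), rep(0, 40)),
                       paste0("g", 1:50))
  sel <- select_gene_sets(z)
  expect_setequal(sel$pls1_pos, paste0("g", 1:5))
  expect_setequal(sel$pls1_neg, paste0("g", 6:10))
  set.seed(6)
  zr <- stats::setNames(rnorm(60, sd = 3), paste0("g", 1:60))
  sel2 <- select_gene_sets(zr, alpha = 0.05)
  p <- 2 * pnorm(-abs(zr))
  n_sig <- sum(bf_bh(p) < 0.05)
  expect_identical(length(sel2$pls1_pos) + length(sel2$pls1_neg), n_sig)
  expect_length(intersect(sel2$pls1_pos, sel2$pls1_neg), 0)
})
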