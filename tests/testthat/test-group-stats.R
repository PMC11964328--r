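test_that("Kruskal-Wallis matches the rank formula on worked examples", {
  g1 <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g1)
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$statistic, bf_kw_h(g1), tolerance = 1e-12)
  g2 <- list(c(1, 2), c(3, 4))
  expect_equal(kruskal_wallis(g2)$statistic, 2.4, tolerance = 1e-12)
  expect_equal(bf_kw_h(g2), 2.4, tolerance = 1e-12)
  tied <- kruskal_wallis(list(c(5, 5), c(5, 5)))
  expect_identical(c(tied$statistic, tied$p_raw), c(0, 1))
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Mann-Whitney U is exact for small tie-free samples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(unname(res$statistic), 0)
  expect_equal(res$p_raw, 1 / 3, tolerance = 1e-12)
  expect_true(res$exact)
  x <- c(1.2, 3.4, 2.2, 8)
  expect_equal(mann_whitney_u(x, x)$p_raw, 1, tolerance = 0.05)
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    ua <- mann_whitney_u(a, b)$statistic
    ub <- mann_whitney_u(b, a)$statistic
    expect_equal(unname(ua + ub), length(a) * length(b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    expect_equal(bh_fdr(p), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches closed forms", {
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, c(1, 3, 2))$r, 0.5)
  expect_error(pearson_correlation(x, c(1, 1, 1)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("t map uses pooled variance with the MDDSI-minus-MDDNSI sign", {
  a <- matrix(c(1, 2, 3), dimnames = list(NULL, "R001"))
  b <- matrix(c(4, 5, 6), dimnames = list(NULL, "R001"))
  tm <- two_sample_tmap(a, b)
  expect_equal(unname(tm$values), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(tm$df, 4L)
  expect_equal(two_sample_tmap(b, a)$values, -tm$values)
  ga <- rbind(c(1, 5), c(3, 7), c(2, 6))
  gb <- ga[c(2, 3, 1), ]
  expect_equal(unname(two_sample_tmap(ga, gb)$values), c(0, 0))
  expect_error(two_sample_tmap(matrix(1, 2, 1), matrix(1, 2, 1)),
               "pooled variance")
})

test_that("staged group analysis gates post-hoc tests on the FDR", {
  tab <- make_entropy_table(effect = 0.25, seed = 3)
  st <- run_group_analysis(tab, behavior_columns = "cognitive_score")
  expect_identical(nrow(st$kw), 8L)
  expect_true("dorsal.attention" %in% st$significant_measures)
  expect_true(all(st$posthoc$measure %in% st$significant_measures))
  expect_identical(sum(st$posthoc$measure == "dorsal.attention"), 3L)
  expect_true(all(st$posthoc$p_fdr >= st$posthoc$p_raw))
  expect_s3_class(st$tmap, "tstat_map")
  # the planted DAN shift is positive (higher entropy in MDDSI)
  dan <- attr(tab, "subnetworks") == "dorsal attention"
  expect_gt(mean(st$tmap$values[dan]), mean(st$tmap$values[!dan]))
  expect_output(print(st), "Kruskal-Wallis")
})

test_that("null tables rarely reach significance and errors are explicit", {
  tab <- make_entropy_table(effect = 0, seed = 4)
  st <- run_group_analysis(tab)
  expect_true(all(st$kw$p_fdr >= st$kw$p_raw))
  single <- make_entropy_table(seed = 5)
  single$group <- factor(rep("HC", nrow(single)),
                         levels = c("HC", "MDDNSI", "MDDSI"))
  expect_error(run_group_analysis(single), "2 groups")
})

test_that("behavior correlations are computed within patient groups", {
  tab <- make_entropy_table(effect = 0.3, seed = 6)
  # tie the score to the DAN entropy inside MDDSI only
  dan_col <- "dorsal.attention"
  mddsi <- tab$group == "MDDSI"
  tab$cognitive_score[mddsi] <- -3 * tab[[dan_col]][mddsi] +
    rnorm(sum(mddsi), sd = 1e-3)
  st <- run_group_analysis(tab, behavior_columns = "cognitive_score")
  cors <- st$correlations
  expect_true(!is.null(cors))
  r_si <- cors$r[cors$group == "MDDSI" & cors$measure == dan_col]
  expect_lt(r_si, -0.9)
})
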