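make_separable <- function(n_per = 20, p = 20, shift = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = shift), n_per))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = factor(rep(c("A", "B"), each = n_per)))
}

test_that("RFE keeps the contract and the informative feature", {
  d <- make_separable(seed = 2)
  sel <- rfe_select(d$X, d$y, n_features = ncol(d$X))
  expect_identical(sel$selected, seq_len(ncol(d$X)))
  sel5 <- rfe_select(d$X, d$y, n_features = 5)
  expect_length(sel5$selected, 5)
  expect_identical(sort(unique(sel5$ranks[-sel5$selected])),
                   2:(ncol(d$X) - 4))
  expect_error(rfe_select(d$X, factor(rep("A", 40)), 5), "2 classes")
  # one informative feature among pure noise survives elimination
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(80 * 20), 80)
    y <- factor(rep(c("A", "B"), each = 40))
    X[, 7] <- X[, 7] + ifelse(y == "B", 2.5, 0)
    hits <- hits + (7 %in% rfe_select(X, y, n_features = 5)$selected)
  }
  expect_gte(hits, 9)
})

test_that("cross-validated SVM is accurate on separable data", {
  d <- make_separable(n_per = 25, shift = 4, seed = 3)
  rep <- train_eval_svm_cv(d$X, d$y, n_features = 10, seed = 1)
  expect_gte(rep$average[["accuracy"]], 95)
  expect_equal(unname(rep$average),
               unname(colMeans(rep$fold_metrics, na.rm = TRUE)),
               tolerance = 1e-12)
  expect_true(all(lengths(rep$selected) == 10))
  expect_identical(sum(rep$confusion), 50L)
  expect_identical(rep, train_eval_svm_cv(d$X, d$y, n_features = 10,
                                          seed = 1))
  idx <- c(1:3, 26:28)
  expect_error(train_eval_svm_cv(d$X[idx, ], d$y[idx], n_folds = 5),
               "fold count")
})

test_that("held-out data cannot influence training-fold selection", {
  d <- make_separable(n_per = 25, shift = 1, seed = 4)
  rep1 <- train_eval_svm_cv(d$X, d$y, n_features = 8, seed = 5)
  X2 <- d$X
  test1 <- which(rep1$folds == 1)
  X2[test1, ] <- X2[test1, ] * 10 + 100  # corrupt fold 1's held-out rows
  rep2 <- train_eval_svm_cv(X2, d$y, n_features = 8, seed = 5)
  expect_identical(rep1$selected[[1]], rep2$selected[[1]])
  expect_identical(rep1$best_cost[1], rep2$best_cost[1])
})

test_that("feature frequency ranks by count with documented tie-breaks", {
  d <- make_separable(seed = 6)
  rep <- train_eval_svm_cv(d$X, d$y, n_features = 6, seed = 2)
  ff <- feature_frequency(rep, top_n = 10)
  expect_true(all(diff(ff$count) <= 0))
  always <- ff$index[ff$count == length(rep$selected)]
  if (length(always)) expect_identical(ff$index[1], always[1])
  # constructed tie: equal counts resolved by mean |weight|, then index
  fake <- structure(list(
    selected = list(c(1L, 2L), c(1L, 3L)),
    fold_weights = list(c(f1 = 0.1, f2 = 0.9), c(f1 = 0.1, f3 = 0.9)),
    feature_names = c("f1", "f2", "f3")), class = "ecn_classifier")
  ff2 <- feature_frequency(fake, top_n = 3)
  expect_identical(ff2$feature, c("f1", "f2", "f3"))
  expect_warning(feature_frequency(fake, top_n = 10), "fewer")
})
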