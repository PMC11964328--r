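# Primal weight vector of a linear SVM: w = t(coefs) %*% SV.
svm_linear_weights <- function(X, y, cost = 1, class_weights = NULL) {
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = class_weights)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  list(fit = fit, w = w)
}

#' Recursive feature elimination with a linear SVM
#'
#' Repeatedly fits a linear SVM and removes the feature with the smallest
#' squared weight, one per iteration, until `n_features` remain.
#'
#' @param X Subjects-by-features numeric matrix.
#' @param y Binary factor of class labels.
#' @param n_features Number of features to retain (default 60).
#' @param cost SVM cost parameter used during elimination.
#' @return List with `selected` (column indices, original order), `ranks`
#'   and `weights` (final SVM weights over the surviving set). Ranks follow
#'   the usual RFE convention: all survivors rank 1, the last eliminated
#'   feature rank 2, and so on.
#' @export
rfe_select <- function(X, y, n_features = 60L, cost = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("RFE needs exactly 2 classes present")
  n_features <- stop_if_not_count(n_features, "n_features")
  p <- ncol(X)
  if (n_features > p) stop("n_features exceeds the number of features")
  remaining <- seq_len(p)
  ranks <- integer(p)
  step <- p - n_features + 1L
  w <- NULL
  while (length(remaining) > n_features) {
    w <- svm_linear_weights(X[, remaining, drop = FALSE], y, cost)$w
    drop_local <- which.min(w^2)
    ranks[remaining[drop_local]] <- step
    step <- step - 1L
    remaining <- remaining[-drop_local]
  }
  ranks[remaining] <- 1L
  final_w <- svm_linear_weights(X[, remaining, drop = FALSE], y, cost)$w
  list(selected = remaining, ranks = ranks, weights = final_w)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin so folds are as balanced as the class sizes allow.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

classification_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  accuracy <- mean(truth == pred) * 100
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Cross-validated RFE + linear SVM classification
#'
#' Stratified k-fold cross-validation. Within each training fold: recursive
#' feature elimination down to `n_features`, then a grid search over the
#' SVM cost C by inner cross-validation on the training fold only, then a
#' final linear SVM fit. Metrics (accuracy, precision, recall, F1, in
#' percent; the second factor level is the positive class) are computed on
#' the held-out fold and averaged over folds. All feature selection and
#' tuning are confined to training folds — the held-out fold never
#' influences them.
#'
#' @param X Subjects-by-features matrix (e.g. nodal entropies).
#' @param y Binary factor (e.g. HC vs MDD, or MDDNSI vs MDDSI).
#' @param n_folds Number of outer folds (default 5).
#' @param c_grid Candidate SVM cost values.
#' @param n_features Features retained by RFE (default 60).
#' @param seed Integer seed driving fold assignment.
#' @param inner_folds Folds for the inner C grid search.
#' @param global_rfe If TRUE, run RFE once on the full data before
#'   cross-validation (leaks selection information; off by default, kept
#'   for comparison).
#' @param balanced If TRUE, apply inverse-frequency class weights.
#' @return Object of class `ecn_classifier`: `fold_metrics` (data frame),
#'   `average` (named vector), `selected` (list of per-fold feature index
#'   vectors), `fold_weights`, `best_cost`, `confusion`, `roc`,
#'   `positive_class`, `n_features`, `folds` (outer fold assignment).
#' @export
train_eval_svm_cv <- function(X, y, n_folds = 5L,
                              c_grid = c(0.01, 0.1, 1, 10, 100),
                              n_features = 60L, seed = 1L,
                              inner_folds = 3L, global_rfe = FALSE,
                              balanced = FALSE) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need exactly 2 classes")
  if (min(table(y)) < n_folds)
    stop("fold count exceeds the size of the smaller class")
  positive <- levels(y)[2L]
  cw <- if (balanced) {
    tab <- table(y); stats::setNames(as.numeric(sum(tab) / (2 * tab)),
                                     names(tab))
  }
  set.seed(as.integer(seed))
  folds <- stratified_folds(y, n_folds)
  global_sel <- if (global_rfe) rfe_select(X, y, n_features)$selected

  fold_metrics <- matrix(NA_real_, n_folds, 4L,
                         dimnames = list(NULL, c("accuracy", "precision",
                                                 "recall", "f1")))
  selected <- vector("list", n_folds)
  fold_weights <- vector("list", n_folds)
  best_cost <- numeric(n_folds)
  confusion <- matrix(0L, 2L, 2L, dimnames = list(truth = levels(y),
                                                  pred = levels(y)))
  roc <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    sel <- if (global_rfe) global_sel else
      rfe_select(Xtr, ytr, n_features)$selected
    selected[[f]] <- sel
    Xs <- Xtr[, sel, drop = FALSE]

    # inner grid search over C on the training fold only
    ninner <- max(2L, min(inner_folds, min(table(ytr))))
    inner <- stratified_folds(ytr, ninner)
    inner_acc <- vapply(c_grid, function(C) {
      accs <- vapply(seq_len(ninner), function(g) {
        itr <- inner != g; ite <- inner == g
        if (length(unique(ytr[itr])) < 2L) return(NA_real_)
        fit <- e1071::svm(Xs[itr, , drop = FALSE], droplevels(ytr[itr]),
                          kernel = "linear", cost = C, scale = FALSE,
                          class.weights = cw)
        mean(stats::predict(fit, Xs[ite, , drop = FALSE]) == ytr[ite])
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
    best_cost[f] <- c_grid[which.max(inner_acc)]

    fit <- e1071::svm(Xs, ytr, kernel = "linear", cost = best_cost[f],
                      scale = FALSE, class.weights = cw)
    fold_weights[[f]] <- stats::setNames(
      as.numeric(t(fit$coefs) %*% fit$SV), colnames(X)[sel])
    pred <- stats::predict(fit, X[te, sel, drop = FALSE],
                           decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    # orient decision values toward the positive class
    if (grepl(paste0("/", positive, "$"),
              colnames(attr(pred, "decision.values"))[1L]))
      dv <- -dv
    fold_metrics[f, ] <- classification_metrics(y[te], pred, positive)
    confusion <- confusion + table(truth = y[te],
                                   pred = factor(pred, levels = levels(y)))
    ord <- order(dv, decreasing = TRUE)
    truth_pos <- (y[te] == positive)[ord]
    roc[[f]] <- data.frame(
      fpr = c(0, cumsum(!truth_pos) / max(1, sum(!truth_pos))),
      tpr = c(0, cumsum(truth_pos) / max(1, sum(truth_pos))))
  }
  structure(list(
    fold_metrics = as.data.frame(fold_metrics),
    average = colMeans(fold_metrics, na.rm = TRUE),
    selected = selected, fold_weights = fold_weights,
    best_cost = best_cost, confusion = confusion, roc = roc,
    positive_class = positive, n_features = as.integer(n_features),
    feature_names = colnames(X), folds = folds, seed = as.integer(seed)
  ), class = "ecn_classifier")
}

#' @export
print.ecn_classifier <- function(x, ...) {
  cat(sprintf("Linear SVM with RFE (%d features), %d-fold CV, positive class %s\n",
              x$n_features, nrow(x$fold_metrics), x$positive_class))
  cat("Average metrics (%):\n")
  print(round(x$average, 2))
  cat("Pooled confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Feature selection frequency across folds
#'
#' Ranks features by how often they were selected across the
#' cross-validation folds; ties are broken by the mean absolute SVM weight
#' over the folds where the feature was selected, then by feature index.
#'
#' @param report An `ecn_classifier` object.
#' @param top_n Number of top features to return (default 10).
#' @return Data frame `feature`, `count`, `mean_abs_weight`, ordered by
#'   rank, with attribute `truncated` = FALSE and a warning flag attribute
#'   `fewer_than_requested` when fewer distinct features exist than
#'   `top_n`.
#' @export
feature_frequency <- function(report, top_n = 10L) {
  stopifnot(inherits(report, "ecn_classifier"))
  if (!length(report$selected)) stop("report contains no fold selections")
  all_idx <- sort(unique(unlist(report$selected)))
  nm <- report$feature_names
  if (is.null(nm)) nm <- paste0("f", seq_len(max(all_idx)))
  count <- vapply(all_idx, function(i)
    sum(vapply(report$selected, function(s) i %in% s, logical(1))),
    integer(1))
  mean_w <- vapply(all_idx, function(i) {
    ws <- unlist(lapply(seq_along(report$selected), function(f) {
      pos <- match(i, report$selected[[f]])
      if (is.na(pos)) NULL else abs(report$fold_weights[[f]][pos])
    }))
    mean(ws)
  }, numeric(1))
  ord <- order(-count, -mean_w, all_idx)
  out <- data.frame(feature = nm[all_idx][ord], index = all_idx[ord],
                    count = count[ord], mean_abs_weight = mean_w[ord],
                    stringsAsFactors = FALSE)
  fewer <- nrow(out) < top_n
  if (fewer)
    warning("fewer distinct selected features than requested top_n")
  out <- utils::head(out, top_n)
  attr(out, "fewer_than_requested") <- fewer
  out
}
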