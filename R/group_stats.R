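#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on (number of
#' groups - 1) degrees of freedom. An input where every value is tied
#' returns H = 0, p = 1 by convention.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `statistic`, `p_raw`, `df`, `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_raw = 1, df = length(groups) - 1L,
                n_per_group = lengths(groups)))
  }
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_raw = kt$p.value,
       df = unname(kt$parameter), n_per_group = lengths(groups))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution when the smaller group has at most 8
#' observations and there are no ties; normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b Numeric vectors.
#' @return List with `statistic` (U for the first sample), `p_raw`,
#'   `n_per_group`, `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_raw = min(wt$p.value, 1),
       n_per_group = c(length(a), length(b)), exact = exact)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false discovery rate adjustment, order-preserving with the
#' input.
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order and length.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return List with `r`, `p_raw`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no defined correlation")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_raw = ct$p.value, n = length(x))
}

#' Per-region two-sample t map
#'
#' Pooled-variance (Student) two-sample t statistic for every region,
#' signed as mean(B) - mean(A). For the study design A is the MDDNSI group
#' and B the MDDSI group, so positive t means higher entropy with suicidal
#' ideation.
#'
#' @param entropy_a,entropy_b Subjects-by-regions matrices for the two
#'   groups (equal region count).
#' @return List of class `tstat_map`: `values` (per-region t, named),
#'   `df` (n_a + n_b - 2).
#' @export
two_sample_tmap <- function(entropy_a, entropy_b) {
  entropy_a <- as.matrix(entropy_a); entropy_b <- as.matrix(entropy_b)
  if (ncol(entropy_a) != ncol(entropy_b)) stop("region count differs")
  na <- nrow(entropy_a); nb <- nrow(entropy_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 subjects")
  ma <- colMeans(entropy_a); mb <- colMeans(entropy_b)
  va <- apply(entropy_a, 2, stats::var)
  vb <- apply(entropy_b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (any(sp2 == 0)) stop("zero pooled variance in at least one region")
  tt <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
  structure(list(values = tt, df = na + nb - 2L), class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("Two-sample t map: %d regions, df = %d, range [%.3f, %.3f]\n",
              length(x$values), x$df, min(x$values), max(x$values)))
  invisible(x)
}

#' Three-group entropy comparison with FDR control
#'
#' Implements the staged group analysis: (i) Kruskal-Wallis tests over
#' global entropy and the 7 subnetwork entropies, BH-corrected as one
#' family of 8; (ii) for measures significant after FDR, the three pairwise
#' Mann-Whitney U post-hoc tests, BH-corrected across all post-hoc p values
#' as one family; (iii) Pearson correlations of the FDR-significant
#' subnetwork entropies with the requested behavior columns, separately
#' within each patient group, BH-corrected within each group's correlation
#' family. Also computes the per-region MDDSI-minus-MDDNSI t map used by
#' the transcriptome association stage.
#'
#' @param table An `entropy_table` (see [cohort_entropy()]).
#' @param behavior_columns Character vector of manifest columns to
#'   correlate with significant subnetwork entropies.
#' @param alpha Significance level applied after FDR correction.
#' @return Object of class `ecn_group_stats`: `kw` (data frame, 8 rows),
#'   `posthoc` (data frame or NULL), `correlations` (data frame or NULL),
#'   `tmap` (`tstat_map`), `alpha`, `significant_measures`.
#' @export
run_group_analysis <- function(table, behavior_columns = character(),
                               alpha = 0.05) {
  stopifnot(inherits(table, "entropy_table"))
  if (anyNA(table$group)) stop("missing group labels")
  groups_present <- levels(droplevels(table$group))
  if (length(groups_present) < 2L)
    stop("need at least 2 groups for a group analysis")
  measures <- c("global", attr(table, "subnetwork_columns"))
  df <- as.data.frame(table)

  kw <- do.call(rbind, lapply(measures, function(m) {
    res <- kruskal_wallis(split(df[[m]], droplevels(table$group)))
    data.frame(measure = m, H = res$statistic, p_raw = res$p_raw,
               stringsAsFactors = FALSE)
  }))
  kw$p_fdr <- bh_fdr(kw$p_raw)
  sig <- kw$measure[kw$p_fdr < alpha]

  posthoc <- NULL
  if (length(sig)) {
    pairs <- utils::combn(groups_present, 2L)
    rows <- list()
    for (m in sig) for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      res <- mann_whitney_u(df[[m]][table$group == g1],
                            df[[m]][table$group == g2])
      rows[[length(rows) + 1L]] <-
        data.frame(measure = m, group1 = g1, group2 = g2,
                   U = res$statistic, p_raw = res$p_raw,
                   stringsAsFactors = FALSE)
    }
    posthoc <- do.call(rbind, rows)
    posthoc$p_fdr <- bh_fdr(posthoc$p_raw)
  }

  correlations <- NULL
  sig_subnets <- setdiff(sig, "global")
  behavior_columns <- intersect(behavior_columns, names(df))
  if (length(sig_subnets) && length(behavior_columns)) {
    rows <- list()
    for (g in intersect(c("MDDNSI", "MDDSI"), groups_present)) {
      gi <- which(table$group == g)
      grows <- list()
      for (m in sig_subnets) for (b in behavior_columns) {
        x <- df[[m]][gi]; y <- df[[b]][gi]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
          next
        res <- pearson_correlation(x[ok], y[ok])
        grows[[length(grows) + 1L]] <-
          data.frame(group = g, measure = m, behavior = b, r = res$r,
                     p_raw = res$p_raw, n = res$n, stringsAsFactors = FALSE)
      }
      if (length(grows)) {
        gdf <- do.call(rbind, grows)
        gdf$p_fdr <- bh_fdr(gdf$p_raw)  # family: one group's correlations
        rows[[length(rows) + 1L]] <- gdf
      }
    }
    if (length(rows)) correlations <- do.call(rbind, rows)
  }

  tmap <- NULL
  if (all(c("MDDNSI", "MDDSI") %in% groups_present)) {
    nodal <- entropy_features(table, "nodal")
    tmap <- two_sample_tmap(nodal[table$group == "MDDNSI", , drop = FALSE],
                            nodal[table$group == "MDDSI", , drop = FALSE])
  }

  structure(list(kw = kw, posthoc = posthoc, correlations = correlations,
                 tmap = tmap, alpha = alpha, significant_measures = sig),
            class = "ecn_group_stats")
}

#' @export
print.ecn_group_stats <- function(x, ...) {
  cat("Three-group entropy comparison (Kruskal-Wallis + BH-FDR)\n")
  print(transform(x$kw, H = round(H, 3), p_raw = signif(p_raw, 3),
                  p_fdr = signif(p_fdr, 3)), row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat(sprintf("\nPost-hoc Mann-Whitney U (measures with FDR p < %g):\n",
                x$alpha))
    print(transform(x$posthoc, p_raw = signif(p_raw, 3),
                    p_fdr = signif(p_fdr, 3)), row.names = FALSE)
  } else cat("\nNo measure passed FDR; post-hoc tests skipped.\n")
  if (!is.null(x$correlations)) {
    cat("\nBrain-behavior correlations within patient groups:\n")
    print(transform(x$correlations, r = round(r, 3),
                    p_raw = signif(p_raw, 3), p_fdr = signif(p_fdr, 3)),
          row.names = FALSE)
  }
  invisible(x)
}
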