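#' Write a synthetic cohort to delimited text files
#'
#' One tab-separated matrix per subject (region ids in the first column),
#' a manifest CSV, a region-to-subnetwork CSV, a region-by-gene CSV, a
#' distance CSV and a JSON ground-truth file.
#'
#' @param cohort An `ecn_cohort`.
#' @param dir Output directory (created if needed).
#' @param expression Optional result of [simulate_expression()].
#' @return Invisibly, the list of written paths.
#' @export
write_cohort <- function(cohort, dir, expression = NULL) {
  stopifnot(inherits(cohort, "ecn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  paths <- list()
  for (id in names(cohort$ts)) {
    p <- file.path(ts_dir, paste0(id, ".tsv"))
    m <- cohort$ts[[id]]
    utils::write.table(data.frame(region_id = rownames(m), m,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$timeseries <- c(paths$timeseries, p)
  }
  paths$manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, paths$manifest, row.names = FALSE)
  paths$subnetworks <- file.path(dir, "subnetworks.csv")
  utils::write.csv(data.frame(region_id = region_ids(cohort$config$n_regions),
                              subnetwork = as.character(cohort$subnetworks)),
                   paths$subnetworks, row.names = FALSE)
  if (!is.null(expression)) {
    paths$expression <- file.path(dir, "expression.csv")
    utils::write.csv(data.frame(region_id = rownames(expression$expression),
                                expression$expression, check.names = FALSE),
                     paths$expression, row.names = FALSE)
    paths$distance <- file.path(dir, "distance.csv")
    utils::write.csv(expression$distance, paths$distance, row.names = FALSE)
  }
  paths$truth <- file.path(dir, "truth.json")
  truth <- cohort$truth
  truth$region_mixing_weights <- NULL  # bulky; entropies carry the target
  if (!is.null(expression)) truth$signal_gene_ids <- expression$signal_gene_ids
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read one subject's time-series matrix
#'
#' @param path Tab-separated file, region ids in the first column.
#' @return Region-by-time numeric matrix with region ids as row names.
#' @export
read_subject_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  attr(m, "subject_id") <- sub("\\.tsv$", "", basename(path))
  m
}

#' Load and validate a subject manifest CSV
#'
#' @param path CSV with at least `subject_id` and `group` columns; group
#'   labels must be HC, MDDNSI or MDDSI.
#' @return Validated data frame (see [validate_manifest()]).
#' @export
load_manifest <- function(path) {
  validate_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end synthetic run with the
#' study defaults: 10 edge communities with 25 K-means restarts, 60 RFE
#' features, 5 CV folds, 15 PLS components, 1000 permutations and 1000
#' bootstrap iterations.
#'
#' @param synth An [synth_config()]; its seed is re-derived from `seed`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "entropy", "stats", "classify", "pls", "celltype")`.
#' @param k,n_restarts Edge-community K-means parameters.
#' @param scope,covariate_mode Entropy-stage options, see
#'   [cohort_entropy()].
#' @param n_features,n_folds Classifier parameters.
#' @param n_components,n_perm,n_boot,alpha Transcriptome-stage parameters.
#' @param celltype_sizes Gene-set sizes for the synthetic cell classes.
#' @param seed Global seed; all stage seeds derive from it.
#' @return List of class `ecn_run_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            stages = c("simulate", "entropy", "stats",
                                       "classify", "pls", "celltype"),
                            k = 10L, n_restarts = 25L,
                            scope = "subject", covariate_mode = "features",
                            n_features = 60L, n_folds = 5L,
                            n_components = 15L, n_perm = 1000L,
                            n_boot = 1000L, alpha = 0.05,
                            celltype_sizes = 20L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(synth = synth, stages = stages, k = k,
                 n_restarts = n_restarts, scope = scope,
                 covariate_mode = covariate_mode,
                 n_features = n_features, n_folds = n_folds,
                 n_components = n_components, n_perm = n_perm,
                 n_boot = n_boot, alpha = alpha,
                 celltype_sizes = celltype_sizes, seed = as.integer(seed)),
            class = "ecn_run_config")
}

read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  synth_args <- raw$synth %||% list()
  if (!is.null(synth_args$group_sizes))
    synth_args$group_sizes <- unlist(synth_args$group_sizes)
  if (!is.null(synth_args$effect_map))
    synth_args$effect_map <- matrix(unlist(synth_args$effect_map),
                                    ncol = 3L, byrow = TRUE)
  raw$synth <- do.call(synth_config, synth_args)
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic edge-centric analysis pipeline
#'
#' Executes the enabled stages in order — simulate, entropy, stats,
#' classify, pls, celltype — writing every intermediate artifact under
#' `outdir` and a single deterministic JSON run report. A stage whose
#' prerequisites are disabled is skipped with a logged reason (e.g.
#' disabling `pls` auto-skips `celltype`). A stage failure aborts the run
#' with the failing stage named and leaves a `FAILED` marker in `outdir`.
#'
#' @param config An `ecn_run_config` (see [pipeline_config()]) or a path
#'   to a JSON/YAML file of the same structure.
#' @param outdir Output directory.
#' @param quiet Suppress progress messages.
#' @return The run report (list), invisibly written as
#'   `file.path(outdir, "run_report.json")`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile(),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "ecn_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  seed <- config$seed
  report <- list(seed = seed, config_hash = config_hash(
    config[setdiff(names(config), "synth")]), stages = list())
  skipped <- list()
  enabled <- config$stages
  run_stage <- function(name, deps, fun) {
    if (!name %in% enabled) {
      skipped[[name]] <<- "disabled in config"
      logf("stage %s skipped: disabled", name)
      return(NULL)
    }
    missing_deps <- setdiff(deps, names(report$stages))
    if (length(missing_deps)) {
      skipped[[name]] <<-
        sprintf("requires stage(s) %s", paste(missing_deps, collapse = ", "))
      logf("stage %s skipped: %s", name, skipped[[name]])
      return(NULL)
    }
    logf("stage %s started", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logf("stage %s finished in %.1f s", name,
         proc.time()[["elapsed"]] - t0)
    out
  }

  env <- new.env()
  res <- run_stage("simulate", character(), function() {
    env$cohort <- simulate_cohort(config$synth)
    truth <- env$cohort$truth$planted_entropy
    diff_map <- colMeans(truth[env$cohort$manifest$group == "MDDSI", ,
                               drop = FALSE]) -
      colMeans(truth[env$cohort$manifest$group == "MDDNSI", , drop = FALSE])
    env$expression <- simulate_expression(
      n_regions = config$synth$n_regions, n_genes = config$synth$n_genes,
      signal_gene_ids = seq_len(config$synth$n_signal_genes),
      target_map = diff_map,
      smoothness = config$synth$spatial_smoothness,
      noise_amp = config$synth$expression_noise,
      seed = derive_seed(seed, 21L))
    write_cohort(env$cohort, file.path(outdir, "data"), env$expression)
    list(n_subjects = nrow(env$cohort$manifest),
         n_regions = config$synth$n_regions,
         n_genes = config$synth$n_genes,
         signal_genes = env$expression$signal_gene_ids)
  })
  if (!is.null(res)) report$stages$simulate <- res

  res <- run_stage("entropy", "simulate", function() {
    env$table <- cohort_entropy(env$cohort, k = config$k,
                                n_restarts = config$n_restarts,
                                seed = derive_seed(seed, 22L),
                                scope = config$scope,
                                covariate_mode = config$covariate_mode)
    utils::write.csv(as.data.frame(env$table),
                     file.path(outdir, "entropy_table.csv"),
                     row.names = FALSE)
    list(k = config$k, n_restarts = config$n_restarts,
         scope = config$scope, covariate_mode = config$covariate_mode,
         mean_global_entropy = mean(env$table$global))
  })
  if (!is.null(res)) report$stages$entropy <- res

  res <- run_stage("stats", "entropy", function() {
    env$stats <- run_group_analysis(env$table,
                                    behavior_columns = "cognitive_score",
                                    alpha = config$alpha)
    utils::write.csv(env$stats$kw, file.path(outdir, "kw_tests.csv"),
                     row.names = FALSE)
    if (!is.null(env$stats$posthoc))
      utils::write.csv(env$stats$posthoc,
                       file.path(outdir, "posthoc_tests.csv"),
                       row.names = FALSE)
    if (!is.null(env$stats$tmap))
      utils::write.csv(data.frame(region_id = names(env$stats$tmap$values),
                                  t = env$stats$tmap$values),
                       file.path(outdir, "tmap.csv"), row.names = FALSE)
    list(significant_measures = env$stats$significant_measures,
         kw = env$stats$kw)
  })
  if (!is.null(res)) report$stages$stats <- res

  res <- run_stage("classify", "entropy", function() {
    nodal <- entropy_features(env$table, "nodal")
    nf <- min(config$n_features, ncol(nodal))
    tasks <- list()
    y1 <- factor(ifelse(env$table$group == "HC", "HC", "MDD"),
                 levels = c("HC", "MDD"))
    tasks$hc_vs_mdd <- train_eval_svm_cv(
      nodal, y1, n_folds = config$n_folds, n_features = nf,
      seed = derive_seed(seed, 23L))
    pat <- env$table$group != "HC"
    tasks$nsi_vs_si <- train_eval_svm_cv(
      nodal[pat, , drop = FALSE], droplevels(env$table$group[pat]),
      n_folds = config$n_folds, n_features = nf,
      seed = derive_seed(seed, 24L))
    env$classify <- tasks
    out <- lapply(tasks, function(tk) list(
      average = as.list(round(tk$average, 4)),
      top_features = feature_frequency(tk, 10L)$feature))
    jsonlite::write_json(out, file.path(outdir, "classifier_report.json"),
                         digits = NA, auto_unbox = TRUE)
    out
  })
  if (!is.null(res)) report$stages$classify <- res

  res <- run_stage("pls", c("simulate", "stats"), function() {
    if (is.null(env$stats$tmap))
      stop("no MDDNSI/MDDSI t map available for PLS")
    X <- env$expression$expression
    nc <- min(config$n_components, nrow(X) - 2L)
    env$pls <- fit_pls(X, env$stats$tmap, n_components = nc)
    perm <- permutation_test_pls(X, env$stats$tmap, n_perm = config$n_perm,
                                 distance = env$expression$distance,
                                 seed = derive_seed(seed, 25L))
    boot <- bootstrap_gene_weights(X, env$stats$tmap,
                                   n_boot = config$n_boot,
                                   seed = derive_seed(seed, 26L))
    env$gene_sets <- select_gene_sets(boot$z, alpha = config$alpha)
    utils::write.csv(env$gene_sets$table,
                     file.path(outdir, "pls_genes.csv"), row.names = FALSE)
    out <- list(n_components = nc,
                pls1_explained_variance = env$pls$explained_variance[1L],
                pls1_explained_cov = env$pls$explained_cov[1L],
                pls1_score_tmap_correlation =
                  stats::cor(env$pls$scores[, 1L], env$pls$y),
                permutation_p = perm$p, permutation_method = perm$method,
                n_pls1_pos = length(env$gene_sets$pls1_pos),
                n_pls1_neg = length(env$gene_sets$pls1_neg),
                bootstrap_degenerate = boot$n_degenerate)
    jsonlite::write_json(out, file.path(outdir, "pls_result.json"),
                         digits = NA, auto_unbox = TRUE)
    out
  })
  if (!is.null(res)) report$stages$pls <- res

  res <- run_stage("celltype", "pls", function() {
    sets <- make_celltype_sets(colnames(env$expression$expression),
                               sizes = config$celltype_sizes,
                               seed = derive_seed(seed, 27L))
    query <- if (length(env$gene_sets$pls1_neg)) env$gene_sets$pls1_neg
             else env$gene_sets$pls1_pos
    if (!length(query)) return(list(note = "no significant genes to test"))
    tab <- celltype_overlap_test(query, sets,
                                 n_perm = min(config$n_perm * 10L, 10000L),
                                 seed = derive_seed(seed, 28L))
    utils::write.csv(tab, file.path(outdir, "celltype_overlap.csv"),
                     row.names = FALSE)
    list(query_set = if (length(env$gene_sets$pls1_neg)) "PLS1-" else "PLS1+",
         query_size = length(query), overlap = tab)
  })
  if (!is.null(res)) report$stages$celltype <- res

  report$skipped <- skipped
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
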