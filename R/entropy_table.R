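#' Build the subject-level entropy table for a cohort
#'
#' Runs the edge-centric entropy pipeline for every subject and assembles
#' one row per subject: identifiers, group, covariates, global entropy, the
#' 7 subnetwork entropies and all N nodal entropies. Optionally removes the
#' effects of sex, age and years of education.
#'
#' Two clustering scopes are available. `"subject"` (default) clusters each
#' subject's own edge time series; `"group"` concatenates all subjects'
#' edge time series along time and derives one shared edge-community
#' labeling. Two covariate modes are available: `"features"` (default)
#' residualizes the subject-level entropy features across subjects after
#' the pipeline; `"bold"` residualizes each (region, time point) BOLD value
#' across subjects before the pipeline (requires equal scan length);
#' `"off"` disables adjustment.
#'
#' @param cohort An `ecn_cohort` object, or a named list of region-by-time
#'   matrices together with `manifest`.
#' @param manifest Data frame with columns `subject_id`, `group` and the
#'   covariates (required when `cohort` is a bare list of matrices).
#' @param subnetworks Region-to-subnetwork assignment (defaults to the
#'   cohort's own).
#' @param k,n_restarts,seed K-means parameters, see [cluster_edges()].
#' @param scope `"subject"` or `"group"` clustering scope.
#' @param covariate_mode `"features"`, `"bold"` or `"off"`.
#' @param covariate_columns Manifest columns treated as nuisance covariates.
#' @return Object of class `entropy_table`: a data frame with attributes
#'   `subnetworks`, `k`, `nodal_columns`, `subnetwork_columns`,
#'   `covariate_mode`, plus per-subject `fits` stored in
#'   `attr(, "restart_sse")` for K-means auditability.
#' @export
cohort_entropy <- function(cohort, manifest = NULL, subnetworks = NULL,
                           k = 10L, n_restarts = 25L, seed = 1L,
                           scope = c("subject", "group"),
                           covariate_mode = c("features", "bold", "off"),
                           covariate_columns = c("sex", "age", "education")) {
  scope <- match.arg(scope)
  covariate_mode <- match.arg(covariate_mode)
  if (inherits(cohort, "ecn_cohort")) {
    ts_list <- cohort$ts
    if (is.null(manifest)) manifest <- cohort$manifest
    if (is.null(subnetworks)) subnetworks <- cohort$subnetworks
  } else {
    ts_list <- cohort
  }
  if (is.null(manifest)) stop("a subject manifest is required")
  manifest <- validate_manifest(manifest)
  if (!setequal(names(ts_list), manifest$subject_id))
    stop("time-series list and manifest cover different subjects")
  ts_list <- ts_list[manifest$subject_id]
  n_regions <- nrow(ts_list[[1L]])
  if (is.null(subnetworks)) subnetworks <- synthetic_subnetworks(n_regions)
  covariate_columns <- intersect(covariate_columns, names(manifest))

  if (covariate_mode == "bold") {
    lens <- vapply(ts_list, ncol, integer(1))
    if (length(unique(lens)) != 1L)
      stop("covariate_mode 'bold' requires equal scan length across subjects")
    if (length(covariate_columns)) {
      flat <- t(vapply(ts_list, as.numeric, numeric(n_regions * lens[1L])))
      flat <- residualize_covariates(flat, manifest[covariate_columns])
      for (i in seq_along(ts_list)) {
        m <- matrix(flat[i, ], n_regions, lens[1L])
        dimnames(m) <- dimnames(ts_list[[i]])
        attr(m, "subject_id") <- attr(ts_list[[i]], "subject_id")
        ts_list[[i]] <- m
      }
    }
  }

  # group scope: shared centroids from time-concatenated edge series; each
  # subject's edges are then assigned within its own time block, giving
  # subject-specific labels in a common community space.
  subject_comms <- vector("list", length(ts_list))
  if (scope == "group") {
    all_ets <- lapply(ts_list, function(x)
      compute_edge_time_series(zscore_timeseries(x))$values)
    shared <- cluster_edges(do.call(cbind, all_ets), k = k,
                            n_restarts = n_restarts, seed = seed)
    offsets <- c(0L, cumsum(vapply(all_ets, ncol, integer(1))))
    for (i in seq_along(ts_list)) {
      cols <- (offsets[i] + 1L):offsets[i + 1L]
      cen <- shared$centers[, cols, drop = FALSE]
      x <- all_ets[[i]]
      d2 <- vapply(seq_len(nrow(cen)), function(j)
        rowSums((x - matrix(cen[j, ], nrow(x), ncol(x), byrow = TRUE))^2),
        numeric(nrow(x)))
      lab <- max.col(-d2, ties.method = "first")
      subject_comms[[i]] <- structure(
        list(labels = lab, k = shared$k, sse = sum(d2[cbind(seq_len(nrow(x)),
                                                            lab)]),
             restart_sse = shared$restart_sse,
             selected_restart = shared$selected_restart),
        class = "edge_communities")
    }
  }
  fits <- vector("list", length(ts_list))
  for (i in seq_along(ts_list)) {
    fits[[i]] <- edge_entropy(ts_list[[i]], k = k, n_restarts = n_restarts,
                              seed = derive_seed(seed, i),
                              subnetworks = subnetworks,
                              communities = subject_comms[[i]])
  }
  nodal <- t(vapply(fits, function(f) f$entropy, numeric(n_regions)))
  agg <- t(vapply(fits, function(f) f$aggregate,
                  numeric(1L + length(SUBNETWORK_LEVELS))))
  subnet_cols <- make.names(SUBNETWORK_LEVELS)
  colnames(agg) <- c("global", subnet_cols)
  nodal_cols <- paste0("nodal_", colnames(nodal))
  colnames(nodal) <- nodal_cols

  features <- cbind(agg, nodal)
  if (covariate_mode == "features" && length(covariate_columns))
    features <- residualize_covariates(features,
                                       manifest[covariate_columns])
  out <- cbind(manifest, as.data.frame(features))
  rownames(out) <- NULL
  structure(out, class = c("entropy_table", "data.frame"),
            subnetworks = subnetworks, k = k,
            nodal_columns = nodal_cols,
            subnetwork_columns = subnet_cols,
            covariate_mode = covariate_mode,
            restart_sse = lapply(fits, function(f) f$communities$restart_sse))
}

#' Extract entropy feature blocks from an entropy table
#'
#' @param table An `entropy_table`.
#' @param which `"nodal"`, `"subnetwork"` or `"aggregate"` (global + the 7
#'   subnetworks).
#' @return Numeric matrix, subjects in rows.
#' @export
entropy_features <- function(table,
                             which = c("nodal", "subnetwork", "aggregate")) {
  which <- match.arg(which)
  cols <- switch(which,
                 nodal = attr(table, "nodal_columns"),
                 subnetwork = attr(table, "subnetwork_columns"),
                 aggregate = c("global", attr(table, "subnetwork_columns")))
  m <- as.matrix(as.data.frame(table)[cols])
  rownames(m) <- table$subject_id
  m
}

#' Validate a subject manifest
#'
#' Checks required columns, unique subject ids and known group labels.
#'
#' @param manifest Data frame with at least `subject_id` and `group`.
#' @return The validated manifest with `group` as a factor with levels
#'   HC, MDDNSI, MDDSI (unused levels allowed).
#' @export
validate_manifest <- function(manifest) {
  manifest <- as.data.frame(manifest)
  req <- c("subject_id", "group")
  missing_cols <- setdiff(req, names(manifest))
  if (length(missing_cols))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  dup <- manifest$subject_id[duplicated(manifest$subject_id)]
  if (length(dup))
    stop(sprintf("duplicated subject id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(as.character(manifest$group)), GROUP_LEVELS)
  if (length(bad))
    stop(sprintf("unknown group label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(GROUP_LEVELS, collapse = ", ")))
  manifest$group <- factor(as.character(manifest$group),
                           levels = GROUP_LEVELS)
  manifest
}
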