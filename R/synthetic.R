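#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: cohort layout, the latent
#' module model that creates edge-community structure, planted group effects,
#' and the gene-expression component. Defaults mirror a resting-state study
#' with 440 retained time points per subject and a 98/60/90 three-group
#' design (healthy controls, patients without and with suicidal ideation),
#' at a 50-region desk scale.
#'
#' The signal model for region r is
#' \deqn{x_r(t) = \sum_s w_{rs} c_s(t) + \epsilon(t),}
#' where the latent module signals \eqn{c_s} switch their variance and
#' pairwise coupling across `n_states` equal-length temporal states (state b
#' activates module b at amplitude `module_amp` and couples it to its
#' successor at `state_coupling`; the other modules idle at `baseline_amp`),
#' and \eqn{\epsilon} is Gaussian noise. A shared base mixing matrix is
#' drawn once per configuration — each region's row is Dirichlet with a
#' region-specific concentration and rows are relabeled so dominant modules
#' are balanced — and each subject's rows are Dirichlet perturbations of the
#' base with precision `subject_fidelity`. In the signal path the rows are
#' L2-normalized so every region has the same signal-to-noise ratio; the
#' truth record keeps the simplex rows. The normalized Shannon entropy of
#' \eqn{w_r} is the planted nodal entropy that the edge-centric pipeline is
#' expected to recover.
#'
#' @param n_regions Number of brain regions (parcels).
#' @param n_time Time points per subject.
#' @param n_latent_modules Number of latent functional modules.
#' @param n_states Number of temporal coupling states (equal-length blocks);
#'   state b activates latent module ((b-1) mod L)+1.
#' @param mixing_concentration Median Dirichlet concentration of the base
#'   mixing rows.
#' @param concentration_spread Regions draw their own concentration as
#'   `mixing_concentration * exp(U(-spread, spread))`, giving a realistic
#'   range from strongly unimodal to evenly mixed regions.
#' @param subject_fidelity Dirichlet precision of per-subject mixing draws
#'   around the shared base weights (larger = subjects closer to the base).
#' @param noise_sd Standard deviation of the additive observation noise.
#' @param module_amp,baseline_amp Latent module signal standard deviation in
#'   its active state block and outside it.
#' @param state_coupling Correlation planted between the active module and
#'   its successor within each state block (the pairwise coupling that
#'   switches across states).
#' @param group_sizes Named integer triple `c(HC, MDDNSI, MDDSI)`.
#' @param effect_map `n_regions x 3` matrix (columns HC, MDDNSI, MDDSI) of
#'   mixing-sharpness shifts per region and group (positive flattens the
#'   region's membership, raising its entropy; negative sharpens it);
#'   `NULL` means no planted group effect.
#' @param n_genes,n_signal_genes Size of the synthetic expression matrix and
#'   the number of genes tracking the planted group-difference map.
#' @param spatial_smoothness Length scale of the spatially smooth component
#'   of the gene maps (regions live in a unit cube).
#' @param expression_noise Amplitude of the smooth spatial noise added to
#'   signal-gene columns (0 makes them exactly proportional to the target).
#' @param behavior_r Target correlation between the synthetic cognitive
#'   score and the planted entropy of `behavior_target` across subjects.
#' @param behavior_target Subnetwork whose planted entropy drives the score.
#' @param covariate_leak Amplitude leakage of (standardized) age, education
#'   and sex into the signal, exercising covariate residualization.
#' @param ar_coef Optional AR(1) coefficient for latent signals and noise.
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return An object of class `ecn_config` (a validated list).
#' @seealso [simulate_bold()], [simulate_cohort()], [simulate_expression()]
#' @export
synth_config <- function(n_regions = 50L, n_time = 440L,
                         n_latent_modules = 4L, n_states = 4L,
                         mixing_concentration = 0.5,
                         concentration_spread = 1.5,
                         subject_fidelity = 20, noise_sd = 0.25,
                         module_amp = 2, baseline_amp = 0.15,
                         state_coupling = 0.3,
                         group_sizes = c(HC = 98L, MDDNSI = 60L, MDDSI = 90L),
                         effect_map = NULL,
                         n_genes = 200L, n_signal_genes = 10L,
                         spatial_smoothness = 0.3, expression_noise = 0.5,
                         behavior_r = -0.5,
                         behavior_target = "dorsal attention",
                         covariate_leak = 0.02, ar_coef = 0, seed = 1L) {
  n_regions <- stop_if_not_count(n_regions, "n_regions", 2L)
  n_time <- stop_if_not_count(n_time, "n_time", 2L)
  n_latent_modules <- stop_if_not_count(n_latent_modules, "n_latent_modules")
  n_states <- stop_if_not_count(n_states, "n_states")
  stop_if_not_positive(mixing_concentration, "mixing_concentration")
  stop_if_not_positive(subject_fidelity, "subject_fidelity")
  if (concentration_spread < 0) stop("'concentration_spread' must be >= 0")
  stop_if_not_positive(noise_sd, "noise_sd")
  stop_if_not_positive(module_amp, "module_amp")
  if (baseline_amp < 0) stop("'baseline_amp' must be >= 0")
  if (abs(state_coupling) >= 1) stop("'state_coupling' must be in (-1, 1)")
  if (length(group_sizes) != 3L) stop("'group_sizes' must have 3 entries")
  if (any(group_sizes < 2L)) stop("each group needs at least 2 subjects")
  group_sizes <- stats::setNames(as.integer(group_sizes), GROUP_LEVELS)
  n_genes <- stop_if_not_count(n_genes, "n_genes")
  n_signal_genes <- stop_if_not_count(n_signal_genes, "n_signal_genes", 0L)
  if (n_signal_genes > n_genes)
    stop("'n_signal_genes' cannot exceed 'n_genes'")
  if (is.null(effect_map)) {
    effect_map <- matrix(0, n_regions, 3L,
                         dimnames = list(NULL, GROUP_LEVELS))
  } else {
    effect_map <- as.matrix(effect_map)
    if (nrow(effect_map) != n_regions || ncol(effect_map) != 3L)
      stop("'effect_map' must be an n_regions x 3 matrix")
    colnames(effect_map) <- GROUP_LEVELS
  }
  if (abs(behavior_r) > 1) stop("'behavior_r' must be in [-1, 1]")
  if (!behavior_target %in% SUBNETWORK_LEVELS)
    stop("'behavior_target' must be one of the 7 canonical subnetworks")
  if (abs(ar_coef) >= 1) stop("'ar_coef' must satisfy |ar_coef| < 1")
  structure(list(
    n_regions = n_regions, n_time = n_time,
    n_latent_modules = n_latent_modules, n_states = n_states,
    mixing_concentration = mixing_concentration,
    concentration_spread = concentration_spread,
    subject_fidelity = subject_fidelity, noise_sd = noise_sd,
    module_amp = module_amp, baseline_amp = baseline_amp,
    state_coupling = state_coupling,
    group_sizes = group_sizes, effect_map = effect_map,
    n_genes = n_genes, n_signal_genes = n_signal_genes,
    spatial_smoothness = spatial_smoothness,
    expression_noise = expression_noise,
    behavior_r = behavior_r, behavior_target = behavior_target,
    covariate_leak = covariate_leak, ar_coef = ar_coef,
    seed = as.integer(seed)
  ), class = "ecn_config")
}

#' @export
print.ecn_config <- function(x, ...) {
  cat("Synthetic edge-centric study configuration\n")
  cat(sprintf("  regions: %d, time points: %d, latent modules: %d, states: %d\n",
              x$n_regions, x$n_time, x$n_latent_modules, x$n_states))
  cat(sprintf("  groups (HC/MDDNSI/MDDSI): %s\n",
              paste(x$group_sizes, collapse = "/")))
  cat(sprintf("  mixing concentration: %g, noise sd: %g, seed: %d\n",
              x$mixing_concentration, x$noise_sd, x$seed))
  cat(sprintf("  genes: %d (%d signal), planted effect: %s\n",
              x$n_genes, x$n_signal_genes,
              if (any(x$effect_map != 0)) "yes" else "none"))
  invisible(x)
}

#' Assign synthetic regions to the 7 canonical subnetworks
#'
#' Contiguous blocks of regions are mapped to the seven canonical
#' resting-state subnetworks, emulating a parcellation's network assignment.
#'
#' @param n_regions Number of regions.
#' @return Factor of length `n_regions` with the 7 canonical levels.
#' @export
synthetic_subnetworks <- function(n_regions) {
  n_regions <- stop_if_not_count(n_regions, "n_regions", 7L)
  idx <- sort(rep_len(seq_along(SUBNETWORK_LEVELS), n_regions))
  factor(SUBNETWORK_LEVELS[idx], levels = SUBNETWORK_LEVELS)
}

region_ids <- function(n_regions) sprintf("R%03d", seq_len(n_regions))

# Shared base mixing weights, drawn once per configuration.  Each region
# gets its own Dirichlet concentration (log-uniform around the configured
# median) so planted entropies span [0, 1]; rows are then relabeled so that
# dominant modules cycle round-robin, keeping module usage balanced across
# the parcellation.
base_mixing <- function(config) {
  N <- config$n_regions; L <- config$n_latent_modules
  set.seed(derive_seed(config$seed, 101L))
  alpha <- config$mixing_concentration *
    exp(stats::runif(N, -config$concentration_spread,
                     config$concentration_spread))
  W <- t(vapply(alpha, function(a) rdirichlet1(rep(a, L)), numeric(L)))
  dom_target <- rep_len(seq_len(L), N)
  for (r in seq_len(N)) {
    dm <- which.max(W[r, ])
    perm <- seq_len(L)
    perm[c(dom_target[r], dm)] <- c(dm, dom_target[r])
    W[r, ] <- W[r, perm]
  }
  list(weights = W, alpha = alpha)
}

# Latent module signals: state b runs module ((b-1) mod L)+1 at full
# amplitude, couples it to its successor module, and idles the rest.
latent_signals <- function(config) {
  L <- config$n_latent_modules; T <- config$n_time
  states <- state_sequence(T, config$n_states)
  C <- matrix(0, L, T)
  rho <- config$state_coupling
  for (b in seq_len(config$n_states)) {
    cols <- which(states == b)
    if (!length(cols)) next
    active <- ((b - 1L) %% L) + 1L
    a <- rep(config$baseline_amp, L)
    a[active] <- config$module_amp
    Z <- matrix(stats::rnorm(L * length(cols)), L)
    if (L > 1L && rho != 0) {
      succ <- (active %% L) + 1L
      Z[succ, ] <- rho * Z[active, ] + sqrt(1 - rho^2) * Z[succ, ]
    }
    C[, cols] <- a * Z
  }
  C
}

# Equal-length state blocks over the scan (remainder absorbed by the last).
state_sequence <- function(n_time, n_states) {
  block <- n_time %/% n_states
  s <- rep(seq_len(n_states), each = block)
  c(s, rep(n_states, n_time - length(s)))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }  # guard tiny-alpha underflow
  g / sum(g)
}

ar1_filter <- function(x, rho) {
  if (rho == 0) return(x)
  t(apply(x, 1, function(row)
    as.numeric(stats::filter(row * sqrt(1 - rho^2), rho,
                             method = "recursive"))))
}

#' Simulate one subject's ROI time series
#'
#' Perturbs the configuration's shared base mixing weights into
#' subject-specific region-by-module weights, generates latent module
#' signals with state-switching amplitude and pairwise coupling, mixes them
#' into regional signals (unit-norm mixing rows, equalizing regional SNR)
#' and adds Gaussian noise. The returned truth record carries both the
#' subject's realized mixing weights and the configuration-level base
#' weights, with their normalized entropies — the planted nodal entropy.
#'
#' @param config An [synth_config()] object.
#' @param subject_seed Integer seed for this subject's draws; identical
#'   (config, subject_seed) pairs reproduce bit-identical output.
#' @param concentration_shift Optional per-region shift planted on the
#'   subject's mixing sharpness (used by [simulate_cohort()] for group
#'   effects): positive values flatten the base row (higher entropy),
#'   negative values sharpen it (lower entropy), via the tempering
#'   `w^exp(-shift)`.
#' @param amplitude Scalar multiplier on the signal component (used to leak
#'   covariates into amplitude).
#' @param subject_id Label stored on the returned matrix.
#' @return List with `ts` (an `n_regions x n_time` matrix, region ids as row
#'   names, subject id in `attr(, "subject_id")`) and `truth` (subject
#'   mixing weights and entropy, base mixing weights and entropy, per-region
#'   base concentration).
#' @export
simulate_bold <- function(config, subject_seed,
                          concentration_shift = NULL, amplitude = 1,
                          subject_id = "S001") {
  stopifnot(inherits(config, "ecn_config"))
  N <- config$n_regions; T <- config$n_time; L <- config$n_latent_modules
  if (is.null(concentration_shift)) concentration_shift <- numeric(N)
  if (length(concentration_shift) != N)
    stop("'concentration_shift' must have one entry per region")
  base <- base_mixing(config)

  set.seed(as.integer(subject_seed))
  # group effect: temper the base row, then draw the subject's row around it
  Wg <- base$weights
  if (any(concentration_shift != 0)) {
    Wg <- Wg^matrix(exp(-concentration_shift), N, L)
    Wg <- Wg / rowSums(Wg)
  }
  W <- t(vapply(seq_len(N), function(r)
    rdirichlet1(config$subject_fidelity * Wg[r, ] + 1e-3), numeric(L)))
  Wsig <- W / sqrt(rowSums(W^2))
  C <- ar1_filter(latent_signals(config), config$ar_coef)
  noise <- matrix(stats::rnorm(N * T, sd = config$noise_sd), N, T)
  noise <- ar1_filter(noise, config$ar_coef)
  X <- amplitude * (Wsig %*% C) + noise
  if (any(apply(X, 1, stats::var) <= 0))
    stop("degenerate simulation: a region has zero variance")
  rownames(X) <- region_ids(N)
  attr(X, "subject_id") <- subject_id
  planted <- apply(W, 1, function(w) normalized_entropy(w, L))
  base_entropy <- apply(base$weights, 1,
                        function(w) normalized_entropy(w, L))
  list(ts = X,
       truth = list(region_mixing_weights = W,
                    planted_entropy = planted,
                    base_mixing_weights = base$weights,
                    base_entropy = base_entropy,
                    concentration = base$alpha))
}

#' Simulate a three-group cohort with covariates and a cognitive score
#'
#' Generates one ROI time-series matrix per subject, a subject manifest
#' (group, sex, age, years of education, cognitive score) and a ground-truth
#' record. Group effects are planted by tempering the targeted regions'
#' base mixing rows per the configured effect map (sharpening or
#' flattening them), which moves that group's expected nodal entropy. The cognitive score is constructed to correlate
#' with the planted entropy of the configured target subnetwork at
#' `config$behavior_r` across the cohort. Covariates leak weakly into signal
#' amplitude so that covariate residualization is exercised downstream.
#'
#' @param config An [synth_config()] object.
#' @return An object of class `ecn_cohort`: list with `ts` (named list of
#'   matrices), `manifest` (data frame), `subnetworks` (factor) and `truth`
#'   (per-subject planted entropies, effect map, behavior target).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ecn_config"))
  sizes <- config$group_sizes
  if (sum(sizes) == 0) stop("group sizes sum to zero")
  n_sub <- sum(sizes)
  groups <- factor(rep(GROUP_LEVELS, times = sizes), levels = GROUP_LEVELS)
  ids <- sprintf("S%03d", seq_len(n_sub))
  subnets <- synthetic_subnetworks(config$n_regions)

  set.seed(derive_seed(config$seed, 555L))
  sex <- factor(sample(c("F", "M"), n_sub, replace = TRUE),
                levels = c("F", "M"))
  age <- round(stats::rnorm(n_sub, 24, 4), 1)
  education <- round(stats::rnorm(n_sub, 14.5, 2.5), 1)
  leak <- config$covariate_leak
  amp <- 1 + leak * as.numeric(scale(age)) +
    leak * as.numeric(scale(education)) +
    leak * (as.integer(sex) - 1.5)

  ts_list <- vector("list", n_sub)
  planted <- matrix(0, n_sub, config$n_regions,
                    dimnames = list(ids, region_ids(config$n_regions)))
  weights <- vector("list", n_sub)
  base_truth <- NULL
  for (i in seq_len(n_sub)) {
    shift <- config$effect_map[, as.character(groups[i])]
    sim <- simulate_bold(config, subject_seed = derive_seed(config$seed, i),
                         concentration_shift = shift, amplitude = amp[i],
                         subject_id = ids[i])
    ts_list[[i]] <- sim$ts
    planted[i, ] <- sim$truth$planted_entropy
    weights[[i]] <- sim$truth$region_mixing_weights
    if (is.null(base_truth))
      base_truth <- sim$truth[c("base_mixing_weights", "base_entropy")]
  }
  names(ts_list) <- ids

  # cognitive score tied to the planted entropy of the target subnetwork
  target_regions <- which(subnets == config$behavior_target)
  target_ent <- rowMeans(planted[, target_regions, drop = FALSE])
  set.seed(derive_seed(config$seed, 999L))
  z <- as.numeric(scale(target_ent))
  r <- config$behavior_r
  score_z <- r * z + sqrt(1 - r^2) * stats::rnorm(n_sub)
  score <- round(40 + 8 * score_z, 2)

  manifest <- data.frame(subject_id = ids, group = groups, sex = sex,
                         age = age, education = education,
                         cognitive_score = score,
                         stringsAsFactors = FALSE)
  structure(list(
    ts = ts_list, manifest = manifest, subnetworks = subnets,
    truth = list(planted_entropy = planted,
                 region_mixing_weights = weights,
                 base_mixing_weights = base_truth$base_mixing_weights,
                 base_entropy = base_truth$base_entropy,
                 effect_map = config$effect_map,
                 behavior_target = config$behavior_target,
                 behavior_r = config$behavior_r),
    config = config
  ), class = "ecn_cohort")
}

#' @export
print.ecn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d regions x %d time points\n",
              nrow(x$manifest),
              paste(table(x$manifest$group), collapse = "/"),
              x$config$n_regions, x$config$n_time))
  invisible(x)
}

#' Build an effect map targeting one subnetwork
#'
#' Convenience constructor for [synth_config()]'s `effect_map`: plants a
#' mixing-sharpness shift on one subnetwork's regions for chosen groups,
#' leaving all other regions untouched.
#'
#' @param n_regions Number of regions.
#' @param subnetwork Target subnetwork label.
#' @param shifts Named numeric vector of sharpness shifts per group, e.g.
#'   `c(MDDSI = -1)` sharpens the MDDSI group's membership rows (lower
#'   entropy) in the target subnetwork.
#' @return `n_regions x 3` matrix suitable for `synth_config(effect_map=)`.
#' @export
subnetwork_effect_map <- function(n_regions, subnetwork, shifts) {
  subnets <- synthetic_subnetworks(n_regions)
  if (!subnetwork %in% SUBNETWORK_LEVELS) stop("unknown subnetwork")
  if (is.null(names(shifts)) || !all(names(shifts) %in% GROUP_LEVELS))
    stop("'shifts' must be named by group")
  em <- matrix(0, n_regions, 3L, dimnames = list(NULL, GROUP_LEVELS))
  em[subnets == subnetwork, names(shifts)] <-
    rep(shifts, each = sum(subnets == subnetwork))
  em
}

#' Simulate a region-by-gene expression matrix with planted signal genes
#'
#' Signal genes track a supplied per-region target map (for the study design
#' this is the group-difference t-map) plus spatially smooth noise;
#' non-signal genes are smooth spatial noise only, emulating the spatial
#' autocorrelation of atlas-derived expression maps. All columns are
#' standardized. Regions are placed uniformly in a unit cube and a Euclidean
#' distance matrix is returned for variogram-based surrogate testing.
#'
#' @param n_regions,n_genes Matrix dimensions.
#' @param signal_gene_ids Integer indices of the signal genes.
#' @param target_map Numeric vector (length `n_regions`) the signal genes
#'   track.
#' @param smoothness Length scale of the spatial covariance
#'   `exp(-d / smoothness)`.
#' @param noise_amp Amplitude of the smooth noise added to signal genes
#'   (0 = signal columns exactly proportional to the target map).
#' @param seed Integer seed.
#' @return List with `expression` (`n_regions x n_genes`, gene ids as column
#'   names), `coords`, `distance` (symmetric, zero diagonal) and
#'   `signal_gene_ids` (character gene ids).
#' @export
simulate_expression <- function(n_regions, n_genes, signal_gene_ids,
                                target_map, smoothness = 0.3,
                                noise_amp = 0.5, seed = 1L) {
  n_regions <- stop_if_not_count(n_regions, "n_regions", 3L)
  n_genes <- stop_if_not_count(n_genes, "n_genes")
  if (length(target_map) != n_regions)
    stop("'target_map' must have one value per region")
  signal_gene_ids <- as.integer(signal_gene_ids)
  if (length(signal_gene_ids) &&
      (min(signal_gene_ids) < 1L || max(signal_gene_ids) > n_genes))
    stop("signal gene indices outside 1..n_genes")
  set.seed(as.integer(seed))
  coords <- matrix(stats::runif(n_regions * 3), n_regions, 3)
  D <- as.matrix(stats::dist(coords))
  K <- exp(-D / smoothness) + diag(n_regions) * 1e-8
  ch <- chol(K)
  smooth_field <- function() as.numeric(t(ch) %*% stats::rnorm(n_regions))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  target_z <- as.numeric(scale(target_map))
  expr <- matrix(0, n_regions, n_genes,
                 dimnames = list(region_ids(n_regions), gene_ids))
  for (g in seq_len(n_genes)) {
    if (g %in% signal_gene_ids) {
      sg <- sign(stats::runif(1) - 0.5)  # signal genes of both signs
      col <- sg * target_z + noise_amp * smooth_field()
    } else {
      col <- smooth_field()
    }
    expr[, g] <- col
  }
  expr <- scale(expr)
  attr(expr, "scaled:center") <- NULL
  attr(expr, "scaled:scale") <- NULL
  list(expression = expr, coords = coords, distance = D,
       signal_gene_ids = gene_ids[signal_gene_ids])
}
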