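test_that("config validation rejects degenerate settings", {
  expect_error(synth_config(n_regions = 1), "n_regions")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(group_sizes = c(1, 5, 5)), "at least 2")
  expect_error(synth_config(n_signal_genes = 300, n_genes = 200),
               "cannot exceed")
  expect_error(synth_config(behavior_target = "DAN"), "subnetwork")
})

test_that("simulate_bold honors the shape contract and is reproducible", {
  cfg <- synth_config()
  sim <- simulate_bold(cfg, subject_seed = 7)
  expect_identical(dim(sim$ts), c(50L, 440L))
  expect_identical(rownames(sim$ts)[1], "R001")
  expect_identical(sim, simulate_bold(cfg, subject_seed = 7))
  # different subject seed gives different data around the same base truth
  sim2 <- simulate_bold(cfg, subject_seed = 8)
  expect_false(identical(sim$ts, sim2$ts))
  expect_identical(sim$truth$base_mixing_weights,
                   sim2$truth$base_mixing_weights)
})

test_that("mixing weights are probability rows with entropy in [0,1]", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_bold(cfg, subject_seed = 11)
  for (W in list(sim$truth$region_mixing_weights,
                 sim$truth$base_mixing_weights)) {
    expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
    expect_true(all(W >= 0))
  }
  expect_true(all(sim$truth$planted_entropy >= 0 &
                    sim$truth$planted_entropy <= 1))
})

test_that("membership concentration drives downstream nodal entropy", {
  # near one-hot memberships vs near uniform memberships: the edge-centric
  # pipeline must rank the uniform regions as higher-entropy
  med_ent <- function(conc) {
    cfg <- small_cfg(seed = 5, mixing_concentration = conc,
                     concentration_spread = 0)
    sim <- simulate_bold(cfg, subject_seed = 1)
    median(edge_entropy(sim$ts, k = 10, n_restarts = 5, seed = 1)$entropy)
  }
  expect_lt(med_ent(0.02), med_ent(50))
})

test_that("simulate_cohort produces a coherent manifest and truth", {
  cfg <- small_cfg(seed = 2, group_sizes = c(10, 10, 10), n_time = 60)
  cohort <- simulate_cohort(cfg)
  expect_length(cohort$ts, 30)
  expect_identical(nrow(cohort$manifest), 30L)
  expect_identical(as.character(unique(cohort$manifest$group)),
                   c("HC", "MDDNSI", "MDDSI"))
  expect_identical(dim(cohort$truth$planted_entropy), c(30L, 30L))
  expect_s3_class(cohort$subnetworks, "factor")
  # determinism
  expect_identical(cohort$manifest, simulate_cohort(cfg)$manifest)
})

test_that("cognitive score tracks planted target-subnetwork entropy", {
  cfg <- small_cfg(seed = 9, n_regions = 28, n_time = 30,
                   group_sizes = c(5, 5, 90))
  cohort <- simulate_cohort(cfg)
  target <- cohort$subnetworks == cfg$behavior_target
  ent <- rowMeans(cohort$truth$planted_entropy[, target])
  r <- cor(cohort$manifest$cognitive_score, ent)
  expect_lt(abs(r - cfg$behavior_r), 0.2)
})

test_that("planted group effect shifts planted entropy in the right direction", {
  em <- subnetwork_effect_map(28, "dorsal attention", c(MDDSI = -2))
  cfg <- small_cfg(seed = 4, n_regions = 28, n_time = 30,
                   group_sizes = c(4, 10, 10), effect_map = em)
  cohort <- simulate_cohort(cfg)
  target <- cohort$subnetworks == "dorsal attention"
  g <- cohort$manifest$group
  ent <- rowMeans(cohort$truth$planted_entropy[, target])
  expect_lt(mean(ent[g == "MDDSI"]), mean(ent[g == "MDDNSI"]))
  other <- rowMeans(cohort$truth$planted_entropy[, !target])
  expect_lt(abs(mean(other[g == "MDDSI"]) - mean(other[g == "MDDNSI"])),
            0.1)
})

test_that("simulate_expression plants recoverable signal genes", {
  target <- rnorm(50)
  ex <- simulate_expression(50, 200, 1:10, target, seed = 6)
  expect_identical(dim(ex$expression), c(50L, 200L))
  expect_identical(ex$signal_gene_ids, sprintf("g%04d", 1:10))
  expect_lt(max(abs(diag(ex$distance))), 1e-12)
  expect_equal(ex$distance, t(ex$distance))
  cors <- abs(cor(ex$expression, target))
  expect_gt(min(cors[1:10]), quantile(cors[-(1:10)], 0.95))
})

test_that("zero smooth-noise amplitude makes signal genes exact copies", {
  target <- rnorm(40)
  ex <- simulate_expression(40, 20, 3, target, noise_amp = 0, seed = 2)
  expect_equal(abs(cor(ex$expression[, 3], target)), 1, tolerance = 1e-12)
  expect_error(simulate_expression(40, 20, 25, target), "outside")
})
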