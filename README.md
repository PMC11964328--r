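# edgentropy

Edge-centric functional brain networks describe resting-state fMRI not by
the correlations between regions but by the *co-fluctuation time series* of
every region pair: with z-scored signals `z_m(t)`, the edge time series is

    e_mn(t) = z_m(t) · z_n(t),

whose time average is exactly the Pearson correlation of the pair.
Clustering the edge time series with K-means (k = 10 communities, 25
restarts, minimum within-community sum of squares) yields *edge
communities*. Mapping each region's incident edges back onto these
communities gives its participation profile

    P_ms = (1 / (N-1)) Σ_{n≠m} δ(g_mn, s),

and the **normalized nodal entropy**

    E_m = − Σ_s P_ms log2 P_ms / log2 k  ∈ [0, 1]

quantifies how evenly a region's edges are spread over communities: 0 means
all incident edges share one community (a functionally integrated node), 1
means maximal overlap across communities (a functionally segregated node).

`edgentropy` implements the full analysis pipeline built around this
statistic, as used in case–control resting-state studies of major
depressive disorder with and without suicidal ideation (groups HC, MDDNSI,
MDDSI):

* **Edge network**: z-scoring, edge time series, restarted K-means edge
  communities, nodal/global/subnetwork entropy over the 7 canonical
  resting-state subnetworks, covariate residualization (sex, age,
  education).
* **Group statistics**: Kruskal–Wallis across the three groups with BH-FDR,
  FDR-gated pairwise Mann–Whitney U post-hocs, brain–behavior Pearson
  correlations within patient groups, and the per-region
  MDDSI-minus-MDDNSI pooled-variance t map.
* **Classification**: per-fold RFE feature selection (linear SVM weights,
  one feature eliminated per step, 60 retained by default), inner grid
  search over the SVM cost, stratified 5-fold cross-validation, averaged
  accuracy/precision/recall/F1 and top-10 feature frequency.
* **Transcriptome association**: NIPALS partial least squares regression of
  a region × gene expression matrix on the t map (15 components, PLS1
  focus), significance by spatial-autocorrelation-preserving
  variogram-matched surrogates, bootstrap gene-weight Z scores, PLS1+/PLS1−
  gene sets, and permutation tests of overlap with 7 cell-type gene sets.
* **Synthetic data**: a generator planting known edge-community structure,
  per-region membership overlap (the ground-truth entropy), group effects,
  covariate leakage, behavior correlations, and spatially smooth expression
  maps with signal genes — so every stage can be validated against known
  truth.

Because the statistic is estimated per subject by an unsupervised
clustering step, none of it can be validated on real data alone; the
package treats the synthetic generator as a first-class module and ships
property-based tests for every stage.

## Worked example

```r
library(edgentropy)

cfg <- synth_config(n_regions = 30, n_time = 200,
                    group_sizes = c(15, 15, 15),
                    effect_map = subnetwork_effect_map(
                      30, "dorsal attention", c(MDDSI = -2)),
                    seed = 1)
cohort <- simulate_cohort(cfg)
tab <- cohort_entropy(cohort, k = 10, n_restarts = 25, seed = 1)
stats <- run_group_analysis(tab, behavior_columns = "cognitive_score")
print(stats)
```

```
Three-group entropy comparison (Kruskal-Wallis + BH-FDR)
                    measure      H    p_raw    p_fdr
                     global 17.758 1.39e-04 5.57e-04
                     visual  3.355 1.87e-01 3.74e-01
                somatomotor  1.888 3.89e-01 5.19e-01
           dorsal.attention 29.469 3.99e-07 3.19e-06
 salience.ventral.attention  2.445 2.95e-01 4.71e-01
                     limbic  1.276 5.28e-01 5.28e-01
     frontoparietal.control  1.384 5.00e-01 5.28e-01
               default.mode  5.623 6.01e-02 1.60e-01

Post-hoc Mann-Whitney U (measures with FDR p < 0.05):
          measure group1 group2   U    p_raw    p_fdr
           global     HC MDDNSI 106 8.03e-01 8.03e-01
           global     HC  MDDSI 209 6.84e-05 1.37e-04
           global MDDNSI  MDDSI 191 1.22e-03 1.82e-03
 dorsal.attention     HC MDDNSI 125 6.19e-01 7.42e-01
 dorsal.attention     HC  MDDSI 225 3.39e-06 1.02e-05
 dorsal.attention MDDNSI  MDDSI 225 3.39e-06 1.02e-05
```

The Kruskal–Wallis H for the dorsal attention network is large with an FDR
p far below 0.05 — the planted MDDSI entropy reduction in that subnetwork —
while the untouched subnetworks stay near their null distribution. The
post-hoc U tests localize the difference to the two MDDSI contrasts, and
global entropy moves with it (sharpening a quarter of the regions lowers
the whole-network mean). The seed reproduces this output bit for bit.

The per-subject estimator is also available directly:

```r
fit <- edge_entropy(cohort$ts[[1]], k = 10, n_restarts = 25, seed = 1,
                    subnetworks = cohort$subnetworks)
summary(fit)
coef(fit)      # per-region normalized nodal entropy
plot(fit)
```

A thin command-line wrapper for shell use lives at `inst/cli/ecn.R`
(subcommands `simulate`, `entropy`, `stats`, `classify`, `pls`, `celltype`,
`run-all`).

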