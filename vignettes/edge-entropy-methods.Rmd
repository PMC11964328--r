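---
title: "Edge-centric nodal entropy: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric nodal entropy: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(edgentropy)
```

This vignette documents the models implemented in `edgentropy`, the
parameters that matter, the design decisions that were genuinely open, and
what the synthetic validation does — and does not — establish about real
data.

## The estimator

For one subject with regional BOLD signals $X \in \mathbb{R}^{N \times T}$:

1. **Z-scoring.** Each region is standardized to mean 0, standard
   deviation 1. We use the *population* (divide-by-$T$) standard
   deviation. This is deliberate: with that convention the time average of
   every edge time series equals the Pearson correlation of the pair
   *exactly*, so the identity is an exact testable invariant rather than
   an approximation that degrades at small $T$.
2. **Edge time series.** For each pair $m<n$,
   $e_{mn}(t) = z_m(t)\,z_n(t)$: the instantaneous co-fluctuation.
   Edges are enumerated in row-major upper-triangle order throughout.
3. **Edge communities.** K-means on the raw (unstandardized) edge rows,
   Euclidean distance over time, $k = 10$ communities. Initialization is
   k-means++, iterations are Lloyd's with a 300-iteration cap; the run is
   repeated 25 times with deterministically derived restart seeds and the
   labeling with the lowest within-community sum of squares wins, ties
   going to the lowest restart index. All 25 SSE values are kept in the
   result so the min-selection protocol is auditable.
4. **Community profile and entropy.** Region $m$'s profile is the fraction
   of its $N-1$ incident edges in each community,
   $P_{ms} = \frac{1}{N-1}\sum_{n \ne m}\delta(g_{mn}, s)$; its nodal
   entropy is the normalized Shannon entropy
   $E_m = -\sum_s P_{ms}\log_2 P_{ms} / \log_2 k \in [0,1]$, with
   $0\log 0 = 0$ and $E \equiv 0$ for $k = 1$. The divisor $N-1$ is the
   number of incident edges, which is the only reading that normalizes
   $P_{m\cdot}$ to a probability vector; the normalization constant is
   $\log_2 k$ (the entropy ceiling over $k$ communities), exposed as a
   parameter for anyone wanting a different base.
5. **Aggregation.** Global entropy is the mean nodal entropy; subnetwork
   entropy is the mean over each of the 7 canonical resting-state
   subnetworks (visual, somatomotor, dorsal attention, salience/ventral
   attention, limbic, frontoparietal control, default mode).

Two conventions deserve an explicit note, since the field's descriptions
vary. First, the entropy is computed with a leading minus sign and is
normalized by $\log_2 k$ with $k$ the *community* count; both choices are
the only ones that land the statistic in $[0,1]$ with the stated
interpretation. Second, the per-region profile is taken over incident
*edges*, not over subnetworks.

### Clustering scope

Whether edge communities should be derived per subject or jointly across a
cohort is genuinely open. The default is **per subject**: each subject's
own edge time series are clustered, which needs no cross-subject alignment
of scan lengths and keeps memory bounded. A **group** scope is available
behind a flag: the edge time series of all subjects are concatenated along
time, shared centroids are estimated once, and each subject's edges are
then assigned within that subject's own time block — giving
subject-specific labels in a common community space. Entropy values are
not comparable across the two scopes; pick one per study.

### Covariate removal

Sex, age and years of education are removed by ordinary least squares.
The default mode (`features`) residualizes the subject-level entropy
features across subjects after the pipeline, which is the statistically
conventional place to adjust and keeps the per-subject clustering
untouched. A literal mode (`bold`) residualizes every (region, time point)
BOLD value across subjects before the pipeline; it requires equal scan
lengths and is provided for fidelity comparisons. Covariate columns are
centered so the returned intercept equals the feature mean — group means
are preserved when the covariates carry no group signal. Behavior scores
are never residualized.

## Group statistics

Kruskal–Wallis (tie-corrected, chi-square reference) over global plus the
7 subnetwork entropies forms one BH-FDR family of 8 tests. Only measures
passing FDR $< 0.05$ receive the three pairwise Mann–Whitney U post-hocs,
all post-hoc p values forming a second BH family. Pearson correlations
between FDR-significant subnetwork entropies and behavior scores are
computed separately within each patient group, BH-corrected within each
group's family. These family boundaries are the minimal reading of the
three-stage protocol; nothing else in the pipeline depends on them. The
Mann–Whitney implementation is exact when the smaller group has at most 8
observations and the data are tie-free, and uses the tie/continuity
corrected normal approximation otherwise.

The per-region t map that feeds the transcriptome stage is a
pooled-variance (Student) two-sample t, signed MDDSI minus MDDNSI. Welch's
variant was considered and rejected: the map's downstream use is as a
spatial pattern in PLS, where only relative values matter, and the pooled
form is the default meaning of an unqualified t statistic.

## Classification

Per outer fold of a stratified 5-fold cross-validation: RFE (linear SVM,
squared-weight importance, one feature eliminated per iteration, 60
retained by default) on the training fold; then a grid search over
$C \in \{0.01, 0.1, 1, 10, 100\}$ by inner cross-validation on the
training fold; then the final linear SVM. The held-out fold contributes
only metrics. A `global_rfe` flag reproduces the alternative protocol in
which one RFE precedes cross-validation; it leaks selection information
and is off by default. Feature importance is summarized as selection
frequency across folds, ties broken by mean absolute SVM weight and then
region index. Class weighting is off by default (a 60 vs 90 imbalance is
mild); a `balanced` flag enables inverse-frequency weights.

## Transcriptome association

PLS regression uses NIPALS with both predictor and response deflation, a
univariate response (the t map), gene columns standardized internally and
the response centered. Fifteen components are extracted; extraction stops
early if the residual cross-covariance vanishes, the remaining components
then explaining zero variance. Two per-component summaries are reported,
because "variance explained" is ambiguous for PLS: the fraction of
*response* variance explained (an $R^2$ decomposition over orthogonal
scores) and the fraction of captured squared *covariance*. PLS1 is
oriented so its region scores correlate non-negatively with the response;
scores and weights flip together, so the orientation is pure reporting
convention and is stated in the output.

Significance of PLS1 uses permutation with spatial-autocorrelation
preservation: surrogate response maps are built by permuting the map,
smoothing with an exponential distance kernel at several candidate length
scales, and matching the binned empirical variogram of the original by a
non-negative smooth + nugget mixture; the best-fitting scale per surrogate
is kept and the achieved variogram error is reported alongside. With no
distance matrix, plain permutation is the fallback. The p value is the
standard add-one estimate $(1 + \#\{\text{null} \ge \text{obs}\})/(1+B)$,
whose smallest attainable value is $1/(B+1)$.

Gene-level inference bootstraps regions with replacement, refits the first
component, sign-aligns each bootstrap weight vector to the original and
forms $Z_g = w_g / \mathrm{sd}_{\text{boot}}(w_g)$. "Strongly positive /
negative" gene sets are defined as two-sided normal $p$ from $Z$, BH-FDR
at 0.05, split by sign — both the correction and the threshold are
parameters, since different studies draw this line differently. Cell-type
enrichment compares the observed overlap of a gene list with each of 7
cell-class sets against overlaps of random same-size lists from the
background universe, BH-corrected across the 7 classes.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, and its defaults
define the validation conditions: 440 time points per subject and a
98/60/90 HC/MDDNSI/MDDSI design mirror the motivating study; the desk
scale of 50 regions (rather than a 200-parcel atlas) keeps a full
validation run in minutes.

Each region $r$ mixes $L = 4$ latent module signals,
$x_r(t) = \sum_s \tilde w_{rs} c_s(t) + \varepsilon(t)$. The scan is split
into $n_{\text{states}} = 4$ equal blocks; in block $b$, module $b$ runs
at amplitude 2, is correlated 0.3 with its successor module, and the
others idle at amplitude 0.15. This "one module bursts per state" design
is what makes K-means edge communities informative about membership: an
edge co-fluctuates in block $b$ only to the extent that *both* endpoints
load on module $b$, so the block-activity pattern of a region's edges —
and hence the spread of its profile over communities — grows with the
evenness of its own membership vector. (An earlier draft that switched
random full correlation matrices between states produced the opposite
mapping: mixed regions' edges all resembled the average pattern,
collapsed into one cluster, and scored *lower* entropy than one-hot
regions. That draft was discarded; the failure is worth recording because
it shows the entropy statistic is only as interpretable as the community
structure underneath it.)

Membership is hierarchical. A **base** mixing matrix is drawn once per
configuration: region $r$ gets a Dirichlet row with its own concentration
$\alpha_r = \alpha\,e^{U(-1.5, 1.5)}$ (median $\alpha = 0.5$), giving a
realistic spread from strongly unimodal to evenly mixed regions, and rows
are relabeled so dominant modules cycle round-robin — chance module
imbalance otherwise makes some draws much harder to recover. Each
**subject**'s rows are Dirichlet perturbations of the base with precision
20. In the signal path rows are L2-normalized so every region has the same
SNR (observation noise sd 0.25); the truth record keeps the simplex rows
and their normalized entropy — the planted nodal entropy. Group effects
temper targeted regions' base rows ($w^{e^{-\delta}}$: negative $\delta$
sharpens, lowering entropy); covariates leak weakly (coefficient 0.02)
into signal amplitude so residualization is exercised; a synthetic
cognitive score is built to correlate at $-0.5$ with the planted dorsal
attention entropy. Temporal autocorrelation of real BOLD is not asserted:
an AR(1) coefficient is available and defaults to 0.

Gene expression places regions uniformly in a unit cube, draws smooth
spatial fields from an exponential-kernel Gaussian process (length scale
0.3), and adds the (standardized) target map to 10 of 200 signal-gene
columns at smooth-noise amplitude 0.5; all columns are standardized and
the Euclidean distance matrix is returned for the surrogate machinery.

### What the validation shows, and what it does not

With these defaults the pipeline's estimated nodal entropy, averaged over
six subjects, recovers the planted base entropy at Spearman $\rho
\approx 0.83$–$0.93$ across generator seeds; null cohorts produce
FDR-significant group differences at well under the nominal rate; planted
subnetwork effects of tempering magnitude 2 are detected in essentially
every replicate; and 10-of-200 planted signal genes are recovered through
the bootstrap-Z gene sets. These checks validate the *implementation* and
the *statistical protocol*. They do not show that real fMRI has
four-module block structure, nor that real nodal entropy differences of
clinical size are detectable at these sample sizes — real data carry
temporal autocorrelation, motion artifacts, inter-regional SNR
differences and parcellation error that the generator deliberately omits.
Headline numbers from any particular clinical study (classification
accuracies, gene-set sizes, variance fractions) depend on restricted data
and are not reproduction targets of the synthetic validation.

## Numerical choices and degenerate inputs

* K-means ties across restarts: lowest restart index wins (determinism).
* Restart seeds, subject seeds and stage seeds derive from one master seed
  by a fixed affine map into 32-bit range; identical configurations
  reproduce bit-identically.
* Constant regions, constant genes, rank-deficient covariate designs and
  empty subnetworks are errors that name the offending unit.
* All-tied Kruskal–Wallis input returns $H = 0$, $p = 1$.
* Degenerate bootstrap resamples (constant response or gene) are redrawn
  and counted.
* $k = 1$ entropy is defined as 0; $k > E$ and empty inputs are errors.

## Problem sizes used in the shipped checks

Unit and property tests run at 10–30 regions and 60–200 time points. The
entropy-recovery check runs the full default configuration (50 regions,
440 time points, 25 restarts, six subjects). Calibration and power checks
use 20 replicate cohorts of 15 subjects per group at 30 regions and 200
time points with 5 restarts; permutation calibration uses 50 replicates at
200 permutations. These sizes were chosen so that a complete validation
pass stays within a coffee break while leaving every acceptance margin
wide; scaling any of them up only tightens the Monte-Carlo error.

## Known limitations

* Entropy values depend on $k$ and on clustering scope; comparisons are
  only meaningful within one protocol.
* The group clustering scope loads all subjects' edge series at once;
  at atlas scale (200 parcels, $\sim$20k edges) this is memory-hungry.
* The variogram surrogate generator assumes an isotropic exponential
  correlation family; strongly anisotropic spatial structure would be
  matched only approximately (the achieved variogram error is reported).
* Exact Mann–Whitney p values are only used for tie-free small samples;
  entropy features are continuous, so ties essentially never arise there.
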