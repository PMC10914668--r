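---
title: "Methods: receptor-affinity fingerprints, clustering, and predictive validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-affinity fingerprints, clustering, and predictive validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apclust)
```

## The problem

Antipsychotic drugs are usually sorted into coarse categories
(typical/atypical, or expert nomenclatures such as NbN) that map poorly onto
either their pharmacology or their clinical behaviour. `apclust` implements a
data-driven alternative: describe each drug by its *receptor fingerprint* —
the vector of its binding affinities across several dozen receptors — group
drugs by fingerprint similarity, and then ask, quantitatively, how well any
grouping scheme predicts a drug's clinical effect profile out of sample.

The pipeline has five stages, each exposed as ordinary functions:

1. **Ingest** — published Ki binding records are filtered to human-tissue
   assays, replicate measurements of a (drug, receptor) pair are collapsed to
   their median Ki, sparse drugs/receptors are removed, and Ki is converted
   to pKi (`9 - log10(Ki[nM])`).
2. **Preprocess** — pKi is floored (default floor 4, the bottom of the
   measurable range, so the weakest affinity scores 0) and affinities at
   sites where the drug is an agonist or partial agonist are multiplied by
   −1, since agonism is functionally opposite to antagonism at the same
   receptor.
3. **Impute + embed** — probabilistic PCA fitted by EM over the observed
   cells fills the missing entries and provides latent component scores and
   receptor loadings.
4. **Cluster** — drugs are Pearson-correlated across receptors; the
   correlation matrix becomes a weighted graph that Louvain modularity
   maximization partitions into clusters.
5. **Predict** — any predictor set (one-hot categories or the full
   fingerprint) is scored by leave-one-drug-out partial least squares
   prediction of the 16 clinical effect scores, summarized by the median of
   per-drug median absolute errors, with significance from a permutation
   null.

## Models and estimators

### Probabilistic PCA with missing entries

The model is the standard latent linear-Gaussian factor model with isotropic
noise: `x = mu + W z + eps`, `z ~ N(0, I_q)`, `eps ~ N(0, sigma2 I)`. With
incomplete rows the observed-data likelihood factorizes over each row's
observed coordinates, and `fit_ppca()` runs the exact EM for that incomplete
likelihood: the E-step computes each row's posterior over `z` from its
observed coordinates only; the M-step solves a joint `(mu_j, W_j)` linear
system per receptor over the rows observing it, then updates `sigma2` from
the expected squared residual over observed cells. Because the M-step is
exact, the observed-data log-likelihood is non-decreasing — this is asserted
in the tests, not assumed.

Numerical choices:

* **Initialization** is the SVD of the column-mean-imputed matrix
  (deterministic); a seeded random initialization is available. The seed is
  consumed either way so identical calls are bit-identical.
* **Convergence**: relative log-likelihood change below `tol` (default
  `1e-6`), at most 1000 iterations; `sigma2` is floored at `1e-12` so
  noiseless data cannot produce a degenerate covariance.
* **Rotation and signs**: the EM loading matrix `W` is only identified up to
  rotation, so the model stores the SVD-rotated orthonormal axes, ordered by
  singular value, with each axis flipped so its largest-magnitude loading is
  positive. Without this convention component outputs would change sign from
  run to run.
* **Imputation rank `q`**: the component count used for imputation is a free
  parameter; the pipeline default is `q = 5` — at least the 3 components that
  are interpreted downstream, plus slack, while remaining far below the drug
  count. Cluster assignments on well-separated data are insensitive to `q`
  in the 3–8 range, which can be checked by re-running `run_all()` with a
  different `q_ppca`.
* **Variance explained** is computed from the eigen-spectrum of the
  covariance of the *completed* matrix, so the fractions over all components
  sum to 1 and the "top-3 share" has an unambiguous denominator.

A single PPCA fit serves both imputation and characterization; refitting on
the completed matrix changes the leading axes negligibly on data with a real
low-rank structure and would add a second arbitrary choice.

### Correlation graph and Louvain clustering

Pearson correlation across receptors is location- and scale-invariant per
drug, so overall potency differences (equivalently, dosing differences)
cancel and only the *shape* of the fingerprint matters. Modularity expects
non-negative weights while correlations may be negative; the default policy
(`clip_zero`) sets negative similarities to zero weight — a negative
correlation carries no attractive force, but is not treated as evidence for
any particular community. `shift_min` and `abs` are provided for sensitivity
analysis and the chosen policy is recorded in the run manifest.

`louvain_partition()` restarts the heuristic over `n_restarts = 100` seeded
node orders and keeps the best modularity, breaking exact ties by the
lexicographically smallest canonical assignment vector; clusters are
relabeled by decreasing size (ties by smallest member name). On graphs small
enough to enumerate (`n <= 8`) the restart protocol attains the brute-force
optimal modularity in essentially every trial — the test suite checks 100
random graphs. Modularity itself (`modularity_q()`) is evaluated directly
from `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`, including
the `i = j` degree terms, so the all-in-one partition scores exactly 0; the
community-detection backend is cross-checked against this formula rather
than trusted.

### Leave-one-out PLS and the permutation null

For every held-out drug, a NIPALS PLS2 model is fitted on the remaining
drugs: missing clinical values are PPCA-imputed *within the training fold
only*, predictors and targets are centered and unit-scaled *within the
fold* (clinical effects arrive on heterogeneous scales — standardized
magnitudes and relative risks), and the held-out drug's 16 effect scores are
predicted. The drug's error is the median absolute error over its *observed*
effects only — imputed values are never scored against. The scheme's summary
is the median of per-drug medians, robust in both directions.

Choices worth knowing:

* **`n_components = 2`** by default, capped per fold at
  `min(D, n_train - 1)`. With 3–7 one-hot predictors and ~26 training rows,
  small component counts are the only defensible region; results for
  components 1–3 can be compared by rerunning. Constant predictor columns
  (e.g. a category emptied by the held-out fold) get zero weight rather than
  breaking the scaling.
* **Full-rank behaviour**: with as many components as the predictor rank,
  PLS predictions coincide with ordinary least squares; the tests verify
  this against a normal-equations oracle, and one-hot predictors with
  group-constant targets give exactly zero leave-one-out error.
* **Permutation null**: within each null replicate the training rows of X
  are shuffled against Y (a fresh permutation per fold; a single global
  shuffle per replicate is available via `shuffle = "global"`), the full
  leave-one-out summary is recomputed, and
  `p = (1 + #{null <= observed}) / (1 + n_perm)` — the add-one estimator,
  strictly positive, with ties counted against the observed statistic.
  Under a no-signal null the test is calibrated: across 200 independent
  replicates the rejection rate at `alpha = 0.05` sits at 5% within
  binomial error (checked in the acceptance tests at `n_perm = 99`).
  Because training-fold imputation depends only on Y, each fold's imputed
  training targets are computed once and reused across replicates — an
  exact optimization, not an approximation.

## The synthetic-data generator

`generate_synthetic()` emulates the four real inputs — Ki records, agonism
flags, clinical scores, grouping schemes — from a planted truth:

* **Cluster geometry.** Every cluster center is a constant weak-binding
  baseline plus a bump on the cluster's own disjoint block of up to 5
  signature receptors. The bump height is `separation * noise_sd`, so
  `separation` is the standardized per-receptor contrast between a cluster
  and the rest at its signature sites. The constant baseline contributes no
  across-receptor variance, which matters because the pipeline's similarity
  is the Pearson correlation across receptors: any shared non-constant
  baseline would inflate all pairwise correlations and mask the planted
  structure. Disjoint blocks make all between-center relations identical
  (a simplex-like layout), so `separation` has a single meaning.
* **Agonism.** With probability `agonist_fraction` a cluster's signature
  bump is negated — the cluster behaves as an agonist at its own signature
  receptors, as dopamine partial agonists do at D2. Because blocks are
  disjoint this leaves the between-cluster geometry unchanged, and the
  planted sign structure round-trips exactly through the floor/inversion
  preprocessing.
* **Records.** Each observed cell emits `records_per_cell` replicate Ki
  measurements scattered log-normally around the cell's true Ki, so median
  aggregation is exercised on the Ki scale; a fraction of cells also emit a
  rat-tissue distractor record, exercising the human-tissue filter.
* **Missingness** is MCAR, rejection-sampled to keep every drug and
  receptor above a minimum observation count. Real binding databases are
  missing *not* at random (research interest drives which assays exist);
  that mechanism is out of scope, so passing tests demonstrate correctness
  of the machinery under MCAR, not robustness to informative missingness.
* **Clinical effects** are a linear function of cluster membership (or,
  optionally, of the full fingerprint) plus Gaussian noise with sd
  `effect_noise_sd`, with per-cluster coefficients drawn at sd
  `group_effect_sd`.

The canonical study conditions (`study_shaped_fixture()`) are 27 drugs, 42
receptors, 4 clusters, 16 effect columns, separation 8, within-cluster noise
sd 0.5, 20% affinity missingness, 10% clinical missingness, 3 replicate
records per cell, and a per-row/column observation minimum of 5 so the
assembled matrix survives the default inclusion filters. Under these
conditions the pipeline recovers the planted partition exactly (ARI = 1)
and the planted grouping's permutation p-value at `n_perm = 500` reaches
the add-one minimum.

## Degenerate inputs and tie-breaking

* Receptor columns that are constant across observed drugs are removed at
  ingest (they carry no information); with a noise-free generator the
  baseline receptors are constant by construction, so round-trip checks
  disable that filter explicitly.
* The inclusion filters run once, in the stated order (receptors, then
  drugs, then constant columns); a `cascade = TRUE` flag iterates them to a
  fixed point for data where removals interact.
* A similarity matrix whose off-diagonal entries are all negative clips to
  an empty graph under the default policy and is a hard error, not a
  silent single cluster.
* Drugs with zero variance across receptors make Pearson correlation
  undefined and are reported by name.
* A held-out drug with no observed clinical effects is excluded from the
  error summary with a warning.

## Problem sizes used in the test suite

Unit and acceptance tests run on deliberately small problems: PPCA oracles
at 40–60 rows, the Louvain brute-force comparison on graphs of 4–8 nodes
(set partitions enumerated exhaustively), permutation calibration on 14
drugs x 4 effects with `n_perm = 99` over 200 replicates, and the
end-to-end recovery run at the canonical 27 x 42 shape with
`n_perm = 500`. These sizes were chosen to make every expected value either
closed-form, enumerable, or a tight simulation envelope.

## Known limitations

* Partial and full agonists are a single binary flip; graded intrinsic
  activity is not modeled, mirroring the binary annotation of the input
  tables.
* MCAR-only synthetic missingness (above).
* The clustering depends on the negative-correlation policy in principle;
  on well-separated data all three policies agree, but on weakly structured
  real data the policy (recorded in the manifest) should be varied.
* No consensus clustering across seeds: the restart protocol reports the
  single best-modularity partition.
* Clinical scores are consumed as given; their derivation (and any dosing
  confounds baked into them) is outside the package's scope.
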