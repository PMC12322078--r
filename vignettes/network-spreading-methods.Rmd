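---
title: "Methods: connectome-based spreading analysis of atrophy"
author: "atrophynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based spreading analysis of atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophynet)
```

This vignette is the package's account of its models and numerical
choices: what each stage assumes, which knobs matter, what the synthetic
generators emulate (and deliberately do not), and where the design was
genuinely open and a choice had to be made.

## Normative w-scores

Deformation-based morphometry yields a per-voxel value on a
Jacobian-determinant scale; values below the control expectation indicate
tissue loss. The normative model is an ordinary least squares fit of
control values on age, sex (0/1), and an intercept, estimated separately
within each imaging-site stratum. A subject's w-score at a voxel is

w = (observed − expected) / sd(control residuals),

multiplied by −1 so that larger values mean more atrophy. Site handling
deserves a note: the expectation formula itself carries no site term, yet
w-scores must be adjusted for site; fitting one model per site stratum
reconciles the two, since each stratum gets its own intercept, slopes, and
residual scale. The residual SD uses the n−1 divisor, which makes the
control w-scores have exactly mean 0 and SD 1 per voxel — a property the
tests assert at machine precision. Voxels whose controls fit exactly
(residual SD 0) are flagged degenerate and propagate `NA` rather than
infinities. The tract-level test is one-sample by default (subject tract
means against 0), because w-scores already encode deviation from the
control norm; a two-sample patients-versus-controls variant is exposed for
users who prefer the other reading.

## Disease exposure and the dual-ranking epicenter

Exposure of parcel *i* is the edge-weighted mean atrophy of its directly
connected neighbours, `D_i = (1/C_i) Σ_j d_j c_ij`. Two exact properties
pin the implementation down: uniform atrophy gives uniform exposure, and
exposure is linear in the atrophy map. Parcels left with no edges after
thresholding are excluded pairwise (`NA`) rather than imputed.

The dual-ranking epicenter likelihood averages a parcel's ascending rank
in atrophy with its ascending rank in exposure, with average ranks on
ties; "ascending" is oriented so that larger atrophy earns a larger rank,
making a larger mean rank mean "more epicenter-like". The statistic is
therefore invariant to positive affine transforms of the atrophy map and
to uniform rescaling of the weights.

For similarity networks (built by correlating parcel feature profiles,
Fisher r-to-z transformed with clipping at ±(1 − 10⁻⁷)), negative entries
are excluded — set to zero — before any spreading statistic. The
two-regressor comparison asks whether a second connectome's exposure adds
predictive value for atrophy beyond the structural connectome's, measured
as the gain in adjusted R². Its null regressor must have "the same spatial
organization" as the real second regressor; the package realizes this by
spin-rotating the atrophy map and recomputing exposure under the second
network, which preserves both the map's autocorrelation and the network's
smoothing while destroying the alignment. That is one specific reading of
an underdetermined requirement, and it is deliberately the most
conservative one available here.

## The agent-based SIR model

The propagation model follows the agent-based
susceptible-infected-removed family used for misfolded-protein spread.
Per time step and region: normal agents are synthesized (one binomial
trial per region-size unit, probability `synthesis_rate`); normal and
misfolded agents are cleared at `clearance_normal` and
`clearance_misfolded`; each remaining normal agent misfolds with
probability `1 − (1 − trans_rate)^density`, where density is the region's
misfolded count per size unit; every agent relocates with probability
`mobility` to a neighbour chosen proportionally to edge weight; and
atrophy accrues as `k1` times the region's misfolded fraction plus `k2`
times the weighted mean of the neighbours' previous-step atrophy increment
(deafferentation), cumulatively capped at 1. Atrophy is cumulative by
construction — monotone non-decreasing in time — which is the readout used
throughout; an instantaneous-burden readout can be reconstructed from the
stored trajectories if needed.

The published description of this model family leaves the exact update
equations and rate values to supplementary material; every rate is
therefore exposed in `sir_params()` and the defaults are package choices,
set by timescale reasoning for unit region sizes and to be treated as
placeholders for any empirical application: synthesis 0.5 against
clearance 0.05 equilibrates at about ten normal agents per region;
misfolded clearance 0.05 gives a twenty-step lifetime during which an
agent migrates about once (mobility 0.05); conversion scale 0.02 makes
local takeoff outpace clearance once a handful of misfolded agents
arrive; and atrophy weights k1 = k2 = 0.01 let an infected region reach
full atrophy over roughly a hundred steps, so that arrival-time ordering
remains visible in the map. Simulations run over 10,000 steps by default;
the desk-scale experiments below use 500-step horizons on 100-parcel
networks, where the epidemic sweeps the network within a few hundred
steps.

Seed inference runs the model from every candidate seed and takes the
maximum over time of the Pearson correlation between simulated and
observed atrophy; steps with zero variance in the simulated pattern
(before spreading starts in earnest, or after full saturation) are
skipped, not scored as zero. Candidate seeds use consecutive RNG seeds so
any single simulation can be reproduced in isolation. The whole
trajectory machinery is implemented in C++ over R's own RNG, so runs are
bit-reproducible and an agent ledger (change in totals = synthesized −
cleared) holds exactly.

## Null models and p-values

Three complementary nulls are provided. Spin surrogates rotate the
spherical parcel centroids by a uniformly random rotation (normalized
quaternions) and reassign each parcel the value of the nearest rotated
centroid; masked parcels are never donors, with assignment falling to the
next closest parcel. Nearest assignment can duplicate or drop values but
preserves the value multiset and the map's spatial smoothness — the tests
check the binned variogram of surrogates against the original. Degree-
preserving rewiring performs Maslov-Sneppen double-edge swaps with weights
travelling on their edges (10 attempted swaps per edge); the binned
variant additionally constrains both replacement edges of a swap to the
original edges' Euclidean-distance bin (10 equal-count bins by default,
equal-width optional; number-of-regions × 20 attempted swaps), preserving
per-bin edge counts exactly.

All nonparametric p-values use the add-one convention
`p = (k + 1)/(n + 1)`, with non-strict exceedance; at 1000 surrogates and
zero exceedances this floors at 1/1001 ≈ 9.99 × 10⁻⁴. Two-sided p-values
count exceedances in absolute value about a configurable center
(default 0). Multiple testing uses Benjamini-Hochberg throughout, via
`stats::p.adjust`.

## Behavioural PLS

The cross-covariance of column-standardized brain and behaviour matrices
is decomposed as `X'Y = USV'`; covariance explained is `s_k²/Σs²`, and
subject scores are projections onto the singular vectors. Whether columns
should be centred or z-scored before the decomposition is not determined
by the formulation; the default is z-scoring (so measures on different
scales contribute comparably), with centring and raw options exposed.
Singular-vector signs are fixed deterministically (largest-magnitude brain
weight positive). Significance permutes the rows of X (1000 by default)
and compares singular values at matched indices; bootstrap ratios divide
each original weight by its bootstrap SE, with resampled vectors
sign-aligned to the originals by correlation — a deliberate simplification
(no Procrustes rotation), adequate for the first latent variable and
noted as a limitation for deeper ones. Split-half cross-validation
projects held-out subjects onto training weights and correlates their
scores; its permutation null re-runs the entire split procedure on
row-shuffled X, with 100 splits and 100 permutations by default.

## Gene category enrichment

Genes below a differential-stability threshold (default 0.1) are removed;
duplicate symbols are averaged before correlation. Each surviving gene's
parcel-wise expression is Pearson-correlated with the phenotype and
Fisher-z transformed; a category's c-score is the mean over member genes.
Significance compares each c-score against the same statistic computed on
spin-surrogate phenotypes — 1000 by default rather than the tens of
thousands used at publication scale, since the add-one convention keeps
p-values valid at any ensemble size and c-score rankings are null-free.
The surrogate generator here is the centroid-rotation spin with nearest
assignment; without-replacement reassignment variants exist in the
literature and are approximated, not reproduced, by this choice.

## The synthetic generators and what passing tests mean

The generators plant known ground truth in data with the same statistical
shape as the real inputs:

- `make_spatial_connectome()` samples parcel centroids uniformly on the
  unit sphere and connects them with probability decaying exponentially in
  centroid distance (rescaled to hit the target density), log-normal
  weights, regenerating until connected. The sphere stands in for the
  cortical sheet so that spin tests are exact rotations of the embedding;
  there is no medial wall by default (a mask argument exists).
- `make_planted_atrophy()` spreads unit mass from the seed with a lazy
  random walk `((I + P)/2)^k`, k = 3, mixes it with the seed indicator,
  and adds Gaussian noise. The lazy walk (rather than the bare `P^k`) is a
  deliberate choice: it guarantees the seed retains at least `2^-k` of the
  mass, so the noiseless map always peaks at the seed regardless of the
  network's local structure, keeping "the seed is the maximum" an exact
  property rather than a usually-true one. The diffusion profile is
  rescaled to unit maximum before mixing so that `noise_sd` is
  interpretable relative to peak atrophy; at the defaults
  (`spread_weight` 0.7, `noise_sd` 0.1) roughly a tenth of the peak signal
  is noise — enough to make recovery nontrivial, not enough to drown the
  network structure.
- `make_voxel_cohort()` draws ages from N(57, 10), balances sexes with a
  random assignment (so sex is never confounded with the round-robin site
  assignment), gives each site its own intercept, and subtracts the
  atrophy effect from patients on the Jacobian scale.
- `make_clinical_latent()` gives each subject two unit-variance latent
  scores with correlation `latent_corr`; brain maps load on a fixed
  unit-norm parcel pattern scaled by the first, clinical measures on a
  unit-norm measure pattern scaled by the second, plus featurewise noise
  (`noise_sd`, default 0.1). Writing the planted coupling as a latent
  correlation — rather than shrinking the behaviour loadings — makes
  `latent_corr` itself the population brain-behaviour score correlation,
  so cross-validated score correlations estimate the planted value
  directly (at the defaults the attenuation from featurewise noise and
  weight estimation is a few percent).
- `make_expression_atlas()` builds background genes from a shared low-rank
  basis of smooth isotropic fields (so each is spatially autocorrelated,
  with positive Moran's I) and planted genes as
  `a·phenotype + √(1−a²)·noise`; differential stability is assigned so 30%
  of background genes fall below the 0.1 filter while planted genes always
  survive it.

Every generator is a pure function of its configuration and seed.

What passing tests do and do not show: the synthetic world is isotropic,
stationary, and Gaussian. Real cortical geometry is a folded sheet with a
medial wall, atrophy effects are not homoscedastic across sites, clinical
measures are bounded and skewed, and expression data carry donor- and
batch-structure that no low-rank field reproduces. Recovery and
calibration results on these generators validate the machinery — the
statistics, the nulls, the bookkeeping — not the biological fidelity of
any particular empirical finding.

## Numerical choices and degenerate inputs

Correlations are clipped at ±(1 − 10⁻⁷) before `atanh`; constant vectors
are an error for correlations, an `NA`-with-warning for similarity rows
and gene maps. Rank ties take average ranks. The all-tied epicenter input
is detected with a tolerance (10⁻¹⁰ relative) because uniform atrophy
yields exposure uniform only up to floating-point summation order.
Zero-variance columns under z-scoring are an error naming the column;
bootstrap resamples that produce one are redrawn (bounded retries).
Isolated parcels cannot be atrophy seeds, and a disconnected SIR seed with
positive mobility warns that no spread is possible.

## Problem sizes

The recovery and calibration experiments in the tests and the acceptance
script use desk-scale sizes chosen to make the checks sharp but cheap:
200-parcel networks with 50 replicates for dual-ranking recovery,
100-parcel networks with 500-step simulations and 25 replicates for SIR
recovery, 1000 runs of a 99-spin test for calibration, and 100 cohorts of
150 subjects for PLS. These sizes are the package's own choices; all of
them scale up by argument.

## Known limitations

Voxel-level inputs are consumed as flat matrices (or parcel-level
matrices); NIfTI ingestion is left to `RNifti`/`oro.nifti` upstream of the
cohort container. The SIR defaults are not fitted to any dataset. Spin
surrogates assume parcels cover the sphere roughly evenly; strongly
clustered centroids degrade the nearest-assignment approximation. PLS
bootstrap sign alignment is per-vector, so latent variables beyond the
first may be unstable under resampling when singular values are close.
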