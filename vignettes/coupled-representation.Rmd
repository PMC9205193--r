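---
title: "Two-level coupled feature representation: model, parameters and design choices"
author: "netCFM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level coupled feature representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netCFM)
```

# The problem and the model

Gray-matter atrophy in Alzheimer's disease is not a collection of
independent regional changes: regions inside the same structural network
covary, and networks change together. netCFM represents a two-group
cohort's ROI-level gray-matter features so that both kinds of dependence
become explicit classifier inputs.

The data model is a `RoiFeatureSet`: `M` subjects by `N = n * L` ROI
features, each feature assigned to one of `L` networks (exactly `n` per
network), a two-level group factor, and an `M x L` matrix of network-level
features. When features are derived from voxel data the network-level
feature is the mean gray-matter value over the network mask, which is why
it is stored rather than recomputed from the ROI columns.

## Intra-network coupling

Within one network, each scaled feature is expanded to its integer powers
`1..E1`, and all pairwise Pearson correlations between expanded columns are
computed. A correlation whose two-sided p-value — from the exact
t-transform `t = r sqrt((M-2)/(1-r^2))` with `M - 2` degrees of freedom —
exceeds 0.05 is revised to exactly zero, so only statistically supported
interactions survive. For feature `k` the `E1 x E1` matrix `R_intra(k)`
collects the correlations among its own powers, and the
`E1 x (E1 (n-1))` matrix `R_inter(k)` those with the other features'
powers. The coupled vector is

$$u_i^{(l)}(k) = (x^{intra}_i \odot \omega)\, R^{intra}(k)^\top +
  (x^{inter}_i \odot [\omega, \ldots, \omega])\, R^{inter}(k)^\top,
  \qquad \omega = (1/1!, \ldots, 1/E_1!),$$

i.e. elementwise Taylor-like damping of the expanded powers followed by a
vector–matrix product. That reading of the composition of the two products
is the only dimensionally consistent one, and the test suite pins it with
a naive triple-loop reference implementation. Blocks from different
networks are built independently — a property the suite checks by
perturbation — and concatenate to `U` (`M x N E1`). With `E1 = 1` the
construction short-circuits to the scaled original features: a single
power with self-correlation 1 carries no interaction information.

## Inter-network coupling

Between every pair of networks, canonical correlation analysis on the two
ROI blocks summarises how strongly the networks covary. The canonical
correlations are computed from the singular values of the whitened
cross-covariance $S_{11}^{-1/2} S_{12} S_{22}^{-1/2}$; each within-block
covariance receives a ridge of `1e-8` times its average variance, which
keeps the computation stable for nearly collinear blocks while preserving
invariance under affine transforms of a block (an absolute ridge would
not). Correlations are clipped to `[0, 1]` and sorted descending; the top
`E2` are retained, zero-padded (with a warning) when fewer than `E2`
exist, so over-asking never fabricates signal.

The network-level inter-coupled feature sums, over the other networks and
powers `1..E2`, the scaled network feature's powers damped by `1/e!` and
weighted by the retained correlations. The original expression for this
quantity admits two readings (with or without power expansion of the
network features); the implemented one parallels the ROI-level formula,
uses all `L - 1` pairs involving the target network, and is pinned by its
own naive-loop oracle. A network's own summary value never enters its own
column.

## Classification

The four benchmark designs are `OFM_ROI`, `OFM_network`, `CFM_ROI`
(whole brain treated as a single network block) and
`CFM_network = [U, f]`. Classification is block-wise AdaBoost: one
sample-weighted linear SVM per block in fixed order (networks ascending,
inter block last — one pass by default, so `L + 1` base learners for
`CFM_network`), weighted training error clipped to
`[1e-10, 1 - 1e-10]`, vote weight `alpha = log((1-eps)/eps)/2` and zero
vote whenever `eps >= 0.5`. Ties in the final weighted vote go to the
patient class, so a completely uninformative ensemble degrades loudly
(all-positive predictions plus a warning), not silently.

No installed SVM implementation accepts per-sample case weights, so the
base learner is an in-package primal solver: L2-regularised squared-hinge
loss (`C = 1` by default), minimised by BFGS from a zero start. The
squared hinge makes the objective differentiable, and the deterministic
start makes refits bit-reproducible — which the AdaBoost reweighting
scheme and the leakage tests both rely on. A resampling realisation of
AdaBoost was rejected for the same reason.

# Evaluation protocol

`evaluateCV` runs stratified `k`-fold cross-validation (default 10).
Within each fold the scaling parameters, coupling weights, canonical
correlations and the ensemble are fitted on the training rows only and
applied to the held-out rows; min-max scaling is deliberately not clipped
on held-out data, so test values may fall outside `[0, 1]`. The
alternative whole-data fitting is available as
`fitPolicy = "transductive"` because the original protocol for fold
handling is not recorded; the leakage-safe policy is the default. The
`(E1, E2)` grid spans `{2,3,4} x {1,...,5}`; the expansion order is capped
at 6 because `1/E1!` damping makes higher powers numerically irrelevant.
Accuracy, sensitivity and specificity use the patient group as the
positive class.

# Network extraction from voxel data

The voxel-mode pipeline mirrors source-based morphometry: the number of
components is chosen by the eigenvalue-based minimum description length
criterion computed on the subjects-by-subjects covariance spectrum with
voxels as observations (the trailing eigenvalue is dropped because row
centering consumes one degree of freedom); spatial ICA then unmixes the
whitened data. The fixed-point iteration uses the cubic (kurtosis)
contrast with symmetric decorrelation, tolerance `1e-6` and at most 1000
iterations with up to five seeded restarts. The cubic contrast was chosen
after the tanh contrast proved to oscillate indefinitely on
sparse disjoint-support sources of the kind the generator produces; when
the iteration still stalls, a near-converged attempt (residual below
`1e-3`) is accepted with a warning, while a large residual — typical when
`K` under-counts genuinely present components and the solution manifold is
degenerate — raises an error rather than returning an arbitrary rotation.
Source maps are z-scored, sign-fixed to nonnegative skewness, binarised at
`z >= 3`, and each surviving component contributes its top 3 atlas regions
by in-mask voxel count ("cluster size" is read as region overlap, not 3D
connected components, because the toy atlas is label-based). Component
relevance is decided by pooled-variance two-sample t-tests on the mixing
coefficients at a Bonferroni-corrected 0.05.

# The synthetic generator

Feature mode draws each network's ROI block from an equicorrelated
Gaussian (correlation `rho`, marginal sd `noiseSd`), independent across
networks — the simplest structure in which same-network regions share
covariate information and different networks do not. Affected networks
lower the patient group's mean by `effectSize * noiseSd` (atrophy) and may
change its within-network correlation by `rhoShift`, a coupling-borne
signal invisible to per-feature mean tests. Network features are exact ROI
means. Voxel mode plants each network as a contiguous component spanning
`n` atlas regions, with a linear amplitude ramp inside every region so
that each region contributes supra-threshold voxels after z-scoring;
subject maps are mixing coefficients (`N(1, mixingSd^2)`, shifted by
`effectSize * mixingSd` for patients on affected networks) times component
maps plus Gaussian voxel noise. All randomness flows from one root seed
through fixed per-operation sub-streams, so feature and voxel outputs are
independently reproducible.

Default conditions (40 + 40 subjects, 4 networks of 3 regions and 50
voxels each, `mixingSd = 0.5`, voxel noise sd 0.1, planted shift `d = 2`)
describe a cohort in which between-subject network variation clearly
dominates measurement noise — the regime in which MDL and ICA are
consistent, and a reasonable idealisation of smoothed gray-matter maps.
The recovery tests run 20 seeds at exactly these conditions. The
representation-comparison tests use 60 + 60 subjects with a modest shift
(`d = 0.5`) plus a correlation increase (0.5 to 0.8) on three of four
networks, chosen so that the group difference lives substantially in
network-level structure rather than in single-feature means — the setting
the two-level representation is designed for. Chance-level behaviour is
verified on label-shuffled data at 15 + 15 subjects over 20 seeds.

What the generator does not emulate: spatial smoothness and scanner
effects, non-Gaussian tails, unequal network sizes, registration error,
site batch structure. Passing tests therefore demonstrate correctness of
the computation and sane statistical behaviour under the assumed model,
not clinical performance; accuracies on real cohorts depend on structure
this model deliberately omits.

# Numerical choices and degenerate inputs

* Constant feature columns scale to 0.5 and are flagged; their expanded
  powers have zero variance, and all their coupling weights are zeroed
  (the intra diagonal stays 1: a feature is perfectly self-coupled).
* Correlation revision compares the exact t-transform p-value with 0.05;
  revised entries are exactly 0, not small.
* CCA requires `M > max(n1, n2) + 1` subjects and errors otherwise.
* MDL errors on constant or (near-)rank-1 input rather than returning a
  meaningless order; eigenvalues are floored at machine precision relative
  to the largest.
* Ranking ties in region selection break by ascending region id; grid
  ties break toward smaller `E1`, then smaller `E2`.
* Degenerate t-tests (zero within-group variance) surface as errors naming
  the component.

# Problem sizes in the test suite

The suite exercises the oracle equivalences on over a hundred random
small instances (`M <= 20`, `n <= 4`, `E1 <= 4`, `E2 <= 3`), the recovery
and calibration simulations on 20 seeds each at the conditions above, and
the representation comparison on 10 seeds of the 60 + 60 cohort; the
whole suite and the acceptance script each complete in a few minutes on a
single CPU. These sizes were chosen as the smallest at which the
statistical assertions have comfortable margins.

# Known limitations

* The coupled features are deterministic transforms with pooled
  (training-fold) weights; a pure correlation difference between groups
  shifts no coupled-feature mean, so such signal is only weakly usable by
  the linear base learners. The representation's gains appear when network
  structure and mean shifts co-occur.
* Boosting uses a single fixed pass over blocks; per-round block selection
  is not implemented.
* Nominal features, kernel or sparse CCA variants, and cross-modality
  coupling are out of scope.
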