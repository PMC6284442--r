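---
title: "Methods: shape models, asymmetry tests and the synthetic world"
author: "shapesym developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape models, asymmetry tests and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the model

Clinical practice often treats paired skeletal structures — here the bones of
the ankle: fibula, tibia, calcaneus, talus — as bilaterally symmetric, using
the healthy contralateral side as a template for surgical planning or as an
intra-subject control. `shapesym` implements the statistical machinery needed
to interrogate that assumption when each bone is represented as a densely
sampled, corresponded 3D point set.

The underlying model is the standard point distribution model. After
mirroring right-side shapes in the sagittal plane and removing position,
orientation and scale, each shape is a vector $x \in \mathbb{R}^{3n}$ and

$$x = \bar{x} + \sum_{j=1}^{m} b_j \sqrt{\lambda_j}\, \phi_j + \varepsilon,$$

with $\bar x$ the mean shape, $\phi_j$ orthonormal principal components,
$\lambda_j$ their variances and $b_j$ the *shape parameters in SD units* —
the scale in which box plots and the familiar "$\pm 3$ SD" mode renderings
are expressed, and the scale this package uses throughout.

Three families of questions are addressed:

1. **Are the left and right groups the same?** Distance-based permutation
   tests on three aspects: *location* (Euclidean distance between group
   means), *variance–covariance scale* (absolute difference of mean
   within-group residuals), and *variance–covariance orientation* (principal
   angles between the two groups' PCA subspaces, summarised by the Grassmann
   projection metric $D_k = \sqrt{k - \sum_{i\le k} \cos^2\theta_i}$). The
   permutation p-value is the plain counting estimate
   $P_{perm} = N_i / N_{perm}$, where $N_i$ counts permuted statistics
   **greater than or equal to** the observed one.
2. **Does sex shape the bones?** Sides pooled, per-mode ANCOVA
   `score ~ age + sex` with a Bonferroni-corrected family level, preceded by
   a Kolmogorov–Smirnov normality screen.
3. **Is within-subject variation smaller than between-subject variation?**
   Per-mode ICC(2,1): single-measurement, absolute-agreement, two-way
   random-effects intraclass correlation between the paired left/right shape
   parameters, with an F-based 95% CI. ICC = 1 means perfect within-subject
   symmetry; a CI containing 0 flags a mode as *not significantly
   symmetric*.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_perm` | 10 000 | — | production default for permutation tests; scaled-down runs only affect p-value resolution, not validity |
| `pa_n_sim` | 100 | — | parallel-analysis null spectra; rank-wise means are stable at 100 |
| `pa_criterion` | `"mean"` | — | crossing of observed vs simulated scree curves; see below |
| `alpha_family` | 0.05 | — | family-wise level; per-mode level is `alpha_family / k` |
| `conf_level` | 0.95 | — | ICC confidence level |
| `sigma`, `n_mean_points`, `lambda_tradeoff` | 3 mm, 2000, 1e-5 | mm, —, — | accepted and logged for compatibility with Gaussian-mixture surface registration configs; drive no equation here (alignment operates on corresponded points) |

# Alignment: design choices

The package assumes point-wise correspondence (synthetic data are generated
in correspondence; meshes can be corresponded by
`correspond_to_reference()`, a deterministic closest-point stand-in with
lowest-triangle-index tie-breaking). Groupwise alignment is then classical
iterative Procrustes: rotate every centred shape onto the evolving mean with
the Kabsch solution, determinant-corrected so reflections can never leak in
— mirroring is an explicit, separate step.

Two choices deserve justification:

* **Scale is removed by unit centroid-size normalisation**, not by the
  per-iteration least-squares similarity scale. The least-squares scale of a
  noisy shape onto the mean is correlation-dependent, so post-alignment
  sizes would differ across samples (and shrink systematically with noise).
  Normalisation makes all centroid sizes exactly equal, keeps the
  block-coordinate descent monotone, and is the conventional partial
  Procrustes choice in morphometrics.
* **The output frame is canonicalised**: after convergence everything is
  rotated into the principal axes of the mean shape, with axis signs fixed
  by the sign of the third moment along each axis (stable for generically
  asymmetric shapes) and determinant +1 enforced. Without this, generalised
  Procrustes output is only defined up to a global rotation, and
  re-running on commonly transformed inputs would give rotated answers.

The mirror plane is fixed to $x = 0$ in the input frame; a convention has to
be stated because scanner frames are arbitrary.

# PCA and parallel analysis: numerical choices

PCA is computed through the economy SVD of the centred data matrix (the dual
/ Gram route), exact and cheap when $3n \gg$ sample count. Components below
$10^{-10}$ relative eigenvalue are dropped; eigenvector signs are fixed by
making the largest-magnitude loading positive.

Parallel analysis simulates element-wise independent Gaussians with
per-variable variance matched to the data and retains all leading components
whose observed eigenvalue exceeds the rank-wise criterion. Two criteria are
offered:

* `"mean"` (default) — the crossing point of the observed and mean simulated
  scree curves. Note its known behaviour at rank 0: on *pure noise* the top
  observed eigenvalue exceeds the simulated mean roughly half the time, so
  the mean criterion retains 1–2 spurious components in a sizeable fraction
  of null datasets. It is nevertheless the default because it is the
  classical scree-intersection rule and behaves well as soon as real
  structure is present.
* `"percentile95"` — the rank-wise 95th percentile; conservative, retains
  nothing on pure noise ~95% of the time. The test suite uses this criterion
  for the null-retention property and the mean criterion everywhere else.

In the separate-groups pipeline the orientation test needs a common subspace
dimension; the pipeline takes `k = max(min(k_left, k_right), 1)`, the
conservative common value.

# Permutation engine

* Two relabelling schemes: `side_swap` (default) swaps each subject's pair
  independently with probability 1/2 — the exchangeability that paired data
  warrant — and `free` relabels all samples while preserving group sizes.
  Which of the two an original study used is usually ambiguous ("permuted
  across groups"); both are provided and the default documented.
* Relabellings are sampled *with replacement* and the identity relabelling
  is legal; ties (permuted value exactly equal to observed) count toward
  $N_i$. Consequently $P_{perm}$ can be exactly 0 only when no relabelling
  reproduces the observed statistic; `add_one = TRUE` switches to
  $(N_i+1)/(N_{perm}+1)$.
* The orientation statistic re-estimates both groups' PCA subspaces at every
  permutation and returns the whole set $D_1 \dots D_k$ with element-wise
  p-values.
* Before permuting, both groups are rotated into the orthonormal basis of
  their common row span. This is exact — all inner products, hence all three
  statistics and all principal angles, are preserved — and turns
  $O(n_{perm} \cdot 3n)$ work into $O(n_{perm} \cdot n_{samples})$.
* The projection metric is implemented in its rooted form
  $\sqrt{k - \sum \cos^2\theta_i}$ (bounded by $\sqrt k$), with
  `squared = TRUE` available; printed formulas in the literature sometimes
  omit the enclosing root, but reported magnitudes match the rooted form.

# Pooled statistics: choices

* **KS normality** uses the Lilliefors correction: the null distribution of
  the estimated-parameter KS statistic is obtained by seeded Monte Carlo
  (default 1000 samples), because the classical KS table is anti-conservative
  once mean and SD are estimated from the data. The p-value uses the add-one
  form.
* **ANCOVA** models age linearly with no interaction; the sex p-value is the
  single-df F (= squared t). Missing ages are excluded with a logged count.
  The Bonferroni-adjusted level is reported both exact and half-up rounded
  to 3 decimals, matching common reporting practice.
* **ICC(2,1)** follows the two-way random-effects, absolute-agreement,
  single-measurement definition with the McGraw & Wong F-based CI (verified
  against `pingouin.intraclass_corr`). Negative estimates are reported as
  computed — truncation at 0 would hide exactly the "within-subject as large
  as between-subject" signal the analysis looks for. The degenerate case of
  exactly identical sides returns ICC = 1 with a collapsed CI.

# The synthetic world

`generate_population()` draws, for subject $i$ and mode $j$, a subject score
$s_{ij} \sim N(0, \mathrm{icc}_j \lambda_j)$ and side deviations
$d_{ij,side} \sim N(0, (1-\mathrm{icc}_j)\lambda_j)$, so the population ICC
of the left/right scores is exactly `icc_per_mode[j]`. Directional
asymmetry, sex and (linear, centred) age effects are planted in SD units.
Shapes are built from a deterministic smooth base surface (a deformed
ellipsoid with odd-in-x harmonic bumps, so mirroring is detectable), receive
isotropic Gaussian coordinate noise, right sides are mirrored, and every
sample gets a random similarity nuisance transform (axis-uniform rotation,
per-axis uniform translation, log-uniform scale). Every latent quantity and
nuisance transform is recorded for recovery tests.

Defaults state the world the pipeline is aimed at: 66 subjects, roughly one
female per five males (`sex_ratio = 1/6`), ages uniform on 40–80 years, four
modes with variances 9/4/2/1 mm² (SDs of 3–1 mm against a base shape tens of
mm across), ICC ladder 0.9/0.7/0.5/0.3, and 0.05 mm measurement noise. When
`n_modes_true` differs from 4 the per-mode defaults truncate or extend
(geometric spectrum decay, last ICC repeated).

**What a green test does not establish.** The generator produces linear-
Gaussian variation around a smooth closed surface in perfect correspondence.
Real bones have correspondence error, non-Gaussian and spatially structured
variation, segmentation artefacts, and OA-related shape change; none of
these is emulated. Green tests establish that the *statistical machinery* is
correct and calibrated, not that any anatomical conclusion transfers.

# Degenerate inputs and tie-breaks

* Rank-deficient point sets are rejected by sample id before alignment.
* Zero-variance data fail PCA, ICC and the KS screen with explicit errors.
* Equidistant triangles in closest-point queries resolve to the lowest
  triangle index; PCA signs and the canonical frame make all outputs
  reproducible across BLAS implementations for a fixed seed.
* Single top-level seeds derive per-stage seeds deterministically (all below
  $2^{31}$), so any stage can be re-run in isolation.

# Known limitations

* No nonrigid/deformable registration: correspondence quality on real
  meshes is limited by the closest-point stand-in and the choice of
  reference.
* The orientation test fixes one common $k$ for both groups; modes near the
  retention boundary can move in or out of the subspace under permutation,
  which is part of the null being tested, not an artefact.
* CLI configs are JSON only.
* Independent component analysis is deliberately out of scope.
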