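# shapesym

Statistical shape modelling and bilateral (a)symmetry analysis of paired
left/right 3D point sets — the kind of question that arises whenever the
healthy contralateral bone (fibula, tibia, calcaneus, talus, ...) is used as
a surgical template or intra-subject control: *is the other side actually
the same shape?*

## What it computes

Shapes are corresponded 3D point sets. After mirroring right-side samples in
the sagittal plane and iterative groupwise similarity alignment, each shape
is a vector `x` in R^(3n) modelled by PCA:

    x = mean + sum_j  b_j * sqrt(lambda_j) * phi_j

with shape parameters `b_j` in SD units. On top of this model:

* **Left vs right as separate groups** — distance-based permutation tests
  (p-value `P_perm = N_i / N_perm`, ties counted) of
  * *location*: Euclidean distance between group means,
  * *variance–covariance scale*: absolute difference of mean within-group
    residuals,
  * *variance–covariance orientation*: principal angles between the two
    groups' PCA subspaces summarised by the Grassmann projection metric
    `D_k = sqrt(k - sum_i cos^2 theta_i)`, with both subspaces re-estimated
    at every permutation. The retained dimension k comes from Horn-style
    parallel analysis.
* **Sides pooled** — per-mode Kolmogorov–Smirnov normality screen
  (Lilliefors-corrected by Monte Carlo), age-adjusted sex ANCOVA with a
  Bonferroni family correction, and ICC(2,1) (single-measurement,
  absolute-agreement, two-way random effects) between paired left/right
  shape parameters with F-based 95% CIs: ICC = 1 means perfect
  within-subject symmetry, a CI containing 0 flags a mode whose
  within-subject variation is as large as the between-subject variation.
* **A synthetic paired-shape generator** with recorded ground truth
  (eigen-spectrum, per-mode ICC, directional asymmetry, sex/age effects,
  nuisance similarity transforms) so every stage is testable without any
  imaging data, plus ASCII PLY/OFF/STL/CSV readers and writers and a CLI.

See `vignettes/shape-asymmetry-methods.Rmd` for assumptions, numerical
choices and limitations.

## Worked example

Simulate the stated study world (66 subjects, 1:5 female:male ratio, four
shape modes with variances 9/4/2/1 mm² and ICC ladder 0.9/0.7/0.5/0.3), with
a 1 SD sex effect planted on mode 1 and no directional asymmetry, then run
both analysis arms:

```r
library(shapesym)
cfg <- run_config(
  synthetic = synthetic_config(n_subjects = 66, n_points = 100,
                               sex_effect = c(1, 0, 0, 0), seed = 1),
  n_perm = 1000, pa_n_sim = 100, seed = 2024)

sep <- run_separate_groups_analysis(cfg)
print(sep$table, row.names = FALSE)
#>           test       D_stat P_perm
#>       location 0.0023327599  0.051
#>          scale 0.0000148795  0.982
#>  orientation_1 0.0454765051  0.359
#>  orientation_2 0.0944202419  0.233
#>  orientation_3 0.1470104382  0.350
#>  orientation_4 0.2087538972  0.086
```

No side bias was planted and none is detected: all `P_perm` values are above
0.05 for location, dispersion and subspace orientation.

```r
pooled <- run_pooled_analysis(cfg)
#> [shapesym:pa] retained k = 4 (96.1% of total variance)
#> [shapesym:ancova] 1/4 modes significant at adjusted level 0.0125
print(pooled$table2, row.names = FALSE)
#>  mode p_value significant
#>     1   0.000        TRUE
#>     2   0.163       FALSE
#>     3   0.799       FALSE
#>     4   0.435       FALSE
print(pooled$table3, row.names = FALSE)
#>  mode  icc ci_low ci_high not_significantly_symmetric
#>     1 0.92   0.87    0.95                       FALSE
#>     2 0.69   0.53    0.80                       FALSE
#>     3 0.46   0.25    0.63                       FALSE
#>     4 0.04  -0.20    0.28                        TRUE
```

Parallel analysis retains all four planted modes (96% of variance). The
ANCOVA flags exactly the mode carrying the planted sex effect at the
Bonferroni-adjusted level 0.05/4. The ICC column tracks the planted ladder;
mode 4 illustrates sampling reality at n = 66: the dataset's realised ICC is
0.10 (truth 0.3), and the 95% CI (−0.20, 0.28) happens to flag it — with 66
subjects, per-mode ICC confidence intervals are about ±0.25 wide, which is
exactly why such flags should be read alongside the interval, not alone.

## Command line

```sh
Rscript inst/cli/shapesym simulate --seed 1 --out data/      # write PLY + sheet + truth
Rscript inst/cli/shapesym all --config cfg.json --out results/
```

Subcommands `simulate`, `separate`, `pooled`, `all`; flags `--config
<json>`, `--seed`, `--out`, `--n-perm`, `--scheme {side_swap,free}`. Exit
code 0 on success, 2 on validation errors.

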