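# Config-driven end-to-end analyses: separate-groups (left vs right
# permutation tests) and pooled (PCA + parallel analysis + KS + ANCOVA + ICC).

#' Pipeline run configuration
#'
#' @param mode "synthetic" (generate data via [generate_population()]) or
#'   "real" (load a sample sheet whose `path` column points at geometry
#'   files).
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param input path to a sample-sheet CSV (real mode).
#' @param registration a [registration_config()].
#' @param n_perm permutations for the side-comparison tests (>= 100).
#' @param scheme permutation scheme, "side_swap" or "free".
#' @param pa_n_sim simulations for parallel analysis.
#' @param pa_criterion "mean" or "percentile95".
#' @param alpha_family family-wise significance level for the ANCOVA block.
#' @param conf_level ICC confidence level.
#' @param seed top-level seed; per-stage seeds are derived deterministically.
#' @param out_dir optional output directory; when NULL nothing is written and
#'   the report is only returned.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       synthetic = synthetic_config(),
                       input = NULL,
                       registration = registration_config(),
                       n_perm = 10000L,
                       scheme = c("side_swap", "free"),
                       pa_n_sim = 100L,
                       pa_criterion = c("mean", "percentile95"),
                       alpha_family = 0.05,
                       conf_level = 0.95,
                       seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  pa_criterion <- match.arg(pa_criterion)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (mode == "synthetic" && !is.null(input))
    stop("specify exactly one of synthetic config or real input", call. = FALSE)
  if (mode == "real" && is.null(input))
    stop("real mode requires `input` (a sample-sheet CSV)", call. = FALSE)
  structure(list(mode = mode, synthetic = synthetic, input = input,
                 registration = registration, n_perm = as.integer(n_perm),
                 scheme = scheme, pa_n_sim = as.integer(pa_n_sim),
                 pa_criterion = pa_criterion, alpha_family = alpha_family,
                 conf_level = conf_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[shapesym:%s] %s", stage, sprintf(fmt, ...)))
}

.load_samples <- function(config) {
  if (config$mode == "synthetic") {
    syn <- config$synthetic
    syn$seed <- .derive_seed(config$seed, "synthetic")
    pop <- generate_population(syn)
    .log_stage("load", "generated %d synthetic samples (%d subjects)",
               length(pop$samples), syn$n_subjects)
    pop
  } else {
    sheet <- read_sample_sheet(config$input)
    if (is.null(sheet$path))
      stop("real mode requires a `path` column in the sample sheet", call. = FALSE)
    base <- dirname(config$input)
    samples <- lapply(seq_len(nrow(sheet)), function(i) {
      p <- sheet$path[i]
      if (!file.exists(p)) p <- file.path(base, sheet$path[i])
      s <- read_shape(p)
      shape_sample(points = s$points, faces = s$faces,
                   sample_id = sheet$sample_id[i],
                   subject_id = sheet$subject_id[i],
                   side = sheet$side[i],
                   sex = ifelse(sheet$sex[i] %in% c("F", "M"), sheet$sex[i], "unknown"),
                   age = sheet$age[i])
    })
    .log_stage("load", "read %d samples from %s", length(samples), config$input)
    list(samples = samples, truth = NULL)
  }
}

# Mirror right-side samples into the left frame, then groupwise-align.
.prepare_aligned <- function(config, samples) {
  mirrored <- lapply(samples, function(s) if (s$side == "R") mirror_sagittal(s) else s)
  .log_stage("mirror", "mirrored %d right-side samples in the sagittal plane",
             sum(vapply(samples, `[[`, "", "side") == "R"))
  t0 <- proc.time()[["elapsed"]]
  ad <- groupwise_align(mirrored, config$registration)
  .log_stage("align", "groupwise alignment converged in %d iterations (%.2fs)",
             length(ad$objective), proc.time()[["elapsed"]] - t0)
  ad
}

.config_for_report <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- if (config$mode == "synthetic") unclass(cfg$synthetic) else NULL
  cfg$registration <- unclass(cfg$registration)
  cfg$out_dir <- NULL
  cfg
}

#' Separate-groups analysis: left vs right permutation tests
#'
#' Runs the side-comparison arm of the pipeline: mirror right-side samples,
#' groupwise alignment, per-side PCA and parallel analysis (the common
#' retained count k = min of the two sides, floored at 1), then the location,
#' variance-covariance scale, and variance-covariance orientation permutation
#' tests. When `config$out_dir` is set, a D-statistic/P-value table is
#' written as CSV and the full report (config, version, permutation
#' distributions) as JSON; reports are byte-identical for a fixed seed.
#'
#' @param config a [run_config()].
#' @return a report list: `table` (rows location, scale, orientation_1..k;
#'   columns D_stat, P_perm), `k_left`, `k_right`, `k`, the three
#'   `permutation_result`s, `config`, `version`.
#' @export
run_separate_groups_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pop <- .load_samples(config)
  ad <- .prepare_aligned(config, pop$samples)

  side <- ad$meta$side
  L <- ad$data[side == "L", , drop = FALSE]
  R <- ad$data[side == "R", , drop = FALSE]
  if (config$scheme == "side_swap") {
    # order both groups by subject so rows are paired
    L <- L[order(ad$meta$subject_id[side == "L"]), , drop = FALSE]
    R <- R[order(ad$meta$subject_id[side == "R"]), , drop = FALSE]
  }

  pa_l <- parallel_analysis(L, n_sim = config$pa_n_sim,
                            criterion = config$pa_criterion,
                            seed = .derive_seed(config$seed, "pa_left"))
  pa_r <- parallel_analysis(R, n_sim = config$pa_n_sim,
                            criterion = config$pa_criterion,
                            seed = .derive_seed(config$seed, "pa_right"))
  k <- max(min(pa_l$k_retained, pa_r$k_retained), 1L)
  .log_stage("pa", "retained k = %d (left %d, right %d)",
             k, pa_l$k_retained, pa_r$k_retained)

  tests <- list(
    location = permutation_test(L, R, "location", n_perm = config$n_perm,
                                scheme = config$scheme,
                                seed = .derive_seed(config$seed, "loc")),
    scale = permutation_test(L, R, "scale", n_perm = config$n_perm,
                             scheme = config$scheme,
                             seed = .derive_seed(config$seed, "scale")),
    orientation = permutation_test(L, R, "orientation", n_perm = config$n_perm,
                                   scheme = config$scheme, k = k,
                                   seed = .derive_seed(config$seed, "orient")))

  tab <- data.frame(
    test = c("location", "scale", paste0("orientation_", seq_len(k))),
    D_stat = c(tests$location$d_observed, tests$scale$d_observed,
               tests$orientation$d_observed),
    P_perm = c(tests$location$p_perm, tests$scale$p_perm,
               tests$orientation$p_perm),
    stringsAsFactors = FALSE)

  report <- list(analysis = "separate_groups",
                 version = .pkg_version(),
                 config = .config_for_report(config),
                 n_samples = nrow(ad$data),
                 k_left = pa_l$k_retained, k_right = pa_r$k_retained, k = k,
                 table = tab,
                 tests = tests)
  if (!is.null(config$out_dir)) .write_separate_report(report, config$out_dir)
  report
}

.write_separate_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(out_dir, "separate_groups_table.csv"),
                   row.names = FALSE, quote = FALSE)
  js <- report
  js$tests <- lapply(report$tests, function(t)
    list(statistic = t$statistic, d_observed = t$d_observed,
         n_perm = t$n_perm, n_exceed = t$n_exceed, p_perm = t$p_perm,
         scheme = t$scheme, seed = t$seed,
         d_perm = t$d_perm))
  jsonlite::write_json(js, file.path(out_dir, "separate_groups_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Pooled analysis: shape variation, sex effects and within-subject symmetry
#'
#' Runs the pooled arm of the pipeline: mirror and align as in
#' [run_separate_groups_analysis()], pool both sides into one PCA, select the
#' retained count by parallel analysis, then per retained mode (i) screen the
#' shape parameters for normality (KS with estimated parameters), (ii)
#' compare sexes adjusted for age with a Bonferroni-corrected ANCOVA and
#' (iii) estimate ICC(2,1) between the paired left/right shape parameters
#' with its confidence interval. For every mode flagged significant by the
#' ANCOVA, point-to-surface distances are computed between the two samples
#' with extreme scores along that mode, and +/-3 SD reconstructions are
#' produced for all retained modes.
#'
#' @param config a [run_config()].
#' @return a report list with `k_retained`, `cumulative_variance_share`,
#'   `ks` (per-mode p-values), `ancova` (an `ancova_result`), `icc` (list of
#'   `icc_result`), `table2`/`table3`-shaped data.frames, `reconstructions`
#'   (+/-3 SD per mode), `p2s_maps`, `config`, `version`.
#' @export
run_pooled_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pop <- .load_samples(config)
  ad <- .prepare_aligned(config, pop$samples)

  model <- fit_pca(ad)
  pa <- parallel_analysis(ad$data, n_sim = config$pa_n_sim,
                          criterion = config$pa_criterion,
                          seed = .derive_seed(config$seed, "pa_pooled"))
  k <- max(pa$k_retained, 1L)
  model$k_retained <- k
  cum_share <- sum(model$eigenvalues[seq_len(k)]) / sum(model$eigenvalues)
  .log_stage("pa", "retained k = %d (%.1f%% of total variance)", k, 100 * cum_share)

  scores <- model$scores_sd[, seq_len(k), drop = FALSE]
  meta <- ad$meta

  ks <- vapply(seq_len(k), function(j)
    ks_normality(scores[, j], seed = .derive_seed(config$seed, paste0("ks", j)))$p_value, 0)

  anc <- ancova_table(scores, meta$sex, meta$age,
                      alpha_family = config$alpha_family)
  .log_stage("ancova", "%d/%d modes significant at adjusted level %.4g",
             length(anc$significant_modes), k, anc$alpha_adjusted)

  # pair left/right scores by subject for the ICC
  ls <- which(meta$side == "L"); rs <- which(meta$side == "R")
  ls <- ls[order(meta$subject_id[ls])]
  rs <- rs[order(meta$subject_id[rs])]
  paired <- intersect(meta$subject_id[ls], meta$subject_id[rs])
  ls <- ls[meta$subject_id[ls] %in% paired]
  rs <- rs[meta$subject_id[rs] %in% paired]
  icc <- lapply(seq_len(k), function(j)
    icc_2_1(scores[ls, j], scores[rs, j], conf_level = config$conf_level))

  recon <- lapply(seq_len(k), function(j)
    list(mode = j,
         plus3 = reconstruct_at_sd(model, j, 3),
         minus3 = reconstruct_at_sd(model, j, -3)))

  p2s <- lapply(anc$significant_modes, function(j) {
    i_lo <- which.min(scores[, j]); i_hi <- which.max(scores[, j])
    a <- .unvec_points(ad$data[i_lo, ]); b <- .unvec_points(ad$data[i_hi, ])
    d <- point_to_surface_distance(a, b)
    list(mode = j, sample_low = meta$sample_id[i_lo],
         sample_high = meta$sample_id[i_hi],
         distances = as.vector(d), method = attr(d, "method"))
  })

  table2 <- data.frame(mode = seq_len(k),
                       p_value = round(anc$p_values, 3),
                       significant = seq_len(k) %in% anc$significant_modes)
  table3 <- data.frame(mode = seq_len(k),
                       icc = round(vapply(icc, `[[`, 0, "estimate"), 2),
                       ci_low = round(vapply(icc, `[[`, 0, "ci_low"), 2),
                       ci_high = round(vapply(icc, `[[`, 0, "ci_high"), 2),
                       not_significantly_symmetric =
                         vapply(icc, `[[`, TRUE, "not_significantly_symmetric"))

  report <- list(analysis = "pooled",
                 version = .pkg_version(),
                 config = .config_for_report(config),
                 n_samples = nrow(ad$data),
                 k_retained = k,
                 cumulative_variance_share = cum_share,
                 eigenvalues = model$eigenvalues[seq_len(k)],
                 ks_p_values = ks,
                 ancova = anc,
                 icc = icc,
                 table2 = table2, table3 = table3,
                 reconstructions = recon,
                 p2s_maps = p2s)
  if (!is.null(config$out_dir)) .write_pooled_report(report, config$out_dir)
  report
}

.write_pooled_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table2, file.path(out_dir, "pooled_ancova_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$table3, file.path(out_dir, "pooled_icc_table.csv"),
                   row.names = FALSE, quote = FALSE)
  for (r in report$reconstructions) {
    write_shape(.unvec_points(r$plus3),
                file.path(out_dir, sprintf("mode%02d_plus3sd.ply", r$mode)))
    write_shape(.unvec_points(r$minus3),
                file.path(out_dir, sprintf("mode%02d_minus3sd.ply", r$mode)))
  }
  js <- report
  js$icc <- lapply(report$icc, unclass)
  js$ancova <- unclass(report$ancova)
  js$reconstructions <- NULL  # geometry goes to PLY, not JSON
  jsonlite::write_json(js, file.path(out_dir, "pooled_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run both pipeline arms
#' @param config a [run_config()].
#' @return list with elements `separate` and `pooled`.
#' @export
run_all <- function(config) {
  list(separate = run_separate_groups_analysis(config),
       pooled = run_pooled_analysis(config))
}
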