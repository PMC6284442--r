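# Side-pooled analyses on shape parameters: normality screening, age-adjusted
# sex comparison with Bonferroni correction, intra- vs inter-subject ICC.

# One-sample KS statistic against a normal law with estimated mean and SD.
.ks_stat_normal <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1L) / n))
}

#' Kolmogorov-Smirnov normality screen (estimated parameters)
#'
#' One-sample KS test of normality with mean and SD estimated from the data.
#' Because estimating the parameters invalidates the classical KS null
#' distribution (making the naive test anti-conservative), the p-value is
#' computed by seeded Monte Carlo against the Lilliefors null: `n_mc`
#' standard-normal samples of the same size, each subjected to the same
#' estimated-parameter statistic. The p-value uses the add-one form so it is
#' never exactly zero.
#'
#' @param scores numeric vector, n >= 8, non-constant.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `n`, `n_mc`.
#' @export
ks_normality <- function(scores, n_mc = 1000L, seed = 1L) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (n < 8L) stop("ks_normality needs at least 8 observations", call. = FALSE)
  if (stats::sd(scores) == 0) stop("constant input: normality test undefined", call. = FALSE)
  D <- .ks_stat_normal(scores)
  sim <- .with_seed(seed, {
    vapply(seq_len(n_mc), function(b) .ks_stat_normal(stats::rnorm(n)), 0)
  })
  list(statistic = D, p_value = (1 + sum(sim >= D)) / (n_mc + 1),
       n = n, n_mc = as.integer(n_mc))
}

#' Age-adjusted sex comparison of one shape parameter (ANCOVA)
#'
#' Fits the linear model `score ~ age + sex` and reports the F-test for the
#' sex factor (equal to the squared t of the sex coefficient, since sex has a
#' single degree of freedom). Age enters as a linear covariate without an
#' interaction term. Observations with missing age are excluded and their
#' count reported.
#'
#' @param scores numeric shape parameters, one per sample.
#' @param sex character or factor with both "F" and "M" present.
#' @param age numeric ages; NAs are excluded.
#' @return list with `p_value`, `f_stat`, `df_residual`, `coefficients`,
#'   `n_used`, `n_excluded_missing_age`.
#' @export
ancova_sex <- function(scores, sex, age) {
  sex <- as.character(sex)
  keep <- is.finite(scores) & is.finite(age) & sex %in% c("F", "M")
  n_excl <- sum(sex %in% c("F", "M") & is.finite(scores) & !is.finite(age))
  scores <- scores[keep]; sex <- factor(sex[keep], levels = c("F", "M"))
  age <- age[keep]
  if (nlevels(droplevels(sex)) < 2L)
    stop("both sexes must be present for the ANCOVA", call. = FALSE)
  fit <- stats::lm(scores ~ age + sex)
  co <- summary(fit)$coefficients
  tval <- co["sexM", "t value"]
  list(p_value = co["sexM", "Pr(>|t|)"],
       f_stat = tval^2,
       df_residual = fit$df.residual,
       coefficients = stats::coef(fit),
       n_used = length(scores),
       n_excluded_missing_age = n_excl)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha_family family-wise level (e.g. 0.05).
#' @param n_tests number of tests in the family (>= 1).
#' @return list with `exact` (= alpha_family / n_tests) and `rounded_3dp`
#'   (half-up rounding to 3 decimals, the convention used in printed tables).
#' @export
bonferroni_alpha <- function(alpha_family, n_tests) {
  if (n_tests < 1L) stop("n_tests must be >= 1", call. = FALSE)
  exact <- alpha_family / n_tests
  rounded <- floor(exact * 1000 + 0.5 + 1e-12) / 1000
  list(exact = exact, rounded_3dp = rounded)
}

#' Run per-mode ANCOVAs with a Bonferroni family correction
#'
#' @param scores_sd n_samples x k matrix of shape parameters.
#' @param sex,age per-sample covariates (length n_samples).
#' @param alpha_family family-wise significance level.
#' @return an `ancova_result`: `p_values` (length k), `f_stats`,
#'   `alpha_family`, `n_tests`, `alpha_adjusted` (exact), `alpha_adjusted_3dp`,
#'   `significant_modes` (p < exact adjusted level), `n_excluded_missing_age`.
#' @export
ancova_table <- function(scores_sd, sex, age, alpha_family = 0.05) {
  k <- ncol(scores_sd)
  fits <- lapply(seq_len(k), function(j) ancova_sex(scores_sd[, j], sex, age))
  p <- vapply(fits, `[[`, 0, "p_value")
  ba <- bonferroni_alpha(alpha_family, k)
  structure(list(p_values = p,
                 f_stats = vapply(fits, `[[`, 0, "f_stat"),
                 alpha_family = alpha_family, n_tests = k,
                 alpha_adjusted = ba$exact,
                 alpha_adjusted_3dp = ba$rounded_3dp,
                 significant_modes = which(p < ba$exact),
                 n_excluded_missing_age = fits[[1L]]$n_excluded_missing_age),
            class = "ancova_result")
}

#' Intraclass correlation ICC(2,1) with confidence interval
#'
#' Single-measurement, absolute-agreement, two-way random-effects intraclass
#' correlation between paired left and right scores. The two-way ANOVA
#' decomposition gives mean squares for rows/subjects (MSR), columns/sides
#' (MSC) and error (MSE), and
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2
#' sides. The confidence interval follows the F-based construction of the
#' two-way random-effects framework (McGraw & Wong). An estimate of 1 means
#' the two sides agree exactly (all variation is between subjects); 0 means
#' within-subject variation equals between-subject variation. Negative
#' estimates are reported as computed, not truncated.
#'
#' @param left_scores,right_scores equal-length numeric vectors paired by
#'   subject, n >= 5.
#' @param conf_level confidence level (default 0.95).
#' @return an `icc_result`: `estimate`, `ci_low`, `ci_high`, `conf_level`,
#'   `ms` (MSR, MSC, MSE), `n_subjects`, `n_raters`,
#'   `not_significantly_symmetric` (TRUE iff 0 lies inside the CI).
#' @export
icc_2_1 <- function(left_scores, right_scores, conf_level = 0.95) {
  if (length(left_scores) != length(right_scores))
    stop("left and right score vectors must be paired (equal length)", call. = FALSE)
  n <- length(left_scores)
  if (n < 5L) stop("icc_2_1 needs at least 5 subjects", call. = FALSE)
  x <- cbind(left_scores, right_scores)
  if (!all(is.finite(x))) stop("scores must be finite", call. = FALSE)
  k <- 2L
  grand <- mean(x)
  if (sum((x - grand)^2) == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- sum((x - grand)^2) - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  alpha <- 1 - conf_level
  if (MSE <= .Machine$double.eps * MSR && MSC <= .Machine$double.eps * MSR) {
    ci <- c(1, 1)  # exact agreement: degenerate ANOVA, interval collapses
  } else {
    a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lo, hi)
  }
  structure(list(estimate = icc, ci_low = ci[1L], ci_high = ci[2L],
                 conf_level = conf_level,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 n_subjects = n, n_raters = k,
                 not_significantly_symmetric = ci[1L] <= 0 && ci[2L] >= 0),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.2f, %d%% CI [%.2f, %.2f] (n = %d)%s\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_subjects,
              if (x$not_significantly_symmetric) " [not significantly symmetric]" else ""))
  invisible(x)
}
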