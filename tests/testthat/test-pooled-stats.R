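# KS normality screen, ANCOVA, Bonferroni, ICC(2,1).

test_that("KS statistic matches a direct max-deviation computation", {
  x <- c(0.2, -1.1, 0.7, 1.9, -0.4, 0.1, 0.9, -2.2)
  r <- ks_normality(x, n_mc = 200, seed = 1)
  expect_equal(r$statistic, bf_ks_stat(x), tolerance = 1e-12)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(rnorm(5)), "at least 8")
})

test_that("KS screen is calibrated on normal data and powered on exponential", {
  set.seed(2)
  ok <- 0L; rej <- 0L
  for (b in 1:100) {
    p_norm <- ks_normality(rnorm(132), n_mc = 400, seed = b)$p_value
    if (p_norm > 0.05) ok <- ok + 1L
    p_exp <- ks_normality(rexp(132), n_mc = 400, seed = b)$p_value
    if (p_exp < 0.05) rej <- rej + 1L
  }
  expect_gte(ok, 90L)
  expect_gte(rej, 90L)
})

test_that("ANCOVA F matches the normal-equations oracle on a 6-row fixture", {
  scores <- c(1.2, 0.4, -0.3, 2.2, 1.1, 0.6)
  sex <- c("F", "F", "F", "M", "M", "M")
  age <- c(54, 61, 48, 66, 59, 70)
  fit <- ancova_sex(scores, sex, age)
  oracle <- bf_ancova_F(scores, sex, age)
  expect_equal(fit$f_stat, oracle$F, tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
  expect_error(ancova_sex(scores, rep("F", 6), age), "both sexes")
})

test_that("ANCOVA excludes missing ages with a logged count and separates in the limit", {
  set.seed(3)
  sex <- rep(c("F", "M"), each = 20)
  age <- runif(40, 40, 80); age[c(3, 17)] <- NA
  scores <- 50 * (sex == "F") + rnorm(40)
  fit <- ancova_sex(scores, sex, age)
  expect_equal(fit$n_excluded_missing_age, 2L)
  expect_equal(fit$n_used, 38L)
  expect_lt(fit$p_value, 1e-12)
})

test_that("ANCOVA type-I error is controlled under the null", {
  set.seed(4)
  rej <- 0L
  for (b in 1:500) {
    sex <- c(rep("F", 15), rep("M", 45))
    age <- runif(60, 40, 80)
    scores <- rnorm(60) + 0.01 * (age - 60)
    if (ancova_sex(scores, sex, age)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("sex-imbalance costs ANCOVA power at fixed total n", {
  set.seed(5)
  power_for <- function(n_f, n_m, effect, reps = 250) {
    rej <- 0L
    for (b in seq_len(reps)) {
      sex <- c(rep("F", n_f), rep("M", n_m))
      age <- runif(n_f + n_m, 40, 80)
      scores <- effect * (sex == "F") + rnorm(n_f + n_m)
      if (ancova_sex(scores, sex, age)$p_value < 0.05) rej <- rej + 1L
    }
    rej / reps
  }
  p_imb <- power_for(11, 55, effect = 1)   # the study's 11/55 split
  p_bal <- power_for(33, 33, effect = 1)
  p_null <- power_for(11, 55, effect = 0)
  expect_gt(p_imb, p_null + 0.3)
  expect_gt(p_bal, p_imb)                  # imbalance-driven power loss
})

test_that("bonferroni_alpha reproduces printed family levels", {
  r8 <- bonferroni_alpha(0.05, 8)
  expect_equal(r8$exact, 0.00625)
  expect_equal(r8$rounded_3dp, 0.006)
  expect_equal(bonferroni_alpha(0.05, 15)$rounded_3dp, 0.003)
  expect_equal(bonferroni_alpha(0.05, 14)$rounded_3dp, 0.004)
  expect_equal(bonferroni_alpha(0.05, 1)$exact, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "n_tests")
})

test_that("icc_2_1 matches the sums-of-squares and pingouin oracles", {
  left <- c(1.20, -0.43, 0.77, 2.10, -1.05, 0.32)
  right <- c(1.05, -0.60, 0.95, 1.80, -0.80, 0.55)
  r <- icc_2_1(left, right)
  ms <- bf_icc_ms(left, right)
  expect_equal(unname(r$ms), unname(ms), tolerance = 1e-10)
  # frozen from pingouin.intraclass_corr (ICC(A,1)) on this fixture:
  # estimate 0.978989581971143, CI95 printed as [0.86, 1.00]
  expect_equal(r$estimate, 0.978989581971143, tolerance = 1e-12)
  expect_equal(round(r$ci_low, 2), 0.86)
  expect_equal(round(r$ci_high, 2), 1.00)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  expect_false(r$not_significantly_symmetric)
})

test_that("icc_2_1 degenerate and null cases behave as interpreted", {
  set.seed(6)
  s <- rnorm(20)
  r <- icc_2_1(s, s)
  expect_identical(r$estimate, 1)         # perfect within-subject symmetry
  expect_identical(c(r$ci_low, r$ci_high), c(1, 1))

  l <- rnorm(500); rr <- rnorm(500)       # no subject effect
  r0 <- icc_2_1(l, rr)
  expect_lt(abs(r0$estimate), 0.1)
  expect_true(r0$not_significantly_symmetric)

  expect_error(icc_2_1(rnorm(6), rnorm(5)), "paired")
  expect_error(icc_2_1(rep(0, 6), rep(0, 6)), "zero total variance")
  expect_error(icc_2_1(rnorm(4), rnorm(4)), "at least 5")
})

test_that("the asymmetry flag fires for icc = 0 modes and not for icc = 0.9", {
  set.seed(7)
  fired0 <- 0L; fired9 <- 0L
  for (b in 1:100) {
    subj <- rnorm(66)
    # icc = 0: sides independent
    f0 <- icc_2_1(rnorm(66), rnorm(66))$not_significantly_symmetric
    # icc = 0.9
    l <- sqrt(0.9) * subj + sqrt(0.1) * rnorm(66)
    r <- sqrt(0.9) * subj + sqrt(0.1) * rnorm(66)
    f9 <- icc_2_1(l, r)$not_significantly_symmetric
    fired0 <- fired0 + f0; fired9 <- fired9 + f9
  }
  expect_gte(fired0, 80L)
  expect_lte(fired9, 5L)
})

test_that("ancova_table assembles the Bonferroni family correctly", {
  set.seed(8)
  n <- 80
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- runif(n, 40, 80)
  scores <- cbind(2 * (sex == "F") + rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  tab <- ancova_table(scores, sex, age)
  expect_equal(tab$n_tests, 4L)
  expect_equal(tab$alpha_adjusted, 0.0125)
  expect_true(1 %in% tab$significant_modes)
  expect_identical(tab$significant_modes,
                   which(tab$p_values < tab$alpha_adjusted))
})
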