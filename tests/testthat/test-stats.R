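test_that("pearson_ci matches the hand-computed product-moment oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  # oracle: sum((x-3)(y-3)) = 8, both sums of squares = 10 -> r = 0.8
  res <- pearson_ci(x, y)
  expect_equal(res$r, 0.8)
  # Fisher-z interval and t-based p computed from first principles
  z <- atanh(0.8); se <- 1 / sqrt(5 - 3)
  expect_equal(res$ci_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(res$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-9)
  tstat <- 0.8 * sqrt((5 - 2) / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tstat, df = 3), tolerance = 1e-9)

  expect_equal(pearson_ci(1:10, 1:10)$r, 1)
  expect_equal(pearson_ci(1:10, -2 * (1:10) + 3)$r, -1)
  # affine invariance (positive slope)
  set.seed(3); a <- rnorm(20); b <- a + rnorm(20, 0, 0.3)
  expect_equal(pearson_ci(a, b)$r, pearson_ci(10 * a - 4, 0.5 * b + 7)$r)
  expect_error(pearson_ci(1:5, rep(2, 5)), "variance")
  expect_error(pearson_ci(1:4, 1:5), "length")
})

test_that("bland_altman reports bias, sample SD, and limits of agreement", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0); expect_equal(same$sd, 0)
  shift <- bland_altman(x + 0.5, x)
  expect_equal(shift$bias, 0.5); expect_equal(shift$sd, 0)
  # two differences (-1, 1): sample SD = sqrt(2)
  two <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(two$bias, 0); expect_equal(two$sd, sqrt(2))
  expect_equal(two$loa_high, 1.96 * sqrt(2))
  # sign convention: a method reading low yields negative bias
  expect_lt(bland_altman(x - 1, x)$bias, 0)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("correlation comparison follows the Fisher and Steiger formulas", {
  equal_f <- compare_correlations(0.7, 0.7, 20, method = "fisher_independent")
  expect_equal(equal_f$p, 1)
  # oracle: hand Fisher z for the study-scale example
  r1 <- 0.81; r2 <- 0.87; n <- 21
  zor <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  res <- compare_correlations(r1, r2, n, method = "fisher_independent")
  expect_equal(res$z, zor, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(zor)), tolerance = 1e-12)
  expect_gt(res$p, 0.05)   # differences of this size are not significant
  # degenerate dependent case: identical correlations
  st <- compare_correlations(0.8, 0.8, 21, method = "steiger_dependent", r12 = 1)
  expect_equal(st$p, 1)
  # sharing more variance with the reference raises |z| vs the Fisher test
  st2 <- compare_correlations(r1, r2, n, method = "steiger_dependent", r12 = 0.9)
  expect_gt(abs(st2$z), abs(res$z))
  expect_error(compare_correlations(0.5, 0.6, 20, method = "steiger_dependent"),
               "r12")
  expect_error(compare_correlations(1, 0.5, 20), "< 1")
})

test_that("KS normality check behaves on known distributions", {
  set.seed(11)
  x <- rnorm(300)
  res <- ks_normality(x)
  expect_gt(res$p, 0.05)
  expect_true(res$statistic >= 0 && res$statistic <= 1)
  bimodal <- c(rnorm(50, -5, 0.5), rnorm(50, 5, 0.5))
  expect_lt(ks_normality(bimodal)$p, 0.01)
  expect_match(attr(res, "caveat"), "Lilliefors")
  # cross-check the statistic against the dedicated Lilliefors implementation
  skip_if_not_installed("nortest")
  expect_equal(res$statistic, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-12)
  expect_error(ks_normality(rep(1, 10)), "variance")
})

make_fake_reports <- function(n = 12, seed = 5, tilt_noise = TRUE) {
  set.seed(seed)
  truth <- runif(n, 1.5, 5)           # true peak speed, m/s
  tilt <- runif(n, 5, 35) * pi / 180
  eps <- function(s) rnorm(n, 0, s)
  mk <- function(method, vpeak) {
    tibble::tibble(
      subject = sprintf("S%02d", 1:n), severity = rep("moderate", n),
      method = method, vpeak_ms = vpeak, vmean_ms = vpeak * 0.6,
      mg_mmhg = 2 * vpeak^2, pg_mmhg = 4 * vpeak^2, vti_cm = vpeak * 19,
      sv_ml = 80 + eps(3), sv_cine_ml = 80, ava_cine_cm2 = 80 / (vpeak * 19),
      ava_flow_cm2 = 80 / (vpeak * 19), ava_cm2 = 80 / (vpeak * 19),
      excluded = FALSE)
  }
  dplyr::bind_rows(
    mk("1Dir", truth * cos(tilt) + eps(0.05)),
    mk("3Dir", truth + eps(0.05)),
    mk("TTE", truth * 0.99 + eps(0.02)))
}

test_that("cohort table reproduces the expected comparison structure", {
  reports <- make_fake_reports(n = 14)
  tab <- cohort_table(reports)
  td <- tidy(tab)
  expect_setequal(unique(td$parameter),
                  c("Vmean", "Vpeak", "MG", "PG", "VTI", "SV",
                    "AVA_Cine", "AVA_Flow"))
  expect_setequal(unique(td$method), c("1Dir", "3Dir"))
  vp <- td[td$parameter == "Vpeak", ]
  expect_gte(vp$r[vp$method == "3Dir"], vp$r[vp$method == "1Dir"])
  expect_lt(vp$bias[vp$method == "1Dir"], 0)
  def_r <- is.finite(td$r)   # constant-reference rows carry NA correlations
  expect_true(all(td$ci_low[def_r] <= td$r[def_r] & td$r[def_r] <= td$ci_high[def_r]))
  expect_true(all(td$loa_low <= td$bias & td$bias <= td$loa_high))
  g <- glance(tab)
  expect_equal(g$n_subjects, 14)
  expect_equal(g$n_parameters, 8)
})

test_that("degenerate cohorts and severity filtering behave", {
  # perfectly aligned, noise-free methods: r = 1, bias = 0
  n <- 8
  truth <- seq(2, 5, length.out = n)
  base <- tibble::tibble(subject = sprintf("S%d", 1:n),
                         severity = rep(c("moderate", "severe"), each = n / 2),
                         vmean_ms = truth * 0.6, vpeak_ms = truth,
                         mg_mmhg = 2 * truth^2, pg_mmhg = 4 * truth^2,
                         vti_cm = truth * 19, sv_ml = 80, sv_cine_ml = 80,
                         ava_cine_cm2 = 1, ava_flow_cm2 = 1, ava_cm2 = 1,
                         excluded = FALSE)
  reports <- dplyr::bind_rows(
    dplyr::mutate(base, method = "1Dir"),
    dplyr::mutate(base, method = "3Dir"),
    dplyr::mutate(base, method = "TTE"))
  tab <- tidy(cohort_table(reports, parameters = c("Vpeak", "MG")))
  expect_true(all(abs(tab$r - 1) < 1e-12))
  expect_true(all(abs(tab$bias) < 1e-12))
  # filtering below the minimum subject count errors out
  few <- dplyr::filter(reports, subject %in% sprintf("S%d", 1:3) |
                         severity == "moderate")
  expect_error(cohort_table(reports, severity_filter = "none"),
               "insufficient subjects")
})

test_that("autoplot and comparison plots return ggplot objects", {
  reports <- make_fake_reports(n = 10)
  tab <- cohort_table(reports)
  expect_s3_class(autoplot(tab), "ggplot")
  expect_s3_class(plot_method_comparison(reports, "Vpeak"), "ggplot")
  expect_s3_class(autoplot(dense_half_sine()), "ggplot")
})
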