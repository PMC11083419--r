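# Independent oracle for the frozen cross-check below: a two-rater matrix
# analyzed with Python pingouin's intraclass_corr (ICC(A,k) row):
# estimate 0.945726086964, 95% CI printed as [0.79, 0.99].
pingouin_matrix <- rbind(
  c(-5.271955946425, -6.322179133717),
  c(10.78309301841, 9.246702176306),
  c(-7.613406526563, -3.288793482863),
  c(-0.009816096116280, -4.057378112905),
  c(-1.461309495715, 0.1562183295726),
  c(-5.307571602073, -3.287224700386),
  c(-7.996860223442, -11.26175105745),
  c(2.028913349072, 5.378874433958),
  c(3.679121820176, 6.976886656017),
  c(-10.87208345164, -7.433722588350))

test_that("ICC(2,k) matches the worked two-way ANOVA decomposition", {
  r <- icc2k(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$ms_rows, 2)
  expect_equal(r$ms_cols, 1.5)
  expect_equal(r$ms_error, 0)
  expect_equal(r$estimate, 0.8)
  expect_equal(r$estimate, aov_icc2k(cbind(c(1, 2, 3), c(2, 3, 4))))
})

test_that("ICC(2,k) edge behavior: perfect agreement, pure noise, errors", {
  perfect <- icc2k(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(perfect$estimate, 1)
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))

  set.seed(21)
  noise <- icc2k(cbind(rnorm(400), rnorm(400)))
  expect_lt(abs(noise$raw$estimate), 0.2)

  expect_error(icc2k(cbind(c(1, 2), c(1, 2))), "at least 3 subjects")
  expect_error(icc2k(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc2k(cbind(c(1, NA, 3), c(1, 2, 3))), "missing cells")
})

test_that("ICC estimate and CI agree with an external reference implementation", {
  r <- icc2k(pingouin_matrix)
  expect_equal(r$estimate, 0.945726086964, tolerance = 1e-9)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(0.79, 0.99))
  expect_equal(r$estimate, aov_icc2k(pingouin_matrix), tolerance = 1e-12)
})

test_that("ICC is invariant to shared affine rescaling, lowered by rater offset", {
  set.seed(22)
  subj <- rnorm(30, 0, 7)
  m <- cbind(subj + rnorm(30, 0, 2), subj + rnorm(30, 0, 2))
  r0 <- icc2k(m)
  r_scaled <- icc2k(3.7 * m + 12)
  expect_equal(r_scaled$estimate, r0$estimate, tolerance = 1e-12)

  offsets <- c(0, 2, 5, 10)
  ests <- vapply(offsets, function(o) icc2k(m + cbind(0 * subj, rep(o, 30)))$estimate,
                 numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("limits of agreement reproduce hand-computed cases", {
  same <- limits_of_agreement(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  offset <- limits_of_agreement(cbind(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(offset$bias, 1)
  expect_equal(c(offset$loa_low, offset$loa_high), c(1, 1))

  spread <- limits_of_agreement(cbind(c(0, 1, 2), c(1, 1, 1)))
  expect_equal(spread$bias, 0)
  expect_equal(spread$sd_diff, 1)
  expect_equal(c(spread$loa_low, spread$loa_high), c(-1.96, 1.96))
  expect_equal(spread$ci_bias, c(-1.96, 1.96) / sqrt(3))
  expect_equal(spread$ci_loa_low, -1.96 + c(-1, 1) * 1.96 * sqrt(3 / 3))
  expect_error(limits_of_agreement(cbind(1, 2)), "at least 2")
})

test_that("swapping raters flips the sign of bias and limits", {
  set.seed(23)
  m <- cbind(rnorm(20, 5), rnorm(20, 4))
  a <- limits_of_agreement(m)
  b <- limits_of_agreement(m[, 2:1])
  expect_equal(b$bias, -a$bias)
  expect_equal(b$loa_low, -a$loa_high)
  expect_equal(b$loa_high, -a$loa_low)
})

test_that("reliability_report on identical cohorts gives ICC 1 and bias 0", {
  cohort <- dplyr::bind_rows(lapply(1:5, function(i) mean_subject(sprintf("S%d", i))))
  set.seed(31)
  # inter-subject variance on every axis so the ICC is defined
  cohort$x_mm <- cohort$x_mm + rep(rnorm(5, 0, 3), each = 29)
  cohort$y_mm <- cohort$y_mm + rep(rnorm(5, 0, 3), each = 29)
  cohort$z_mm <- cohort$z_mm + rep(rnorm(5, 0, 3), each = 29)
  rep <- reliability_report(cohort, cohort)
  expect_equal(nrow(rep$icc), 87)
  expect_true(all(rep$icc$estimate == 1))
  expect_true(all(rep$loa$bias == 0))
})

test_that("reliability_report aggregates sides for LoA and summarizes axes", {
  params <- sim_params(n_subjects = 10, seed = 41)
  truth <- generate_cohort(params)
  raters <- simulate_raters(truth, 2, seed = 41)
  rep <- reliability_report(raters$rater1, raters$rater2)
  expect_equal(nrow(rep$icc), 87)
  # 12 mirrored lateral points pooled + 5 midline points, times 3 axes
  expect_equal(nrow(rep$loa), 51)
  expect_equal(sort(rep$axis_summary$axis), c("x", "y", "z"))
  expect_true(all(rep$axis_summary$n_points == 29))

  rep2 <- reliability_report(raters$rater1, raters$rater2, aggregate_sides = FALSE)
  expect_equal(nrow(rep2$loa), 87)

  bad <- raters$rater2[raters$rater2$subject_id != "S0003", ]
  expect_error(reliability_report(raters$rater1, bad), "S0003")
})

test_that("ICC CIs cover the closed-form truth at the nominal rate", {
  # two-way model, zero rater bias: true ICC(2,k) = s^2 / (s^2 + e^2 / k)
  sigma_s <- 7; sigma_e <- 2; n <- 50; k <- 2
  truth <- sigma_s^2 / (sigma_s^2 + sigma_e^2 / k)
  withr::with_seed(2718, {
    hits <- vapply(1:300, function(i) {
      subj <- rnorm(n, 0, sigma_s)
      m <- cbind(subj + rnorm(n, 0, sigma_e), subj + rnorm(n, 0, sigma_e))
      r <- icc2k(m)
      r$raw$ci_low <= truth && truth <= r$raw$ci_high
    }, logical(1))
    expect_gt(mean(hits), 0.91)
    expect_lt(mean(hits), 0.99)
  })
})
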