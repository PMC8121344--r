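test_that("margin matrix columns are the requested indicators", {
  s <- demo_sample(3)
  s$sex <- c("female", "male", "female")
  mm <- build_margin_matrix(s, margin_set("regional", c(female = 2)))
  expect_equal(unname(mm$X[, "female"]), c(1, 0, 1))

  # a margin with no sample representation fails by name
  s$ethnicity <- "European"
  expect_error(build_margin_matrix(s, margin_set("regional", c(asian = 5))),
               "asian")
  # collinear columns are reported
  s2 <- demo_sample(8)
  s2$sex <- rep(c("female", "male"), 4)
  expect_error(
    build_margin_matrix(
      s2, margin_set("regional", c(female = 4, male = 4), grand_total = 8)),
    "rank-deficient")
})

test_that("targets equal to the design margins leave weights unchanged", {
  s <- demo_sample(20, w = seq(2, 9, length.out = 20))
  des_female <- sum(s$weight * (s$sex == "female"))
  des_maori <- sum(s$weight * (s$ethnicity == "Maori"))
  ms <- margin_set("regional", c(female = des_female, maori = des_maori))
  for (fit in list(calibrate_linear(s, ms), calibrate_raking(s, ms))) {
    expect_equal(fit$w_cal, s$weight, tolerance = 1e-10)
    expect_equal(unname(coef(fit)), rep(0, 2), tolerance = 1e-8)
    expect_true(fit$converged)
  }
})

test_that("a lone grand-total constraint is the ratio adjustment", {
  s <- demo_sample(3, w = c(2, 2, 6))
  ms <- margin_set("regional", NULL, grand_total = 20)
  fit <- calibrate_linear(s, ms)
  expect_equal(fit$w_cal, c(4, 4, 12))
  expect_equal(sum(weights(fit)), 20)
})

test_that("a 2-constraint system solves to the hand-computed weights", {
  # 3 respondents, w = (1,1,1), intercept + Maori indicator, targets (10, 4):
  # solving (sum w x x') lambda = T - t_hat gives w_cal = (4, 3, 3).
  s <- demo_sample(3, w = c(1, 1, 1))
  s$ethnicity <- c("Maori", "European", "Pacific")
  ms <- margin_set("regional", c(maori = 4), grand_total = 10)
  fit <- calibrate_linear(s, ms)
  expect_equal(fit$w_cal, c(4, 3, 3))
  expect_equal(sum(fit$w_cal), 10)
  expect_equal(sum(fit$w_cal * (s$ethnicity == "Maori")), 4)
})

test_that("calibrated totals equal the independent regression (GREG) oracle", {
  sr <- study_respondents(seed = 31)
  ms <- sr$mainstream
  # fully observed variables (the identity is over a common row set)
  set.seed(8)
  ms$yc <- as.numeric(ms$age_band %in% c("a15", "a16")) +
    0.3 * (ms$ethnicity == "Maori") + stats::rnorm(nrow(ms), sd = 0.2)
  ms$yb <- as.numeric(ms$sex == "female" & !is.na(ms$decile) & ms$decile <= 3)
  fit <- calibrate_linear(ms, sr$pop$margins_regional)
  mm <- fit$mm
  for (v in c("yc", "yb")) {
    oracle <- greg_regression_total(ms[[v]], mm$X, ms$weight, mm$target)
    est <- calibrated_estimate(fit, v, "total")$point
    expect_equal(est, sum(fit$w_cal * ms[[v]]))
    expect_equal(est, oracle, tolerance = 1e-12)
  }
})

test_that("achieved margins match targets to 1e-8 relative and recalibration is idempotent", {
  sr <- study_respondents(seed = 31)
  fit <- calibrate_linear(sr$mainstream, sr$pop$margins_regional)
  expect_lt(fit$max_rel_err, 1e-8)
  refit <- calibrate_linear(sr$mainstream, sr$pop$margins_regional,
                            weights = fit$w_cal)
  expect_equal(refit$w_cal, fit$w_cal, tolerance = 1e-10)
  expect_equal(max(abs(refit$g - 1)), 0, tolerance = 1e-8)
})

test_that("raking scales a single binary margin's group by T/that", {
  s <- demo_sample(6, w = rep(2, 6))
  s$sex <- c("female", "female", "male", "male", "male", "male")
  that <- sum(s$weight * (s$sex == "female"))  # 4
  ms <- margin_set("regional", c(female = 6))
  fit <- calibrate_raking(s, ms)
  expect_true(fit$converged)
  expect_equal(fit$w_cal[s$sex == "female"], rep(2 * 6 / that, 2))
  # complement untouched (no intercept constraint)
  expect_equal(fit$w_cal[s$sex == "male"], rep(2, 4))
  expect_true(all(fit$w_cal > 0))
})

test_that("raking on a 2x2 table reproduces iterative proportional fitting", {
  # rows: sex, cols: Maori indicator; constrain grand total, one row margin
  # and one column margin -- the raking factors must equal the IPF factors.
  s <- demo_sample(8, w = c(3, 1, 2, 2, 4, 1, 2, 5))
  s$sex <- rep(c("female", "male"), each = 4)
  s$ethnicity <- rep(c("Maori", "Other", "Maori", "Other"), 2)
  cells <- matrix(c(sum(s$weight[s$sex == "female" & s$ethnicity == "Maori"]),
                    sum(s$weight[s$sex == "female" & s$ethnicity == "Other"]),
                    sum(s$weight[s$sex == "male" & s$ethnicity == "Maori"]),
                    sum(s$weight[s$sex == "male" & s$ethnicity == "Other"])),
                  2, 2, byrow = TRUE)
  row_t <- c(12, 10); col_t <- c(13, 9)
  fitted_cells <- ipf_2x2(cells, row_t, col_t)
  ms <- margin_set("regional", c(female = row_t[1], maori = col_t[1]),
                   grand_total = sum(row_t))
  fit <- calibrate_raking(s, ms, tol = 1e-12)
  expect_true(fit$converged)
  got <- matrix(c(sum(fit$w_cal[s$sex == "female" & s$ethnicity == "Maori"]),
                  sum(fit$w_cal[s$sex == "female" & s$ethnicity == "Other"]),
                  sum(fit$w_cal[s$sex == "male" & s$ethnicity == "Maori"]),
                  sum(fit$w_cal[s$sex == "male" & s$ethnicity == "Other"])),
                2, 2, byrow = TRUE)
  expect_equal(got, fitted_cells, tolerance = 1e-8)
})

test_that("raking flags non-convergence instead of raising", {
  sr <- study_respondents(seed = 31)
  fit <- calibrate_raking(sr$mainstream, sr$pop$margins_regional,
                          max_iter = 1L, tol = 1e-14)
  expect_false(fit$converged)
  expect_s3_class(fit, "svycal_calibration")
})

test_that("raking and linear calibration agree when adjustments are small", {
  s <- demo_sample(200, w = runif(200, 3, 8))
  des <- c(female = sum(s$weight * (s$sex == "female")),
           maori = sum(s$weight * (s$ethnicity == "Maori")))
  ms <- margin_set("regional", des * c(1.02, 0.985))
  lin <- calibrate_linear(s, ms)
  rak <- calibrate_raking(s, ms)
  expect_lt(max(abs(lin$g - 1)), 0.05)
  s$z <- as.numeric(s$age_band %in% c("a15", "a16")) + 0.2 * (s$decile > 5)
  t_lin <- sum(lin$w_cal * s$z)
  t_rak <- sum(rak$w_cal * s$z)
  expect_lt(abs(t_rak - t_lin) / abs(t_lin), 0.001)
})

test_that("calibration-margin variables have zero variance; orthogonal ones keep the HT variance", {
  sr <- study_respondents(seed = 31)
  ms <- sr$mainstream
  fit <- calibrate_linear(ms, sr$pop$margins_regional)
  est <- calibrated_estimate(fit, "maori", "total")
  expect_equal(est$point, unname(sr$pop$margins_regional$totals["maori"]))
  ht_se <- svy_total(transform(ms, mv = as.numeric(ethnicity == "Maori")),
                     "mv")$se
  expect_lt(est$se, 1e-6 * ht_se)

  # exact linear combination of margins -> zero residuals, zero se
  comb <- 2 * (ms$sex == "female") + 0.5 * (ms$ethnicity == "Asian")
  ms$comb <- comb
  fit2 <- calibrate_linear(ms, sr$pop$margins_regional)
  expect_lt(calibrated_estimate(fit2, "comb", "total")$se,
            1e-6 * svy_total(ms, "comb")$se)

  # at the fixed point (targets = design margins, g = 1), a variable
  # orthogonal to the margins keeps its HT standard error
  s <- demo_sample(24, w = rep(3, 24))
  s$sex <- rep(c("female", "male"), 12)
  des <- c(female = sum(s$weight * (s$sex == "female")))
  fitfp <- calibrate_linear(s, margin_set("regional", des))
  set.seed(5)
  y <- rnorm(24)
  y[s$sex == "female"] <- y[s$sex == "female"] -
    mean(y[s$sex == "female"])  # weighted-orthogonal to the female column
  s$y <- y
  fitfp$sample <- s
  expect_equal(calibrated_estimate(fitfp, "y", "total")$se,
               svy_total(s, "y")$se, tolerance = 1e-10)
})

test_that("negative calibrated weights are reported, not suppressed", {
  # 3 units, 3 independent constraints: the unique feasible weights are
  # w_cal = (f + m - t, f - w1, m - w1) = (-0.1, 0.5, 2.6)
  s <- demo_sample(3, w = rep(1, 3))
  s$sex <- c("female", "female", "male")
  s$ethnicity <- c("Maori", "Other", "Maori")
  ms <- margin_set("regional", c(female = 0.4, maori = 2.5),
                   grand_total = 3)
  fit <- calibrate_linear(s, ms)
  expect_equal(fit$w_cal, c(-0.1, 0.5, 2.6))
  expect_equal(fit$n_negative, 1)
  expect_lt(fit$max_rel_err, 1e-8)
})
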