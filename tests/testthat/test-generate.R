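test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config()
  p1 <- generate_population(cfg, seed = 123)
  p2 <- generate_population(cfg, seed = 123)
  expect_identical(p1, p2)
  p3 <- generate_population(cfg, seed = 124)
  expect_false(identical(p1$students, p3$students))
})

test_that("emitted margin sets are exact recounts of the generated population", {
  pop <- generate_population(small_config(), seed = 55)
  stu <- pop$students
  ms <- stu[!is.na(stu$stratum) & stu$stratum != "kura" &
              stu$region %in% c("Auckland", "TaiTokerau", "Waikato"), ]
  expect_equal(unname(pop$margins_regional$totals["female"]),
               sum(ms$sex == "female"))
  expect_equal(unname(pop$margins_regional$totals["maori"]),
               sum(ms$ethnicity == "Maori"))
  expect_equal(unname(pop$margins_regional$totals["decile5"]),
               sum(!is.na(ms$decile) & ms$decile == 5))
  # zero-count margins are dropped rather than emitted as degenerate targets
  expect_false("decile3" %in% names(pop$margins_regional$totals))
  expect_equal(unname(pop$margins_regional$totals["age16"]),
               sum(ms$age_band == "a16"))
  nat <- stu[is.na(stu$stratum) | stu$stratum != "kura", ]
  expect_equal(unname(pop$margins_national$totals["asian"]),
               sum(nat$ethnicity == "Asian"))
})

test_that("default frame sizes hit the study dimensions on average", {
  cfg <- generator_config()
  set.seed(2)
  totals <- replicate(50, {
    f <- generate_frame(cfg, seed = sample.int(1e6, 1))
    sum(filter_eligible(f)$roll_9_13)
  })
  # students in eligible study-region schools: 130,692 published
  expect_lt(abs(mean(totals) / 130692 - 1), 0.05)
})

test_that("outcome prevalences follow the configured logistic model", {
  cfg <- small_config()
  cfg$outcomes <- list(
    flat = list(intercept = 0),
    rare = list(intercept = stats::qlogis(0.18)),
    female_up = list(intercept = stats::qlogis(0.3),
                     sex = c(female = 1.0)))
  cfg$outcome_missing_rate <- 0
  pop <- generate_population(cfg, seed = 9)
  stu <- pop$students
  n <- nrow(stu)
  # no effects, intercept 0 -> prevalence 1/2 within 3 binomial SEs
  expect_lt(abs(mean(stu$flat) - 0.5), 3 * sqrt(0.25 / n))
  # intercept logit(0.18), no effects -> prevalence 0.18
  expect_lt(abs(mean(stu$rare) - 0.18), 3 * sqrt(0.18 * 0.82 / n))
  # strong positive female effect: female prevalence above male in
  # every one of 20 fresh outcome draws
  frame_el <- filter_eligible(pop$frame, regions = NULL)
  wins <- vapply(1:20, function(i) {
    o <- generate_outcomes(stu[, !names(stu) %in% "female_up"], cfg,
                           frame_el, seed = 1000 + i)
    mean(o$female_up[o$sex == "female"]) > mean(o$female_up[o$sex == "male"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("outcome missingness is completely at random at the configured rate", {
  cfg <- small_config()
  cfg$outcome_missing_rate <- 0.1
  pop <- generate_population(cfg, seed = 12)
  miss <- mean(is.na(pop$students$depressive_symptoms))
  expect_equal(miss, 0.1, tolerance = 0.05)
})

test_that("response model produces the configured selectivity", {
  cfg <- generator_config()
  pop <- generate_population(small_config(), seed = 21)
  stu <- pop$students
  stu$decile <- pop$frame$decile[match(stu$school_id,
                                       pop$frame$school_id)]

  # no effects: MCAR at plogis(intercept)
  cfg0 <- generator_config()
  cfg0$response$sex[] <- 0
  cfg0$response$ethnicity[] <- 0
  cfg0$response$decile[] <- 0
  m0 <- response_model(cfg0)
  expect_equal(unique(m0$student_prob(stu)),
               stats::plogis(cfg0$response$intercept))

  # default effects: responding sample over-represents females in >= 18/20
  # realisations (and Asian students in most)
  m <- response_model(cfg)
  set.seed(77)
  fem_pop <- mean(stu$sex == "female")
  wins <- replicate(20, {
    keep <- stats::runif(nrow(stu)) < m$student_prob(stu)
    mean(stu$sex[keep] == "female") > fem_pop
  })
  expect_gte(sum(wins), 18)

  # full response in the limit
  cfg1 <- generator_config()
  cfg1$response$p_school <- 1
  cfg1$response$intercept <- 100
  m1 <- response_model(cfg1)
  expect_true(all(m1$student_prob(stu) > 1 - 1e-10))
})

test_that("kura schools are one stratum and overwhelmingly Maori", {
  pop <- generate_population(small_config(), seed = 31)
  kura <- pop$students[!is.na(pop$students$stratum) &
                         pop$students$stratum == "kura", ]
  expect_gt(nrow(kura), 0)
  expect_gt(mean(kura$ethnicity == "Maori"), 0.85)
})
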