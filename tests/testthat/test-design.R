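toy_frame <- function(n = 4, stratum = "mainstream_auckland", roll = 1L) {
  data.frame(school_id = paste0("t", seq_len(n)),
             stratum = stratum,
             region = "Auckland",
             decile = 5L,
             roll_9_13 = roll,
             school_type = "mainstream")
}

toy_students <- function(frame) {
  reps <- rep(seq_len(nrow(frame)), frame$roll_9_13)
  data.frame(student_id = paste0("stu", seq_along(reps)),
             school_id = frame$school_id[reps],
             age_band = "a15", sex = "female", ethnicity = "European",
             year_level = 11L, responded = 0L)
}

test_that("inclusion probabilities multiply the stage fractions", {
  spec <- design_spec(f1 = c(mainstream_auckland = 0.5, kura = 6 / 8),
                      f2 = c(mainstream_auckland = 0.3, kura = 1),
                      certainty_schools = "c1")
  expect_equal(inclusion_probability(spec, "mainstream_auckland", "s9"), 0.15)
  expect_equal(1 / inclusion_probability(spec, "mainstream_auckland", "s9"),
               20 / 3)
  expect_equal(inclusion_probability(spec, "kura", "k1"), 0.75)
  expect_equal(1 / inclusion_probability(spec, "kura", "k1"), 4 / 3)
  # certainty override: full roll invited, pi = f1 * 1
  expect_equal(inclusion_probability(spec, "mainstream_auckland", "c1"), 0.5)
  expect_error(inclusion_probability(spec, "mainstream_waikato", "s1"),
               "mainstream_waikato")
  expect_error(design_spec(f1 = c(a = 0), f2 = c(a = 1)), "fractions")
})

test_that("census fractions return the whole population with unit weights", {
  frame <- toy_frame(3, roll = 5L)
  students <- toy_students(frame)
  spec <- design_spec(f1 = c(mainstream_auckland = 1),
                      f2 = c(mainstream_auckland = 1))
  s <- draw_sample(frame, students, spec, seed = 1)
  expect_equal(nrow(s), nrow(students))
  expect_true(all(s$weight == 1))
  expect_setequal(s$student_id, students$student_id)
})

test_that("draws are reproducible for a fixed seed and weights are 1/pi >= 1", {
  frame <- toy_frame(10, roll = 20L)
  students <- toy_students(frame)
  spec <- design_spec(f1 = c(mainstream_auckland = 0.5),
                      f2 = c(mainstream_auckland = 0.3))
  s1 <- draw_sample(frame, students, spec, seed = 42)
  s2 <- draw_sample(frame, students, spec, seed = 42)
  expect_identical(s1$student_id, s2$student_id)
  expect_true(all(s1$weight >= 1))
  expect_equal(s1$weight, 1 / s1$pi)
  s3 <- draw_sample(frame, students, spec, seed = 43)
  expect_false(identical(s1$student_id, s3$student_id))
})

test_that("stage-1 selection frequencies match f1 over replicates", {
  frame <- toy_frame(20, roll = 1L)
  students <- toy_students(frame)
  spec <- design_spec(f1 = c(mainstream_auckland = 0.5),
                      f2 = c(mainstream_auckland = 1))
  set.seed(99)
  hits <- integer(20)
  for (r in 1:200) {
    s <- draw_sample(frame, students, spec)
    hits <- hits + as.integer(frame$school_id %in% s$school_id)
  }
  # each school expected 100 times, binomial sd ~7; allow +-4 sd
  expect_true(all(hits >= 72 & hits <= 128))
})

test_that("mean of the weighted count over all possible samples equals N", {
  # full enumeration of a 4-school stratum, 2 sampled (f1 = 0.5, f2 = 1):
  # the HT estimate of the population count averages exactly to N over the
  # 6 possible stage-1 samples.
  frame <- toy_frame(4, roll = c(3L, 5L, 7L, 9L))
  N <- sum(frame$roll_9_13)
  spec <- design_spec(f1 = c(mainstream_auckland = 0.5),
                      f2 = c(mainstream_auckland = 1))
  w <- 1 / inclusion_probability(spec, frame$stratum, frame$school_id)
  combos <- utils::combn(frame$school_id, 2)
  nhat <- apply(combos, 2, function(ids) {
    in_s <- frame$school_id %in% ids
    sum(w[in_s] * frame$roll_9_13[in_s])
  })
  expect_equal(mean(nhat), N)
})

test_that("nonresponse keeps design weights and has the correct limits", {
  frame <- toy_frame(6, roll = 30L)
  students <- toy_students(frame)
  spec <- design_spec(f1 = c(mainstream_auckland = 1),
                      f2 = c(mainstream_auckland = 1))
  s <- draw_sample(frame, students, spec, seed = 1)

  all_respond <- list(p_school = 1, student_prob = function(df) 1)
  r1 <- apply_nonresponse(s, all_respond, seed = 2)
  expect_setequal(r1$student_id, s$student_id)
  expect_equal(sort(r1$weight), sort(s$weight))

  none <- list(p_school = 0, student_prob = function(df) 1)
  expect_equal(nrow(apply_nonresponse(s, none, seed = 2)), 0)

  # responding share ~= p_school * p_student over replicates
  model <- list(p_school = 0.56, student_prob = function(df) 0.6)
  set.seed(11)
  shares <- replicate(300, nrow(apply_nonresponse(s, model)) / nrow(s))
  expect_equal(mean(shares), 0.56 * 0.6, tolerance = 0.05)
  # weights untouched on the responding subset
  r2 <- apply_nonresponse(s, model, seed = 3)
  expect_true(all(r2$weight == 1))
})

test_that("a stratum reduced below two selected schools is flagged", {
  frame <- toy_frame(2, roll = 10L)
  students <- toy_students(frame)
  spec <- design_spec(f1 = c(mainstream_auckland = 0.5),
                      f2 = c(mainstream_auckland = 1))
  expect_warning(draw_sample(frame, students, spec, seed = 1),
                 "fewer than 2")
})
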