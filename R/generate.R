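# Synthetic school-population generator.
#
# Emulates the frame and microdata structure the estimation framework
# assumes: a national population of secondary schools (years 9-13) in which
# the three study regions (Auckland, Tai Tokerau, Waikato) hold 161 eligible
# mainstream schools (100/23/38) plus 8 kura kaupapa Maori schools, and the
# rest of the country holds a further 238 eligible mainstream schools --
# 407 eligible schools in all, with rolls drawn log-normal so the expected
# student totals match the published frame counts (~129,765 mainstream
# students in the study regions, ~927 kura students, ~280,163 nationally).
# Demographics follow the national 2018 composition (female 0.503; Maori
# 0.207, Pacific 0.096, Asian 0.117, European 0.519; five age bands around
# 0.17-0.22) with region-specific ethnic mixes (more Asian students in the
# Auckland analogue) and a school-decile tilt (more Maori/Pacific students
# in low-decile schools).  Outcomes are Bernoulli draws from a logistic
# model additive in sex, ethnicity, age band and decile tercile.  The
# response model refuses schools at rate 1 - 0.563 and students via a
# logistic model whose defaults over-represent female and Asian students,
# giving an overall student response near 0.6.
#
# Margin sets emitted with a population are exact tabulations of the
# generated mainstream students (kura excluded, matching the reproduction
# convention of the published margin tables), so calibration targets are
# internally consistent by construction.

#' Configuration for the synthetic population generator
#'
#' All arguments have defaults describing the emulated study; override any
#' subset.  Shares of a partition are renormalized to sum to one.
#'
#' @param seed integer master seed stored with the config (individual
#'   generator calls may override it).
#' @param n_schools named counts of eligible mainstream schools per study
#'   region plus `Other` (rest of country).
#' @param n_kura named counts of kura per study region.
#' @param n_small,n_special,n_partnership counts of ineligible schools mixed
#'   into the study-region frame (small rolls <= 50; special; partnership),
#'   so eligibility filtering is exercised.
#' @param roll_mean,roll_sdlog named expected roll and log-scale sd of the
#'   log-normal roll distribution for `mainstream` (study regions), `other`
#'   (non-study mainstream) and `kura`; rolls are rounded and truncated
#'   below at 51 for eligible schools.
#' @param decile_probs 4 x 10 matrix (rows `Auckland`, `TaiTokerau`,
#'   `Waikato`, `Other`) of school decile probabilities.
#' @param decile_unknown_prob probability a school's decile is unknown.
#' @param p_female female share.
#' @param age_probs named shares of the five age bands.
#' @param ethnicity_probs 5 x 5 matrix (rows the four regions plus `Kura`)
#'   of base prioritised-ethnicity shares.
#' @param ethnicity_decile_tilt named log-odds tilt per ethnicity applied as
#'   `exp(tilt * (decile - 5.5)/4.5)`, creating the decile-ethnicity
#'   correlation (negative = concentrated in low-decile schools).
#' @param outcomes named list of outcome models; each a list with
#'   `intercept` (log-odds) and optional named effect vectors `sex`,
#'   `ethnicity`, `age`, `decile` (terciles `low` deciles 1-3, `mid` 4-7,
#'   `high` 8-10; unknown decile gets `mid`).
#' @param outcome_missing_rate per-outcome completely-at-random missingness.
#' @param response list with `p_school` (school-level response probability),
#'   `intercept`, and named effect vectors `sex`, `ethnicity`,
#'   `decile` on the student response log-odds.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    seed = 20190501L,
    n_schools = c(Auckland = 100, TaiTokerau = 23, Waikato = 38,
                  Other = 238),
    n_kura = c(Auckland = 3, TaiTokerau = 3, Waikato = 2),
    n_small = 12, n_special = 3, n_partnership = 5,
    roll_mean = c(mainstream = 806, other = 628, kura = 116),
    roll_sdlog = c(mainstream = 0.55, other = 0.5, kura = 0.35),
    decile_probs = rbind(
      Auckland   = c(.08, .07, .08, .09, .09, .10, .11, .12, .13, .13),
      TaiTokerau = c(.25, .18, .14, .11, .09, .07, .06, .05, .03, .02),
      Waikato    = c(.12, .12, .12, .11, .10, .10, .09, .09, .08, .07),
      Other      = c(.10, .10, .10, .10, .10, .10, .10, .10, .10, .10)),
    decile_unknown_prob = 0.017,
    p_female = 0.503,
    age_probs = c(le13 = 0.170, a14 = 0.205, a15 = 0.206, a16 = 0.201,
                  ge17 = 0.218),
    ethnicity_probs = rbind(
      Auckland   = c(Maori = .16, Pacific = .18, Asian = .22,
                     European = .38, Other = .06),
      TaiTokerau = c(Maori = .43, Pacific = .04, Asian = .03,
                     European = .45, Other = .05),
      Waikato    = c(Maori = .26, Pacific = .05, Asian = .07,
                     European = .56, Other = .06),
      Other      = c(Maori = .21, Pacific = .06, Asian = .07,
                     European = .60, Other = .06),
      Kura       = c(Maori = .96, Pacific = .02, Asian = 0,
                     European = 0, Other = .02)),
    ethnicity_decile_tilt = c(Maori = -0.5, Pacific = -0.6, Asian = 0.3,
                              European = 0.45, Other = 0),
    outcomes = list(
      depressive_symptoms = list(
        intercept = stats::qlogis(0.20),
        sex = c(female = 0.60),
        ethnicity = c(Maori = 0.15, Pacific = 0.20, Asian = 0.25),
        age = c(a15 = 0.10, a16 = 0.15, ge17 = 0.20),
        decile = c(low = 0.10)),
      binge_drinking = list(
        intercept = stats::qlogis(0.16),
        sex = c(female = -0.25),
        ethnicity = c(Maori = 0.25, Pacific = -0.30, Asian = -0.90),
        age = c(a15 = 0.40, a16 = 0.80, ge17 = 1.20),
        decile = c(low = 0.10, high = -0.10)),
      regular_smoking = list(
        intercept = stats::qlogis(0.045),
        sex = c(female = -0.10),
        ethnicity = c(Maori = 0.70, Pacific = 0.20, Asian = -0.60),
        age = c(a15 = 0.30, a16 = 0.60, ge17 = 0.90),
        decile = c(low = 0.40, high = -0.30))),
    outcome_missing_rate = 0.04,
    response = list(
      p_school = 0.563,
      intercept = 0.16,
      sex = c(female = 0.35),
      ethnicity = c(Maori = -0.15, Pacific = -0.10, Asian = 0.55),
      decile = c(low = -0.15, high = 0.15))) {
  norm1 <- function(p) p / sum(p)
  age_probs <- norm1(age_probs)
  decile_probs <- t(apply(decile_probs, 1, norm1))
  ethnicity_probs <- t(apply(ethnicity_probs, 1, norm1))
  stopifnot(p_female >= 0, p_female <= 1,
            all(n_schools >= 0), all(n_kura >= 0),
            all(roll_mean > 0), all(roll_sdlog > 0),
            decile_unknown_prob >= 0, decile_unknown_prob < 1,
            outcome_missing_rate >= 0, outcome_missing_rate < 1,
            response$p_school >= 0, response$p_school <= 1)
  structure(list(seed = as.integer(seed), n_schools = n_schools,
                 n_kura = n_kura, n_small = n_small, n_special = n_special,
                 n_partnership = n_partnership, roll_mean = roll_mean,
                 roll_sdlog = roll_sdlog, decile_probs = decile_probs,
                 decile_unknown_prob = decile_unknown_prob,
                 p_female = p_female, age_probs = age_probs,
                 ethnicity_probs = ethnicity_probs,
                 ethnicity_decile_tilt = ethnicity_decile_tilt,
                 outcomes = outcomes,
                 outcome_missing_rate = outcome_missing_rate,
                 response = response),
            class = "generator_config")
}

# Log-normal rolls with mean `target_mean`: meanlog = log(mean) - sdlog^2/2.
draw_rolls <- function(n, target_mean, sdlog, min_roll = 51) {
  r <- round(stats::rlnorm(n, meanlog = log(target_mean) - sdlog^2 / 2,
                           sdlog = sdlog))
  pmax(r, min_roll)
}

#' Generate a synthetic school frame
#'
#' Builds the national school frame (eligible mainstream + kura schools in
#' the study regions, eligible mainstream elsewhere, plus small/special/
#' partnership ineligible schools) with log-normal rolls and region-specific
#' deciles.  With defaults, the study regions contain exactly 161 eligible
#' mainstream and 8 kura schools.
#'
#' @param cfg a [generator_config()].
#' @param seed integer; defaults to `cfg$seed`.
#' @return a validated school frame data.frame.
#' @export
generate_frame <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  rows <- list()
  add <- function(region, type, n, roll, decile) {
    if (n == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      region = region, school_type = type, roll_9_13 = roll,
      decile = decile, stringsAsFactors = FALSE)
  }
  draw_decile <- function(region, n) {
    d <- sample.int(10, n, replace = TRUE, prob = cfg$decile_probs[region, ])
    d[stats::runif(n) < cfg$decile_unknown_prob] <- NA
    d
  }
  for (r in names(cfg$n_schools)) {
    n <- cfg$n_schools[[r]]
    kind <- if (r == "Other") "other" else "mainstream"
    add(r, "mainstream", n,
        draw_rolls(n, cfg$roll_mean[[kind]], cfg$roll_sdlog[[kind]]),
        draw_decile(r, n))
  }
  for (r in names(cfg$n_kura)) {
    n <- cfg$n_kura[[r]]
    add(r, "kura", n,
        draw_rolls(n, cfg$roll_mean[["kura"]], cfg$roll_sdlog[["kura"]]),
        draw_decile(r, n))
  }
  # Ineligible schools, spread over the study regions.
  study <- rep(STUDY_REGIONS, length.out = cfg$n_small + cfg$n_special +
                 cfg$n_partnership)
  k <- 0
  if (cfg$n_small > 0) {
    add_regions <- study[k + seq_len(cfg$n_small)]; k <- k + cfg$n_small
    rows[[length(rows) + 1]] <- data.frame(
      region = add_regions, school_type = "mainstream",
      roll_9_13 = sample(10:50, cfg$n_small, replace = TRUE),
      decile = draw_decile("Other", cfg$n_small), stringsAsFactors = FALSE)
  }
  if (cfg$n_special > 0) {
    add(study[k + seq_len(cfg$n_special)], "special", cfg$n_special,
        sample(60:200, cfg$n_special, replace = TRUE),
        draw_decile("Other", cfg$n_special))
    k <- k + cfg$n_special
  }
  if (cfg$n_partnership > 0) {
    add(study[k + seq_len(cfg$n_partnership)], "partnership",
        cfg$n_partnership,
        sample(60:300, cfg$n_partnership, replace = TRUE),
        draw_decile("Other", cfg$n_partnership))
  }
  frame <- do.call(rbind, rows)
  frame$school_id <- sprintf("sch%04d", seq_len(nrow(frame)))
  frame$stratum <- assign_stratum(frame$region, frame$school_type)
  validate_schools(frame[, c("school_id", "stratum", "region", "decile",
                             "roll_9_13", "school_type")])
}

# Per-student categorical draws whose probabilities depend on the school's
# (region|kura, decile) cell: loop over the distinct cells, vectorized
# within each.
draw_ethnicity <- function(region, kura, decile, cfg) {
  out <- character(length(region))
  base_row <- ifelse(kura, "Kura", region)
  dec_num <- ifelse(is.na(decile), 5.5, decile)
  cell <- paste(base_row, dec_num)
  for (cl in unique(cell)) {
    i <- which(cell == cl)
    p <- cfg$ethnicity_probs[base_row[i[1]], ]
    tilt <- exp(cfg$ethnicity_decile_tilt[names(p)] *
                  (dec_num[i[1]] - 5.5) / 4.5)
    p <- p * tilt
    p <- p / sum(p)
    out[i] <- sample(names(p), length(i), replace = TRUE, prob = p)
  }
  out
}

#' Generate the students of a school frame
#'
#' One row per enrolled student of every school in `frame` (filter the frame
#' to the eligible set first; students of ineligible schools are not
#' needed).  Sex, age band and prioritised ethnicity are drawn from the
#' configured shares, ethnicity with the region- and decile-specific mix.
#'
#' @param frame a school frame (typically `filter_eligible(..., regions =
#'   NULL)` output).
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return a validated student data.frame (no outcome columns yet).
#' @export
generate_students <- function(frame, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  n <- sum(frame$roll_9_13)
  reps <- rep(seq_len(nrow(frame)), frame$roll_9_13)
  students <- data.frame(
    student_id = sprintf("stu%06d", seq_len(n)),
    school_id = frame$school_id[reps],
    stringsAsFactors = FALSE)
  students$sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
  students$age_band <- sample(names(cfg$age_probs), n, replace = TRUE,
                              prob = cfg$age_probs)
  students$ethnicity <- draw_ethnicity(frame$region[reps],
                                       frame$school_type[reps] == "kura",
                                       frame$decile[reps], cfg)
  # Year level loosely follows the age band (not used in estimation).
  year_map <- c(le13 = 9L, a14 = 10L, a15 = 11L, a16 = 12L, ge17 = 13L)
  students$year_level <- unname(year_map[students$age_band])
  students$responded <- 0L
  validate_students(students[, STUDENT_BASE_COLS])
}

decile_tercile <- function(decile) {
  out <- rep("mid", length(decile))
  out[!is.na(decile) & decile <= 3] <- "low"
  out[!is.na(decile) & decile >= 8] <- "high"
  out
}

# Linear predictor of a logistic model additive in the demographic fields.
# `effects` holds optional named vectors sex/ethnicity/age/decile.
demographic_eta <- function(students, decile, intercept, effects) {
  eta <- rep(intercept, nrow(students))
  pick <- function(v, key) {
    if (is.null(v)) return(0)
    x <- v[key]
    x[is.na(x)] <- 0
    unname(x)
  }
  eta <- eta + pick(effects$sex, students$sex)
  eta <- eta + pick(effects$ethnicity, students$ethnicity)
  eta <- eta + pick(effects$age, students$age_band)
  eta + pick(effects$decile, decile_tercile(decile))
}

#' Draw binary outcomes from the configured logistic models
#'
#' Each outcome is `Bernoulli(plogis(intercept + effects))`, independent
#' across outcomes given demographics, with completely-at-random missingness
#' at the configured rate.
#'
#' @param students student data.frame.
#' @param cfg a [generator_config()].
#' @param frame the school frame (source of school deciles).
#' @param seed integer seed.
#' @return `students` with one 0/1/NA column per configured outcome.
#' @export
generate_outcomes <- function(students, cfg, frame, seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  decile <- frame$decile[match(students$school_id, frame$school_id)]
  n <- nrow(students)
  for (nm in names(cfg$outcomes)) {
    oc <- cfg$outcomes[[nm]]
    p <- stats::plogis(demographic_eta(students, decile, oc$intercept, oc))
    y <- as.integer(stats::runif(n) < p)
    if (cfg$outcome_missing_rate > 0) {
      y[stats::runif(n) < cfg$outcome_missing_rate] <- NA_integer_
    }
    students[[nm]] <- y
  }
  students
}

#' Response model for schools and students
#'
#' Returns the callable pair used by [apply_nonresponse()]: a school-level
#' response probability and a student-level logistic model over sex,
#' ethnicity and school-decile tercile.  Defaults over-represent female and
#' Asian students among respondents with overall student response near 0.6.
#'
#' @param cfg a [generator_config()].
#' @return list with `p_school` and `student_prob(df)`.
#' @export
response_model <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  rs <- cfg$response
  list(
    p_school = rs$p_school,
    student_prob = function(df) {
      stats::plogis(demographic_eta(df, df$decile, rs$intercept, rs))
    }
  )
}

# Exact tabulation of the standard margin list over a student subset.
# Margins with a zero population total are dropped: a zero target is a
# degenerate constraint (any sample representation would be infeasible).
tabulate_margins <- function(students, level) {
  nm <- c(paste0("decile", 1:9), "age_le13", "age14", "age15", "age16",
          "female", "maori", "european", "pacific", "asian")
  totals <- vapply(nm, function(m) sum(margin_indicator(students, m)),
                   numeric(1))
  margin_set(level, totals[totals > 0])
}

#' Generate a full synthetic population
#'
#' Frame, students, outcomes, and the two margin sets (exact tabulations of
#' the generated mainstream students: regional over the three study regions,
#' national over all regions; kura students excluded from both, as in the
#' published margin tables).  Reproducible: the same seed gives identical
#' output.
#'
#' @param cfg a [generator_config()].
#' @param seed master seed; sub-seeds for frame, students and outcomes are
#'   derived from it.
#' @return list with `frame` (national eligible + ineligible schools),
#'   `students` (students of nationally eligible schools, with outcomes and
#'   school `decile`/`region`/`stratum` joined), `margins_regional`,
#'   `margins_national`, and `summary` (a [population_summary()] of the
#'   study regions).
#' @export
generate_population <- function(cfg = generator_config(), seed = cfg$seed) {
  seeds <- derive_seeds(seed, 3)
  frame <- generate_frame(cfg, seed = seeds[1])
  eligible_nat <- filter_eligible(frame, regions = NULL)
  students <- generate_students(eligible_nat, cfg, seed = seeds[2])
  students <- generate_outcomes(students, cfg, eligible_nat,
                                seed = seeds[3])
  pos <- match(students$school_id, frame$school_id)
  students$region <- frame$region[pos]
  students$decile <- frame$decile[pos]
  students$stratum <- frame$stratum[pos]
  mainstream <- students[frame$school_type[pos] == "mainstream", ]
  regional <- mainstream[mainstream$region %in% STUDY_REGIONS, ]
  list(frame = frame,
       students = students,
       margins_regional = tabulate_margins(regional, "regional"),
       margins_national = tabulate_margins(mainstream, "national"),
       summary = population_summary(frame))
}
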