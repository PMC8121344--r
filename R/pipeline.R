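# End-to-end orchestration: generate -> sample -> nonresponse -> estimate
# with four estimators (unweighted, design-weighted HT, regionally
# calibrated, nationally calibrated) -> comparison tables, participation
# accounting and diagnostics; plus the Monte-Carlo evaluation harness.
#
# National quantities are only ever reported with calibrated weights: the
# sampling design is regional, so design-weighted "national" estimates do
# not exist and no such column is produced.

#' Configuration of a full study run
#'
#' @param generator a [generator_config()].
#' @param design a [design_spec()]; defaults to the study design (50% of
#'   mainstream schools, 30% of students; 6/8 kura with full rolls).
#' @param response apply the school/student response model (`TRUE`) or
#'   assume full response (`FALSE`).
#' @param outcomes outcome columns to tabulate; default all configured.
#' @param margins optional list with elements `regional` and `national`
#'   ([margin_set()]s) to calibrate to; defaults to the exact margins
#'   emitted with the generated population.
#' @param seed master seed for the run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       design = default_design_spec(),
                       response = TRUE,
                       outcomes = names(generator$outcomes),
                       margins = NULL,
                       seed = generator$seed) {
  structure(list(generator = generator, design = design,
                 response = isTRUE(response), outcomes = outcomes,
                 margins = margins, seed = as.integer(seed)),
            class = "run_config")
}

# Add one column per margin name so margin variables can go through the
# column-based estimators.
with_margin_columns <- function(sample, names) {
  for (m in names) sample[[paste0("m_", m)]] <- margin_indicator(sample, m)
  sample
}

#' Run the full study pipeline once
#'
#' Generates a population, draws the two-stage sample, applies nonresponse,
#' calibrates the mainstream respondents to the regional and national margin
#' sets, and tabulates: a margin-reproduction table (actual totals vs HT vs
#' calibrated, with 95% CIs), comparison tables of totals and proportions
#' for the configured outcomes under the four estimators, a participation
#' summary, and calibration diagnostics.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @param seed overrides `cfg$seed`.
#' @return an object of class `svycal_study` with elements `margin_table`,
#'   `totals`, `proportions`, `participation`, `diagnostics`, `calibration`
#'   (the two `svycal_calibration` fits), `sample_sizes`.
#' @export
run_study <- function(cfg = run_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- derive_seeds(seed, 3)
  pop <- generate_population(cfg$generator, seed = seeds[1])
  frame_study <- filter_eligible(pop$frame)
  students <- pop$students[pop$students$school_id %in%
                             frame_study$school_id, ]
  smp <- draw_sample(frame_study, students, cfg$design, seed = seeds[2])
  resp <- if (cfg$response) {
    apply_nonresponse(smp, response_model(cfg$generator), seed = seeds[3])
  } else {
    smp$responded <- 1L
    smp
  }
  ms <- resp[resp$stratum != "kura", , drop = FALSE]

  margins_reg <- cfg$margins$regional %||% pop$margins_regional
  margins_nat <- cfg$margins$national %||% pop$margins_national
  cal_reg <- calibrate_linear(ms, margins_reg)
  cal_nat <- calibrate_linear(ms, margins_nat)

  # Margin-reproduction table (actual vs HT vs calibrated, regional and
  # national): the calibrated columns must equal the actual columns with
  # zero-width intervals.
  mnames <- names(margins_reg$totals)
  ms_m <- with_margin_columns(ms, mnames)
  margin_table <- do.call(rbind, lapply(mnames, function(m) {
    ht <- svy_total(ms_m, paste0("m_", m))
    cr <- calibrated_estimate(cal_reg, m)
    cn <- calibrated_estimate(cal_nat, m)
    data.frame(margin = m,
               actual_regional = unname(margins_reg$totals[m]),
               ht_regional = ht$point, ht_lo = ht$ci95[["lo"]],
               ht_hi = ht$ci95[["hi"]],
               cal_regional = cr$point, cal_reg_lo = cr$ci95[["lo"]],
               cal_reg_hi = cr$ci95[["hi"]],
               actual_national = unname(margins_nat$totals[m]),
               cal_national = cn$point, cal_nat_lo = cn$ci95[["lo"]],
               cal_nat_hi = cn$ci95[["hi"]])
  }))

  fmt_rows <- function(kind) {
    do.call(rbind, lapply(cfg$outcomes, function(v) {
      y <- ms[[v]]
      n_used <- sum(!is.na(y))
      if (kind == "total") {
        unw <- sum(y == 1, na.rm = TRUE)
        ht <- svy_total(ms, v)
        cr <- calibrated_estimate(cal_reg, v, "total")
        cn <- calibrated_estimate(cal_nat, v, "total")
      } else {
        unw <- mean(y, na.rm = TRUE)
        ht <- svy_proportion(ms, v)
        cr <- calibrated_estimate(cal_reg, v, "proportion")
        cn <- calibrated_estimate(cal_nat, v, "proportion")
      }
      data.frame(variable = v, unweighted = unw,
                 ht = ht$point, ht_lo = ht$ci95[["lo"]],
                 ht_hi = ht$ci95[["hi"]],
                 cal_regional = cr$point, cal_reg_lo = cr$ci95[["lo"]],
                 cal_reg_hi = cr$ci95[["hi"]],
                 cal_national = cn$point, cal_nat_lo = cn$ci95[["lo"]],
                 cal_nat_hi = cn$ci95[["hi"]],
                 n = n_used)
    }))
  }
  totals <- fmt_rows("total")
  proportions <- fmt_rows("proportion")

  n_inv <- attr(smp, "schools_sampled")
  n_part <- attr(resp, "schools_responding") %||% n_inv
  cnt <- function(tb, strata) sum(tb[names(tb) %in% strata], na.rm = TRUE)
  ms_strata <- setdiff(STRATA, "kura")
  participation <- participation_summary(data.frame(
    stage = c("mainstream schools invited / eligible",
              "mainstream schools participating / invited",
              "kura invited / eligible",
              "kura participating / invited",
              "mainstream students responding / sampled",
              "kura students responding / sampled"),
    numerator = c(cnt(n_inv, ms_strata), cnt(n_part, ms_strata),
                  cnt(n_inv, "kura"), cnt(n_part, "kura"),
                  sum(resp$stratum != "kura"), sum(resp$stratum == "kura")),
    denominator = c(sum(frame_study$stratum != "kura"),
                    cnt(n_inv, ms_strata),
                    sum(frame_study$stratum == "kura"), cnt(n_inv, "kura"),
                    sum(smp$stratum != "kura"), sum(smp$stratum == "kura"))))

  diagnostics <- list(
    n_sampled = nrow(smp), n_responding = nrow(resp),
    n_mainstream_respondents = nrow(ms),
    design_weight_sum = sum(ms$weight),
    cal_regional = list(g_range = range(cal_reg$g), g_var = stats::var(cal_reg$g),
                        n_negative = cal_reg$n_negative,
                        lambda_norm = sqrt(sum(cal_reg$lambda^2)),
                        weight_sum = sum(cal_reg$w_cal),
                        max_rel_err = cal_reg$max_rel_err),
    cal_national = list(g_range = range(cal_nat$g), g_var = stats::var(cal_nat$g),
                        n_negative = cal_nat$n_negative,
                        lambda_norm = sqrt(sum(cal_nat$lambda^2)),
                        weight_sum = sum(cal_nat$w_cal),
                        max_rel_err = cal_nat$max_rel_err))

  structure(list(margin_table = margin_table, totals = totals,
                 proportions = proportions, participation = participation,
                 diagnostics = diagnostics,
                 calibration = list(regional = cal_reg, national = cal_nat),
                 population = pop$summary, seed = seed),
            class = "svycal_study")
}

#' @export
print.svycal_study <- function(x, digits = 3, ...) {
  cat("Study run (seed ", x$seed, "): ",
      x$diagnostics$n_mainstream_respondents,
      " mainstream respondents\n\n", sep = "")
  cat("Participation:\n")
  print(x$participation, row.names = FALSE)
  cat("\nOutcome proportions (point estimates):\n")
  print(x$proportions[, c("variable", "unweighted", "ht", "cal_regional",
                          "cal_national", "n")],
        row.names = FALSE, digits = digits)
  cat("\nCalibration g-weights (regional): [",
      sprintf("%.3f, %.3f", x$diagnostics$cal_regional$g_range[1],
              x$diagnostics$cal_regional$g_range[2]), "], ",
      x$diagnostics$cal_regional$n_negative, " negative\n", sep = "")
  invisible(x)
}

#' Participation percentages from explicit count pairs
#'
#' The published participation rates are percentages of explicitly stated
#' numerator/denominator pairs; this reproduces that accounting, rounding
#' half-up to one decimal place.  A zero denominator yields `NA`.
#'
#' @param counts data.frame with columns `stage`, `numerator`,
#'   `denominator`.
#' @return the input with a `percent` column.
#' @examples
#' participation_summary(data.frame(stage = "schools agreed / invited",
#'                                  numerator = 45, denominator = 80))
#' @export
participation_summary <- function(counts) {
  check_columns(counts, c("stage", "numerator", "denominator"),
                "participation counts")
  counts$percent <- ifelse(counts$denominator == 0, NA_real_,
                           round_half_up(100 * counts$numerator /
                                           counts$denominator, 1))
  counts
}

#' Monte-Carlo evaluation of the estimators
#'
#' Generates one population from the config, then repeatedly redraws the
#' two-stage sample (and nonresponse, if configured), estimating every
#' outcome with the design-weighted HT estimator and both calibrated
#' estimators.  HT and regionally calibrated estimates are judged against
#' the regional population truth; nationally calibrated estimates against
#' the national truth.  Replicates where a variance or calibration step is
#' infeasible (e.g. a stratum reduced to one responding school) are counted
#' and skipped.
#'
#' @param cfg a [run_config()].
#' @param R number of replicates (>= 2).
#' @param seed master seed; the population and every replicate derive their
#'   seeds from it.
#' @return data.frame with one row per (outcome, kind, estimator): `truth`,
#'   mean estimate, `bias`, `rel_bias`, empirical SD, mean estimated SE,
#'   95% CI `coverage`, and `n_reps` used; failed-replicate count in
#'   `attr(, "n_failed")`.
#' @export
simulation_study <- function(cfg = run_config(), R = 100, seed = cfg$seed) {
  stopifnot(inherits(cfg, "run_config"), R >= 2)
  seeds <- derive_seeds(seed, 2 * R + 1)
  pop <- generate_population(cfg$generator, seed = seeds[1])
  frame_study <- filter_eligible(pop$frame)
  students <- pop$students[pop$students$school_id %in%
                             frame_study$school_id, ]
  idx <- school_index(students)
  margins_reg <- cfg$margins$regional %||% pop$margins_regional
  margins_nat <- cfg$margins$national %||% pop$margins_national
  rmodel <- if (cfg$response) response_model(cfg$generator) else NULL

  # Population truths over mainstream students.
  nat <- pop$students[pop$students$stratum != "kura" |
                        is.na(pop$students$stratum), ]
  reg <- nat[nat$region %in% STUDY_REGIONS, ]
  truth <- function(df, v, kind) {
    if (kind == "total") sum(df[[v]], na.rm = TRUE)
    else mean(df[[v]], na.rm = TRUE)
  }

  kinds <- c("total", "proportion")
  ests <- c("ht", "calibrated_regional", "calibrated_national")
  grid <- expand.grid(variable = cfg$outcomes, kind = kinds,
                      estimator = ests, stringsAsFactors = FALSE)
  grid$truth <- mapply(function(v, k, e) {
    truth(if (e == "calibrated_national") nat else reg, v, k)
  }, grid$variable, grid$kind, grid$estimator)

  point <- matrix(NA_real_, nrow(grid), R)
  sehat <- matrix(NA_real_, nrow(grid), R)
  n_failed <- 0L
  for (r in seq_len(R)) {
    res <- tryCatch({
      smp <- suppressWarnings(
        draw_sample(frame_study, students, cfg$design,
                    seed = seeds[2 * r], .index = idx))
      rs <- if (is.null(rmodel)) smp else {
        apply_nonresponse(smp, rmodel, seed = seeds[2 * r + 1])
      }
      ms <- rs[rs$stratum != "kura", , drop = FALSE]
      cal_r <- calibrate_linear(ms, margins_reg)
      cal_n <- calibrate_linear(ms, margins_nat)
      est <- function(v, k, e) {
        switch(e,
          ht = if (k == "total") svy_total(ms, v) else svy_proportion(ms, v),
          calibrated_regional = calibrated_estimate(cal_r, v, k),
          calibrated_national = calibrated_estimate(cal_n, v, k))
      }
      vapply(seq_len(nrow(grid)), function(i) {
        e <- est(grid$variable[i], grid$kind[i], grid$estimator[i])
        c(e$point, e$se)
      }, numeric(2))
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      point[, r] <- res[1, ]
      sehat[, r] <- res[2, ]
    }
  }

  ok <- !is.na(point[1, ])
  grid$mean_est <- rowMeans(point[, ok, drop = FALSE])
  grid$bias <- grid$mean_est - grid$truth
  grid$rel_bias <- grid$bias / grid$truth
  grid$emp_sd <- apply(point[, ok, drop = FALSE], 1, stats::sd)
  grid$mean_se <- rowMeans(sehat[, ok, drop = FALSE])
  cover <- abs(point[, ok, drop = FALSE] - grid$truth) <=
    1.96 * sehat[, ok, drop = FALSE]
  grid$coverage <- rowMeans(cover)
  grid$n_reps <- sum(ok)
  attr(grid, "n_failed") <- n_failed
  grid
}
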