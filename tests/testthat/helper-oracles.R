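# Independent oracles and toy builders shared across the test files.
# Each oracle is implemented from its own definition, not by calling the
# code path it is meant to check.

# Delete-one-PSU jackknife (with-replacement form): drop PSU j of stratum h,
# rescale the remaining PSUs of h by n_h/(n_h - 1), and combine as
# sum_h (n_h - 1)/n_h sum_j (theta_(hj) - thetabar_h)^2.
# `est_fun(mult)` evaluates the estimator under per-row weight multipliers.
jackknife_var <- function(est_fun, stratum, psu) {
  v <- 0
  for (h in unique(stratum)) {
    psus <- unique(psu[stratum == h])
    n_h <- length(psus)
    reps <- vapply(psus, function(j) {
      mult <- rep(1, length(stratum))
      mult[stratum == h] <- n_h / (n_h - 1)
      mult[psu == j] <- 0
      est_fun(mult)
    }, numeric(1))
    v <- v + (n_h - 1) / n_h * sum((reps - mean(reps))^2)
  }
  v
}

# Iterative proportional fitting on a 2x2 table of base weights, to row- and
# column-margin targets; returns the fitted cell totals.
ipf_2x2 <- function(cells, row_targets, col_targets, tol = 1e-12,
                    max_iter = 1000) {
  w <- cells
  for (i in seq_len(max_iter)) {
    w <- w * (row_targets / rowSums(w))
    w <- t(t(w) * (col_targets / colSums(w)))
    if (max(abs(rowSums(w) - row_targets) / row_targets) < tol &&
        max(abs(colSums(w) - col_targets) / col_targets) < tol) break
  }
  w
}

# Regression (GREG) form of the calibrated total, computed without touching
# the calibrated weights: T_y-hat + (T_x - T_x-hat)' B-hat with B-hat the
# design-weighted least-squares slope of y on the margin columns.
greg_regression_total <- function(y, X, w, target) {
  beta <- solve(crossprod(X, X * w), crossprod(X, w * y))
  t_hat <- as.numeric(crossprod(X, w))
  sum(w * y) + sum((target - t_hat) * beta)
}

# A small 2-stratum, 3-PSUs-per-stratum sample with several students per
# school and mild heterogeneity; used for variance-oracle comparisons.
toy_multi_psu <- function(seed = 421) {
  set.seed(seed)
  rows <- list()
  for (h in c("hA", "hB")) {
    w_h <- if (h == "hA") 4 else 2.5
    for (j in 1:3) {
      n <- 8
      rows[[length(rows) + 1]] <- data.frame(
        student_id = paste(h, j, 1:n, sep = "_"),
        school_id = paste(h, j, sep = "_"),
        stratum = h, weight = w_h, pi = 1 / w_h,
        y = rbinom(n, 1, 0.5 + 0.05 * j),
        x = rnorm(n))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("svycal_sample", "data.frame"))
}

# Minimal demographic sample for calibration tests: one row per respondent
# with the fields the margin registry needs.
demo_sample <- function(n = 12, w = rep(1, n), seed = 99) {
  set.seed(seed)
  out <- data.frame(
    student_id = paste0("s", seq_len(n)),
    school_id = paste0("psu", rep(seq_len(max(2, ceiling(n / 3))),
                                  length.out = n)),
    stratum = rep(c("h1", "h2"), length.out = n),
    sex = sample(c("female", "male"), n, replace = TRUE),
    ethnicity = sample(c("Maori", "Pacific", "Asian", "European", "Other"),
                       n, replace = TRUE),
    age_band = sample(c("le13", "a14", "a15", "a16", "ge17"), n,
                      replace = TRUE),
    decile = sample(1:10, n, replace = TRUE),
    weight = w)
  out$pi <- 1 / out$weight
  structure(out, class = c("svycal_sample", "data.frame"))
}

# A down-scaled generator configuration for structural tests that do not
# depend on the full study dimensions (census limits, determinism etc.).
small_config <- function(seed = 7L) {
  # three-point decile distribution so the emitted decile margins stay
  # representable in small frames
  dp <- c(0.4, 0, 0, 0, 0.35, 0, 0, 0, 0.25, 0)
  generator_config(
    seed = seed,
    n_schools = c(Auckland = 8, TaiTokerau = 5, Waikato = 5, Other = 8),
    n_kura = c(Auckland = 1, TaiTokerau = 1, Waikato = 1),
    n_small = 3, n_special = 1, n_partnership = 1,
    roll_mean = c(mainstream = 150, other = 130, kura = 70),
    roll_sdlog = c(mainstream = 0.3, other = 0.3, kura = 0.2),
    decile_probs = rbind(Auckland = dp, TaiTokerau = dp, Waikato = dp,
                         Other = dp),
    decile_unknown_prob = 0)
}

# Draw a default-design respondent sample from a default population; the
# workhorse input for calibration tests.
study_respondents <- function(seed = 31, response = TRUE) {
  cfg <- generator_config()
  pop <- generate_population(cfg, seed = seed)
  fs <- filter_eligible(pop$frame)
  stu <- pop$students[pop$students$school_id %in% fs$school_id, ]
  smp <- suppressWarnings(
    draw_sample(fs, stu, default_design_spec(), seed = seed + 1))
  rs <- if (response) {
    apply_nonresponse(smp, response_model(cfg), seed = seed + 2)
  } else smp
  list(pop = pop, sample = smp,
       mainstream = rs[rs$stratum != "kura", , drop = FALSE])
}
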