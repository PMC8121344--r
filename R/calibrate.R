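# Weight calibration: adjust design weights w so that weighted totals of
# margin indicator variables exactly reproduce known population totals T_x,
# while staying as close as possible to w under a distance function.
#
# Two distances are provided.  The chi-square distance sum (wt - w)^2 / (2w)
# gives the closed-form GREG solution
#
#   wt_i = w_i (1 + x_i' lambda),   (sum_i w_i x_i x_i') lambda = T_x - sum w x,
#
# algebraically identical to the regression estimator
# T_y-hat + (T_x - T_x-hat)' B-hat.  The multiplicative (raking) distance
# gives wt_i = w_i exp(x_i' lambda), solved by damped Newton iterations;
# raked weights are positive by construction and, on saturated categorical
# margins, coincide with iterative proportional fitting.
#
# Variance of a calibrated estimator uses the residual technique: residuals
# e_i = y_i - x_i' B-hat from the design-weighted regression of y on the
# margin columns are scaled by the g-weights g_i = wt_i / w_i and fed to the
# stratified linearization.  A variable lying in the span of the margins has
# zero residuals, hence zero estimated variance -- known totals are
# reproduced with no uncertainty.

# Registry mapping margin names to indicator columns on a sample.
margin_indicator <- function(sample, name) {
  dec <- function(k) as.numeric(!is.na(sample$decile) & sample$decile == k)
  switch(name,
    decile1 = dec(1), decile2 = dec(2), decile3 = dec(3), decile4 = dec(4),
    decile5 = dec(5), decile6 = dec(6), decile7 = dec(7), decile8 = dec(8),
    decile9 = dec(9), decile10 = dec(10),
    age_le13 = as.numeric(sample$age_band == "le13"),
    age14 = as.numeric(sample$age_band == "a14"),
    age15 = as.numeric(sample$age_band == "a15"),
    age16 = as.numeric(sample$age_band == "a16"),
    age_ge17 = as.numeric(sample$age_band == "ge17"),
    female = as.numeric(sample$sex == "female"),
    male = as.numeric(sample$sex == "male"),
    maori = as.numeric(sample$ethnicity == "Maori"),
    pacific = as.numeric(sample$ethnicity == "Pacific"),
    asian = as.numeric(sample$ethnicity == "Asian"),
    european = as.numeric(sample$ethnicity == "European"),
    other_ethnicity = as.numeric(sample$ethnicity == "Other"),
    kura = as.numeric(sample$stratum == "kura"),
    stop(sprintf("unknown margin name '%s'", name), call. = FALSE)
  )
}

#' Build the margin (auxiliary) matrix for calibration
#'
#' One 0/1 column per margin in the set, resolved against the sample's
#' demographic fields; an all-ones column is prepended only when the margin
#' set carries a grand total.  Errors if a margin has no sample
#' representation or the columns are collinear on the sample.
#'
#' @param sample a `svycal_sample`.
#' @param margins a [margin_set()].
#' @return list with matrix `X` (n x k), aligned `target` vector, and
#'   `names`.
#' @export
build_margin_matrix <- function(sample, margins) {
  stopifnot(inherits(margins, "margin_set"))
  nm <- names(margins$totals)
  X <- matrix(numeric(0), nrow = nrow(sample), ncol = 0)
  for (m in nm) X <- cbind(X, margin_indicator(sample, m))
  colnames(X) <- nm
  target <- unname(margins$totals)
  if (!is.null(margins$grand_total)) {
    X <- cbind(`(total)` = 1, X)
    target <- c(margins$grand_total, target)
    nm <- c("(total)", nm)
  }
  empty <- nm[colSums(X) == 0]
  if (length(empty)) {
    stop(sprintf("margin(s) with zero sample representation: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- nm[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("margin matrix is rank-deficient on this sample; dependent column(s): %s",
                 paste(dep, collapse = ", ")), call. = FALSE)
  }
  list(X = X, target = target, names = nm)
}

calibration_result <- function(sample, mm, w, w_cal, lambda, method,
                               iterations, converged) {
  achieved <- as.numeric(crossprod(mm$X, w_cal))
  rel_err <- max(abs(achieved - mm$target) /
                   pmax(abs(mm$target), .Machine$double.eps))
  g <- w_cal / w
  structure(list(sample = sample, mm = mm, w_design = w, w_cal = w_cal,
                 g = g, lambda = stats::setNames(lambda, mm$names),
                 method = method,
                 achieved = stats::setNames(achieved, mm$names),
                 target = stats::setNames(mm$target, mm$names),
                 max_rel_err = rel_err,
                 n_negative = sum(w_cal < 0),
                 iterations = iterations, converged = converged),
            class = "svycal_calibration")
}

#' Calibrate weights under the chi-square distance (GREG)
#'
#' Minimizes `sum (wt - w)^2 / (2 w)` subject to `X' wt = T_x`; the solution
#' is closed-form (one linear solve), so constraint satisfaction is exact up
#' to floating point.  Negative calibrated weights are possible and are
#' reported in the diagnostics, not suppressed.
#'
#' @param sample a `svycal_sample` of respondents with design weights.
#' @param margins a [margin_set()] (or prebuilt [build_margin_matrix()]
#'   output).
#' @param weights optional starting weights; defaults to `sample$weight`.
#' @return an object of class `svycal_calibration`; see
#'   [calibrated_estimate()], [weights.svycal_calibration()],
#'   [coef.svycal_calibration()].
#' @export
calibrate_linear <- function(sample, margins, weights = NULL) {
  w <- weights %||% sample$weight
  mm <- if (inherits(margins, "margin_set")) {
    build_margin_matrix(sample, margins)
  } else margins
  t_hat <- as.numeric(crossprod(mm$X, w))
  A <- crossprod(mm$X, mm$X * w)
  lambda <- solve(A, mm$target - t_hat)
  w_cal <- w * (1 + as.numeric(mm$X %*% lambda))
  calibration_result(sample, mm, w, w_cal, lambda, "linear", 1L, TRUE)
}

#' Calibrate weights under the multiplicative (raking) distance
#'
#' Solves `sum w exp(X lambda) x = T_x` by damped Newton iteration.
#' Calibrated weights are strictly positive by construction.  On saturated
#' categorical margins this is iterative proportional fitting.
#'
#' @inheritParams calibrate_linear
#' @param max_iter maximum Newton iterations.
#' @param tol relative tolerance on the achieved margins.
#' @return an object of class `svycal_calibration`; non-convergence is
#'   flagged (`converged = FALSE`), not raised.
#' @export
calibrate_raking <- function(sample, margins, weights = NULL,
                             max_iter = 50L, tol = 1e-8) {
  w <- weights %||% sample$weight
  mm <- if (inherits(margins, "margin_set")) {
    build_margin_matrix(sample, margins)
  } else margins
  if (any(mm$target <= 0)) {
    stop("raking requires strictly positive targets", call. = FALSE)
  }
  lambda <- numeric(ncol(mm$X))
  rel_err <- function(l) {
    wt <- w * exp(as.numeric(mm$X %*% l))
    max(abs(as.numeric(crossprod(mm$X, wt)) - mm$target) / mm$target)
  }
  err <- rel_err(lambda)
  iter <- 0L
  while (err > tol && iter < max_iter) {
    iter <- iter + 1L
    wt <- w * exp(as.numeric(mm$X %*% lambda))
    F <- as.numeric(crossprod(mm$X, wt)) - mm$target
    J <- crossprod(mm$X, mm$X * wt)
    step <- tryCatch(solve(J, F), error = function(e) NULL)
    if (is.null(step)) break
    damp <- 1
    repeat {
      cand <- lambda - damp * step
      e2 <- rel_err(cand)
      if (is.finite(e2) && e2 < err) break
      damp <- damp / 2
      if (damp < 1e-8) break
    }
    if (damp < 1e-8) break
    lambda <- lambda - damp * step
    err <- rel_err(lambda)
  }
  w_cal <- w * exp(as.numeric(mm$X %*% lambda))
  calibration_result(sample, mm, w, w_cal, lambda, "raking", iter,
                     err <= tol)
}

#' @export
print.svycal_calibration <- function(x, ...) {
  cat(sprintf("Weight calibration (%s distance), %d constraints, n = %d\n",
              x$method, length(x$target), length(x$w_cal)))
  cat(sprintf("  g-weights: min %.3f, max %.3f; negative weights: %d\n",
              min(x$g), max(x$g), x$n_negative))
  cat(sprintf("  max relative margin error: %.3g; iterations: %d%s\n",
              x$max_rel_err, x$iterations,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.svycal_calibration <- function(object, ...) {
  out <- data.frame(margin = object$mm$names,
                    target = unname(object$target),
                    achieved = unname(object$achieved),
                    lambda = unname(object$lambda))
  structure(list(table = out, cal = object),
            class = "summary.svycal_calibration")
}

#' @export
print.summary.svycal_calibration <- function(x, ...) {
  print(x$cal)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Calibrated weights and solver multipliers
#'
#' `weights()` returns the calibrated weight vector; `coef()` the Lagrange
#' multiplier vector lambda; `residuals()` the g-weights minus one (the
#' relative adjustment each respondent received).
#'
#' @param object a `svycal_calibration`.
#' @param ... unused.
#' @name calibration_accessors
NULL

#' @rdname calibration_accessors
#' @export
weights.svycal_calibration <- function(object, ...) object$w_cal

#' @rdname calibration_accessors
#' @export
coef.svycal_calibration <- function(object, ...) object$lambda

#' @rdname calibration_accessors
#' @export
residuals.svycal_calibration <- function(object, ...) object$g - 1

# Design-weighted regression coefficients of y on the margin columns,
# restricted to rows `ok`; returns the residual vector on those rows.
calibration_residuals <- function(cal, y, ok) {
  X <- cal$mm$X[ok, , drop = FALSE]
  w <- cal$w_design[ok]
  A <- crossprod(X, X * w)
  b <- as.numeric(crossprod(X, w * y[ok]))
  beta <- tryCatch(solve(A, b),
                   error = function(e) qr.coef(qr(X * sqrt(w)),
                                               sqrt(w) * y[ok]))
  beta[is.na(beta)] <- 0
  y[ok] - as.numeric(X %*% beta)
}

#' Estimate a total or proportion with calibrated weights
#'
#' Point estimates use the calibrated weights; standard errors use the GREG
#' residual technique (residuals of the variable on the margin columns,
#' multiplied by the g-weights, through the stratified linearization).  A
#' variable that is itself a calibration margin therefore has zero estimated
#' variance and a degenerate confidence interval.  Proportions use
#' `sum(wt)` over the estimation rows as denominator (no grand-total
#' constraint is imposed unless the margin set carries one).
#'
#' @param cal a `svycal_calibration` fitted on this sample.
#' @param variable outcome column name, or a margin name known to
#'   [build_margin_matrix()] (e.g. `"maori"`) to estimate a demographic
#'   total.
#' @param kind `"total"` or `"proportion"`.
#' @param domain optional 0/1 column restricting estimation, as in
#'   [svy_proportion()].
#' @param fpc optional stage-1 fractions for the variance.
#' @return an object of class `svycal_estimate` with estimator label
#'   `"calibrated"`.
#' @export
calibrated_estimate <- function(cal, variable, kind = c("total", "proportion"),
                                domain = NULL, fpc = NULL) {
  stopifnot(inherits(cal, "svycal_calibration"))
  kind <- match.arg(kind)
  sample <- cal$sample
  y <- if (variable %in% names(sample)) sample[[variable]] else {
    margin_indicator(sample, variable)
  }
  if (all(is.na(y))) {
    stop(sprintf("variable '%s' has no non-missing observations", variable),
         call. = FALSE)
  }
  ok <- !is.na(y)
  if (!is.null(domain)) {
    d <- sample[[domain]]
    if (is.null(d)) stop(sprintf("domain '%s' not found", domain),
                         call. = FALSE)
    ok <- ok & !is.na(d) & d == 1
  }
  if (!any(ok)) stop("no observations in estimation domain", call. = FALSE)
  wt <- cal$w_cal
  u <- numeric(nrow(sample))
  if (kind == "total") {
    point <- sum(wt[ok] * y[ok])
    e <- calibration_residuals(cal, y, ok)
    u[ok] <- cal$w_design[ok] * cal$g[ok] * e
  } else {
    W <- sum(wt[ok])
    point <- sum(wt[ok] * y[ok]) / W
    z <- numeric(nrow(sample))
    z[ok] <- (y[ok] - point) / W
    e <- calibration_residuals(cal, z, ok)
    u[ok] <- cal$w_design[ok] * cal$g[ok] * e
  }
  v <- linearized_variance(u, sample$stratum, sample$school_id, fpc = fpc)
  estimate_result(variable, "calibrated", point, sqrt(v), sum(ok))
}
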