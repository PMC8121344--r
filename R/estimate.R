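# Horvitz-Thompson estimation with linearized design-based variance.
#
# Totals are estimated as T-hat = sum(w_i y_i) over non-missing respondents;
# proportions as the ratio sum(w y)/sum(w) with Taylor linearization.  The
# variance estimator is the standard stratified with-replacement-PSU
# linearization
#
#   v = sum_h n_h/(n_h - 1) * sum_j (t_hj - tbar_h)^2,
#
# where t_hj is the weighted PSU (school) total of the score within stratum
# h.  No finite-population correction is applied by default, matching the
# usual complex-survey software default and erring conservative; an optional
# stage-1 FPC multiplier (1 - f1_h) can be switched on.

#' Stratified with-replacement linearized variance
#'
#' Computes `sum_h n_h/(n_h-1) sum_j (t_hj - tbar_h)^2` from per-row
#' *weighted* score contributions `u_i` (for a total of y this is `w_i y_i`).
#'
#' @param u numeric vector of weighted score contributions, one per sample
#'   row (rows outside the estimation domain contribute 0, not dropped).
#' @param stratum,psu stratum and PSU (school) identifiers per row.
#' @param fpc optional named vector of stage-1 sampling fractions `f1_h`;
#'   when supplied, each stratum's contribution is multiplied by
#'   `(1 - f1_h)`.
#' @return nonnegative variance estimate.
#' @export
linearized_variance <- function(u, stratum, psu, fpc = NULL) {
  t_hj <- rowsum(u, group = paste(stratum, psu, sep = "\r"), reorder = FALSE)
  h_of <- sub("\r.*$", "", rownames(t_hj))
  v <- 0
  for (h in unique(h_of)) {
    t_h <- t_hj[h_of == h, 1]
    n_h <- length(t_h)
    if (n_h < 2) {
      stop(sprintf(
        "stratum '%s' has a single sampled PSU; variance is undefined (consider a certainty-school/fpc treatment or merging strata)",
        h), call. = FALSE)
    }
    contrib <- n_h / (n_h - 1) * sum((t_h - mean(t_h))^2)
    if (!is.null(fpc)) {
      if (is.na(fpc[h])) stop(sprintf("no fpc fraction for stratum '%s'", h),
                              call. = FALSE)
      contrib <- contrib * (1 - fpc[[h]])
    }
    v <- v + contrib
  }
  v
}

estimate_result <- function(variable, estimator, point, se, n_used) {
  structure(list(variable = variable, estimator = estimator,
                 point = point, se = se,
                 ci95 = c(lo = point - 1.96 * se, hi = point + 1.96 * se),
                 n_used = n_used),
            class = "svycal_estimate")
}

#' @export
print.svycal_estimate <- function(x, ...) {
  cat(sprintf("%s (%s): %.4g  se %.4g  95%% CI [%.4g, %.4g]  n=%d\n",
              x$variable, x$estimator, x$point, x$se,
              x$ci95[["lo"]], x$ci95[["hi"]], x$n_used))
  invisible(x)
}

#' @export
coef.svycal_estimate <- function(object, ...) {
  stats::setNames(object$point, object$variable)
}

get_variable <- function(sample, variable) {
  if (!variable %in% names(sample)) {
    stop(sprintf("variable '%s' not found in sample", variable),
         call. = FALSE)
  }
  y <- sample[[variable]]
  if (all(is.na(y))) {
    stop(sprintf("variable '%s' has no non-missing observations", variable),
         call. = FALSE)
  }
  y
}

#' Horvitz-Thompson total
#'
#' `sum(w_i y_i)` over respondents with non-missing `variable`; rows with a
#' missing value are dropped per variable (complete-case; their weights are
#' not reallocated).  Confidence intervals are symmetric normal-approximation
#' at 1.96 and are not truncated at zero.
#'
#' @param sample a `svycal_sample` with a `weight` column.
#' @param variable name of the column to total.
#' @param weights optional replacement weight vector (e.g. all ones for the
#'   unweighted estimator); defaults to the design weights.
#' @param fpc optional stage-1 fractions passed to [linearized_variance()].
#' @return an object of class `svycal_estimate`.
#' @examples
#' s <- toy_sample(w = c(10, 10, 20), y = c(1, 0, 1))
#' svy_total(s, "y")$point  # 30
#' @export
svy_total <- function(sample, variable, weights = NULL, fpc = NULL) {
  y <- get_variable(sample, variable)
  w <- weights %||% sample$weight
  ok <- !is.na(y)
  point <- sum(w[ok] * y[ok])
  u <- numeric(nrow(sample))
  u[ok] <- w[ok] * y[ok]
  v <- linearized_variance(u, sample$stratum, sample$school_id, fpc = fpc)
  estimate_result(variable, "ht", point, sqrt(v), sum(ok))
}

#' Horvitz-Thompson (ratio) proportion
#'
#' `sum(w y)/sum(w)` over non-missing (and, if given, in-domain) respondents
#' -- a ratio estimator, with variance by Taylor linearization of the ratio:
#' score `z_i = w_i (y_i - p)/sum(w)` inside the domain and 0 outside (rows
#' outside the domain stay in the variance computation with zero score, the
#' standard domain-estimation treatment).
#'
#' @inheritParams svy_total
#' @param domain optional name of a 0/1 column restricting estimation (e.g.
#'   a question asked only of a subgroup); rows with `domain != 1` or
#'   missing are excluded from numerator and denominator.
#' @return an object of class `svycal_estimate`.
#' @export
svy_proportion <- function(sample, variable, weights = NULL, domain = NULL,
                           fpc = NULL) {
  y <- get_variable(sample, variable)
  w <- weights %||% sample$weight
  ok <- !is.na(y)
  if (!is.null(domain)) {
    d <- sample[[domain]]
    if (is.null(d)) stop(sprintf("domain '%s' not found", domain),
                         call. = FALSE)
    ok <- ok & !is.na(d) & d == 1
  }
  if (!any(ok)) stop("no observations in estimation domain", call. = FALSE)
  W <- sum(w[ok])
  point <- sum(w[ok] * y[ok]) / W
  z <- numeric(nrow(sample))
  z[ok] <- w[ok] * (y[ok] - point) / W
  v <- linearized_variance(z, sample$stratum, sample$school_id, fpc = fpc)
  estimate_result(variable, "ht", point, sqrt(v), sum(ok))
}

#' Build a tiny single-stratum sample for examples and tests
#'
#' Each element is its own PSU in one stratum with the given weights --
#' convenient for arithmetic checks.
#'
#' @param w weights; @param y outcome values.
#' @return a `svycal_sample` data.frame.
#' @keywords internal
#' @export
toy_sample <- function(w, y) {
  n <- length(w)
  structure(data.frame(student_id = paste0("s", seq_len(n)),
                       school_id = paste0("psu", seq_len(n)),
                       stratum = "h1", weight = w, pi = 1 / w, y = y),
            class = c("svycal_sample", "data.frame"))
}
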