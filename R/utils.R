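# Shared constants and small helpers.

STRATA <- c("kura", "mainstream_auckland", "mainstream_taitokerau",
            "mainstream_waikato")
STUDY_REGIONS <- c("Auckland", "TaiTokerau", "Waikato")
REGIONS <- c(STUDY_REGIONS, "Other")
SCHOOL_TYPES <- c("mainstream", "kura", "special", "partnership")
AGE_BANDS <- c("le13", "a14", "a15", "a16", "ge17")
SEXES <- c("female", "male")
ETHNICITIES <- c("Maori", "Pacific", "Asian", "European", "Other")

# Prioritised-ethnicity order (NZ Census convention): a multi-ethnic
# respondent is assigned the first of these they report.
ETHNICITY_PRIORITY <- c("Maori", "Pacific", "Asian", "Other", "European")

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (5 rounds away from
#' zero), unlike [base::round()]'s round-half-even.  Used wherever a printed
#' convention or a sample-size rule needs reproducible half-up behaviour.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(56.25, 1)  # 56.3, where round() gives 56.2
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive n reproducible child seeds from one master seed without disturbing
# the caller's RNG stream more than once.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Validate that values of `x` lie in `allowed`; NA permitted when na_ok.
check_enum <- function(x, allowed, field, na_ok = FALSE) {
  bad <- if (na_ok) !is.na(x) & !(x %in% allowed) else !(x %in% allowed)
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf("invalid value(s) for '%s' at row(s) %s: %s",
                 field, paste(utils::head(rows, 5), collapse = ", "),
                 paste(unique(utils::head(x[bad], 5)), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
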