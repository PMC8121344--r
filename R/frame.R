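# Population frame: school and student tables, margin sets, eligibility.
#
# Schools carry the design structure (stratum, region, decile, roll); students
# carry demographics and binary outcome indicators.  Files are plain UTF-8
# comma-separated text with a header row and "NA" for unknown/missing; margin
# sets are JSON maps of known population totals.

#' Map region and school type to the design stratum
#'
#' The design has four strata: all kura kaupapa Maori schools form a single
#' stratum regardless of region; mainstream schools are stratified by the
#' three study regions.  Schools outside the study regions, and special or
#' partnership schools, sit outside the design and get `NA`.
#'
#' @param region character vector of regions (`"Auckland"`, `"TaiTokerau"`,
#'   `"Waikato"`, `"Other"`).
#' @param school_type character vector (`"mainstream"`, `"kura"`,
#'   `"special"`, `"partnership"`).
#' @return character vector of stratum labels or `NA`.
#' @export
assign_stratum <- function(region, school_type) {
  out <- rep(NA_character_, length(region))
  in_study <- region %in% STUDY_REGIONS
  out[in_study & school_type == "kura"] <- "kura"
  ms <- in_study & school_type == "mainstream"
  out[ms] <- paste0("mainstream_", tolower(region[ms]))
  out
}

#' Validate a school frame
#'
#' Checks column presence, enum values (with offending row numbers), decile
#' range, nonnegative rolls, and consistency of `stratum` with
#' `(region, school_type)`.
#'
#' @param schools data.frame with columns `school_id`, `stratum`, `region`,
#'   `decile`, `roll_9_13`, `school_type`.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_schools <- function(schools) {
  check_columns(schools, c("school_id", "stratum", "region", "decile",
                           "roll_9_13", "school_type"), "school frame")
  check_enum(schools$region, REGIONS, "region")
  check_enum(schools$school_type, SCHOOL_TYPES, "school_type")
  check_enum(schools$stratum, STRATA, "stratum", na_ok = TRUE)
  dec <- schools$decile
  if (any(!is.na(dec) & (dec < 1 | dec > 10 | dec != floor(dec)))) {
    stop("decile must be an integer in 1..10 or NA", call. = FALSE)
  }
  if (any(is.na(schools$roll_9_13)) || any(schools$roll_9_13 < 0)) {
    stop("roll_9_13 must be a nonnegative integer", call. = FALSE)
  }
  expected <- assign_stratum(schools$region, schools$school_type)
  bad <- which(!is.na(expected) & (is.na(schools$stratum) |
                                     schools$stratum != expected))
  if (length(bad)) {
    stop(sprintf("stratum inconsistent with (region, school_type) at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(schools$school_id)) {
    stop("duplicate school_id in frame", call. = FALSE)
  }
  schools
}

#' Validate a student table
#'
#' @param students data.frame with columns `student_id`, `school_id`,
#'   `age_band`, `sex`, `ethnicity`, `year_level`, `responded`, plus any
#'   number of 0/1/NA outcome columns.
#' @return the validated data.frame.
#' @export
validate_students <- function(students) {
  check_columns(students, c("student_id", "school_id", "age_band", "sex",
                            "ethnicity", "year_level", "responded"),
                "student table")
  check_enum(students$age_band, AGE_BANDS, "age_band")
  check_enum(students$sex, SEXES, "sex")
  check_enum(students$ethnicity, ETHNICITIES, "ethnicity")
  if (any(!students$year_level %in% 9:13)) {
    stop("year_level must be in 9..13", call. = FALSE)
  }
  for (v in outcome_names(students)) {
    y <- students[[v]]
    if (any(!is.na(y) & !(y %in% c(0, 1)))) {
      stop(sprintf("outcome '%s' must be 0, 1 or NA", v), call. = FALSE)
    }
  }
  students
}

STUDENT_BASE_COLS <- c("student_id", "school_id", "age_band", "sex",
                       "ethnicity", "year_level", "responded")

#' Names of the outcome columns of a student table
#'
#' Every column that is not part of the fixed student schema (nor design
#' metadata added by sampling) is treated as a binary outcome.
#'
#' @param students a student data.frame.
#' @return character vector of outcome column names.
#' @export
outcome_names <- function(students) {
  setdiff(names(students),
          c(STUDENT_BASE_COLS, "stratum", "region", "decile", "weight", "pi"))
}

#' Prioritised single ethnicity from multiple reports
#'
#' Collapses multi-ethnicity reports to one value by the NZ Census priority
#' order Maori > Pacific > Asian > Other > European.  The synthetic generator
#' emits already-prioritised values, so this is only needed for external
#' multi-valued input.
#'
#' @param eth_list list whose elements are character vectors of reported
#'   ethnic groups.
#' @return character vector of single prioritised ethnicities.
#' @export
prioritise_ethnicity <- function(eth_list) {
  vapply(eth_list, function(e) {
    hit <- ETHNICITY_PRIORITY[ETHNICITY_PRIORITY %in% e]
    if (!length(hit)) stop("no recognised ethnic group in report",
                           call. = FALSE)
    hit[1]
  }, character(1))
}

#' Filter a school frame to survey-eligible schools
#'
#' Eligible schools have strictly more than `min_roll` students in years
#' 9-13, are not special or partnership schools, and (by default) lie in the
#' three study regions.  Pass `regions = NULL` to apply the roll/type rules
#' nationally.
#'
#' @param schools a validated school frame.
#' @param min_roll roll threshold; schools with `roll_9_13 > min_roll` are
#'   kept (strict inequality: a roll of exactly `min_roll` is excluded).
#' @param regions regions to keep, or `NULL` for all.
#' @return the eligible subset of `schools`.
#' @export
filter_eligible <- function(schools, min_roll = 50,
                            regions = STUDY_REGIONS) {
  stopifnot(min_roll >= 0)
  keep <- schools$roll_9_13 > min_roll &
    !(schools$school_type %in% c("special", "partnership"))
  if (!is.null(regions)) keep <- keep & schools$region %in% regions
  schools[keep, , drop = FALSE]
}

#' Summarise a population frame
#'
#' @param schools a school frame (filtered to the eligibility rule of
#'   interest before calling, or filtered here via `min_roll`/`regions`).
#' @param min_roll,regions passed to [filter_eligible()]; use
#'   `regions = NULL` for a national summary.
#' @return list with `N` (total roll over eligible schools), `n_schools`,
#'   and a per-stratum table of school and student counts.
#' @export
population_summary <- function(schools, min_roll = 50,
                               regions = STUDY_REGIONS) {
  el <- filter_eligible(schools, min_roll = min_roll, regions = regions)
  strat <- ifelse(is.na(el$stratum), "out_of_design", el$stratum)
  by_stratum <- data.frame(
    stratum = sort(unique(strat)),
    n_schools = as.integer(table(strat)[sort(unique(strat))]),
    n_students = as.numeric(tapply(el$roll_9_13, strat,
                                   sum)[sort(unique(strat))]),
    row.names = NULL
  )
  structure(list(N = sum(el$roll_9_13), n_schools = nrow(el),
                 by_stratum = by_stratum),
            class = "svycal_population_summary")
}

#' @export
print.svycal_population_summary <- function(x, ...) {
  cat("Population summary:", x$n_schools, "eligible schools,",
      format(x$N, big.mark = ","), "students\n")
  print(x$by_stratum, row.names = FALSE)
  invisible(x)
}

# ---- margin sets -----------------------------------------------------------

#' Construct a margin set of known population totals
#'
#' A margin set names the calibration targets: known totals of demographic
#' indicator variables (for example `female`, `maori`, `decile1`) at either
#' the regional or national level, with an optional grand total.
#'
#' @param level `"regional"` or `"national"`.
#' @param totals named numeric vector or list of nonnegative totals.
#' @param grand_total optional nonnegative population size; every margin
#'   total must not exceed it.
#' @return an object of class `margin_set`.
#' @export
margin_set <- function(level, totals, grand_total = NULL) {
  level <- match.arg(level, c("regional", "national"))
  totals <- unlist(totals) %||% stats::setNames(numeric(0), character(0))
  if (length(totals) == 0 && is.null(grand_total)) {
    stop("margin set needs at least one total or a grand_total",
         call. = FALSE)
  }
  if (length(totals) &&
      (is.null(names(totals)) || any(names(totals) == ""))) {
    stop("margin totals must be named", call. = FALSE)
  }
  if (any(totals < 0)) stop("margin totals must be nonnegative",
                            call. = FALSE)
  if (!is.null(grand_total)) {
    if (grand_total < 0) stop("grand_total must be nonnegative",
                              call. = FALSE)
    if (any(totals > grand_total)) {
      stop("margin total exceeds grand_total", call. = FALSE)
    }
  }
  structure(list(level = level, totals = totals, grand_total = grand_total),
            class = "margin_set")
}

#' @export
print.margin_set <- function(x, ...) {
  cat(sprintf("Margin set (%s), %d margins%s\n", x$level, length(x$totals),
              if (is.null(x$grand_total)) ""
              else sprintf(", grand total %s",
                           format(x$grand_total, big.mark = ","))))
  print(x$totals)
  invisible(x)
}

#' Select a subset of margins by name
#'
#' @param margins a [margin_set()].
#' @param names margin names to keep.
#' @return a `margin_set` restricted to `names`.
#' @export
select_margins <- function(margins, names) {
  missing <- setdiff(names, names(margins$totals))
  if (length(missing)) {
    stop(sprintf("margin set has no entry for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  margin_set(margins$level, margins$totals[names], margins$grand_total)
}

# ---- file I/O --------------------------------------------------------------

#' Read and write school frames, student tables, and margin sets
#'
#' Plain comma-separated UTF-8 text with a header row; unknown/missing values
#' are written and parsed as `NA` (an `"NA"` decile reads back as unknown).
#' Margin sets are JSON documents `{level, totals: {name: value},
#' grand_total?}`.  Round trips are exact field-for-field.
#'
#' @param path file path.
#' @param schools,students,margins objects to write.
#' @return the read functions return validated objects; the write functions
#'   return the input invisibly.
#' @name frame_io
NULL

#' @rdname frame_io
#' @export
read_school_frame <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_schools(df)
}

#' @rdname frame_io
#' @export
write_school_frame <- function(schools, path) {
  utils::write.csv(validate_schools(schools), path, row.names = FALSE,
                   na = "NA")
  invisible(schools)
}

#' @rdname frame_io
#' @export
read_students <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_students(df)
}

#' @rdname frame_io
#' @export
write_students <- function(students, path) {
  utils::write.csv(validate_students(students), path, row.names = FALSE,
                   na = "NA")
  invisible(students)
}

#' @rdname frame_io
#' @export
read_margins <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_columns(x, c("level", "totals"), "margins file")
  margin_set(x$level, unlist(x$totals), x$grand_total)
}

#' @rdname frame_io
#' @export
write_margins <- function(margins, path) {
  stopifnot(inherits(margins, "margin_set"))
  x <- list(level = margins$level, totals = as.list(margins$totals))
  if (!is.null(margins$grand_total)) x$grand_total <- margins$grand_total
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(margins)
}
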