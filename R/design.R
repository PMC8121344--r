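# Two-stage stratified cluster sampling and design weights.
#
# Stage 1 samples schools (the PSUs) by simple random sampling without
# replacement within each stratum at fraction f1; stage 2 samples students
# within each selected school at fraction f2 (f2 = 1 in kura and in
# certainty-override schools).  Design weights are exact inverse inclusion
# probabilities w = 1/(f1 * f2).  Stage-2 draws are independent across
# schools; joint inclusion probabilities are not tracked (the downstream
# variance estimator uses the with-replacement PSU approximation).

#' Specify the two-stage sampling design
#'
#' @param f1 named numeric vector of per-stratum school sampling fractions in
#'   (0, 1].
#' @param f2 named numeric vector of per-stratum student sampling fractions
#'   in (0, 1].
#' @param certainty_schools character vector of school ids whose whole roll
#'   is invited (stage-2 fraction forced to 1), regardless of stratum f2.
#' @return an object of class `design_spec`.
#' @examples
#' # The study design: 50% of mainstream schools, 30% of their students;
#' # 6 of 8 kura invited with all their students.
#' default_design_spec()
#' @export
design_spec <- function(f1, f2, certainty_schools = character(0)) {
  stopifnot(is.numeric(f1), is.numeric(f2),
            !is.null(names(f1)), !is.null(names(f2)))
  if (any(f1 <= 0 | f1 > 1) || any(f2 <= 0 | f2 > 1)) {
    stop("sampling fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(f1 = f1, f2 = f2,
                 certainty_schools = as.character(certainty_schools)),
            class = "design_spec")
}

#' @rdname design_spec
#' @export
default_design_spec <- function(certainty_schools = character(0)) {
  design_spec(
    f1 = c(kura = 6 / 8, mainstream_auckland = 0.5,
           mainstream_taitokerau = 0.5, mainstream_waikato = 0.5),
    f2 = c(kura = 1, mainstream_auckland = 0.3,
           mainstream_taitokerau = 0.3, mainstream_waikato = 0.3),
    certainty_schools = certainty_schools
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Two-stage design: school fractions f1 =",
      paste(sprintf("%s:%.3g", names(x$f1), x$f1), collapse = ", "), "\n")
  cat("  student fractions f2 =",
      paste(sprintf("%s:%.3g", names(x$f2), x$f2), collapse = ", "), "\n")
  if (length(x$certainty_schools)) {
    cat("  certainty (100% roll) schools:",
        paste(x$certainty_schools, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Inclusion probability of a student under the design
#'
#' For a student in `school_id` within `stratum`, the inclusion probability
#' is the product of the stage-1 school fraction and the stage-2 student
#' fraction, `pi = f1[stratum] * f2`, with `f2 = 1` for certainty-override
#' schools.  Deterministic given the spec.
#'
#' @param spec a [design_spec()].
#' @param stratum stratum label(s).
#' @param school_id school id(s), recycled against `stratum`.
#' @return numeric vector of inclusion probabilities.
#' @export
inclusion_probability <- function(spec, stratum, school_id) {
  stopifnot(inherits(spec, "design_spec"))
  missing <- setdiff(unique(stratum), names(spec$f1))
  if (length(missing)) {
    stop(sprintf("no sampling fraction defined for stratum: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  f2 <- unname(spec$f2[stratum])
  f2[school_id %in% spec$certainty_schools] <- 1
  unname(spec$f1[stratum]) * f2
}

# Precompute the row-index split of a student table by school, so repeated
# draws (simulation mode) avoid re-splitting 10^5 rows each time.
school_index <- function(students) {
  split(seq_len(nrow(students)), students$school_id)
}

#' Draw a two-stage sample and attach design weights
#'
#' Stage 1: within each stratum of the (eligibility-filtered) frame,
#' `round_half_up(f1 * N_h)` schools are drawn by SRSWOR.  Stage 2: within
#' each selected school, `round_half_up(f2 * roll)` of its students are drawn
#' by SRSWOR (all of them when f2 = 1 or the school is a certainty school).
#' Every sampled student gets `pi = f1 * f2` and `weight = 1/pi`.
#'
#' @param frame eligible school frame (rows must have non-`NA` stratum).
#' @param students student table; only students of sampled schools appear in
#'   the output.
#' @param spec a [design_spec()] covering every stratum in `frame`.
#' @param seed optional integer; set for a reproducible draw.
#' @param .index optional precomputed [school_index()] of `students`.
#' @return a `svycal_sample`: the sampled student rows joined to `stratum`,
#'   `region`, `decile`, `pi` and `weight`, with the per-stratum school
#'   counts in `attr(, "schools_sampled")`.  A stratum with fewer than two
#'   selected schools is flagged in `attr(, "lonely_strata")` with a warning
#'   (its variance cannot be estimated later).
#' @export
draw_sample <- function(frame, students, spec, seed = NULL, .index = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (any(is.na(frame$stratum))) {
    stop("frame contains out-of-design schools (NA stratum); filter first",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- .index %||% school_index(students)

  sel_schools <- character(0)
  for (h in unique(frame$stratum)) {
    ids <- frame$school_id[frame$stratum == h]
    n_h <- round_half_up(spec$f1[[h]] * length(ids))
    n_h <- max(0L, min(length(ids), as.integer(n_h)))
    sel_schools <- c(sel_schools, sample(ids, n_h))
  }
  sel <- frame[match(sel_schools, frame$school_id), , drop = FALSE]

  rows <- vector("list", nrow(sel))
  for (k in seq_len(nrow(sel))) {
    sid <- sel$school_id[k]
    pool <- idx[[sid]]
    if (is.null(pool)) next
    f2 <- if (sid %in% spec$certainty_schools) 1 else spec$f2[[sel$stratum[k]]]
    m <- if (f2 >= 1) length(pool) else {
      max(1L, min(length(pool),
                  as.integer(round_half_up(f2 * length(pool)))))
    }
    rows[[k]] <- if (m == length(pool)) pool else sample(pool, m)
  }
  take <- unlist(rows, use.names = FALSE)
  out <- students[take, , drop = FALSE]

  pos <- match(out$school_id, sel$school_id)
  out$stratum <- sel$stratum[pos]
  out$region <- sel$region[pos]
  out$decile <- sel$decile[pos]
  out$pi <- inclusion_probability(spec, out$stratum, out$school_id)
  out$weight <- 1 / out$pi
  rownames(out) <- NULL

  n_sel <- table(sel$stratum)
  lonely <- names(n_sel)[n_sel < 2]
  if (length(lonely)) {
    warning(sprintf("stratum with fewer than 2 sampled schools: %s",
                    paste(lonely, collapse = ", ")), call. = FALSE)
  }
  structure(out, class = c("svycal_sample", "data.frame"),
            schools_sampled = n_sel, lonely_strata = lonely)
}

#' Apply school- and student-level nonresponse
#'
#' Drops refusing schools and absent students according to a response model
#' (see [response_model()]).  Design weights are left untouched: nonresponse
#' is corrected only downstream by calibration, never by reweighting here.
#'
#' @param sample a `svycal_sample` from [draw_sample()].
#' @param model a list with `p_school` (per-school response probability) and
#'   `student_prob` (function mapping student rows to response
#'   probabilities), as returned by [response_model()].
#' @param seed optional integer for a reproducible realisation.
#' @return the responding subset of `sample`, with `responded` set to 1.
#' @export
apply_nonresponse <- function(sample, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  schools <- unique(sample$school_id)
  resp_school <- schools[stats::runif(length(schools)) < model$p_school]
  out <- sample[sample$school_id %in% resp_school, , drop = FALSE]
  if (nrow(out)) {
    p <- model$student_prob(out)
    out <- out[stats::runif(nrow(out)) < p, , drop = FALSE]
  }
  if (nrow(out)) out$responded <- 1L
  rownames(out) <- NULL
  n_resp <- table(out$stratum[!duplicated(out$school_id)])
  structure(out, class = c("svycal_sample", "data.frame"),
            schools_sampled = attr(sample, "schools_sampled"),
            schools_responding = n_resp,
            lonely_strata = names(n_resp)[n_resp < 2])
}
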