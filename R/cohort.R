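#' Cohort selection rules
#'
#' Bundle of the cohort-selection and windowing rules: adult patients
#' (age >= 18 years), ICU stay of at least 4 hours (inclusive), first ICU
#' admission only, and a 24-hour observation window.
#'
#' @param window_hours Observation window length in hours (default 24).
#' @param min_stay_hours Minimum ICU length of stay in hours (default 4).
#' @param min_age_years Minimum age in years (default 18).
#' @return An object of class `cohort_window`.
#' @export
cohort_window <- function(window_hours = 24, min_stay_hours = 4,
                          min_age_years = 18) {
  stopifnot(window_hours > 0, min_stay_hours > 0, min_age_years > 0)
  structure(list(window_hours = window_hours,
                 min_stay_hours = min_stay_hours,
                 min_age_years = min_age_years),
            class = "cohort_window")
}

#' Apply cohort-selection rules to a stay table
#'
#' Retains stays with `age >= min_age_years`, `icu_los_hours >=
#' min_stay_hours` ("at least 4 hours" is inclusive) and `icu_admit_rank ==
#' 1` (first ICU admission). Input row order is preserved; the operation is
#' idempotent.
#'
#' @param stays Stay table (data.frame).
#' @param rules A [cohort_window()].
#' @return The filtered stay table.
#' @export
select_cohort <- function(stays, rules = cohort_window()) {
  req <- c("age", "icu_los_hours", "icu_admit_rank")
  missing_cols <- setdiff(req, names(stays))
  if (length(missing_cols) > 0)
    stop("stay table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- stays$age >= rules$min_age_years &
    stays$icu_los_hours >= rules$min_stay_hours &
    stays$icu_admit_rank == 1
  out <- stays[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clip observation and note tables to the observation window
#'
#' Retains events with `t` in the half-open interval `[0, window_hours)`.
#' The half-open convention avoids double-counting an event falling exactly
#' on the boundary. Original row order is preserved; applying the operation
#' twice equals applying it once.
#'
#' @param observations Observation table with column `t` (hours since ICU
#'   admission), or NULL.
#' @param notes Note table with column `t`, or NULL.
#' @param rules A [cohort_window()].
#' @return A list with elements `observations` and `notes`.
#' @export
clip_window <- function(observations, notes, rules = cohort_window()) {
  clip1 <- function(tab) {
    if (is.null(tab)) return(NULL)
    if (nrow(tab) == 0) return(tab)
    if (any(tab$t < 0))
      stop("negative event time t; times are hours since ICU admission",
           call. = FALSE)
    out <- tab[tab$t < rules$window_hours, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(observations = clip1(observations), notes = clip1(notes))
}
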