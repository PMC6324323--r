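# Trajectory feature engineering: per-variable summaries over all
# observations in the 24-hour window, assembled into patient x predictor
# matrices with train-only median imputation.

.measures_all <- c("min", "max", "mean", "sd", "first", "last",
                   "delta", "slope")
.measures_baseline <- c("min", "max")

# Minimum observation time span (hours) for a least-squares slope to count
# as an estimate of the 24-hour trend. Slopes from observations clustered
# within a shorter span are dominated by measurement noise divided by a
# near-zero time spread (heavy-tailed, practically meaningless) and are
# treated as missing, like any other unavailable measure.
.slope_min_span <- 1

#' Ordinary least-squares slope of value on time
#'
#' @param t Numeric vector of times (hours).
#' @param value Numeric vector of observed values.
#' @return The OLS slope in units per hour, or `NA_real_` with fewer than
#'   two points or when all times coincide (missing is a value, not an
#'   error).
#' @export
ls_slope <- function(t, value) {
  n <- length(t)
  if (n < 2) return(NA_real_)
  td <- t - mean(t)
  den <- sum(td^2)
  if (den == 0) return(NA_real_)
  sum(td * (value - mean(value))) / den
}

#' Summarize one patient's observations of one variable
#'
#' Computes the eight trajectory measures: minimum, maximum, mean, sample
#' (n-1) SD, first value, last value, last-minus-first difference, and
#' least-squares slope per hour. "First" and "last" are by ascending time
#' with ties broken by input order. With fewer than two observations the
#' SD, slope and difference are missing (downstream median imputation fills
#' them); with none, all eight are missing. The slope is additionally
#' missing when the observations span less than one hour: dividing
#' measurement noise by a near-zero time spread yields heavy-tailed values
#' that estimate nothing about the 24-hour trend.
#'
#' @param t Numeric vector of observation times (hours), already windowed.
#' @param value Numeric vector of observed values.
#' @return Named numeric vector of the eight measures.
#' @export
summarize_variable <- function(t, value) {
  out <- setNames(rep(NA_real_, 8L), .measures_all)
  n <- length(t)
  if (n == 0) return(out)
  ord <- order(t)  # stable: ties keep input order
  v <- value[ord]
  out["min"] <- min(value)
  out["max"] <- max(value)
  out["mean"] <- mean(value)
  out["first"] <- v[1L]
  out["last"] <- v[n]
  if (n >= 2) {
    out["sd"] <- sd(value)
    out["delta"] <- v[n] - v[1L]
    if (max(t) - min(t) >= .slope_min_span)
      out["slope"] <- ls_slope(t, value)
  }
  out
}

# Grouped computation of the 8 measures for all (patient, variable) pairs.
# Returns a numeric matrix (patients x 8V) with NA for unobserved cells;
# rows follow patient_ids, columns are variable-major, measure-minor.
.trajectory_raw <- function(observations, patient_ids, variables) {
  n <- length(patient_ids)
  cols <- as.vector(t(outer(variables, .measures_all, paste, sep = ".")))
  M <- matrix(NA_real_, n, length(cols),
              dimnames = list(patient_ids, cols))
  if (is.null(observations) || nrow(observations) == 0) return(M)
  DT <- data.table::as.data.table(
    observations[, c("patient_id", "variable", "t", "value")])
  DT <- DT[patient_id %in% patient_ids & variable %in% variables]
  if (nrow(DT) == 0) return(M)
  DT[, obs_idx := .I]
  data.table::setorder(DT, variable, patient_id, t, obs_idx)
  agg <- DT[, {
    nn <- .N
    vord <- value
    list(min = min(value), max = max(value), mean = mean(value),
         sd = if (nn >= 2) stats::sd(value) else NA_real_,
         first = vord[1L], last = vord[nn],
         delta = if (nn >= 2) vord[nn] - vord[1L] else NA_real_,
         slope = {
           if (nn < 2 || t[nn] - t[1L] < .slope_min_span) NA_real_ else {
             td <- t - mean(t); den <- sum(td^2)
             if (den == 0) NA_real_
             else sum(td * (value - mean(value))) / den
           }
         })
  }, by = list(variable, patient_id)]
  ri <- match(agg$patient_id, patient_ids)
  for (m in .measures_all) {
    ci <- match(paste(agg$variable, m, sep = "."), cols)
    M[cbind(ri, ci)] <- agg[[m]]
  }
  M
}

#' Build a structured feature matrix from cohort tables
#'
#' Assembles the patient-by-predictor design matrix for the structured
#' (non-text) part of the model. In `baseline` mode each variable
#' contributes its minimum and maximum (2V columns, a surrogate for
#' worst-value severity scores); in `trajectory` mode all eight summary
#' measures (8V columns). Column order is variable-major, measure-minor and
#' stable. Cells remain `NA` until imputation ([fit_impute()]).
#'
#' @param stays Selected stay table (defines patients and outcomes).
#' @param observations Windowed observation table.
#' @param variables Character vector of variable names; every name must
#'   appear in the observation table's configured variable set (unknown
#'   names are a configuration error). Defaults to the generator's
#'   24-variable set.
#' @param mode `"baseline"` or `"trajectory"`.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `patient_id`, `y` (0/1 in-hospital death), `mode`,
#'   `variables`, and slots `medians` / `standardization` filled at fit
#'   time.
#' @export
build_feature_matrix <- function(stays, observations,
                                 variables = default_variable_specs()$variable,
                                 mode = c("trajectory", "baseline")) {
  mode <- match.arg(mode)
  if (nrow(observations) > 0) {
    unknown <- setdiff(variables, unique(observations$variable))
    # unknown variables yield all-NA columns; a name absent everywhere is
    # almost always a configuration typo
    if (length(unknown) == length(variables))
      stop("none of the requested variables appear in the observation table",
           call. = FALSE)
  }
  raw <- .trajectory_raw(observations, stays$patient_id, variables)
  measures <- if (mode == "baseline") .measures_baseline else .measures_all
  keep <- as.vector(t(outer(variables, measures, paste, sep = ".")))
  x <- raw[, keep, drop = FALSE]
  structure(
    list(x = x, patient_id = stays$patient_id,
         y = as.integer(stays$died_in_hospital),
         mode = mode, variables = variables,
         medians = NULL, standardization = NULL),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d patients x %d predictors (%s mode)\n",
              nrow(x$x), ncol(x$x), x$mode))
  cat(sprintf("  missing cells: %.1f%%; imputation medians %s\n",
              100 * mean(is.na(x$x)),
              if (is.null(x$medians)) "not fitted" else "fitted"))
  invisible(x)
}

#' Learn per-predictor imputation medians on training data
#'
#' Computes the median nonmissing value of each predictor column and
#' replaces missing cells with it. Must be called on training rows only;
#' the stored medians are reused on test data via [apply_impute()] so no
#' information leaks from test to train.
#'
#' @param fm A `feature_matrix` (training rows only).
#' @return The `feature_matrix` with `x` imputed and `medians` set.
#' @export
fit_impute <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  med <- apply(fm$x, 2, median, na.rm = TRUE)
  all_na <- !is.finite(med)
  if (any(all_na))
    stop("predictor(s) missing in all training rows: ",
         paste(names(med)[all_na], collapse = ", "),
         "; drop these predictors before fitting", call. = FALSE)
  fm$x <- .impute_with(fm$x, med)
  fm$medians <- med
  fm
}

#' Apply previously learned imputation medians
#'
#' @param fm A `feature_matrix` (e.g. test rows).
#' @param medians Named vector of per-predictor medians from [fit_impute()].
#' @return The `feature_matrix` with `x` imputed using the supplied medians.
#' @export
apply_impute <- function(fm, medians) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!identical(colnames(fm$x), names(medians)))
    stop("median names do not match predictor columns", call. = FALSE)
  fm$x <- .impute_with(fm$x, medians)
  fm$medians <- medians
  fm
}

.impute_with <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[j]
  }
  x
}
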