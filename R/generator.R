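#' Default laboratory and vital-sign specifications
#'
#' Returns the 24-variable specification table used by the synthetic cohort
#' generator. Each row describes one lab or vital sign: a between-patient
#' baseline distribution, an additive baseline shift for nonsurvivors, a
#' within-patient measurement noise SD, a linear trend per hour for survivors
#' and nonsurvivors, a Poisson sampling rate per hour, and the probability
#' that the variable is entirely unobserved for a patient (elevated for
#' arterial blood-gas values and lactate, where ICU missingness is
#' characteristically high).
#'
#' The Glasgow Coma Scale trends (total and eye/verbal/motor components) are
#' the published survivor/nonsurvivor mean trends; for the chemistry panel
#' the published survivor/nonsurvivor last-minus-first differences over the
#' 24-hour window are encoded as trend = difference / 24 h. Remaining rates,
#' SDs and shifts are fixed realistic defaults (see the methods vignette).
#'
#' @return A data.frame with columns `variable`, `baseline_mean`,
#'   `baseline_sd`, `shift_nonsurvivor`, `noise_sd`, `trend_survivor`,
#'   `trend_nonsurvivor`, `rate_per_hour`, `missing_prob`.
#' @export
default_variable_specs <- function() {
  spec <- rbind(
    # variable         mean   bsd  shift  nsd   tr_s      tr_n      rate  miss
    c("gcs_total",     13.2,  2.0, -0.35, 2.2,  0.124,   -0.034,    0.30, 0.01),
    c("gcs_eye",        3.4,  0.6, -0.10, 1.2,  0.031,   -0.012,    0.30, 0.01),
    c("gcs_verbal",     4.2,  0.8, -0.12, 1.5,  0.049,   -0.016,    0.30, 0.01),
    c("gcs_motor",      5.5,  0.7, -0.10, 1.4,  0.043,   -0.002,    0.30, 0.01),
    c("heart_rate",    86,   14,    2,   10,    0,        0.08,     1.0,  0.005),
    c("resp_rate",     18,    4,    0.6,  3,    0,        0.02,     1.0,  0.005),
    c("sbp",          122,   17,   -2.5, 12,    0,       -0.10,     1.0,  0.005),
    c("dbp",           68,   11,   -1.5,  8,    0,       -0.05,     1.0,  0.005),
    c("map",           86,   12,   -1.8,  9,    0,       -0.08,     1.0,  0.005),
    c("temperature",   37.0,  0.6,  0.08, 0.4,  0,        0,        0.5,  0.01),
    c("spo2",          96.5,  2.0, -0.3,  1.5,  0,       -0.02,     1.0,  0.005),
    c("sodium",       139,    3.5,  0.5,  2.0,  0.014375, 0.04125,  0.15, 0.05),
    c("potassium",      4.1,  0.5,  0.06, 0.3, -0.003083, 0.004125, 0.15, 0.05),
    c("bilirubin",      0.9,  0.6,  0.1,  0.25,-0.001458, 0.005167, 0.10, 0.15),
    c("urea",          22,    9,    1.2,  4,   -0.027375, 0.012833, 0.12, 0.05),
    c("creatinine",     1.1,  0.5,  0.08, 0.2,  0,        0.005,    0.12, 0.05),
    c("lactate",        1.6,  0.8,  0.25, 0.5, -0.016125, 0.033417, 0.08, 0.55),
    c("ph",             7.38, 0.05,-0.008,0.03, 0,       -0.0005,   0.10, 0.60),
    c("pao2",          95,   25,   -3.5, 15,    0,       -0.15,     0.10, 0.60),
    c("paco2",         40,    6,    0.8,  4,    0,        0.05,     0.10, 0.60),
    c("bicarbonate",   24,    3.5, -0.5,  2,    0,       -0.03,     0.12, 0.30),
    c("wbc",            9.5,  3.5,  0.5,  1.5,  0,        0.02,     0.10, 0.05),
    c("hematocrit",    34,    5,   -0.6,  2,    0,       -0.01,     0.12, 0.05),
    c("platelets",    230,   80,  -10,   25,    0,       -0.5,      0.10, 0.05)
  )
  out <- data.frame(
    variable = spec[, 1],
    baseline_mean = as.numeric(spec[, 2]),
    baseline_sd = as.numeric(spec[, 3]),
    shift_nonsurvivor = as.numeric(spec[, 4]),
    noise_sd = as.numeric(spec[, 5]),
    trend_survivor = as.numeric(spec[, 6]),
    trend_nonsurvivor = as.numeric(spec[, 7]),
    rate_per_hour = as.numeric(spec[, 8]),
    missing_prob = as.numeric(spec[, 9]),
    stringsAsFactors = FALSE
  )
  out
}

# Common clinical filler words given the largest background weights so
# synthetic notes read plausibly; purely neutral with respect to outcome.
.common_words <- c(
  "patient", "plan", "stable", "continue", "monitor", "assessment", "icu",
  "admitted", "history", "exam", "labs", "noted", "overnight", "status",
  "today", "family", "care", "daily", "review", "medications", "fluids",
  "output", "improved", "unchanged", "tolerating", "remains", "will",
  "follow", "consult", "ordered"
)

#' Default note term specifications
#'
#' Returns the term table used by the synthetic note generator: a list of
#' outcome-associated clinical terms with signed log-odds shifts (terms such
#' as "pupils", "fixed", "gag", "ecmo", "sepsis", "shock" are more frequent
#' in notes of patients who die; "extubated", "awake", "alert", "denies",
#' "pod", "perrl" are more frequent in survivors' notes), a set of common
#' neutral clinical words, and a Zipf-weighted background vocabulary of
#' `n_filler` neutral filler terms so that top-k vocabulary filtering is
#' meaningful.
#'
#' @param n_filler Number of neutral background terms (default 1500).
#' @return A data.frame with columns `term`, `base_weight` (unnormalized
#'   sampling weight) and `outcome_shift` (log-odds shift applied to the
#'   weight for patients who die in hospital).
#' @export
default_term_specs <- function(n_filler = 1500) {
  signal <- data.frame(
    term = c("pupils", "fixed", "gag", "ecmo", "coagulopathy", "shock",
             "intubated", "pea", "chemotherapy", "ascites", "cvvh",
             "sepsis", "meropenem",
             "etoh", "ohns", "alert", "ebl", "diet", "awake", "perrl",
             "denies", "pod", "extubated"),
    base_weight = c(0.030, 0.030, 0.020, 0.008, 0.012, 0.035,
                    0.040, 0.010, 0.012, 0.015, 0.008,
                    0.035, 0.010,
                    0.020, 0.012, 0.070, 0.025, 0.030, 0.060, 0.040,
                    0.050, 0.040, 0.045),
    outcome_shift = c(1.8, 1.8, 1.6, 1.5, 1.2, 1.2,
                      1.0, 1.4, 0.8, 1.3, 1.0,
                      1.1, 0.9,
                      -0.6, -0.7, -0.9, -1.0, -0.8, -1.0, -1.2,
                      -1.1, -1.3, -1.5),
    stringsAsFactors = FALSE
  )
  n_common <- length(.common_words)
  filler_names <- c(.common_words,
                    sprintf("w%04d", seq_len(max(0L, n_filler - n_common))))
  filler <- data.frame(
    term = filler_names,
    base_weight = 1 / seq_along(filler_names)^0.8,
    outcome_shift = 0,
    stringsAsFactors = FALSE
  )
  rbind(signal, filler)
}

#' Default site effects
#'
#' Three synthetic hospital sites with mixture weights, mortality and
#' missingness scalings, a case-mix age shift, and per-site boosted "local
#' jargon" terms so that per-site top-k vocabularies differ. Mortality
#' scalings are renormalized at generation time so the cohort-wide
#' prevalence equals the configured value exactly in expectation.
#'
#' @return A list with `sites` (data.frame: `site`, `weight`,
#'   `prevalence_scale`, `missing_scale`, `age_shift`) and `term_scale`
#'   (named list per site of named term weight multipliers).
#' @export
default_site_effects <- function() {
  list(
    sites = data.frame(
      site = c("site_a", "site_b", "site_c"),
      weight = c(0.40, 0.25, 0.35),
      prevalence_scale = c(1.00, 1.15, 0.88),
      missing_scale = c(1.0, 1.3, 0.8),
      age_shift = c(0, 3, -2),
      stringsAsFactors = FALSE
    ),
    term_scale = list(
      site_a = c(w0150 = 8, w0151 = 8, w0152 = 8),
      site_b = c(w0160 = 8, w0161 = 8, w0162 = 8),
      site_c = c(w0170 = 8, w0171 = 8, w0172 = 8)
    )
  )
}

#' Generator configuration
#'
#' Assemble and validate the configuration of the synthetic multi-site ICU
#' cohort generator. Defaults reproduce the statistical structure the
#' downstream models assume: 10.4% in-hospital mortality, 14.7% of deaths
#' within the first 24 hours, outcome-dependent trajectory trends (Glasgow
#' Coma Scale trend +0.124 points/h in survivors vs -0.034 in nonsurvivors),
#' outcome-dependent note term frequencies, and per-site case mix,
#' vocabulary and missingness differences.
#'
#' @param n_patients Number of patients to generate.
#' @param mortality_prevalence Probability of in-hospital death (default 0.104).
#' @param frac_deaths_within_24h Fraction of decedents dying before 24 h
#'   (default 0.147).
#' @param variable_specs Data frame as returned by [default_variable_specs()].
#' @param term_specs Data frame as returned by [default_term_specs()].
#' @param site_effects List as returned by [default_site_effects()].
#' @param mean_tokens Mean note-set token count per patient (Poisson).
#' @param mean_notes Mean number of notes per patient in excess of one.
#' @param seed Integer seed; the full output is a deterministic function of
#'   the configuration including the seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             mortality_prevalence = 0.104,
                             frac_deaths_within_24h = 0.147,
                             variable_specs = default_variable_specs(),
                             term_specs = default_term_specs(),
                             site_effects = default_site_effects(),
                             mean_tokens = 120,
                             mean_notes = 2,
                             seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer", call. = FALSE)
  for (p in c(mortality_prevalence, frac_deaths_within_24h)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.data.frame(variable_specs) || nrow(variable_specs) < 1)
    stop("variable_specs must contain at least one variable", call. = FALSE)
  req_v <- c("variable", "baseline_mean", "baseline_sd", "shift_nonsurvivor",
             "noise_sd", "trend_survivor", "trend_nonsurvivor",
             "rate_per_hour", "missing_prob")
  if (!all(req_v %in% names(variable_specs)))
    stop("variable_specs is missing columns: ",
         paste(setdiff(req_v, names(variable_specs)), collapse = ", "),
         call. = FALSE)
  if (any(variable_specs$missing_prob < 0 | variable_specs$missing_prob > 1))
    stop("missing_prob must lie in [0, 1]", call. = FALSE)
  if (!is.data.frame(term_specs) || nrow(term_specs) < 1)
    stop("term_specs must contain at least one term", call. = FALSE)
  if (!all(c("term", "base_weight", "outcome_shift") %in% names(term_specs)))
    stop("term_specs needs columns term, base_weight, outcome_shift",
         call. = FALSE)
  if (any(term_specs$base_weight <= 0))
    stop("term base_weight must be positive", call. = FALSE)
  sites <- site_effects$sites
  if (is.null(sites) || nrow(sites) < 1)
    stop("site_effects$sites must contain at least one site", call. = FALSE)
  if (abs(sum(sites$weight) - 1) > 1e-8)
    stop("site mixture weights must sum to 1", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients),
         mortality_prevalence = mortality_prevalence,
         frac_deaths_within_24h = frac_deaths_within_24h,
         variable_specs = variable_specs,
         term_specs = term_specs,
         site_effects = site_effects,
         mean_tokens = mean_tokens,
         mean_notes = mean_notes,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic ICU cohort generator configuration\n")
  cat(sprintf("  patients: %d across %d sites\n", x$n_patients,
              nrow(x$site_effects$sites)))
  cat(sprintf("  mortality prevalence: %.3f (%.1f%% of deaths < 24 h)\n",
              x$mortality_prevalence, 100 * x$frac_deaths_within_24h))
  cat(sprintf("  variables: %d; note terms: %d; seed: %d\n",
              nrow(x$variable_specs), nrow(x$term_specs), x$seed))
  invisible(x)
}

#' Sample one patient's trajectory for a single variable
#'
#' Observation times are a homogeneous Poisson process on `[0, t_max)`;
#' values follow `baseline + trend * t + noise`. With probability
#' `missing_prob` the variable is entirely unobserved (empty result). Uses
#' the current RNG state.
#'
#' @param spec One row of a variable specification table
#'   (see [default_variable_specs()]).
#' @param died Logical; selects the nonsurvivor trend and baseline shift.
#' @param t_max Upper end of the observation window in hours (default 24;
#'   decedents dying earlier stop generating observations at death).
#' @param site_missing_scale Multiplier on the missingness probability.
#' @return A data.frame with columns `t` (hours) and `value`, ordered by `t`.
#' @export
sample_trajectory <- function(spec, died, t_max = 24, site_missing_scale = 1) {
  pmiss <- min(spec$missing_prob * site_missing_scale, 1)
  if (runif(1) < pmiss) return(data.frame(t = numeric(0), value = numeric(0)))
  n <- rpois(1, spec$rate_per_hour * t_max)
  if (n == 0) return(data.frame(t = numeric(0), value = numeric(0)))
  t <- sort(runif(n, 0, t_max))
  base <- rnorm(1, spec$baseline_mean + if (died) spec$shift_nonsurvivor else 0,
                spec$baseline_sd)
  trend <- if (died) spec$trend_nonsurvivor else spec$trend_survivor
  value <- base + trend * t + rnorm(n, 0, spec$noise_sd)
  data.frame(t = t, value = value)
}

#' Sample one patient's note-set token counts
#'
#' Token counts are multinomial over the configured term list with weights
#' `base_weight * exp(outcome_shift * died) * site_scale`, so a term with a
#' positive shift is strictly more frequent in expectation among decedents.
#' Uses the current RNG state.
#'
#' @param term_specs Term specification table (see [default_term_specs()]).
#' @param died Logical outcome.
#' @param n_tokens Total number of tokens to draw.
#' @param site_scale Optional named vector of per-term weight multipliers.
#' @return Named integer vector of token counts (terms with zero count are
#'   dropped).
#' @export
sample_note_set <- function(term_specs, died, n_tokens, site_scale = NULL) {
  w <- term_specs$base_weight * exp(term_specs$outcome_shift * as.numeric(died))
  if (!is.null(site_scale)) {
    i <- match(names(site_scale), term_specs$term)
    ok <- !is.na(i)
    w[i[ok]] <- w[i[ok]] * site_scale[ok]
  }
  if (n_tokens == 0) return(setNames(integer(0), character(0)))
  counts <- as.integer(rmultinom(1, n_tokens, w))
  keep <- counts > 0
  setNames(counts[keep], term_specs$term[keep])
}

#' Generate a synthetic multi-site ICU cohort
#'
#' Draws a complete cohort -- stay table, long-format observation table and
#' note table -- from the configured multi-site generative model. The output
#' is a deterministic function of the configuration (including its seed).
#' Decedents assigned a death time before 24 hours stop generating
#' observations and notes at death, enabling the alive-at-24-hours
#' sensitivity analysis.
#'
#' @param config A [generator_config()].
#' @return A list with elements `stays`, `observations`, `notes`
#'   (data.frames). Stay columns: `patient_id`, `site`, `age`, `sex`,
#'   `icu_type`, `icu_admit_rank`, `icu_los_hours`, `died_in_hospital`,
#'   `death_time_hours` (NA for survivors). Observation columns:
#'   `patient_id`, `variable`, `t`, `value`. Note columns: `patient_id`,
#'   `t`, `text`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    se <- config$site_effects
    sites <- se$sites
    ids <- sprintf("p%06d", seq_len(n))

    site <- sites$site[sample.int(nrow(sites), n, replace = TRUE,
                                  prob = sites$weight)]
    si <- match(site, sites$site)

    # renormalize prevalence scalings so the marginal prevalence is exact
    pscale <- sites$prevalence_scale /
      sum(sites$prevalence_scale * sites$weight)
    pdie <- pmin(config$mortality_prevalence * pscale[si], 1)
    died <- rbinom(n, 1, pdie) == 1

    age <- pmin(pmax(rnorm(n, 61.3 + sites$age_shift[si], 17.1), 18), 100)
    sex <- ifelse(runif(n) < 0.513, "male", "female")
    icu_type <- sample(c("med_surg_combined", "medical", "surgical",
                         "neurologic", "coronary"), n, replace = TRUE,
                       prob = c(0.318, 0.189, 0.216, 0.141, 0.136))

    # death timing: a configured fraction of decedents die inside the window
    death_time <- rep(NA_real_, n)
    early <- died & (runif(n) < config$frac_deaths_within_24h)
    death_time[early] <- runif(sum(early), 4, 24)
    late <- died & !early
    death_time[late] <- 24 + rexp(sum(late), 1 / 96)

    los <- 4 + rlnorm(n, log(44), 1)
    los[early] <- death_time[early]
    los[late] <- pmin(los[late], death_time[late])

    stays <- data.frame(
      patient_id = ids, site = site, age = age, sex = sex,
      icu_type = icu_type, icu_admit_rank = 1L, icu_los_hours = los,
      died_in_hospital = died, death_time_hours = death_time,
      stringsAsFactors = FALSE
    )

    # observation window per patient: truncated at death when < 24 h
    t_max <- rep(24, n)
    t_max[early] <- death_time[early]
    mscale <- sites$missing_scale[si]

    vs <- config$variable_specs
    obs_list <- vector("list", nrow(vs))
    for (v in seq_len(nrow(vs))) {
      sp <- vs[v, ]
      pmiss <- pmin(sp$missing_prob * mscale, 1)
      present <- runif(n) >= pmiss
      nobs <- ifelse(present, rpois(n, sp$rate_per_hour * t_max), 0L)
      tot <- sum(nobs)
      if (tot == 0) next
      pi <- rep.int(seq_len(n), nobs)
      t <- runif(tot) * t_max[pi]
      base <- rnorm(n, sp$baseline_mean + sp$shift_nonsurvivor * died,
                    sp$baseline_sd)
      trend <- ifelse(died, sp$trend_nonsurvivor, sp$trend_survivor)
      value <- base[pi] + trend[pi] * t + rnorm(tot, 0, sp$noise_sd)
      obs_list[[v]] <- data.frame(patient_id = ids[pi],
                                  variable = sp$variable,
                                  t = t, value = value,
                                  stringsAsFactors = FALSE)
    }
    observations <- do.call(rbind, obs_list[!vapply(obs_list, is.null, TRUE)])
    observations <- observations[order(observations$patient_id,
                                       observations$variable,
                                       observations$t), , drop = FALSE]
    rownames(observations) <- NULL

    # notes: per-patient multinomial token counts, split across 1+Pois notes
    ts <- config$term_specs
    w_base <- ts$base_weight
    notes <- .generate_notes(ids, died, site, t_max, ts, se$term_scale,
                             config$mean_tokens, config$mean_notes)

    list(stays = stays, observations = observations, notes = notes)
  })
}

# Bulk note generation: one multinomial token stream per (site, outcome)
# group, split back into per-patient, per-note text strings.
.generate_notes <- function(ids, died, site, t_max, term_specs, term_scale,
                            mean_tokens, mean_notes) {
  n <- length(ids)
  n_tokens <- pmax(rpois(n, mean_tokens), 1L)
  n_notes <- 1L + rpois(n, mean_notes)
  groups <- split(seq_len(n), list(site, died), drop = TRUE)
  tok_by_patient <- vector("list", n)
  for (g in groups) {
    s <- site[g[1]]
    d <- died[g[1]]
    w <- term_specs$base_weight * exp(term_specs$outcome_shift * as.numeric(d))
    sc <- term_scale[[s]]
    if (!is.null(sc)) {
      i <- match(names(sc), term_specs$term)
      ok <- !is.na(i)
      w[i[ok]] <- w[i[ok]] * sc[ok]
    }
    tot <- sum(n_tokens[g])
    draws <- sample.int(nrow(term_specs), tot, replace = TRUE, prob = w)
    tok_by_patient[g] <- split(term_specs$term[draws],
                               rep.int(seq_along(g), n_tokens[g]))
  }
  # distribute each patient's tokens over that patient's notes
  note_pi <- rep.int(seq_len(n), n_notes)
  note_t <- runif(length(note_pi)) * t_max[note_pi]
  texts <- character(length(note_pi))
  note_start <- c(1L, cumsum(n_notes) + 1L)
  for (i in seq_len(n)) {
    toks <- tok_by_patient[[i]]
    k <- n_notes[i]
    assign_note <- sample.int(k, length(toks), replace = TRUE)
    rows <- note_start[i] + seq_len(k) - 1L
    texts[rows] <- vapply(seq_len(k), function(j)
      paste(toks[assign_note == j], collapse = " "), character(1))
  }
  keep <- nzchar(texts)
  data.frame(patient_id = ids[note_pi[keep]], t = note_t[keep],
             text = texts[keep], stringsAsFactors = FALSE)
}
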