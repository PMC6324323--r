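# Validation harness: repeated nested K-fold cross-validation, the
# cross-site train/test transfer matrix, the alive-at-24-hours sensitivity
# analysis, and construct-validity comparisons.

#' Harness configuration
#'
#' @param model_modes Subset of `"baseline"`, `"trajectory"`,
#'   `"trajectory_nlp"` (baseline: min/max only; trajectory: all eight
#'   summary measures; trajectory_nlp: trajectory plus TF-IDF note terms).
#' @param outer_folds Outer folds K (default 10).
#' @param repetitions Repetitions R of the outer loop (default 100; R x K
#'   fold AUCs are produced per mode).
#' @param inner_folds Inner folds for penalty selection (default 5).
#' @param bootstrap_B Bootstrap resamples for the CI of the mean fold AUC.
#' @param lambda_grid Candidate ridge penalties; a single value skips inner
#'   selection.
#' @param vocab_k Vocabulary size for the text features (default 1000).
#' @param variables Variable names for the structured features.
#' @param hl_groups Risk groups for the calibration test.
#' @param window Cohort windowing rules ([cohort_window()]).
#' @param seed Master seed; repetition r uses a fold seed derived from
#'   `(seed, r)` by a fixed counter scheme, so the full harness output is
#'   reproducible.
#' @return An object of class `harness_config`.
#' @export
harness_config <- function(model_modes = c("baseline", "trajectory",
                                           "trajectory_nlp"),
                           outer_folds = 10L, repetitions = 100L,
                           inner_folds = 5L, bootstrap_B = 1000L,
                           lambda_grid = 10^seq(-3, 3, by = 1),
                           vocab_k = 1000L,
                           variables = default_variable_specs()$variable,
                           hl_groups = 10L,
                           window = cohort_window(),
                           seed = 1L) {
  model_modes <- match.arg(model_modes,
                           c("baseline", "trajectory", "trajectory_nlp"),
                           several.ok = TRUE)
  stopifnot(outer_folds >= 2, repetitions >= 1, inner_folds >= 2,
            length(lambda_grid) >= 1)
  structure(list(model_modes = model_modes,
                 outer_folds = as.integer(outer_folds),
                 repetitions = as.integer(repetitions),
                 inner_folds = as.integer(inner_folds),
                 bootstrap_B = as.integer(bootstrap_B),
                 lambda_grid = lambda_grid,
                 vocab_k = as.integer(vocab_k),
                 variables = variables,
                 hl_groups = as.integer(hl_groups),
                 window = window,
                 seed = as.integer(seed)),
            class = "harness_config")
}

# Columns of the full 8-measure raw matrix belonging to a model mode's
# structured part.
.mode_columns <- function(variables, mode) {
  measures <- if (mode == "baseline") .measures_baseline else .measures_all
  as.vector(t(outer(variables, measures, paste, sep = ".")))
}

# Fit one model on a training partition: median imputation, optional
# vocabulary + TF-IDF, optional inner-CV penalty selection, ridge fit.
# Every fit-time artifact is a pure function of the training rows.
.fit_fold <- function(raw_tr, note_sets_tr, y_tr, mode, cfg, seed) {
  X <- raw_tr[, .mode_columns(cfg$variables, mode), drop = FALSE]
  med <- apply(X, 2, median, na.rm = TRUE)
  if (any(!is.finite(med)))
    stop("predictor(s) missing in all training rows: ",
         paste(colnames(X)[!is.finite(med)], collapse = ", "), call. = FALSE)
  X <- .impute_with(X, med)
  vocab <- NULL
  if (mode == "trajectory_nlp") {
    vocab <- fit_vocabulary(note_sets_tr, cfg$vocab_k)
    X <- cbind(X, tfidf_matrix(note_sets_tr, vocab))
  }
  lambda <- if (length(cfg$lambda_grid) == 1) cfg$lambda_grid
            else select_lambda(X, y_tr, cfg$lambda_grid, cfg$inner_folds,
                               seed = seed)
  model <- ridge_fit(X, y_tr, ridge_config(lambda = lambda))
  list(medians = med, vocab = vocab, model = model, lambda = lambda,
       mode = mode)
}

.predict_fold <- function(fit, raw_te, note_sets_te) {
  X <- raw_te[, names(fit$medians), drop = FALSE]
  X <- .impute_with(X, fit$medians)
  if (!is.null(fit$vocab))
    X <- cbind(X, tfidf_matrix(note_sets_te, fit$vocab))
  predict_risk(fit$model, X)
}

# Shared preprocessing: window clipping, per-patient raw trajectory matrix
# and note sets (each a pure function of that patient's own rows, so safe
# to compute once for all folds).
.prepare_dataset <- function(stays, observations, notes, cfg) {
  clipped <- clip_window(observations, notes, cfg$window)
  raw <- .trajectory_raw(clipped$observations, stays$patient_id,
                         cfg$variables)
  note_sets <- NULL
  if ("trajectory_nlp" %in% cfg$model_modes)
    note_sets <- build_note_sets(clipped$notes, stays$patient_id)
  list(raw = raw, note_sets = note_sets,
       y = as.integer(stays$died_in_hospital))
}

#' Repeated nested cross-validation
#'
#' Runs R repetitions of nested K-fold cross-validation per model mode. In
#' every outer fold the imputation medians, vocabulary, IDF,
#' standardization and penalty are fitted on the outer-training portion
#' only; the held-out fold contributes one test AUC. Each mode therefore
#' yields R x K fold AUCs; the reported discrimination estimate is their
#' mean, with a percentile-bootstrap CI. Calibration, AUPRC and the optimal
#' cut point are computed on the pooled out-of-fold predictions of the
#' first repetition (each patient predicted exactly once).
#'
#' @param stays Stay table already passing the cohort rules.
#' @param observations,notes Event tables (clipped internally).
#' @param config A [harness_config()].
#' @param keep_artifacts Store first-repetition fit-time artifacts
#'   (imputation medians, vocabulary terms/IDF, standardization, penalty)
#'   per fold, e.g. for leakage audits.
#' @return An object of class `nested_cv_result`: per-mode list with
#'   `fold_auc` (R*K values), `auc`, `auc_ci`, `auprc`, `hl`, `cutpoint`,
#'   `lambdas`, `oof_risk`, plus `n`, `prevalence`, `config`.
#' @export
nested_cv <- function(stays, observations, notes, config = harness_config(),
                      keep_artifacts = FALSE) {
  cfg <- config
  prep <- .prepare_dataset(stays, observations, notes, cfg)
  y <- prep$y
  n <- length(y)
  R <- cfg$repetitions; K <- cfg$outer_folds
  res <- lapply(cfg$model_modes, function(m)
    list(fold_auc = numeric(0), oof_risk = rep(NA_real_, n),
         lambdas = numeric(0), artifacts = list()))
  names(res) <- cfg$model_modes
  for (r in seq_len(R)) {
    folds <- make_folds(y, K, derive_seed(cfg$seed, r))
    for (k in seq_len(K)) {
      tr <- folds != k
      for (m in cfg$model_modes) {
        fit <- .fit_fold(prep$raw[tr, , drop = FALSE],
                         prep$note_sets[tr], y[tr], m, cfg,
                         seed = derive_seed(cfg$seed, r, k))
        risk <- .predict_fold(fit, prep$raw[!tr, , drop = FALSE],
                              prep$note_sets[!tr])
        res[[m]]$fold_auc <- c(res[[m]]$fold_auc, auc(risk, y[!tr]))
        res[[m]]$lambdas <- c(res[[m]]$lambdas, fit$lambda)
        if (r == 1) {
          res[[m]]$oof_risk[!tr] <- risk
          if (keep_artifacts)
            res[[m]]$artifacts[[k]] <- list(
              medians = fit$medians,
              vocab_terms = fit$vocab$terms, vocab_idf = fit$vocab$idf,
              center = fit$model$center, scale = fit$model$scale,
              coefficients = fit$model$coefficients,
              lambda = fit$lambda)
        }
      }
    }
  }
  for (m in cfg$model_modes) {
    fa <- res[[m]]$fold_auc
    res[[m]]$auc <- mean(fa)
    res[[m]]$auc_ci <- bootstrap_ci(fa, cfg$bootstrap_B,
                                    seed = derive_seed(cfg$seed, 999))
    oof <- res[[m]]$oof_risk
    res[[m]]$auprc <- auprc(oof, y)
    res[[m]]$hl <- hosmer_lemeshow(oof, y, cfg$hl_groups)
    res[[m]]$cutpoint <- optimal_cutpoint(oof, y)
  }
  structure(list(modes = res, n = n, prevalence = mean(y), config = cfg),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "nested %d-fold cross-validation, %d repetition(s), n = %d (prevalence %.3f)\n",
    cfg$outer_folds, cfg$repetitions, x$n, x$prevalence))
  for (m in names(x$modes)) {
    r <- x$modes[[m]]
    cat(sprintf(
      "  %-15s AUC %.3f (95%% CI %.3f-%.3f; %d fold values)  AUPRC %.3f  HL C = %.1f (p = %.2g)\n",
      m, r$auc, r$auc_ci[1], r$auc_ci[2], length(r$fold_auc), r$auprc,
      r$hl$statistic, r$hl$p_value))
  }
  invisible(x)
}

#' Cross-site external validation matrix
#'
#' For every model mode and every ordered pair of distinct sites, fits a
#' site-specific model on all data from the training site (with internal
#' penalty selection and the training site's vocabulary/IDF) and evaluates
#' its AUC on all data from the test site. Tokens outside the training
#' site's vocabulary contribute nothing to the test-site predictions.
#'
#' @param stays,observations,notes Cohort tables; `stays$site` defines the
#'   sites (at least 2 required).
#' @param config A [harness_config()].
#' @return An object of class `cross_site_result`: `auc` is a 3-d array
#'   (train site x test site x mode) with an absent (NA) diagonal; `fits`
#'   holds the per-site fitted models.
#' @export
cross_site <- function(stays, observations, notes,
                       config = harness_config()) {
  cfg <- config
  sites <- sort(unique(stays$site))
  if (length(sites) < 2) stop("cross-site validation needs >= 2 sites",
                              call. = FALSE)
  prep <- .prepare_dataset(stays, observations, notes, cfg)
  idx_by_site <- lapply(sites, function(s) which(stays$site == s))
  names(idx_by_site) <- sites
  out <- array(NA_real_, c(length(sites), length(sites),
                           length(cfg$model_modes)),
               dimnames = list(train = sites, test = sites,
                               mode = cfg$model_modes))
  fits <- list()
  for (m in cfg$model_modes) {
    for (s_tr in sites) {
      i_tr <- idx_by_site[[s_tr]]
      fit <- .fit_fold(prep$raw[i_tr, , drop = FALSE],
                       prep$note_sets[i_tr], prep$y[i_tr], m, cfg,
                       seed = derive_seed(cfg$seed, match(s_tr, sites),
                                          match(m, cfg$model_modes)))
      fits[[paste(m, s_tr, sep = ".")]] <- fit
      for (s_te in setdiff(sites, s_tr)) {
        i_te <- idx_by_site[[s_te]]
        risk <- .predict_fold(fit, prep$raw[i_te, , drop = FALSE],
                              prep$note_sets[i_te])
        out[s_tr, s_te, m] <- auc(risk, prep$y[i_te])
      }
    }
  }
  structure(list(auc = out, sites = sites, fits = fits, config = cfg),
            class = "cross_site_result")
}

#' @export
print.cross_site_result <- function(x, ...) {
  cat("cross-site external validation (rows: training site; columns: test site)\n")
  for (m in dimnames(x$auc)$mode) {
    cat(sprintf("  mode %s:\n", m))
    print(round(x$auc[, , m], 3))
  }
  invisible(x)
}

#' Sensitivity analysis restricted to patients alive at 24 hours
#'
#' Drops patients who died before 24 hours after ICU admission (those whose
#' note and observation streams end at death inside the window, which could
#' let the model learn peri-death documentation) and reruns the nested
#' cross-validation on the restricted cohort with the same configuration.
#'
#' @inheritParams nested_cv
#' @return A `nested_cv_result` for the restricted cohort.
#' @export
sensitivity_alive_24h <- function(stays, observations, notes,
                                  config = harness_config()) {
  early <- stays$died_in_hospital &
    !is.na(stays$death_time_hours) & stays$death_time_hours < 24
  keep_ids <- stays$patient_id[!early]
  nested_cv(stays[!early, , drop = FALSE],
            observations[observations$patient_id %in% keep_ids, ,
                         drop = FALSE],
            notes[notes$patient_id %in% keep_ids, , drop = FALSE],
            config)
}

#' Construct-validity comparison of trajectory measures by outcome
#'
#' For every derived measure, compares survivors and nonsurvivors: group
#' means of the nonmissing values, Welch unpaired t test p value, and
#' Wilcoxon rank sum p value. A measure behaves as clinically expected when
#' e.g. the mean Glasgow Coma Scale slope is positive (improving) among
#' survivors and negative among nonsurvivors.
#'
#' @param fm A `feature_matrix` built in trajectory mode (pre-imputation;
#'   missing cells are excluded pairwise).
#' @param y Optional binary outcome vector; defaults to `fm$y`.
#' @return A data.frame with columns `measure`, `mean_survivor`,
#'   `mean_nonsurvivor`, `n_survivor`, `n_nonsurvivor`, `t_p_value`,
#'   `wilcoxon_p_value`.
#' @export
construct_validity <- function(fm, y = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- y %||% fm$y
  stopifnot(length(y) == nrow(fm$x))
  rows <- lapply(colnames(fm$x), function(cn) {
    v <- fm$x[, cn]
    s <- v[y == 0 & !is.na(v)]
    d <- v[y == 1 & !is.na(v)]
    if (length(unique(c(s, d))) <= 1) {
      # constant measure: no evidence of any outcome difference
      tp <- NA_real_
      wp <- 1
    } else {
      tp <- tryCatch(t.test(s, d)$p.value, error = function(e) NA_real_)
      wp <- tryCatch(suppressWarnings(wilcox.test(s, d)$p.value),
                     error = function(e) NA_real_)
    }
    data.frame(measure = cn,
               mean_survivor = mean(s), mean_nonsurvivor = mean(d),
               n_survivor = length(s), n_nonsurvivor = length(d),
               t_p_value = tp, wilcoxon_p_value = wp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a mortality model on full cohort tables
#'
#' Convenience wrapper fitting one model mode on an entire dataset (for
#' example one site): clips the window, builds structured and text
#' features, learns imputation medians, vocabulary/IDF and penalty on the
#' supplied data, and fits the ridge logistic model.
#'
#' @param stays,observations,notes Cohort tables (stays already selected).
#' @param mode One model mode (see [harness_config()]).
#' @param config A [harness_config()].
#' @return An object of class `icu_model`.
#' @export
fit_mortality_model <- function(stays, observations, notes,
                                mode = "trajectory_nlp",
                                config = harness_config()) {
  cfg <- config
  cfg$model_modes <- mode
  prep <- .prepare_dataset(stays, observations, notes, cfg)
  fit <- .fit_fold(prep$raw, prep$note_sets, prep$y, mode, cfg,
                   seed = derive_seed(cfg$seed, 0))
  structure(c(fit, list(config = cfg)), class = "icu_model")
}

#' Predict in-hospital mortality risk for new patients
#'
#' @param object An [fit_mortality_model()] fit.
#' @param stays,observations,notes Cohort tables for the new patients.
#' @param ... Unused.
#' @return Named numeric vector of predicted risks (one per stay row).
#' @export
predict.icu_model <- function(object, stays, observations, notes = NULL, ...) {
  cfg <- object$config
  prep <- .prepare_dataset(stays, observations, notes, cfg)
  setNames(.predict_fold(object, prep$raw, prep$note_sets),
           stays$patient_id)
}
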