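test_that("least-squares slope matches closed forms and the normal equations", {
  expect_equal(ls_slope(c(0, 12, 24), c(10, 13, 16)), 0.25)
  expect_equal(ls_slope(c(0, 24), c(5, 5)), 0)
  t <- c(1, 5, 20); v <- c(7, 9, 8)
  expect_equal(ls_slope(t, v), slope_normal_equations(t, v), tolerance = 1e-12)
  expect_equal(ls_slope(t, v), 0.0199335548, tolerance = 1e-8)
  # missing, not an error
  expect_true(is.na(ls_slope(3, 7)))
  expect_true(is.na(ls_slope(c(2, 2), c(1, 5))))
  # random cases against the normal equations
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    t <- runif(n, 0, 24); v <- rnorm(n)
    if (length(unique(t)) > 1)
      expect_equal(ls_slope(t, v), slope_normal_equations(t, v),
                   tolerance = 1e-10)
  }
})

test_that("variable summaries produce the eight measures with correct degeneracies", {
  s <- summarize_variable(c(1, 5, 20), c(7, 9, 8))
  expect_equal(unname(s[c("min", "max", "mean", "sd", "first", "last", "delta")]),
               c(7, 9, 8, 1, 7, 8, 1))
  expect_equal(unname(s["slope"]), 0.0199335548, tolerance = 1e-8)

  one <- summarize_variable(2, 5)
  expect_equal(unname(one[c("min", "max", "mean", "first", "last")]),
               rep(5, 5))
  expect_true(all(is.na(one[c("sd", "delta", "slope")])))

  none <- summarize_variable(numeric(0), numeric(0))
  expect_true(all(is.na(none)))

  # first/last follow ascending time with input order breaking ties
  tied <- summarize_variable(c(3, 1, 3), c(10, 20, 30))
  expect_equal(unname(tied["first"]), 20)
  expect_equal(unname(tied["last"]), 30)
})

test_that("feature matrices obey the column-count law", {
  coh <- generate_cohort(generator_config(n_patients = 80, seed = 13))
  fb <- build_feature_matrix(coh$stays, coh$observations, mode = "baseline")
  ft <- build_feature_matrix(coh$stays, coh$observations, mode = "trajectory")
  expect_equal(ncol(fb$x), 48)   # 2 per variable, 24 variables
  expect_equal(ncol(ft$x), 192)  # 8 per variable
  # single-variable case: composition with summarize_variable
  f1 <- build_feature_matrix(coh$stays, coh$observations,
                             variables = "gcs_total", mode = "trajectory")
  expect_equal(ncol(f1$x), 8)
  pid <- coh$stays$patient_id[5]
  sub <- coh$observations[coh$observations$patient_id == pid &
                            coh$observations$variable == "gcs_total", ]
  expect_equal(unname(f1$x[pid, ]),
               unname(summarize_variable(sub$t, sub$value)))
  # baseline columns are an exact value subset of trajectory columns
  expect_equal(ft$x[, colnames(fb$x)], fb$x)
})

test_that("matrix summaries agree with per-patient summaries everywhere", {
  coh <- generate_cohort(generator_config(n_patients = 40, seed = 17))
  vars <- c("gcs_total", "lactate", "sodium")
  fm <- build_feature_matrix(coh$stays, coh$observations,
                             variables = vars, mode = "trajectory")
  for (pid in coh$stays$patient_id[c(1, 7, 23, 40)]) {
    for (v in vars) {
      sub <- coh$observations[coh$observations$patient_id == pid &
                                coh$observations$variable == v, ]
      expect_equal(unname(fm$x[pid, paste(v, names(summarize_variable(0, 0)),
                                          sep = ".")]),
                   unname(summarize_variable(sub$t, sub$value)))
    }
  }
})

test_that("median imputation learns on training rows and transfers", {
  x <- matrix(c(1, 2, NA, 4,
                5, NA, 7, 9), 4, 2,
              dimnames = list(NULL, c("a.min", "b.min")))
  fm <- structure(list(x = x, patient_id = paste0("p", 1:4), y = c(0, 1, 0, 1),
                       mode = "baseline", variables = c("a", "b"),
                       medians = NULL, standardization = NULL),
                  class = "feature_matrix")
  fit <- fit_impute(fm)
  expect_equal(unname(fit$medians), c(2, 7))
  expect_equal(fit$x[3, "a.min"], c("a.min" = 2), ignore_attr = TRUE)
  # no missing values: matrix unchanged, medians still recorded
  fm2 <- fm; fm2$x[] <- 1:8
  fit2 <- fit_impute(fm2)
  expect_equal(fit2$x, fm2$x)
  expect_equal(unname(fit2$medians), c(2.5, 6.5))
  # all-missing predictor is an instructive error
  fm3 <- fm; fm3$x[, 2] <- NA
  expect_error(fit_impute(fm3), "drop these predictors")
})

test_that("imputed values equal independent column medians under random missingness", {
  set.seed(31)
  x <- matrix(rnorm(600), 60, 10,
              dimnames = list(NULL, paste0("v", 1:10, ".min")))
  x[sample(length(x), 180)] <- NA
  keep <- colSums(!is.na(x)) > 0
  x <- x[, keep, drop = FALSE]
  fm <- structure(list(x = x, patient_id = paste0("p", 1:60),
                       y = rep(0:1, 30), mode = "baseline",
                       variables = colnames(x),
                       medians = NULL, standardization = NULL),
                  class = "feature_matrix")
  fit <- fit_impute(fm)
  for (j in seq_len(ncol(x))) {
    ref <- sort(x[!is.na(x[, j]), j])
    m <- length(ref)
    med <- if (m %% 2 == 1) ref[(m + 1) / 2] else (ref[m / 2] + ref[m / 2 + 1]) / 2
    expect_equal(unname(fit$medians[j]), med)
    expect_equal(unname(fit$x[is.na(x[, j]), j]),
                 rep(med, sum(is.na(x[, j]))))
  }
})

test_that("imputation medians are a pure function of training rows", {
  set.seed(32)
  coh <- generate_cohort(generator_config(n_patients = 100, seed = 33))
  fm <- build_feature_matrix(coh$stays, coh$observations, mode = "trajectory")
  tr <- 1:70
  train <- fm; train$x <- fm$x[tr, ]; train$patient_id <- fm$patient_id[tr]
  train$y <- fm$y[tr]
  med1 <- fit_impute(train)$medians
  # mutate the held-out rows arbitrarily; training medians must not move
  fm$x[71:100, ] <- 1e6
  train2 <- fm; train2$x <- fm$x[tr, ]; train2$patient_id <- fm$patient_id[tr]
  train2$y <- fm$y[tr]
  expect_identical(med1, fit_impute(train2)$medians)
  # applying stored medians to test rows uses only those medians
  test <- fm; test$x <- fm$x[71:100, ] * NA; test$patient_id <- fm$patient_id[71:100]
  test$y <- fm$y[71:100]
  applied <- apply_impute(test, med1)
  expect_equal(unname(applied$x[1, ]), unname(med1))
})
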