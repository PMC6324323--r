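# L2-penalized logistic regression fit from first principles by iteratively
# reweighted least squares (Newton) with step-halving, plus inner-CV
# selection of the penalty.

#' Ridge logistic configuration
#'
#' @param lambda Non-negative L2 penalty applied as `(lambda/2) * ||beta||^2`
#'   subtracted from the log-likelihood; the intercept is unpenalized.
#' @param lambda_grid Candidate penalties for [select_lambda()]; default 7
#'   log-spaced points from 1e-3 to 1e3.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the max-norm of the penalized
#'   gradient.
#' @param standardize Z-standardize columns before fitting (constant
#'   columns get unit scale); predictions are then invariant to affine
#'   rescaling of any input column.
#' @return An object of class `ridge_config`.
#' @export
ridge_config <- function(lambda = 1,
                         lambda_grid = 10^seq(-3, 3, by = 1),
                         max_iter = 50L, tol = 1e-6, standardize = TRUE) {
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1)
  structure(list(lambda = lambda, lambda_grid = lambda_grid,
                 max_iter = as.integer(max_iter), tol = tol,
                 standardize = isTRUE(standardize)),
            class = "ridge_config")
}

# Numerically stable sum of per-observation log-likelihoods y*eta - log(1+e^eta)
.loglik <- function(y, eta) {
  sum(ifelse(eta > 0,
             (y - 1) * eta - log1p(exp(-eta)),
             y * eta - log1p(exp(eta))))
}

#' Fit an L2-penalized logistic regression
#'
#' Maximizes `loglik(beta0, beta) - (lambda/2) * ||beta||^2` (intercept
#' unpenalized) by Newton/IRLS with step-halving, which makes the penalized
#' objective nondecreasing across iterations. Deterministic given the
#' inputs. The solution certificate is the max-norm of the penalized
#' gradient at the returned coefficients.
#'
#' @param x Fully imputed numeric design matrix (no missing values).
#' @param y Binary outcome vector (0/1); both classes must be present.
#' @param config A [ridge_config()]; `config$lambda` is the penalty used.
#' @return An object of class `ridge_fit`: list with `intercept`,
#'   `coefficients` (on the standardized scale when `standardize = TRUE`),
#'   `lambda`, `center`, `scale`, `converged`, `iterations`,
#'   `grad_max_norm`, `objective`.
#' @export
ridge_fit <- function(x, y, config = ridge_config()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit", call. = FALSE)
  if (anyNA(x))
    stop("design matrix contains missing values; impute first", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  lambda <- config$lambda

  if (config$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  } else {
    center <- rep(0, p); scale <- rep(1, p)
    xs <- x
  }

  beta <- rep(0, p)
  pbar <- mean(y)
  b0 <- log(pbar / (1 - pbar))
  eta <- rep(b0, n)
  pen_obj <- function(b0, beta, eta) .loglik(y, eta) - lambda / 2 * sum(beta^2)
  obj <- pen_obj(b0, beta, eta)

  converged <- FALSE
  iter <- 0L
  grad_norm <- Inf
  while (iter < config$max_iter) {
    iter <- iter + 1L
    mu <- plogis(eta)
    r <- y - mu
    g <- c(sum(r), drop(crossprod(xs, r)) - lambda * beta)
    grad_norm <- max(abs(g))
    if (grad_norm <= config$tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    Zw <- cbind(1, xs) * sqrt(w)
    H <- crossprod(Zw)
    diag(H)[-1L] <- diag(H)[-1L] + lambda
    delta <- unname(tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, p + 1L), g)))
    # step-halving: accept the first step that does not decrease the
    # penalized objective
    step <- 1
    repeat {
      b0_new <- b0 + step * delta[1L]
      beta_new <- beta + step * delta[-1L]
      eta_new <- b0_new + drop(xs %*% beta_new)
      obj_new <- pen_obj(b0_new, beta_new, eta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        stop("IRLS step-halving failed to find an ascent step",
             call. = FALSE)
    }
    b0 <- b0_new; beta <- beta_new; eta <- eta_new; obj <- obj_new
  }
  if (!converged) {
    mu <- plogis(eta)
    g <- c(sum(y - mu), drop(crossprod(xs, y - mu)) - lambda * beta)
    grad_norm <- max(abs(g))
    if (grad_norm <= config$tol) converged <- TRUE
    else stop(sprintf(
      "IRLS did not converge in %d iterations (penalized gradient max-norm %.3g, tol %.3g)",
      config$max_iter, grad_norm, config$tol), call. = FALSE)
  }
  structure(
    list(intercept = b0, coefficients = setNames(beta, colnames(x)),
         lambda = lambda, center = center, scale = scale,
         converged = converged, iterations = iter,
         grad_max_norm = grad_norm, objective = obj),
    class = "ridge_fit"
  )
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf(
    "ridge logistic fit: %d predictors, lambda = %g\n  converged in %d IRLS iterations (penalized gradient max-norm %.2g)\n",
    length(x$coefficients), x$lambda, x$iterations, x$grad_max_norm))
  invisible(x)
}

#' Predicted in-hospital mortality risk
#'
#' Inverse-logit of the linear predictor; values lie strictly in (0, 1) and
#' are monotone in the linear predictor.
#'
#' @param model A [ridge_fit()] object.
#' @param x Design matrix with the model's predictor columns, on the
#'   original (unstandardized) scale.
#' @return Numeric vector of predicted probabilities.
#' @export
predict_risk <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(names(model$coefficients))) {
    if (!identical(colnames(x), names(model$coefficients))) {
      if (!all(names(model$coefficients) %in% colnames(x)))
        stop("design matrix columns do not match model predictors",
             call. = FALSE)
      x <- x[, names(model$coefficients), drop = FALSE]
    }
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  plogis(model$intercept + drop(xs %*% model$coefficients))
}

#' Select the ridge penalty by inner cross-validation
#'
#' Evaluates each candidate penalty by stratified k-fold cross-validated
#' AUC and returns the penalty with the highest mean validation AUC; exact
#' ties go to the larger penalty (more regularization). With
#' `one_se = TRUE` the largest penalty whose mean AUC is within one
#' standard error of the best is returned instead.
#'
#' @param x Fully imputed design matrix.
#' @param y Binary outcome.
#' @param grid Non-empty vector of candidate penalties.
#' @param inner_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param one_se Use the one-standard-error rule (default FALSE).
#' @return The selected penalty (scalar).
#' @export
select_lambda <- function(x, y, grid = ridge_config()$lambda_grid,
                          inner_folds = 5, seed = NULL, one_se = FALSE) {
  if (length(grid) == 0) stop("empty lambda grid", call. = FALSE)
  grid <- sort(grid)
  if (length(grid) == 1) return(grid)
  folds <- make_folds(y, inner_folds, seed)
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2)) {
    folds <- make_folds(y, inner_folds,
                        if (is.null(seed)) NULL else derive_seed(seed, 1))
    if (any(tapply(y, folds, function(v) length(unique(v))) < 2))
      stop("single-class inner fold even after stratified retry", call. = FALSE)
  }
  fold_auc <- matrix(NA_real_, inner_folds, length(grid))
  for (k in seq_len(inner_folds)) {
    tr <- folds != k
    for (j in seq_along(grid)) {
      fit <- ridge_fit(x[tr, , drop = FALSE], y[tr],
                       ridge_config(lambda = grid[j]))
      fold_auc[k, j] <- auc(predict_risk(fit, x[!tr, , drop = FALSE]), y[!tr])
    }
  }
  mean_auc <- colMeans(fold_auc)
  if (one_se) {
    best <- which.max(mean_auc)
    se <- sd(fold_auc[, best]) / sqrt(inner_folds)
    ok <- mean_auc >= mean_auc[best] - se
    return(grid[max(which(ok))])
  }
  # which.max takes the first maximum; reverse so exact ties go large
  grid[length(grid) + 1 - which.max(rev(mean_auc))]
}
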