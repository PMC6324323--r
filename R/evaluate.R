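# Discrimination, calibration, cut-point metrics and resampling-based
# uncertainty, as reported by the validation harness.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n1 * n0)`, computed via
#' midranks. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric predicted scores or risks.
#' @param labels Binary outcomes (0/1); both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as half-concordant
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision step form of the PR area: thresholds sweep the
#' distinct scores in descending order and each recall increment is paired
#' with the precision at that threshold (no trapezoidal interpolation,
#' which overstates PR area). Chance level equals the outcome prevalence.
#'
#' @param scores Numeric predicted scores.
#' @param labels Binary outcomes; at least one positive required.
#' @return The AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("at least one positive required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct threshold (ties processed together)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  npred <- seq_along(y)[last_of_group]
  precision <- tp / npred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Modified Hosmer-Lemeshow calibration test
#'
#' Splits observations into `G` equal-count groups by predicted risk (ties
#' at a group boundary go to the lower group) and computes
#' `C = sum_g (O_g - E_g)^2 / (E_g * (1 - E_g / n_g))`, referred to a
#' chi-square distribution with `G - 2` degrees of freedom (the classical
#' convention for a model estimated on the same data). Nonsignificance
#' (p > 0.05) indicates good calibration. Groups with expected counts of 0
#' or n_g are merged into an adjacent group with a warning, reducing the
#' degrees of freedom accordingly.
#'
#' @param risks Predicted probabilities.
#' @param labels Binary outcomes.
#' @param G Number of risk groups (default 10).
#' @return An object of class `hl_test`: list with `statistic`, `groups`,
#'   `df`, `p_value`, and the per-group table `table` (n, observed,
#'   expected).
#' @export
hosmer_lemeshow <- function(risks, labels, G = 10) {
  labels <- as.numeric(labels)
  stopifnot(length(risks) == length(labels), G >= 3)
  n <- length(risks)
  if (n < 5 * G)
    warning(sprintf("only %d observations for %d groups; test unreliable",
                    n, G))
  qs <- quantile(risks, probs = seq_len(G - 1) / G, type = 2)
  grp <- 1L + rowSums(outer(risks, qs, ">"))
  tab <- data.frame(
    n = as.vector(tapply(labels, factor(grp, levels = 1:G), length)),
    observed = as.vector(tapply(labels, factor(grp, levels = 1:G), sum)),
    expected = as.vector(tapply(risks, factor(grp, levels = 1:G), sum))
  )
  tab[is.na(tab$n), ] <- 0
  tab <- tab[tab$n > 0, , drop = FALSE]
  # merge degenerate groups (all or no expected events) into a neighbor
  degen <- function(t) t$expected <= 0 | t$expected >= t$n
  while (any(degen(tab)) && nrow(tab) > 1) {
    i <- which(degen(tab))[1]
    j <- if (i == 1) 2L else i - 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, , drop = FALSE]
    warning("merged a risk group with degenerate expected count")
  }
  C <- sum((tab$observed - tab$expected)^2 /
             (tab$expected * (1 - tab$expected / tab$n)))
  df <- max(nrow(tab) - 2L, 1L)
  structure(
    list(statistic = C, groups = nrow(tab), df = df,
         p_value = pchisq(C, df, lower.tail = FALSE), table = tab),
    class = "hl_test"
  )
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf(
    "modified Hosmer-Lemeshow: C = %.3f on %d groups (df = %d), p = %.4g\n",
    x$statistic, x$groups, x$df, x$p_value))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Bootstraps the mean of the supplied values (for example fold-level AUCs
#' from repeated cross-validation) and returns the percentile interval.
#'
#' @param values Numeric vector (length >= 2).
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the resampling.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, B = 1000, level = 0.95, seed = NULL) {
  stopifnot(length(values) >= 2, B >= 1, level > 0, level < 1)
  with_seed(seed, {
    n <- length(values)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    means <- colMeans(matrix(values[idx], n, B))
    unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Optimal classification cut point
#'
#' Exhaustively searches the observed scores as thresholds (classify
#' positive when `score >= threshold`) and maximizes the chosen criterion:
#' Youden's J (`sensitivity + specificity - 1`, default) or F1. Ties go to
#' the highest threshold. Reports sensitivity (recall) and positive
#' predictive value (precision) at the optimum.
#'
#' @param scores Numeric predicted scores.
#' @param labels Binary outcomes; both classes required.
#' @param method `"youden"` or `"f1"`.
#' @return An object of class `cutpoint`: list with `threshold`,
#'   `sensitivity`, `ppv`, `method`, `criterion`.
#' @export
optimal_cutpoint <- function(scores, labels, method = c("youden", "f1")) {
  method <- match.arg(method)
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  crit <- vapply(th, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    sens <- tp / n1
    spec <- 1 - fp / n0
    if (method == "youden") sens + spec - 1
    else {
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    }
  }, numeric(1))
  best <- which(crit == max(crit))[1]  # th is descending: first max = highest threshold
  t_star <- th[best]
  pred <- scores >= t_star
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  structure(
    list(threshold = t_star, sensitivity = tp / n1,
         ppv = if (tp + fp == 0) 0 else tp / (tp + fp),
         method = method, criterion = max(crit)),
    class = "cutpoint"
  )
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf(
    "optimal cut point (%s): threshold %.4f, sensitivity %.3f, PPV %.3f\n",
    x$method, x$threshold, x$sensitivity, x$ppv))
  invisible(x)
}

#' Compare two sets of fold-level AUCs by unpaired t test
#'
#' Welch (unequal-variance) two-sample t test on fold-level AUC values from
#' two models, returning the t statistic and the two-tailed p value.
#'
#' @param values_a,values_b Numeric vectors (length >= 2 each).
#' @return A list with `t`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_auc <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(list(t = 0, p_value = 1, df = NA_real_,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}
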