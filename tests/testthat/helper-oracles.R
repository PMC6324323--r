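# Independent brute-force oracles used across tests. These deliberately use
# the slowest, most literal formulation of each quantity.

# AUC by O(n^2) pair enumeration: concordant + half of tied score pairs.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Average precision by literal descending-threshold sweep over distinct
# scores, accumulating precision at each recall increment.
auprc_bruteforce <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# OLS slope through the normal equations, solved with a generic linear
# solver rather than the centered covariance formula.
slope_normal_equations <- function(t, value) {
  X <- cbind(1, t)
  solve(crossprod(X), crossprod(X, value))[2]
}

# Rule-equivalent reference tokenizer: replace every non-alphanumeric
# character with a space, then split on whitespace.
tokenize_reference <- function(text) {
  out <- strsplit(trimws(gsub("[^a-z0-9]+", " ", tolower(text))), " +")
  out <- lapply(out, function(x) x[nzchar(x)])
  if (length(out) == 1) out[[1]] else out
}

# Small deterministic hand-built cohort used by cohort/windowing tests.
toy_stays <- function() {
  data.frame(
    patient_id = paste0("s", 1:5),
    site = "site_a",
    age = c(17, 45, 60, 70, 55),
    sex = "female",
    icu_type = "medical",
    icu_admit_rank = c(1L, 1L, 2L, 1L, 1L),
    icu_los_hours = c(50, 3, 48, 4.0, 90),
    died_in_hospital = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    death_time_hours = c(NA, NA, 30, NA, 70),
    stringsAsFactors = FALSE
  )
}
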