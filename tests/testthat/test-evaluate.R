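test_that("AUC matches closed-form cases and brute-force pair counting", {
  expect_equal(auc(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), auc_bruteforce(scores, labels))
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(63)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.4)
  a <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a)
  expect_equal(auc(qlogis(plogis(scores)), labels), a, tolerance = 1e-12)
  expect_equal(auc(rank(scores), labels), a)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.2)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("AUPRC matches enumeration and its chance level equals prevalence", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  s6 <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  y6 <- c(1, 0, 1, 0, 0, 1)
  expect_equal(auprc(s6, y6), auprc_bruteforce(s6, y6))
  set.seed(67)
  for (i in 1:15) {
    n <- sample(5:60, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) next
    expect_equal(auprc(s, y), auprc_bruteforce(s, y))
  }
  # chance level: uniform scores give AUPRC ~ prevalence
  set.seed(69)
  n <- 100000; p <- 0.104
  y <- rbinom(n, 1, p)
  s <- runif(n)
  expect_lt(abs(auprc(s, y) - p), 0.01)
})

test_that("Hosmer-Lemeshow statistic matches direct formula evaluation", {
  # hand-built 2-group table: n=(50,50), O=(10,30), E=(15,25)
  risks <- c(rep(15 / 50, 50), rep(25 / 50, 50))
  labels <- c(rep(1, 10), rep(0, 40), rep(1, 30), rep(0, 20))
  hl <- suppressWarnings(hosmer_lemeshow(risks, labels, G = 3))
  C_direct <- (10 - 15)^2 / (15 * (1 - 15 / 50)) +
    (30 - 25)^2 / (25 * (1 - 25 / 50))
  expect_equal(hl$statistic, C_direct)
  # risks exactly equal to group event rates: C = 0, p = 1
  risks2 <- c(rep(0.1, 100), rep(0.4, 100))
  labels2 <- c(rep(1, 10), rep(0, 90), rep(1, 40), rep(0, 60))
  hl2 <- suppressWarnings(hosmer_lemeshow(risks2, labels2, G = 3))
  expect_equal(hl2$statistic, 0)
  expect_equal(hl2$p_value, 1)
})

test_that("Hosmer-Lemeshow groups evenly and merges degenerate groups", {
  set.seed(71)
  risks <- runif(1000)
  labels <- rbinom(1000, 1, risks)
  hl <- hosmer_lemeshow(risks, labels, G = 10)
  expect_equal(hl$groups, 10)
  expect_equal(hl$df, 8)
  expect_equal(sum(hl$table$n), 1000)
  expect_true(all(abs(hl$table$n - 100) <= 1))
  # all-zero risks in the bottom group force a merge
  risks2 <- c(rep(0, 300), runif(700, 0.2, 0.9))
  labels2 <- rbinom(1000, 1, risks2)
  expect_warning(hl2 <- hosmer_lemeshow(risks2, labels2, G = 5), "merged")
  expect_lt(hl2$groups, 5)
})

test_that("bootstrap CI is a percentile interval around the mean", {
  expect_equal(bootstrap_ci(rep(3.3, 10), B = 50, seed = 1), c(3.3, 3.3))
  set.seed(73)
  for (i in 1:20) {
    v <- rnorm(40, 10, 2)
    ci <- bootstrap_ci(v, B = 400, seed = i)
    expect_lte(ci[1], mean(v))
    expect_gte(ci[2], mean(v))
  }
  # coverage of the true mean under repeated sampling
  set.seed(75)
  cover <- mean(replicate(150, {
    v <- rnorm(500)
    ci <- bootstrap_ci(v, B = 300)
    ci[1] <= 0 && 0 <= ci[2]
  }))
  expect_gt(cover, 0.88)
  expect_lt(cover, 0.995)
})

test_that("optimal cut point matches exhaustive threshold search", {
  # perfect separation: sensitivity and PPV both 1
  cp <- optimal_cutpoint(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(cp$sensitivity, 1.0)
  expect_equal(cp$ppv, 1.0)
  # 8-score toy set against enumeration for both criteria
  s <- c(0.95, 0.9, 0.7, 0.65, 0.5, 0.4, 0.3, 0.1)
  y <- c(1, 0, 1, 1, 0, 1, 0, 0)
  for (method in c("youden", "f1")) {
    cp <- optimal_cutpoint(s, y, method)
    best <- -Inf
    for (t in sort(unique(s), decreasing = TRUE)) {
      pred <- s >= t
      tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
      sens <- tp / sum(y); spec <- 1 - fp / sum(y == 0)
      prec <- tp / (tp + fp)
      crit <- if (method == "youden") sens + spec - 1
              else 2 * prec * sens / (prec + sens)
      if (crit > best) { best <- crit; t_best <- t }
    }
    expect_equal(cp$threshold, t_best)
    expect_equal(cp$criterion, best)
  }
})

test_that("fold-AUC comparison is a Welch unpaired t test", {
  same <- rep(c(0.8, 0.82, 0.84), 4)
  res <- compare_auc(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  set.seed(77)
  a <- rnorm(1000, 0, 1); b <- rnorm(1000, 5, 1)
  expect_lt(compare_auc(a, b)$p_value, 1e-10)
  # textbook two-sample case against the direct Welch formulas
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7, 23.2,
         17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 23.9, 13.3)
  got <- compare_auc(x, y)
  se <- sqrt(var(x) / 10 + var(y) / 20)
  t_ref <- (mean(x) - mean(y)) / se
  df_ref <- se^4 / ((var(x) / 10)^2 / 9 + (var(y) / 20)^2 / 19)
  expect_equal(got$t, t_ref, tolerance = 1e-10)
  expect_equal(got$df, df_ref, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-10)
})
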