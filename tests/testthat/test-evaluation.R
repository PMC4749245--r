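test_that("AUC equals brute-force pairwise concordance, including ties", {
  expect_equal(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(4:200, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
      expect_equal(roc_curve(scores, labels)$auc, auc_brute(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_curve(runif(5), rep(1, 5)), "both outcome classes")
})

test_that("stored ROC points integrate (trapezoid) to the reported AUC", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      labels <- c(0, 1, rbinom(40, 1, 0.5))
      scores <- round(runif(42), 2)
      roc <- roc_curve(scores, labels)
      fpr <- 1 - roc$specificity
      tpr <- roc$sensitivity
      # append the (1,1) endpoint reached below the smallest threshold
      fpr <- c(fpr, 1)
      tpr <- c(tpr, 1)
      trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
      expect_equal(trap, roc$auc, tolerance = 1e-12)
    }
  })
})

test_that("fixed-specificity threshold is the smallest qualifying cut", {
  # 10 negatives scored 1..10: at target 0.9 only the top negative may be
  # called positive
  scores <- c(1:10, 10.5)
  labels <- c(rep(0, 10), 1)
  thr <- threshold_at_specificity(roc_curve(scores, labels), 0.90)
  expect_equal(thr, 10)
  m <- classification_metrics(scores, labels, thr)
  expect_equal(m$specificity, 90)
  # perfectly separated: threshold reaches specificity and sensitivity 1
  sep <- roc_curve(c(1:5, 11:15), rep(c(0, 1), each = 5))
  thr2 <- threshold_at_specificity(sep, 0.90)
  m2 <- classification_metrics(c(1:5, 11:15), rep(c(0, 1), each = 5), thr2)
  expect_equal(m2$specificity, 100)
  expect_equal(m2$sensitivity, 100)
  # unattainable target falls back to the smallest level >= target
  thr3 <- threshold_at_specificity(roc_curve(scores, labels), 0.999)
  expect_gt(thr3, 10)
  expect_equal(classification_metrics(scores, labels, thr3)$specificity, 100)
  expect_error(threshold_at_specificity(roc_curve(scores, labels), 1.2),
               "target_specificity")
})

test_that("threshold re-applied to its own training scores meets the target", {
  withr::with_seed(77, {
    for (rep in 1:50) {
      n <- sample(20:150, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.3))
      scores <- rnorm(n) + labels
      thr <- threshold_at_specificity(roc_curve(scores, labels), 0.90)
      m <- classification_metrics(scores, labels, thr)
      expect_gte(m$specificity, 90)
    }
  })
})

test_that("classification metrics reproduce the confusion-count identities", {
  # counts reconstructed from a 51-success / 122-failure validation set
  scores <- c(rep(1, 39), rep(0, 12), rep(1, 12), rep(0, 110))
  labels <- c(rep(1, 51), rep(0, 122))
  m <- classification_metrics(scores, labels, threshold = 0.5)
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(39L, 12L, 12L, 110L))
  expect_equal(m$sensitivity, 76.5, tolerance = 0.05)
  expect_equal(m$specificity, 90.2, tolerance = 0.05)
  expect_equal(m$npv, 90.2, tolerance = 0.05)
  expect_equal(m$ppv, 76.5, tolerance = 0.05)
  expect_equal(m$pa, 86.1, tolerance = 0.05)
  # identities recompute from stored counts
  expect_equal(m$sensitivity, 100 * m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, 100 * m$tn / (m$tn + m$fp))
  expect_equal(m$npv, 100 * m$tn / (m$tn + m$fn))
  expect_equal(m$ppv, 100 * m$tp / (m$tp + m$fp))
  expect_equal(m$pa, 100 * (m$tp + m$tn) / 173)
})

test_that("degenerate thresholds are handled explicitly", {
  scores <- c(0.2, 0.3, 0.8, 0.9)
  labels <- c(0, 1, 0, 1)
  expect_warning(low <- classification_metrics(scores, labels, -Inf),
                 "NPV undefined")
  expect_equal(low$sensitivity, 100)
  expect_equal(low$specificity, 0)
  expect_warning(
    high <- classification_metrics(scores, labels, 2),
    "PPV undefined")
  expect_equal(high$sensitivity, 0)
  expect_true(is.nan(high$ppv))
  expect_error(classification_metrics(scores, labels, NaN), "threshold")
})

test_that("paired AUC comparison matches an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(55, {
    for (rep in 1:5) {
      n <- 60
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      a <- rnorm(n) + labels
      b <- 0.7 * a + rnorm(n, 0, 0.5)
      got <- compare_auc(a, b, labels, paired = TRUE)
      ref <- pROC::roc.test(
        pROC::roc(labels, a, quiet = TRUE, direction = "<",
                  levels = c(0, 1)),
        pROC::roc(labels, b, quiet = TRUE, direction = "<",
                  levels = c(0, 1)),
        method = "delong", paired = TRUE)
      expect_equal(unname(got$statistic), unname(ref$statistic),
                   tolerance = 1e-9)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("identical scores give z = 0 and paired reduces to unpaired when uncorrelated", {
  labels <- rep(c(0, 1), 20)
  s <- runif(40)
  same <- compare_auc(s, s, labels)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # scores_b separates perfectly: its placement values are constant, so the
  # paired covariance vanishes and the paired variance equals the unpaired
  a <- rnorm(40) + labels
  b <- labels * 10 + c(rep(0, 20), rep(1, 20)) * 0  # perfect separation
  paired <- compare_auc(a, b, labels, paired = TRUE)
  unpaired <- compare_auc(a, b, labels, paired = FALSE)
  expect_equal(paired$variance, unpaired$variance, tolerance = 1e-12)
})

test_that("chi-square, Kendall and t-test match hand computations", {
  p_same <- compare_proportions(30, 100, 30, 100)
  expect_equal(p_same$p_value, 1)
  # 2x2 table (39,12; 18,33): chi-square = sum (O-E)^2 / E
  tab <- matrix(c(39, 12, 18, 33), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(compare_proportions(39, 51, 18, 51)$statistic,
               sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_lt(compare_proportions(50, 50, 0, 50)$p_value, 1e-10)
  expect_error(compare_proportions(1, 0, 2, 5), "positive")

  expect_equal(kendall_tau(1:6, 2 * (1:6))$estimate, 1)
  expect_equal(kendall_tau(1:6, -(1:6))$estimate, -1)
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 1, 4, 4, 6, 7)
  expect_equal(kendall_tau(x, y)$estimate, tau_b_brute(x, y),
               tolerance = 1e-12)
  expect_warning(flagged <- kendall_tau(rep(1, 5), 1:5), "constant")
  expect_equal(flagged$estimate, 0)

  same_groups <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same_groups$statistic, 0)
  expect_equal(same_groups$p_value, 1)
  expect_lt(t_test_independent(c(1, 2, 3), c(101, 102, 103))$p_value, 1e-6)
  a <- c(1.2, 2.5, 3.1)
  b <- c(2.0, 2.2, 4.4)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(t_test_independent(a, b)$statistic, t_hand, tolerance = 1e-12)
})

test_that("Hausman test is defined exactly when outcomes vary within patients", {
  rows <- simulate_glmm_rows(120, -1, 0.03, 1, seed = 61)
  h <- hausman_specification_test(rows)
  expect_s3_class(h, "amsa_test")
  if (!is.na(h$statistic)) {
    expect_gte(h$p_value, 0)
    expect_lte(h$p_value, 1)
  }
  constant <- data.frame(patient_id = rep(c("A", "B"), each = 3),
                         shock_index = rep(1:3, 2),
                         amsa = runif(6, 5, 20),
                         outcome = rep(c(0L, 1L), each = 3))
  expect_error(hausman_specification_test(constant), "undefined")
})
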