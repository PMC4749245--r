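#' ROC curve over all score thresholds
#'
#' Builds the receiver operating characteristic of a continuous score for a
#' binary outcome (1 = shock success, the positive class). The decision
#' rule everywhere in this package is `score >= threshold` predicts
#' success. The AUC is computed as the pairwise concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie), which equals the trapezoidal
#' area under the stored curve points.
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector (0/1 or logical), same length.
#' @return Object of class `roc_curve` with `thresholds` (decreasing, from
#'   `Inf`), `sensitivity`, `specificity` at each threshold, and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(is.na(scores)) || any(!labels %in% c(0L, 1L))) {
    stop("scores must be non-missing and labels binary 0/1")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC undefined: both outcome classes must be present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  # Mann-Whitney form of concordance; ties count one half
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%d successes, %d failures, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Operating threshold at a fixed training specificity
#'
#' Returns the smallest threshold whose specificity on the (training)
#' scores is at least `target_specificity`; because sensitivity is
#' non-increasing in the threshold, this is also the qualifying threshold
#' with maximal sensitivity. Exact equality with the target is rarely
#' attainable on finite data, so "at least" is used.
#'
#' @param roc A [roc_curve()] built from training scores.
#' @param target_specificity Specificity level in (0, 1); default 0.90.
#' @return The threshold value (possibly `Inf` when no finite threshold
#'   reaches the target).
#' @export
threshold_at_specificity <- function(roc, target_specificity = 0.90) {
  stopifnot(inherits(roc, "roc_curve"))
  if (!is.numeric(target_specificity) || length(target_specificity) != 1L ||
      target_specificity <= 0 || target_specificity >= 1) {
    stop("`target_specificity` must be in (0, 1)")
  }
  ok <- roc$specificity >= target_specificity
  # thresholds are stored in decreasing order; the last qualifying entry is
  # the smallest qualifying threshold
  min(roc$thresholds[ok])
}

#' Threshold-based classification metrics
#'
#' Applies the rule `score >= threshold` predicts success and reports the
#' confusion counts plus sensitivity, specificity, negative and positive
#' predictive value, and prediction accuracy, as percentages. Undefined
#' ratios (zero denominator) are reported as `NaN` with a warning.
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcomes (1 = success).
#' @param threshold Decision threshold.
#' @param feature_set Optional label stored in the report.
#' @return Object of class `performance_report`.
#' @export
classification_metrics <- function(scores, labels, threshold,
                                   feature_set = NA_character_) {
  labels <- as.integer(labels)
  if (is.na(threshold) || !is.numeric(threshold)) {
    stop("`threshold` must be a (possibly infinite) number")
  }
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  pct <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    100 * num / den
  }
  auc <- if (tp + fn > 0L && tn + fp > 0L) roc_curve(scores, labels)$auc
         else NA_real_
  structure(list(
    feature_set = feature_set, auc = auc, threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = pct(tp, tp + fn, "sensitivity"),
    specificity = pct(tn, tn + fp, "specificity"),
    npv = pct(tn, tn + fn, "NPV"),
    ppv = pct(tp, tp + fp, "PPV"),
    pa = pct(tp + tn, tp + fp + tn + fn, "accuracy")),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "<performance_report>%s AUC %.3f | sens %.1f%% spec %.1f%% NPV %.1f%% PPV %.1f%% PA %.1f%% (thr %.4g)\n",
    if (is.na(x$feature_set)) "" else paste0(" ", x$feature_set),
    x$auc, x$sensitivity, x$specificity, x$npv, x$ppv, x$pa, x$threshold))
  invisible(x)
}

test_result <- function(method, statistic, p_value, df = NA_real_,
                        estimate = NA_real_, flag = NA_character_, ...) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 df = df, estimate = estimate, flag = flag, ...),
            class = "amsa_test")
}

#' @export
print.amsa_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value, if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(s) mean(neg < s) + 0.5 * mean(neg == s),
                numeric(1))
  v01 <- vapply(neg, function(s) mean(pos > s) + 0.5 * mean(pos == s),
                numeric(1))
  list(theta = mean(v10), v10 = v10, v01 = v01)
}

#' Compare two AUCs on the same outcome vector
#'
#' Z-test for the difference of two AUCs. For `paired = TRUE` (two scores
#' for the same shocks, the usual case when comparing feature combinations
#' on one validation set) the variance of the difference accounts for the
#' correlation between the curves through the covariance of the placement
#' values; for `paired = FALSE` the variances simply add.
#'
#' @param scores_a,scores_b Two score vectors over the same shocks.
#' @param labels Binary outcomes (1 = success).
#' @param paired Treat the curves as correlated (default `TRUE`).
#' @return An `amsa_test` with the z statistic, two-sided p-value, and the
#'   AUC difference as `estimate` (also fields `auc_a`, `auc_b`).
#' @export
compare_auc <- function(scores_a, scores_b, labels, paired = TRUE) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) ||
      (paired && length(scores_b) != length(labels))) {
    stop("paired comparison needs both score vectors on the same shocks")
  }
  if (length(unique(labels)) < 2L) {
    stop("ROC undefined: both outcome classes must be present")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  if (paired) {
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  } else {
    v <- stats::var(pa$v10) / m + stats::var(pa$v01) / n +
         stats::var(pb$v10) / m + stats::var(pb$v01) / n
  }
  d <- pa$theta - pb$theta
  if (v <= 0 || !is.finite(v)) {
    z <- 0
    p <- 1
    flag <- if (abs(d) > 0) "zero-variance difference" else NA_character_
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    flag <- NA_character_
  }
  test_result("paired AUC z-test", z, p, estimate = d, flag = flag,
              auc_a = pa$theta, auc_b = pb$theta, variance = v)
}

#' Chi-square comparison of two proportions
#'
#' 2x2 chi-square test without continuity correction (the default used for
#' comparing sensitivities, predictive values and accuracies between
#' feature combinations); Yates correction available by flag.
#'
#' @param x_a,n_a Successes and total in group A.
#' @param x_b,n_b Successes and total in group B.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return An `amsa_test` with the chi-square statistic (1 df).
#' @export
compare_proportions <- function(x_a, n_a, x_b, n_b, correct = FALSE) {
  if (n_a <= 0 || n_b <= 0) stop("group totals must be positive")
  if (x_a < 0 || x_b < 0 || x_a > n_a || x_b > n_b) {
    stop("successes must lie in [0, total]")
  }
  tab <- matrix(c(x_a, n_a - x_a, x_b, n_b - x_b), nrow = 2, byrow = TRUE)
  if (abs(x_a / n_a - x_b / n_b) < .Machine$double.eps^0.5) {
    return(test_result("chi-square (2x2)", 0, 1, df = 1,
                       estimate = x_a / n_a - x_b / n_b))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  test_result("chi-square (2x2)", unname(ct$statistic), ct$p.value, df = 1,
              estimate = x_a / n_a - x_b / n_b)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a normal-approximation p-value,
#' used to quantify association among AMSA, PSI and delta-AMSA (PSI is
#' ternary, so tie correction matters).
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return An `amsa_test` with `estimate` = tau-b. A constant input yields
#'   tau 0 with a warning and a flag.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant vector; reporting tau = 0")
    return(test_result("Kendall tau-b", NA_real_, NA_real_, estimate = 0,
                       flag = "constant input"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  test_result("Kendall tau-b", unname(ct$statistic), ct$p.value,
              estimate = unname(ct$estimate))
}

#' Independent-samples t-test
#'
#' Two-sided comparison of group means (pooled variance by default, Welch
#' optional), as used to compare AMSA between successful and failed shocks.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance test (default `TRUE`); `FALSE` = Welch.
#' @return An `amsa_test`; `estimate` is the mean difference a - b.
#' @export
t_test_independent <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  d <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (abs(d) < .Machine$double.eps^0.5) {
      return(test_result("independent t-test", 0, 1, estimate = 0,
                         flag = "zero variance in both groups"))
    }
    stop("degenerate data: zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  test_result("independent t-test", unname(tt$statistic), tt$p.value,
              df = unname(tt$parameter), estimate = d)
}

#' Hausman specification test: fixed vs random patient effects
#'
#' Fits the covariate's effect on shock success by conditional
#' (fixed-effects) logistic regression stratified on patient and by
#' random-intercept logistic regression, and compares the two estimates
#' with the Hausman statistic `H = (b_FE - b_RE)^2 / (var_FE - var_RE)`,
#' referred to a chi-square with 1 df. Under exogeneity of the patient
#' effect both estimators are consistent and H is small; a significant H
#' indicates the random-effects specification is inconsistent.
#'
#' @param rows data.frame with `outcome`, `patient_id` and the covariate.
#' @param covariate Covariate column name (default `"amsa"`).
#' @param nAGQ Gauss-Hermite nodes for the random-intercept fit.
#' @return An `amsa_test`; a negative variance difference is reported as
#'   inconclusive with a flag (statistic `NA`).
#' @export
hausman_specification_test <- function(rows, covariate = "amsa", nAGQ = 15L) {
  varies <- tapply(rows$outcome, rows$patient_id,
                   function(y) length(unique(y)) > 1L)
  if (!any(varies)) {
    stop("test undefined: no patient has within-sequence outcome variation")
  }
  d <- data.frame(y = as.integer(rows$outcome), x = rows[[covariate]],
                  g = as.factor(rows$patient_id))
  # conditional logistic likelihood == exact-ties Cox likelihood on a
  # constant follow-up time, stratified by patient
  fe <- survival::coxph(survival::Surv(rep(1, nrow(d)), d$y) ~ x +
                          survival::strata(g),
                        data = d, method = "exact")
  b_fe <- unname(stats::coef(fe)["x"])
  v_fe <- stats::vcov(fe)["x", "x"]
  re <- fit_logistic(rows, covariates = covariate, random_intercept = TRUE,
                     nAGQ = nAGQ)
  b_re <- re$coefficients[[covariate]]
  v_re <- re$vcov[covariate, covariate]
  dv <- v_fe - v_re
  if (dv <= 0) {
    return(test_result("Hausman specification test", NA_real_, NA_real_,
                       df = 1, estimate = b_fe - b_re,
                       flag = "inconclusive: non-positive variance difference",
                       beta_fe = b_fe, beta_re = b_re))
  }
  h <- (b_fe - b_re)^2 / dv
  test_result("Hausman specification test", h,
              stats::pchisq(h, df = 1, lower.tail = FALSE), df = 1,
              estimate = b_fe - b_re, beta_fe = b_fe, beta_re = b_re)
}
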