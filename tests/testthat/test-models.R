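make_toy_rows <- function(n = 200, seed = 17, separable = FALSE) {
  withr::with_seed(seed, {
    amsa <- runif(n, 2, 30)
    psi <- sample(c(-1, 0, 1), n, replace = TRUE)
    delta <- rnorm(n, 0, 3)
    eta <- -3 + 0.25 * amsa + 0.8 * psi
    y <- if (separable) as.integer(amsa + 3 * psi > 16)
         else rbinom(n, 1, plogis(eta))
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               shock_index = 1L, amsa = amsa, psi = psi,
               delta_amsa = delta, outcome = y)
  })
}

test_that("the network separates linearly separable training data", {
  rows <- make_toy_rows(200, seed = 2, separable = TRUE)
  m <- train_bp_network(rows, "C1", seed = 4)
  auc <- roc_curve(predict(m, rows), rows$outcome)$auc
  expect_gt(auc, 0.99)
})

test_that("a constant-feature network has no predictive power", {
  rows <- make_toy_rows(150, seed = 3)
  rows$amsa <- 5  # only feature, constant
  m <- suppressWarnings(train_bp_network(rows, "AMSA", seed = 1))
  val <- make_toy_rows(150, seed = 8)
  val$amsa <- 5
  scores <- predict(m, val)
  expect_lt(diff(range(scores)), 1e-8)
  expect_equal(roc_curve(scores + 1e-9 * seq_along(scores) * 0,
                         val$outcome)$auc, 0.5)
})

test_that("network training is deterministic given the seed", {
  rows <- make_toy_rows(120, seed = 5)
  m1 <- train_bp_network(rows, "C3", seed = 11)
  m2 <- train_bp_network(rows, "C3", seed = 11)
  expect_identical(m1$w_vec, m2$w_vec)
  m3 <- train_bp_network(rows, "C3", seed = 12)
  expect_false(isTRUE(all.equal(m1$w_vec, m3$w_vec)))
  expect_identical(predict(m1, rows), predict(m2, rows))
})

test_that("the per-cycle training trace is non-increasing", {
  rows <- make_toy_rows(150, seed = 6)
  m <- train_bp_network(rows, "C3", seed = 2)
  for (trace in m$training_trace) {
    expect_true(all(diff(trace) <= 1e-12))
  }
  expect_error(train_bp_network(transform(rows, outcome = 1L), "C3"),
               "degenerate")
})

test_that("logistic predictions are the inverse-logit of the linear score", {
  rows <- make_toy_rows(300, seed = 7)
  fit <- fit_logistic(rows, c("amsa", "psi"))
  eta <- fit$coefficients[["(Intercept)"]] +
    fit$coefficients[["amsa"]] * rows$amsa +
    fit$coefficients[["psi"]] * rows$psi
  expect_equal(predict(fit, rows), plogis(eta), tolerance = 1e-12)
  expect_true(all(predict(fit, rows) > 0 & predict(fit, rows) < 1))
  # positive coefficient implies scores increase with AMSA
  ord <- order(rows$amsa)
  single <- fit_logistic(rows, "amsa")
  expect_true(all(diff(predict(single, rows[ord, ])) > 0))
})

test_that("odds ratios come with consistent Wald intervals", {
  rows <- make_toy_rows(400, seed = 10)
  fit <- fit_logistic(rows, c("amsa", "psi"))
  rr <- fit$regression_result
  expect_true(all(rr$ci_low <= rr$odds_ratio))
  expect_true(all(rr$odds_ratio <= rr$ci_high))
  expect_true(all(rr$odds_ratio > 0))
})

test_that("random-intercept fit collapses to the pooled fit when sigma_b = 0", {
  rows <- simulate_glmm_rows(300, -1, 0.03, sigma_b = 0, seed = 21,
                             shocks_min = 4L, shocks_max = 6L)
  re <- fit_logistic(rows, "amsa", random_intercept = TRUE)
  pooled <- fit_logistic(rows, "amsa", random_intercept = FALSE)
  expect_lt(re$sigma_b, 0.15)
  expect_equal(re$coefficients[["amsa"]], pooled$coefficients[["amsa"]],
               tolerance = 0.05)
})

test_that("adding an informative covariate never lowers in-sample likelihood", {
  rows <- make_toy_rows(250, seed = 13)
  l1 <- fit_logistic(rows, "amsa")$logLik
  l2 <- fit_logistic(rows, c("amsa", "psi"))$logLik
  expect_gte(l2, l1 - 1e-8)
})

test_that("all four combinations are fitted with the expected input widths", {
  rows <- make_toy_rows(150, seed = 19)
  nets <- fit_all_combinations(rows, "network", seed = 5)
  expect_named(nets, c("AMSA", "C1", "C2", "C3"))
  expect_identical(vapply(nets, function(m) m$shape$p, integer(1)),
                   c(AMSA = 1L, C1 = 2L, C2 = 2L, C3 = 3L))
  glms <- fit_all_combinations(rows, "logistic")
  expect_identical(vapply(glms, function(m) length(m$covariates),
                          integer(1)),
                   c(AMSA = 1L, C1 = 2L, C2 = 2L, C3 = 3L))
  # logistic fits carry no seed dependence
  glms2 <- fit_all_combinations(rows, "logistic", seed = 99)
  expect_equal(glms$C3$coefficients, glms2$C3$coefficients)
})

test_that("on first shocks all combination models reduce to AMSA-only ranking", {
  co <- generate_cohort(generator_config(n_patients = 120, seed = 14),
                        generate_episodes = FALSE)
  first <- build_feature_table(co, "C3", "first")
  glms <- fit_all_combinations(first, "logistic")
  aucs <- vapply(glms, function(m) {
    roc_curve(predict(m, first), first$outcome)$auc
  }, numeric(1))
  expect_equal(unname(aucs), rep(aucs[["AMSA"]], 4), tolerance = 1e-12)
  nets <- fit_all_combinations(first, "network", seed = 6)
  net_aucs <- vapply(nets, function(m) {
    roc_curve(predict(m, first), first$outcome)$auc
  }, numeric(1))
  expect_lt(max(net_aucs) - min(net_aucs), 0.01)
})

test_that("sequential intercept updating uses earlier shocks of the same patient", {
  rows <- simulate_glmm_rows(150, -1, 0.05, 1.2, seed = 33)
  fit <- fit_logistic(rows, "amsa", random_intercept = TRUE)
  marginal <- predict(fit, rows)
  updated <- predict(fit, rows, re_update = TRUE)
  firsts <- rows$shock_index == 1L
  expect_equal(updated[firsts], marginal[firsts])
  expect_false(isTRUE(all.equal(updated[!firsts], marginal[!firsts])))
})

test_that("serialized networks reload with bit-identical predictions", {
  rows <- make_toy_rows(120, seed = 23)
  m <- train_bp_network(rows, "C3", seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_bp_network(m, path)
  back <- read_bp_network(path)
  expect_identical(predict(back, rows), predict(m, rows))
  expect_identical(back$w_vec, m$w_vec)
  expect_identical(back$center, m$center)
  expect_error(read_bp_network(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "not a serialized")
})
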