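# --- small feed-forward network -------------------------------------------
#
# Topology: inputs -> 3 logistic-sigmoid units -> 2 linear units -> 1
# logistic-sigmoid output giving P(success). Trained by minimizing
# cross-entropy plus an L2 weight penalty lambda * sum(w^2) (biases are not
# penalized), with lambda either fixed or re-estimated between optimization
# cycles by an evidence-style update (see nn_evidence_update). Optimization
# is quasi-Newton with monotone accepted steps; the recorded per-cycle
# trace is non-increasing.

nn_pack_shape <- function(p, hidden = c(3L, 2L)) {
  list(p = p, h1 = hidden[1], h2 = hidden[2])
}

nn_unpack <- function(w, s) {
  i <- 0L
  take <- function(n) {
    out <- w[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  list(W1 = matrix(take(s$p * s$h1), s$p, s$h1), b1 = take(s$h1),
       W2 = matrix(take(s$h1 * s$h2), s$h1, s$h2), b2 = take(s$h2),
       W3 = matrix(take(s$h2), s$h2, 1L), b3 = take(1L))
}

nn_penalty_mask <- function(s) {
  c(rep(TRUE, s$p * s$h1), rep(FALSE, s$h1),
    rep(TRUE, s$h1 * s$h2), rep(FALSE, s$h2),
    rep(TRUE, s$h2), FALSE)
}

nn_forward <- function(wl, x) {
  h1 <- stats::plogis(sweep(x %*% wl$W1, 2, wl$b1, "+"))
  h2 <- sweep(h1 %*% wl$W2, 2, wl$b2, "+")
  z3 <- drop(h2 %*% wl$W3) + wl$b3
  list(h1 = h1, h2 = h2, p = stats::plogis(z3))
}

nn_objective <- function(w, s, x, y, lambda, mask) {
  wl <- nn_unpack(w, s)
  p <- pmin(pmax(nn_forward(wl, x)$p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(w[mask]^2)
}

nn_gradient <- function(w, s, x, y, lambda, mask) {
  wl <- nn_unpack(w, s)
  fwd <- nn_forward(wl, x)
  n <- nrow(x)
  dz3 <- matrix((fwd$p - y) / n, ncol = 1L)
  dW3 <- t(fwd$h2) %*% dz3
  db3 <- sum(dz3)
  dh2 <- dz3 %*% t(wl$W3)
  dW2 <- t(fwd$h1) %*% dh2
  db2 <- colSums(dh2)
  dh1 <- dh2 %*% t(wl$W2)
  dz1 <- dh1 * fwd$h1 * (1 - fwd$h1)
  dW1 <- t(x) %*% dz1
  db1 <- colSums(dz1)
  g <- c(as.vector(dW1), db1, as.vector(dW2), db2, as.vector(dW3), db3)
  g[mask] <- g[mask] + 2 * lambda * w[mask]
  g
}

# One optimization cycle at fixed lambda: a sequence of quasi-Newton
# (BFGS) segments, each started from the previous accepted iterate and
# accepted only if it lowers the objective, so the recorded trace is
# non-increasing by construction. BFGS handles the sigmoid plateaus that
# defeat plain gradient descent on this tiny network.
nn_descend <- function(w, s, x, y, lambda, mask, max_segments = 8L,
                       maxit = 150L, tol = 1e-10) {
  f <- nn_objective(w, s, x, y, lambda, mask)
  trace <- f
  converged <- FALSE
  for (seg in seq_len(max_segments)) {
    opt <- stats::optim(w, fn = nn_objective, gr = nn_gradient,
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12),
                        s = s, x = x, y = y, lambda = lambda, mask = mask)
    if (is.finite(opt$value) && opt$value <= f) {
      improved <- f - opt$value
      w <- opt$par
      f <- opt$value
      trace <- c(trace, f)
      if (improved < tol * max(1, abs(f))) {
        converged <- TRUE
        break
      }
    } else {
      converged <- TRUE
      break
    }
  }
  list(w = w, f = f, trace = trace, converged = converged)
}

#' Train the combination feed-forward network
#'
#' Fits the small back-propagation network (3 sigmoid units, 2 linear
#' units, sigmoid output) that maps a feature combination to the
#' probability of shock success. Inputs are z-scored with the training
#' columns' mean/SD (a zero-variance column gets scale 1 and therefore no
#' influence). The objective is cross-entropy plus an L2 weight penalty;
#' under the default `"evidence"` policy the penalty weight is re-estimated
#' between optimization cycles from the curvature of the objective, which
#' keeps the tiny network from overfitting the training shocks.
#'
#' @param rows Training table from [build_feature_table()] (columns:
#'   features plus `outcome`).
#' @param feature_set `"AMSA"`, `"C1"`, `"C2"` or `"C3"`.
#' @param lambda_policy `"evidence"` (re-estimate, default) or `"fixed"`.
#' @param lambda Initial (or fixed) penalty weight, >= 0. The default is
#'   deliberately weak: the mean cross-entropy of a near-balanced problem
#'   is O(0.7), and a stronger initial penalty can make the zero-weight
#'   saddle the nearest basin before the evidence update has any fit to
#'   work from.
#' @param seed Integer seed for the weight initialization; training is a
#'   pure function of data + seed.
#' @param n_cycles Optimization cycles between penalty updates (default 3).
#' @param n_restarts Independent seeded initializations; the restart with
#'   the lowest final objective is kept (default 3). Multi-start guards the
#'   tiny network against poor local minima.
#' @return Object of class `bp_network` with the trained weights, the
#'   per-cycle objective traces, the standardization constants, and the
#'   final penalty weight and effective number of parameters.
#' @export
train_bp_network <- function(rows, feature_set = "C3",
                             lambda_policy = c("evidence", "fixed"),
                             lambda = 0.001, seed = 1L, n_cycles = 3L,
                             n_restarts = 3L) {
  lambda_policy <- match.arg(lambda_policy)
  cols <- feature_set_columns(feature_set)
  if (!all(cols %in% names(rows))) {
    stop("training rows lack feature columns: ",
         paste(setdiff(cols, names(rows)), collapse = ", "))
  }
  y <- as.integer(rows$outcome)
  if (length(unique(y)) < 2L) {
    stop("degenerate training data: only one outcome class present")
  }
  if (any(y == 1L) && sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("need at least 2 rows per outcome class")
  }
  x_raw <- as.matrix(rows[, cols, drop = FALSE])
  if (any(!is.finite(x_raw))) stop("non-finite feature values")
  center <- colMeans(x_raw)
  scale <- apply(x_raw, 2, stats::sd)
  scale[scale == 0] <- 1
  x <- sweep(sweep(x_raw, 2, center), 2, scale, "/")
  s <- nn_pack_shape(ncol(x))
  mask <- nn_penalty_mask(s)
  n_par <- length(mask)
  lambda0 <- lambda
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w <- withr::with_seed(as.integer(seed) + 7919L * (r - 1L),
                          stats::runif(n_par, -0.5, 0.5))
    lambda <- lambda0
    traces <- list()
    gamma <- NA_real_
    converged <- TRUE
    for (cycle in seq_len(n_cycles)) {
      fit <- nn_descend(w, s, x, y, lambda, mask)
      w <- fit$w
      traces[[cycle]] <- fit$trace
      converged <- converged && fit$converged
      if (lambda_policy == "evidence" && cycle < n_cycles) {
        upd <- nn_evidence_update(w, s, x, y, lambda, mask)
        lambda <- upd$lambda
        gamma <- upd$gamma
      }
    }
    obj <- traces[[n_cycles]][length(traces[[n_cycles]])]
    if (is.null(best) || obj < best$objective) {
      best <- list(w = w, lambda = lambda, gamma = gamma, traces = traces,
                   converged = converged, objective = obj)
    }
  }
  if (!best$converged) {
    warning("network training hit the step limit before converging; ",
            "model flagged")
  }
  structure(list(
    weights = nn_unpack(best$w, s), w_vec = best$w, shape = s,
    feature_set = feature_set, feature_cols = cols,
    center = center, scale = scale,
    lambda = best$lambda, lambda_policy = lambda_policy, gamma = best$gamma,
    seed = as.integer(seed), training_trace = best$traces,
    converged = best$converged, objective = best$objective),
    class = "bp_network")
}

# MacKay-style evidence re-estimation of the L2 penalty. On the summed
# log-likelihood scale the update is alpha <- gamma / (2 E_W) with
# gamma = sum_i e_i / (e_i + alpha) the effective number of parameters
# (e_i: eigenvalues of the data-misfit Hessian); with the mean
# cross-entropy objective used here that translates to
# lambda <- gamma / (2 n sum(w^2)).
nn_evidence_update <- function(w, s, x, y, lambda, mask) {
  k_w <- sum(mask)
  gamma <- k_w / 2
  h <- try(stats::optimHess(w, fn = nn_objective, gr = nn_gradient,
                            s = s, x = x, y = y, lambda = 0, mask = mask),
           silent = TRUE)
  if (!inherits(h, "try-error") && all(is.finite(h))) {
    eig <- pmax(eigen(0.5 * (h + t(h)), symmetric = TRUE,
                      only.values = TRUE)$values, 0)
    gamma <- sum(eig / (eig + 2 * lambda))
  }
  # keep at least one effective parameter and damp the growth of the
  # penalty: the raw fixed-point iteration can spiral into pruning the
  # whole network when the class signal is weak
  gamma <- max(gamma, 1)
  ew <- sum(w[mask]^2)
  n <- nrow(x)
  lambda_new <- gamma / (2 * n * max(ew, 1e-6))
  list(lambda = min(max(lambda_new, 1e-6), 4 * lambda, 10),
       gamma = gamma)
}

#' @export
print.bp_network <- function(x, ...) {
  cat(sprintf(
    "<bp_network> %s: %d-3-2-1, lambda %.4g (%s), objective %.4f%s\n",
    x$feature_set, x$shape$p, x$lambda, x$lambda_policy, x$objective,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict success probabilities
#'
#' Forward pass of a trained [train_bp_network()] model on new shocks.
#' Scores are strictly inside (0, 1).
#'
#' @param object A `bp_network`.
#' @param newdata data.frame carrying the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of success probabilities.
#' @export
predict.bp_network <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_cols, names(newdata))
  if (length(miss)) stop("newdata lacks columns: ", paste(miss, collapse = ", "))
  x <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- nn_forward(object$weights, x)$p
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

# --- logistic models -------------------------------------------------------

#' Logistic regression with optional patient random intercept
#'
#' Fits shock success on one or more features by ordinary (pooled) logistic
#' regression or by a random-intercept logistic model with a patient-level
#' intercept `b ~ N(0, sigma_b^2)`, integrated by adaptive Gauss-Hermite
#' quadrature. The random-intercept form is the appropriate specification
#' when repeated shocks of one patient are correlated. Odds ratios with
#' Wald 95% confidence intervals are reported per covariate.
#'
#' @param rows data.frame with `outcome`, `patient_id` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param random_intercept Fit the patient random intercept (default
#'   `FALSE` = pooled model).
#' @param nAGQ Number of Gauss-Hermite quadrature nodes (default 15).
#' @return Object of class `shock_logistic` with `coefficients` (including
#'   `(Intercept)`), fixed-effect `vcov`, `sigma_b` (0 for pooled),
#'   `regression_result` (data.frame: odds_ratio, ci_low, ci_high,
#'   p_value), `logLik` and a `converged` flag. Zero-variance covariates
#'   are dropped (recorded in `$dropped`).
#' @export
fit_logistic <- function(rows, covariates = "amsa", random_intercept = FALSE,
                         nAGQ = 15L) {
  y <- as.integer(rows$outcome)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  miss <- setdiff(covariates, names(rows))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  keep <- covariates[vapply(covariates,
                            function(v) stats::sd(rows[[v]]) > 0, logical(1))]
  dropped <- setdiff(covariates, keep)
  d <- rows[, c("patient_id", keep, "outcome"), drop = FALSE]
  d$outcome <- y
  converged <- TRUE
  if (random_intercept) {
    if (length(unique(d$patient_id)) < 2L) {
      stop("random-intercept fit needs >= 2 patients")
    }
    fml <- stats::reformulate(c(keep, "(1 | patient_id)"),
                              response = "outcome")
    fit <- withCallingHandlers(
      suppressMessages(
        lme4::glmer(fml, data = d, family = stats::binomial(),
                    nAGQ = as.integer(nAGQ))),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    sigma_b <- sqrt(unname(lme4::VarCorr(fit)$patient_id[1]))
  } else {
    fml <- stats::reformulate(if (length(keep)) keep else "1",
                              response = "outcome")
    fit <- suppressWarnings(stats::glm(fml, data = d,
                                       family = stats::binomial()))
    converged <- fit$converged &&
      !any(fit$fitted.values > 1 - 1e-10 | fit$fitted.values < 1e-10)
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
    sigma_b <- 0
  }
  if (any(!is.finite(unlist(beta)))) {
    stop("non-finite coefficient estimates (complete separation?)")
  }
  rr <- NULL
  if (length(keep)) {
    se <- sqrt(diag(vc))[keep]
    b <- beta[keep]
    z <- b / se
    rr <- data.frame(covariate = keep, odds_ratio = exp(b),
                     ci_low = exp(b - 1.959964 * se),
                     ci_high = exp(b + 1.959964 * se),
                     p_value = 2 * stats::pnorm(-abs(z)),
                     row.names = NULL)
  }
  dimnames(vc) <- list(names(beta), names(beta))
  structure(list(fit = fit, covariates = keep, dropped = dropped,
                 random_intercept = random_intercept,
                 coefficients = as.list(beta), vcov = vc, sigma_b = sigma_b,
                 regression_result = rr, logLik = as.numeric(stats::logLik(fit)),
                 converged = converged),
            class = "shock_logistic")
}

#' @export
print.shock_logistic <- function(x, ...) {
  cat(sprintf("<shock_logistic> %s model, covariates: %s%s\n",
              if (x$random_intercept)
                sprintf("random-intercept (sigma_b = %.3f)", x$sigma_b)
              else "pooled",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(intercept only)",
              if (x$converged) "" else " [convergence flagged]"))
  if (!is.null(x$regression_result)) {
    print(x$regression_result, digits = 4)
  }
  invisible(x)
}

#' Predict success probabilities from a logistic model
#'
#' Marginal prediction: the patient random intercept is set to its prior
#' mean 0, since a new patient's intercept is unobservable at prediction
#' time. With `re_update = TRUE` the intercept is instead replaced, shock
#' by shock, with its posterior mode given the same patient's *earlier*
#' shocks in `newdata` (a sequential update usable in real time, where
#' previous outcomes are known by the time the next shock is scored).
#'
#' @param object A `shock_logistic`.
#' @param newdata data.frame with the covariates (plus `patient_id`,
#'   `shock_index`, `outcome` when `re_update = TRUE`).
#' @param re_update Sequentially update the patient intercept (default
#'   `FALSE`).
#' @param ... Unused.
#' @return Numeric vector of success probabilities in (0, 1).
#' @export
predict.shock_logistic <- function(object, newdata, re_update = FALSE, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) stop("newdata lacks columns: ", paste(miss, collapse = ", "))
  eta0 <- object$coefficients[["(Intercept)"]]
  eta <- rep(eta0, nrow(newdata))
  for (v in object$covariates) {
    eta <- eta + object$coefficients[[v]] * newdata[[v]]
  }
  if (re_update && object$sigma_b > 0) {
    b <- vapply(seq_len(nrow(newdata)), function(i) {
      prev <- newdata$patient_id == newdata$patient_id[i] &
        newdata$shock_index < newdata$shock_index[i]
      if (!any(prev)) return(0)
      posterior_mode_b(eta[prev], newdata$outcome[prev], object$sigma_b)
    }, numeric(1))
    eta <- eta + b
  }
  stats::plogis(eta)
}

# posterior mode of the patient intercept given earlier shocks' linear
# predictors and outcomes, prior N(0, sigma_b^2)
posterior_mode_b <- function(eta_prev, y_prev, sigma_b) {
  nll <- function(b) {
    p <- stats::plogis(eta_prev + b)
    -sum(y_prev * log(p) + (1 - y_prev) * log(1 - p)) + b^2 / (2 * sigma_b^2)
  }
  stats::optimize(nll, c(-6 * sigma_b, 6 * sigma_b))$minimum
}

#' Fit all four feature combinations
#'
#' Trains one model per feature set (AMSA, C1, C2, C3) on the same training
#' rows, with per-set seeds derived from the shared seed (network) or no
#' randomness at all (logistic).
#'
#' @param rows Training table with all three feature columns and `outcome`.
#' @param method `"network"` or `"logistic"`.
#' @param seed Shared seed; the network for feature set j uses `seed + j`.
#' @param random_intercept For the logistic method (default `FALSE`).
#' @param ... Passed to [train_bp_network()] or [fit_logistic()].
#' @return Named list of models (`AMSA`, `C1`, `C2`, `C3`).
#' @export
fit_all_combinations <- function(rows, method = c("network", "logistic"),
                                 seed = 1L, random_intercept = FALSE, ...) {
  method <- match.arg(method)
  sets <- c("AMSA", "C1", "C2", "C3")
  models <- lapply(seq_along(sets), function(j) {
    if (method == "network") {
      train_bp_network(rows, feature_set = sets[j], seed = seed + j, ...)
    } else {
      fit_logistic(rows, covariates = feature_set_columns(sets[j]),
                   random_intercept = random_intercept, ...)
    }
  })
  names(models) <- sets
  models
}

#' Serialize a trained network to a structured text file
#'
#' Writes every field needed to reproduce predictions exactly — layer
#' sizes, feature columns, standardization constants, weights, penalty and
#' seed — as full-precision JSON. `read_bp_network()` restores a model
#' whose predictions are bit-identical to the original's.
#'
#' @param model A `bp_network`.
#' @param path Output file path.
#' @return `path` (write) / the restored `bp_network` (read), invisibly.
#' @export
write_bp_network <- function(model, path) {
  stopifnot(inherits(model, "bp_network"))
  # doubles are written as %.17g strings: 17 significant digits
  # round-trip IEEE doubles exactly, which plain JSON numbers do not
  # guarantee through every serializer
  num <- function(x) sprintf("%.17g", x)
  payload <- list(
    format = "amsaShock/bp_network/1",
    feature_set = model$feature_set,
    feature_cols = model$feature_cols,
    shape = model$shape,
    center_names = names(model$center),
    center = num(model$center),
    scale = num(model$scale),
    w_vec = num(model$w_vec),
    lambda = num(model$lambda),
    lambda_policy = model$lambda_policy,
    gamma = num(model$gamma),
    seed = model$seed,
    converged = model$converged,
    objective = num(model$objective))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bp_network
#' @export
read_bp_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "amsaShock/bp_network/1")) {
    stop("not a serialized bp_network file: ", path)
  }
  s <- list(p = as.integer(p$shape$p), h1 = as.integer(p$shape$h1),
            h2 = as.integer(p$shape$h2))
  w_vec <- as.numeric(p$w_vec)
  structure(list(
    weights = nn_unpack(w_vec, s), w_vec = w_vec, shape = s,
    feature_set = p$feature_set, feature_cols = p$feature_cols,
    center = stats::setNames(as.numeric(p$center), p$center_names),
    scale = stats::setNames(as.numeric(p$scale), p$center_names),
    lambda = as.numeric(p$lambda), lambda_policy = p$lambda_policy,
    gamma = as.numeric(p$gamma),
    seed = as.integer(p$seed), training_trace = NULL,
    converged = p$converged, objective = as.numeric(p$objective)),
    class = "bp_network")
}
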