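# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so that they share no
# code path with the implementation they check.

# O(N^2) discrete Fourier transform
dft_naive <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  drop(exp(-2i * pi * outer(k, k) / n) %*% x)
}

# single-sided amplitude spectrum from the naive DFT, same normalization
# convention as the package (interior bins doubled)
amplitude_spectrum_naive <- function(x, fs) {
  n <- length(x)
  dft <- dft_naive(x)
  n_half <- floor(n / 2) + 1L
  k <- seq_len(n_half) - 1L
  amp <- Mod(dft[seq_len(n_half)]) / n
  doubled <- k > 0L & !(n %% 2L == 0L & k == n / 2L)
  amp[doubled] <- 2 * amp[doubled]
  list(frequencies = k * fs / n, amplitudes = amp)
}

amsa_naive <- function(x, fs, lo = 2, hi = 48) {
  sp <- amplitude_spectrum_naive(x, fs)
  keep <- sp$frequencies >= lo & sp$frequencies <= hi
  sum(sp$amplitudes[keep] * sp$frequencies[keep])
}

# AUC as explicit pairwise concordance over all (positive, negative) pairs
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Kendall tau-b by explicit pair counting with tie corrections
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n_pairs <- n * (n - 1) / 2
  (conc - disc) / sqrt((n_pairs - tx_total(x)) * (n_pairs - tx_total(y)))
}

tx_total <- function(v) {
  tt <- table(v)
  sum(tt * (tt - 1) / 2)
}

# PSI / delta-AMSA directly from the recursive definitions, one shock at a
# time
psi_brute <- function(outcomes) {
  vapply(seq_along(outcomes), function(k) {
    if (k == 1) 0 else if (outcomes[k - 1] == 1) 1 else -1
  }, numeric(1))
}

delta_amsa_brute <- function(amsa) {
  vapply(seq_along(amsa), function(k) {
    if (k == 1) 0 else amsa[k] - amsa[k - 1]
  }, numeric(1))
}

# per-shock rows for a random-intercept logistic simulation with known
# coefficients (used by the recovery / calibration tests)
simulate_glmm_rows <- function(n_patients, beta0, beta_amsa, sigma_b, seed,
                               shocks_min = 2L, shocks_max = 4L,
                               null_covariate = FALSE) {
  withr::with_seed(seed, {
    out <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      k <- sample(shocks_min:shocks_max, 1L)
      b <- stats::rnorm(1, 0, sigma_b)
      amsa <- pmax(stats::rnorm(k, 12, 8), 0.5)
      z <- stats::rnorm(k)  # covariate unrelated to outcome
      y <- stats::rbinom(k, 1, stats::plogis(beta0 + beta_amsa * amsa + b))
      out[[i]] <- data.frame(patient_id = sprintf("P%04d", i),
                             shock_index = seq_len(k), amsa = amsa,
                             noise_cov = z, outcome = y)
    }
    do.call(rbind, out)
  })
}
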