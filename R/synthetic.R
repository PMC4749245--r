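#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the synthetic out-of-hospital cardiac arrest (OHCA)
#' cohort generator. The defaults are calibrated so that the generated
#' cohorts reproduce the summary structure of a real defibrillation series:
#' first-shock AMSA of roughly 16 +/- 9 mV·Hz before successful and
#' 9 +/- 6 mV·Hz before failed shocks, an overall per-shock success rate
#' near 38%, about 64% of patients needing more than one shock, a
#' subsequent-shock success rate near 29%, and positive rank correlation
#' between AMSA and the previous shock index.
#'
#' The latent model: each patient carries a random log-odds intercept
#' `b ~ N(0, sigma_patient^2)`. The first shock's outcome is Bernoulli
#' (`p_success_first`) and its AMSA is drawn from the outcome-conditional
#' normal (truncated below at 0.5 mV·Hz). Later shocks follow an AR(1)
#' carryover `AMSA_k = amsa_carryover * AMSA_{k-1} + drift(outcome_{k-1}) +
#' noise`, and succeed with probability
#' `plogis(beta0 + beta_amsa * AMSA_k + b)`. After a successful shock the
#' patient refibrillates (and so needs another shock) with probability
#' `p_refib`; after a failed shock resuscitation continues with probability
#' `p_continue_after_fail`. A sequence ends at a sustained success, at
#' abandonment, or at `max_shocks`. Setting `p_refib = 0` and
#' `p_continue_after_fail = 1` gives the simpler stop-at-first-success
#' model in which every subsequent shock follows a failure.
#'
#' @param n_patients Number of patients (>= 2).
#' @param sampling_rate ECG sampling rate, Hz.
#' @param episode_duration Pre-shock episode length, seconds.
#' @param amsa_mean_success_first,amsa_sd_success_first Mean/SD (mV·Hz) of
#'   first-shock AMSA given success.
#' @param amsa_mean_fail_first,amsa_sd_fail_first Mean/SD given failure.
#' @param amsa_mean_success_subseq,amsa_sd_subseq_success Reference mean/SD
#'   (mV·Hz) for successful subsequent shocks; reported alongside the
#'   realized values by [calibration_report()] (subsequent-shock AMSA is
#'   generated by the carryover recursion, not drawn from these directly).
#' @param amsa_mean_fail_subseq,amsa_sd_fail_subseq Reference mean/SD for
#'   failed subsequent shocks.
#' @param p_success_first First-shock success probability.
#' @param p_refib Probability that a successful shock is followed by
#'   refibrillation, so the patient needs a further shock.
#' @param p_continue_after_fail Probability that resuscitation continues
#'   after a failed shock (models termination of effort).
#' @param beta0,beta_amsa Intercept and AMSA slope (log-odds per mV·Hz) of
#'   the subsequent-shock outcome model.
#' @param sigma_patient SD of the patient random intercept (log-odds).
#' @param amsa_carryover AR coefficient in (0, 1] linking consecutive
#'   AMSA values of one patient.
#' @param amsa_drift_success,amsa_drift_fail Additive drift (mV·Hz) applied
#'   to the next shock's AMSA after a successful / failed shock.
#' @param amsa_noise_sd Innovation SD (mV·Hz) of the AMSA recursion.
#' @param max_shocks Hard cap on shocks per patient.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 200L,
                             sampling_rate = 250,
                             episode_duration = 2.05,
                             amsa_mean_success_first = 15.9,
                             amsa_sd_success_first = 9.0,
                             amsa_mean_fail_first = 9.3,
                             amsa_sd_fail_first = 5.8,
                             amsa_mean_success_subseq = 16.8,
                             amsa_sd_subseq_success = 8.7,
                             amsa_mean_fail_subseq = 8.3,
                             amsa_sd_fail_subseq = 5.6,
                             p_success_first = 0.53,
                             p_refib = 0.45,
                             p_continue_after_fail = 0.82,
                             beta0 = -3.9,
                             beta_amsa = 0.25,
                             beta_psi = 0.8,
                             sigma_patient = 1.0,
                             amsa_carryover = 0.75,
                             amsa_drift_success = 4.2,
                             amsa_drift_fail = 2.1,
                             amsa_noise_sd = 4.0,
                             max_shocks = 8L,
                             seed = 1018L) {
  cfg <- list(n_patients = as.integer(n_patients),
              sampling_rate = sampling_rate,
              episode_duration = episode_duration,
              amsa_mean_success_first = amsa_mean_success_first,
              amsa_sd_success_first = amsa_sd_success_first,
              amsa_mean_fail_first = amsa_mean_fail_first,
              amsa_sd_fail_first = amsa_sd_fail_first,
              amsa_mean_success_subseq = amsa_mean_success_subseq,
              amsa_sd_subseq_success = amsa_sd_subseq_success,
              amsa_mean_fail_subseq = amsa_mean_fail_subseq,
              amsa_sd_fail_subseq = amsa_sd_fail_subseq,
              p_success_first = p_success_first,
              p_refib = p_refib,
              p_continue_after_fail = p_continue_after_fail,
              beta0 = beta0, beta_amsa = beta_amsa, beta_psi = beta_psi,
              sigma_patient = sigma_patient,
              amsa_carryover = amsa_carryover,
              amsa_drift_success = amsa_drift_success,
              amsa_drift_fail = amsa_drift_fail,
              amsa_noise_sd = amsa_noise_sd,
              max_shocks = as.integer(max_shocks),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c("p_success_first", "p_refib", "p_continue_after_fail")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("`", p, "` must be in [0, 1]")
  }
  sds <- c("amsa_sd_success_first", "amsa_sd_fail_first",
           "amsa_sd_subseq_success", "amsa_sd_fail_subseq",
           "sigma_patient", "amsa_noise_sd")
  for (s in sds) if (cfg[[s]] < 0) stop("`", s, "` must be >= 0")
  if (cfg$amsa_carryover <= 0 || cfg$amsa_carryover > 1) {
    stop("`amsa_carryover` must be in (0, 1]")
  }
  if (cfg$max_shocks < 1L) stop("`max_shocks` must be >= 1")
  if (round(cfg$episode_duration * cfg$sampling_rate) < 64) {
    stop("episode_duration x sampling_rate must round to >= 64 samples")
  }
  invisible(cfg)
}

# AMSA floor (mV·Hz): a VF waveform cannot have negative spectral energy,
# and values this low are below anything seen in practice.
AMSA_FLOOR <- 0.5

rtruncnorm_low <- function(n, mean, sd, low = AMSA_FLOOR) {
  pmax(stats::rnorm(n, mean, sd), low)
}

#' Synthesize a VF-like episode with a prescribed AMSA
#'
#' Builds a band-limited VF surrogate as a sum of sinusoids at frequencies
#' aligned to the DFT bins of the analysis window, with random phases and a
#' VF-like spectral envelope peaking near 5 Hz. Component amplitudes are
#' pre-compensated for the analysis band-pass response and scaled so that
#' [amsa_from_episode()] of the returned episode equals `target_amsa`
#' (within ~2%, limited only by filter edge transients). Because every
#' component sits exactly on a DFT bin, the rectangular-window spectrum has
#' no leakage and the construction is exact up to filtering.
#'
#' @param target_amsa Desired AMSA in mV·Hz (> 0).
#' @param sampling_rate Sampling rate, Hz (default 250).
#' @param duration Episode duration, seconds (default 2.05).
#' @param seed Integer seed; the waveform is a pure function of the
#'   arguments.
#' @param n_components Number of sinusoids (>= 8, default 12).
#' @param patient_id,shock_index Identity attached to the episode.
#' @return An [ecg_episode()].
#' @export
generate_vf_waveform <- function(target_amsa, sampling_rate = 250,
                                 duration = 2.05, seed = 1L,
                                 n_components = 12L,
                                 patient_id = NA_character_,
                                 shock_index = 1L) {
  if (!is.numeric(target_amsa) || length(target_amsa) != 1L ||
      !is.finite(target_amsa) || target_amsa <= 0) {
    stop("`target_amsa` must be a single positive number")
  }
  n <- as.integer(round(duration * sampling_rate))
  if (n < 64L) stop("episode too short: need at least 64 samples")
  if (n_components < 8L) stop("`n_components` must be >= 8")
  df <- sampling_rate / n
  # usable bins: comfortably inside the 2-48 Hz band so the compensated
  # band-pass response stays close to unity
  k_lo <- ceiling(3.2 / df)
  k_hi <- floor(36 / df)
  if (k_hi - k_lo + 1L < n_components) {
    stop("episode too short for the analysis band: only ",
         max(0L, k_hi - k_lo + 1L), " usable DFT bins")
  }
  withr::with_seed(as.integer(seed), {
    k <- sort(sample(k_lo:k_hi, n_components))
    freq <- k * df
    # VF-like envelope: rises to ~5 Hz, decays above
    envelope <- freq / (1 + (freq / 5)^2.5)
    raw_amp <- envelope * exp(stats::rnorm(n_components, 0, 0.35))
    phase <- stats::runif(n_components, 0, 2 * pi)
    gain <- bandpass_gain(freq, 2, 48, sampling_rate)
    amp <- raw_amp / gain          # pre-compensate the zero-phase band-pass
    scale <- target_amsa / sum(amp * gain * freq)
    amp <- amp * scale
    t <- (seq_len(n) - 1L) / sampling_rate
    x <- drop(cos(outer(t, 2 * pi * freq) +
                    matrix(phase, n, n_components, byrow = TRUE)) %*% amp)
    ecg_episode(x, sampling_rate, patient_id = patient_id,
                shock_index = shock_index)
  })
}

#' Generate a synthetic shock cohort
#'
#' Simulates the shock sequences of `config$n_patients` OHCA patients under
#' the latent model described in [generator_config()], optionally with a
#' synthetic pre-shock waveform per shock. The per-shock table stores the
#' latent AMSA driving the outcome model; when waveforms are generated, the
#' downstream pipeline re-measures AMSA from the episodes.
#'
#' @param config A [generator_config()].
#' @param generate_episodes If `TRUE` (default), synthesize one waveform per
#'   shock via [generate_vf_waveform()].
#' @return An object of class `shock_cohort`: a list with `shocks` (one row
#'   per shock: `patient_id`, `shock_index`, `amsa`, `outcome`, `psi`,
#'   `delta_amsa`, `is_first`), `episodes` (list of [ecg_episode()] in row
#'   order, or `NULL`), and `config`.
#' @export
generate_cohort <- function(config = generator_config(),
                            generate_episodes = TRUE) {
  validate_generator_config(config)
  if (config$n_patients < 2L) stop("`n_patients` must be >= 2")
  cfg <- config
  rows <- withr::with_seed(cfg$seed, {
    out <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      b <- stats::rnorm(1, 0, cfg$sigma_patient)
      amsa <- numeric(0)
      outcome <- integer(0)
      k <- 0L
      repeat {
        k <- k + 1L
        if (k == 1L) {
          y <- stats::rbinom(1, 1, cfg$p_success_first)
          a <- if (y == 1) {
            rtruncnorm_low(1, cfg$amsa_mean_success_first,
                           cfg$amsa_sd_success_first)
          } else {
            rtruncnorm_low(1, cfg$amsa_mean_fail_first, cfg$amsa_sd_fail_first)
          }
        } else {
          drift <- if (outcome[k - 1L] == 1) cfg$amsa_drift_success
                   else cfg$amsa_drift_fail
          a <- max(cfg$amsa_carryover * amsa[k - 1L] + drift +
                     stats::rnorm(1, 0, cfg$amsa_noise_sd), AMSA_FLOOR)
          psi_k <- if (outcome[k - 1L] == 1) 1 else -1
          y <- stats::rbinom(1, 1, stats::plogis(
            cfg$beta0 + cfg$beta_amsa * a + cfg$beta_psi * psi_k + b))
        }
        amsa[k] <- a
        outcome[k] <- y
        if (k >= cfg$max_shocks) break
        goes_on <- if (y == 1) stats::runif(1) < cfg$p_refib
                   else stats::runif(1) < cfg$p_continue_after_fail
        if (!goes_on) break
      }
      out[[i]] <- data.frame(
        patient_id = sprintf("P%04d", i),
        shock_index = seq_len(k),
        amsa = amsa, outcome = outcome)
    }
    do.call(rbind, out)
  })
  rows <- add_shock_features(rows)
  rownames(rows) <- NULL
  episodes <- NULL
  if (generate_episodes) {
    ep_seeds <- withr::with_seed(cfg$seed + 1L, {
      sample.int(.Machine$integer.max - 1L, nrow(rows))
    })
    episodes <- lapply(seq_len(nrow(rows)), function(j) {
      generate_vf_waveform(rows$amsa[j], cfg$sampling_rate,
                           cfg$episode_duration, seed = ep_seeds[j],
                           patient_id = rows$patient_id[j],
                           shock_index = rows$shock_index[j])
    })
  }
  structure(list(shocks = rows, episodes = episodes, config = cfg),
            class = "shock_cohort")
}

#' @export
print.shock_cohort <- function(x, ...) {
  cat(sprintf("<shock_cohort> %d shocks from %d patients (%s episodes)\n",
              nrow(x$shocks), length(unique(x$shocks$patient_id)),
              if (is.null(x$episodes)) "no" else "with"))
  invisible(x)
}

#' Calibration summary of a cohort
#'
#' Computes the summary quantities the generator is calibrated against:
#' success rates by stratum, the fraction of patients needing more than one
#' shock, outcome-conditional AMSA mean/SD per stratum, and Kendall tau-b
#' correlations among AMSA, PSI and delta-AMSA on subsequent shocks.
#'
#' @param cohort A `shock_cohort` or a per-shock data.frame.
#' @return A list of class `calibration_report`.
#' @export
calibration_report <- function(cohort) {
  shocks <- if (inherits(cohort, "shock_cohort")) cohort$shocks else cohort
  if (nrow(shocks) == 0L) stop("empty cohort")
  if (!all(c("psi", "delta_amsa") %in% names(shocks))) {
    shocks <- add_shock_features(shocks)
  }
  first <- shocks[shocks$shock_index == 1L, ]
  subseq <- shocks[shocks$shock_index > 1L, ]
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  grp <- function(df) list(success = msd(df$amsa[df$outcome == 1]),
                           fail = msd(df$amsa[df$outcome == 0]))
  n_per_patient <- table(shocks$patient_id)
  taus <- if (nrow(subseq) >= 3L) {
    list(amsa_psi = kendall_tau(subseq$amsa, subseq$psi),
         amsa_delta = kendall_tau(subseq$amsa, subseq$delta_amsa),
         delta_psi = kendall_tau(subseq$delta_amsa, subseq$psi))
  } else NULL
  structure(list(
    n_patients = length(n_per_patient),
    n_shocks = nrow(shocks),
    shocks_per_patient = mean(n_per_patient),
    frac_multi_shock = mean(n_per_patient > 1L),
    overall_success_rate = mean(shocks$outcome),
    first_success_rate = mean(first$outcome),
    subsequent_success_rate = if (nrow(subseq)) mean(subseq$outcome) else NA_real_,
    amsa_first = grp(first),
    amsa_subsequent = if (nrow(subseq)) grp(subseq) else NULL,
    kendall = taus), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Cohort calibration summary\n")
  cat(sprintf("  patients: %d, shocks: %d (%.2f per patient), multi-shock: %.1f%%\n",
              x$n_patients, x$n_shocks, x$shocks_per_patient,
              100 * x$frac_multi_shock))
  cat(sprintf("  success rate: overall %.1f%%, first %.1f%%, subsequent %.1f%%\n",
              100 * x$overall_success_rate, 100 * x$first_success_rate,
              100 * x$subsequent_success_rate))
  f <- x$amsa_first
  cat(sprintf("  first-shock AMSA (mV.Hz): success %.1f+/-%.1f, fail %.1f+/-%.1f\n",
              f$success["mean"], f$success["sd"], f$fail["mean"], f$fail["sd"]))
  if (!is.null(x$amsa_subsequent)) {
    s <- x$amsa_subsequent
    cat(sprintf("  subsequent AMSA (mV.Hz): success %.1f+/-%.1f, fail %.1f+/-%.1f\n",
                s$success["mean"], s$success["sd"], s$fail["mean"], s$fail["sd"]))
  }
  if (!is.null(x$kendall)) {
    cat(sprintf("  Kendall tau-b (subsequent): AMSA~PSI %.3f, AMSA~dAMSA %.3f, dAMSA~PSI %.3f\n",
                x$kendall$amsa_psi$estimate, x$kendall$amsa_delta$estimate,
                x$kendall$delta_psi$estimate))
  }
  invisible(x)
}
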