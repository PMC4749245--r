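#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the cohort generator
#' settings, the patient-level train/validation split, the analysis band,
#' the fixed-specificity operating point and the modelling method. A single
#' top-level `seed` fans out deterministically: the generator uses `seed`,
#' the split uses `seed + 1`, and the network for feature set j in stratum
#' s uses `seed + 100 * s + j`, so each component is reproducible in
#' isolation.
#'
#' @param generator A [generator_config()]; its `seed` is overridden by
#'   `seed` here.
#' @param seed Top-level integer seed (< 2^31 - 1000).
#' @param split_fraction_training Fraction of patients assigned to the
#'   training set (default 0.5).
#' @param target_specificity Training specificity defining the operating
#'   threshold (default 0.90).
#' @param method `"network"` or `"logistic"`.
#' @param strata Strata to analyse, subset of `c("first", "subsequent")`.
#' @param band AMSA band in Hz (default `c(2, 48)`).
#' @param use_episodes If `TRUE` (default), synthesize waveforms and
#'   re-measure AMSA from them through the waveform pipeline; if `FALSE`,
#'   use the generator's latent AMSA directly (faster, identical structure).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(), seed = 1L,
                              split_fraction_training = 0.5,
                              target_specificity = 0.90,
                              method = c("network", "logistic"),
                              strata = c("first", "subsequent"),
                              band = c(2, 48), use_episodes = TRUE) {
  method <- match.arg(method)
  if (split_fraction_training <= 0 || split_fraction_training >= 1) {
    stop("`split_fraction_training` must be in (0, 1)")
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 1000L) {
    stop("`seed` must be a non-negative integer below 2^31 - 1000")
  }
  stopifnot(all(strata %in% c("first", "subsequent")))
  structure(list(generator = generator, seed = seed,
                 split_fraction_training = split_fraction_training,
                 target_specificity = target_specificity, method = method,
                 strata = strata, band = band, use_episodes = use_episodes),
            class = "experiment_config")
}

#' Split a cohort into training and validation sets by patient
#'
#' Randomly partitions patients (never individual shocks) so that all of a
#' patient's shocks land on the same side; splitting by shock would leak
#' within-patient correlation into the validation set.
#'
#' @param cohort A `shock_cohort`.
#' @param fraction Fraction of patients in the training set.
#' @param seed Integer seed.
#' @return List with `training` and `validation`, both `shock_cohort`s.
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "shock_cohort"))
  ids <- unique(cohort$shocks$patient_id)
  if (length(ids) < 2L) stop("need >= 2 patients to split")
  n_train <- round(fraction * length(ids))
  if (n_train < 1L || n_train >= length(ids)) {
    stop("`fraction` leaves an empty side of the split")
  }
  train_ids <- withr::with_seed(as.integer(seed), sample(ids, n_train))
  subset_cohort <- function(keep) {
    idx <- cohort$shocks$patient_id %in% keep
    structure(list(shocks = cohort$shocks[idx, , drop = FALSE],
                   episodes = if (is.null(cohort$episodes)) NULL
                              else cohort$episodes[idx],
                   config = cohort$config),
              class = "shock_cohort")
  }
  list(training = subset_cohort(train_ids),
       validation = subset_cohort(setdiff(ids, train_ids)))
}

measure_cohort_amsa <- function(cohort, band = c(2, 48)) {
  if (is.null(cohort$episodes)) return(cohort)
  cohort$shocks$amsa <- vapply(cohort$episodes, amsa_from_episode,
                               numeric(1), band_low = band[1],
                               band_high = band[2])
  cohort$shocks$psi <- NULL
  cohort$shocks$delta_amsa <- NULL
  cohort$shocks <- add_shock_features(cohort$shocks)
  cohort
}

evaluate_stratum <- function(train_tab, valid_tab, method, seed,
                             target_specificity, random_intercept) {
  models <- fit_all_combinations(train_tab, method = method, seed = seed,
                                 random_intercept = random_intercept)
  sets <- names(models)
  scores_tr <- lapply(models, function(m) predict(m, train_tab))
  scores_va <- lapply(models, function(m) predict(m, valid_tab))
  thresholds <- vapply(sets, function(fs) {
    threshold_at_specificity(roc_curve(scores_tr[[fs]], train_tab$outcome),
                             target_specificity)
  }, numeric(1))
  reports <- lapply(sets, function(fs) {
    classification_metrics(scores_va[[fs]], valid_tab$outcome,
                           thresholds[[fs]], feature_set = fs)
  })
  names(reports) <- sets
  safe_prop <- function(x_a, n_a, x_b, n_b) {
    if (n_a <= 0 || n_b <= 0) {
      return(test_result("chi-square (2x2)", NA_real_, NA_real_, df = 1,
                         flag = "undefined: empty group"))
    }
    compare_proportions(x_a, n_a, x_b, n_b)
  }
  tests <- lapply(setdiff(sets, "AMSA"), function(fs) {
    r <- reports[[fs]]
    r0 <- reports$AMSA
    list(feature_set = fs,
         auc = compare_auc(scores_va[[fs]], scores_va$AMSA,
                           valid_tab$outcome, paired = TRUE),
         sensitivity = safe_prop(r$tp, r$tp + r$fn, r0$tp, r0$tp + r0$fn),
         npv = safe_prop(r$tn, r$tn + r$fn, r0$tn, r0$tn + r0$fn),
         ppv = safe_prop(r$tp, r$tp + r$fp, r0$tp, r0$tp + r0$fp),
         pa = safe_prop(r$tp + r$tn, r$tp + r$fp + r$tn + r$fn,
                        r0$tp + r0$tn,
                        r0$tp + r0$fp + r0$tn + r0$fn))
  })
  names(tests) <- setdiff(sets, "AMSA")
  list(models = models, thresholds = thresholds, reports = reports,
       comparisons = tests,
       n_train = nrow(train_tab), n_valid = nrow(valid_tab),
       valid_success = sum(valid_tab$outcome))
}

#' Run the full simulation-to-report experiment
#'
#' Executes the complete protocol: generate (or reuse) a cohort, measure
#' AMSA from the pre-shock episodes, derive PSI and delta-AMSA, split
#' patients into training and validation halves, train all four feature
#' combinations per stratum, pick the threshold at the target training
#' specificity, and evaluate on the validation shocks with paired AUC and
#' proportion comparisons against AMSA alone.
#'
#' @param config An [experiment_config()].
#' @param cohort Optionally a pre-built `shock_cohort`; by default one is
#'   generated from `config$generator` with the derived seed.
#' @return Object of class `experiment_result`: per-stratum reports,
#'   comparisons, thresholds and models, plus a dataset summary, the config
#'   and the derived seeds.
#' @export
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  gen_cfg <- config$generator
  gen_cfg$seed <- config$seed
  if (is.null(cohort)) {
    cohort <- generate_cohort(gen_cfg, generate_episodes = config$use_episodes)
  }
  cohort <- measure_cohort_amsa(cohort, band = config$band)
  halves <- split_cohort(cohort, config$split_fraction_training,
                         seed = config$seed + 1L)
  strata <- config$strata
  out <- vector("list", length(strata))
  names(out) <- strata
  for (si in seq_along(strata)) {
    st <- strata[si]
    train_tab <- build_feature_table(halves$training, "C3", stratum = st)
    valid_tab <- build_feature_table(halves$validation, "C3", stratum = st)
    # patient random effects are only identifiable with repeated shocks,
    # so the random-intercept logistic is used on the subsequent stratum
    out[[si]] <- evaluate_stratum(
      train_tab, valid_tab, config$method,
      seed = config$seed + 100L * si,
      target_specificity = config$target_specificity,
      random_intercept = config$method == "logistic" && st == "subsequent")
  }
  summarize <- function(co) {
    list(n_patients = length(unique(co$shocks$patient_id)),
         n_shocks = nrow(co$shocks),
         success_rate = mean(co$shocks$outcome))
  }
  structure(list(strata = out,
                 summary = list(training = summarize(halves$training),
                                validation = summarize(halves$validation)),
                 config = config,
                 seeds = list(generator = config$seed,
                              split = config$seed + 1L,
                              network_base = config$seed + 100L),
                 version = as.character(utils::packageVersion("amsaShock"))),
            class = "experiment_result")
}

#' Tabulate an experiment result
#'
#' One row per feature set with AUC, the five threshold metrics and the
#' p-values of the comparisons against AMSA alone.
#'
#' @param result An `experiment_result`.
#' @param stratum Which stratum to tabulate (default `"subsequent"`).
#' @return data.frame shaped like the package's performance tables.
#' @export
result_table <- function(result, stratum = "subsequent") {
  st <- result$strata[[stratum]]
  if (is.null(st)) stop("stratum '", stratum, "' not in result")
  rows <- lapply(names(st$reports), function(fs) {
    r <- st$reports[[fs]]
    cmp <- st$comparisons[[fs]]
    data.frame(feature_set = fs, auc = r$auc, sensitivity = r$sensitivity,
               specificity = r$specificity, npv = r$npv, ppv = r$ppv,
               pa = r$pa, threshold = r$threshold,
               tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
               p_auc_vs_amsa = if (is.null(cmp)) NA_real_ else cmp$auc$p_value,
               p_sens_vs_amsa = if (is.null(cmp)) NA_real_
                                else cmp$sensitivity$p_value,
               p_npv_vs_amsa = if (is.null(cmp)) NA_real_ else cmp$npv$p_value,
               p_pa_vs_amsa = if (is.null(cmp)) NA_real_ else cmp$pa$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> method %s | training %d shocks / %d patients, validation %d / %d\n",
              x$config$method,
              x$summary$training$n_shocks, x$summary$training$n_patients,
              x$summary$validation$n_shocks, x$summary$validation$n_patients))
  for (st in names(x$strata)) {
    cat(sprintf("-- %s shocks (validation n = %d, %d successes)\n", st,
                x$strata[[st]]$n_valid, x$strata[[st]]$valid_success))
    tab <- result_table(x, st)
    print(tab[, c("feature_set", "auc", "sensitivity", "specificity",
                  "npv", "ppv", "pa")], digits = 3)
  }
  invisible(x)
}
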