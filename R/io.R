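# File formats:
#  - cohort directory: manifest.csv (patient_id, shock_index, outcome,
#    amsa_mvhz, episode_file), one episode CSV per shock (comment line
#    "# fs_hz=<rate>" then one mV sample per line), config.json echoing the
#    generator configuration
#  - feature table CSV: patient_id, shock_index, amsa_mvhz, psi,
#    delta_amsa, outcome (UTF-8, dot decimal)
#  - experiment result: result.json plus one <stratum>_table.csv per
#    stratum

#' Write a cohort to a directory
#'
#' @param cohort A `shock_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_episodes Write one episode CSV per shock when episodes are
#'   present (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_episodes = TRUE) {
  stopifnot(inherits(cohort, "shock_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shocks <- cohort$shocks
  ep_files <- rep(NA_character_, nrow(shocks))
  if (write_episodes && !is.null(cohort$episodes)) {
    ep_files <- sprintf("episode_%s_%02d.csv", shocks$patient_id,
                        shocks$shock_index)
    for (j in seq_along(cohort$episodes)) {
      ep <- cohort$episodes[[j]]
      con <- file.path(dir, ep_files[j])
      writeLines(c(sprintf("# fs_hz=%g", ep$sampling_rate),
                   format(ep$samples, digits = 12, trim = TRUE,
                          scientific = FALSE)), con)
    }
  }
  manifest <- data.frame(patient_id = shocks$patient_id,
                         shock_index = shocks$shock_index,
                         outcome = shocks$outcome,
                         amsa_mvhz = shocks$amsa,
                         episode_file = ep_files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_episode_csv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# fs_hz=", lines[1])) {
    stop("episode file ", path, " lacks the '# fs_hz=' header line")
  }
  fs <- as.numeric(sub("^# fs_hz=", "", lines[1]))
  as_ecg <- function(x) ecg_episode(as.numeric(x), fs)
  as_ecg(lines[-1])
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates the manifest schema (duplicate patient/shock pairs and
#' non-consecutive shock indices are reported with their row numbers) and
#' reloads episodes when episode files are referenced.
#'
#' @param dir Cohort directory.
#' @return A `shock_cohort`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("patient_id", "shock_index", "outcome")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  }
  key <- paste(manifest$patient_id, manifest$shock_index)
  if (anyDuplicated(key)) {
    stop("manifest schema error: duplicate (patient_id, shock_index) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  bad <- !manifest$outcome %in% c(0L, 1L)
  if (any(bad)) {
    stop("manifest schema error: non-binary outcome at row(s) ",
         paste(which(bad), collapse = ", "))
  }
  shocks <- data.frame(patient_id = as.character(manifest$patient_id),
                       shock_index = as.integer(manifest$shock_index),
                       amsa = if ("amsa_mvhz" %in% names(manifest))
                                manifest$amsa_mvhz else NA_real_,
                       outcome = as.integer(manifest$outcome))
  episodes <- NULL
  if ("episode_file" %in% names(manifest) &&
      any(!is.na(manifest$episode_file))) {
    episodes <- lapply(seq_len(nrow(manifest)), function(j) {
      f <- manifest$episode_file[j]
      if (is.na(f)) return(NULL)
      ep <- read_episode_csv(file.path(dir, f))
      ep$patient_id <- shocks$patient_id[j]
      ep$shock_index <- shocks$shock_index[j]
      ep
    })
  }
  if (all(is.na(shocks$amsa))) {
    if (is.null(episodes)) {
      stop("manifest has neither amsa_mvhz nor episode files")
    }
    shocks$amsa <- vapply(episodes, amsa_from_episode, numeric(1))
  }
  shocks <- add_shock_features(shocks)
  config <- NULL
  cpath <- file.path(dir, "config.json")
  if (file.exists(cpath)) {
    config <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  }
  structure(list(shocks = shocks, episodes = episodes, config = config),
            class = "shock_cohort")
}

#' Write / read a feature table CSV
#'
#' Columns `patient_id`, `shock_index`, `amsa_mvhz`, `psi`, `delta_amsa`,
#' `outcome`; UTF-8, dot decimal.
#'
#' @param shocks Per-shock data.frame (features added if absent).
#' @param path CSV path.
#' @return `path` invisibly (write); the data.frame with internal column
#'   names (read).
#' @export
write_feature_csv <- function(shocks, path) {
  if (inherits(shocks, "shock_cohort")) shocks <- shocks$shocks
  if (!all(c("psi", "delta_amsa") %in% names(shocks))) {
    shocks <- add_shock_features(shocks)
  }
  out <- data.frame(patient_id = shocks$patient_id,
                    shock_index = shocks$shock_index,
                    amsa_mvhz = shocks$amsa, psi = shocks$psi,
                    delta_amsa = shocks$delta_amsa,
                    outcome = shocks$outcome)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "shock_index", "amsa_mvhz", "psi", "delta_amsa",
            "outcome")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("feature CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  data.frame(patient_id = as.character(d$patient_id),
             shock_index = as.integer(d$shock_index),
             amsa = d$amsa_mvhz, psi = as.numeric(d$psi),
             delta_amsa = as.numeric(d$delta_amsa),
             outcome = as.integer(d$outcome),
             is_first = as.integer(d$shock_index) == 1L)
}

result_to_list <- function(result) {
  list(summary = result$summary,
       seeds = result$seeds,
       version = result$version,
       method = result$config$method,
       target_specificity = result$config$target_specificity,
       tables = lapply(stats::setNames(names(result$strata),
                                       names(result$strata)),
                       function(st) result_table(result, st)))
}

#' Write / read an experiment result
#'
#' Writes `result.json` (summary, seeds, per-stratum tables) and one
#' `<stratum>_table.csv` per stratum. `read_result()` reloads the JSON into
#' the same list-of-tables structure.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory.
#' @return The directory (write) / the reloaded list (read).
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lst <- result_to_list(result)
  jsonlite::write_json(lst, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (st in names(lst$tables)) {
    utils::write.csv(lst$tables[[st]],
                     file.path(dir, paste0(st, "_table.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_result
#' @export
read_result <- function(dir) {
  path <- file.path(dir, "result.json")
  if (!file.exists(path)) stop("no result.json in ", dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
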