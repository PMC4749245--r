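#' Previous shock index (PSI)
#'
#' PSI encodes the outcome of the immediately preceding shock of the same
#' patient: 0 for a patient's first shock, +1 if the previous shock was
#' successful, -1 if it failed. It carries the within-patient information
#' that repeated shocks in one patient are dependent events.
#'
#' @param shock_index Integer vector of shock positions for one patient;
#'   must be consecutive 1..n after sorting.
#' @param outcome Binary vector (1 = success, 0 = failure), same order as
#'   `shock_index`.
#' @return Numeric vector of PSI values aligned with the sorted sequence.
#' @export
compute_psi <- function(shock_index, outcome) {
  seq_check(shock_index, outcome)
  ord <- order(shock_index)
  outcome <- outcome[ord]
  n <- length(outcome)
  psi <- numeric(n)
  if (n > 1L) psi[-1L] <- ifelse(outcome[-n] == 1, 1, -1)
  psi[order(ord)]
}

#' Change in AMSA between consecutive shocks
#'
#' For a patient's shock k > 1, the difference `AMSA_k - AMSA_{k-1}`
#' (mV·Hz); 0 for the first shock. Rising AMSA over the course of
#' resuscitation reflects improving myocardial state.
#'
#' @param shock_index Integer vector of shock positions for one patient;
#'   must be consecutive 1..n after sorting.
#' @param amsa AMSA values (mV·Hz), same order as `shock_index`.
#' @return Numeric vector of delta-AMSA values aligned with the input order.
#' @export
compute_delta_amsa <- function(shock_index, amsa) {
  seq_check(shock_index, amsa)
  ord <- order(shock_index)
  amsa <- amsa[ord]
  delta <- c(0, diff(amsa))
  delta[order(ord)]
}

seq_check <- function(shock_index, values) {
  if (length(shock_index) != length(values)) {
    stop("`shock_index` and the value vector must have the same length")
  }
  if (length(shock_index) == 0L) stop("empty shock sequence")
  s <- sort(as.integer(shock_index))
  if (!identical(s, seq_len(length(s)))) {
    stop("malformed sequence: shock indices must be consecutive 1..n ",
         "(got ", paste(s, collapse = ","), ")")
  }
  invisible(TRUE)
}

#' Attach PSI and delta-AMSA to a per-shock table
#'
#' Takes a table with one row per shock (columns `patient_id`,
#' `shock_index`, `amsa`, `outcome`) and adds the previous-shock features
#' `psi` and `delta_amsa` plus the `is_first` indicator, computed per
#' patient. Row order of the input is preserved.
#'
#' @param shocks A data.frame with columns `patient_id`, `shock_index`,
#'   `amsa`, `outcome`.
#' @return The same data.frame with `psi`, `delta_amsa`, `is_first` added.
#' @export
add_shock_features <- function(shocks) {
  need <- c("patient_id", "shock_index", "amsa", "outcome")
  miss <- setdiff(need, names(shocks))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  shocks$psi <- stats::ave(
    seq_len(nrow(shocks)), shocks$patient_id,
    FUN = function(i) compute_psi(shocks$shock_index[i], shocks$outcome[i]))
  shocks$delta_amsa <- stats::ave(
    seq_len(nrow(shocks)), shocks$patient_id,
    FUN = function(i) compute_delta_amsa(shocks$shock_index[i], shocks$amsa[i]))
  shocks$is_first <- shocks$shock_index == 1L
  shocks
}

#' Feature combinations
#'
#' The four feature sets compared throughout: AMSA alone, AMSA with the
#' previous shock index (C1), AMSA with the change in AMSA (C2), and all
#' three together (C3).
#'
#' @param name One of `"AMSA"`, `"C1"`, `"C2"`, `"C3"`.
#' @return Character vector of feature column names, in the fixed order
#'   (amsa, psi, delta_amsa).
#' @export
feature_set_columns <- function(name) {
  sets <- list(AMSA = "amsa",
               C1 = c("amsa", "psi"),
               C2 = c("amsa", "delta_amsa"),
               C3 = c("amsa", "psi", "delta_amsa"))
  if (!name %in% names(sets)) {
    stop("unknown feature set '", name, "'; expected AMSA, C1, C2 or C3")
  }
  sets[[name]]
}

#' Build a modelling table for one feature set and stratum
#'
#' Restricts a per-shock table to a stratum (first shocks, subsequent
#' shocks, or all) and selects the columns of one feature combination, in
#' the fixed order (amsa, psi, delta_amsa).
#'
#' @param shocks A per-shock data.frame; [add_shock_features()] is applied
#'   if `psi`/`delta_amsa` are absent. A `shock_cohort` is also accepted.
#' @param feature_set `"AMSA"`, `"C1"`, `"C2"` or `"C3"`.
#' @param stratum `"all"`, `"first"` (shock_index == 1) or `"subsequent"`
#'   (shock_index > 1).
#' @return data.frame with columns `patient_id`, `shock_index`, the selected
#'   features, and `outcome`. An empty stratum yields a zero-row table with
#'   a warning.
#' @export
build_feature_table <- function(shocks, feature_set = "C3",
                                stratum = c("all", "first", "subsequent")) {
  stratum <- match.arg(stratum)
  if (inherits(shocks, "shock_cohort")) shocks <- shocks$shocks
  if (!all(c("psi", "delta_amsa") %in% names(shocks))) {
    shocks <- add_shock_features(shocks)
  }
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(shocks)),
                 first = shocks$shock_index == 1L,
                 subsequent = shocks$shock_index > 1L)
  out <- shocks[keep, c("patient_id", "shock_index",
                        feature_set_columns(feature_set), "outcome"),
                drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("stratum '", stratum, "' is empty")
  out
}
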