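#' Quality-control thresholds
#'
#' The study's cell-inclusion gates: cells are excluded when the baseline
#' resting membrane potential is more depolarized than -50 mV, when the
#' uncompensated series resistance exceeds 35 MOhm, or when the physiology
#' index reaches 5. All comparisons are strict, so boundary values pass.
#'
#' @param rmp_max Most depolarized acceptable resting potential (mV).
#' @param rs_max Largest acceptable series resistance (MOhm).
#' @param physiology_index_max Gate on the composite physiology index.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(rmp_max = -50, rs_max = 35,
                          physiology_index_max = 5) {
  stopifnot(rmp_max < 0, rs_max > 0)
  structure(list(rmp_max = rmp_max, rs_max = rs_max,
                 physiology_index_max = physiology_index_max),
            class = "qc_thresholds")
}

#' Assess the measurement-quality gates for one cell
#'
#' Applies the resting-potential and series-resistance gates with strict
#' boundary semantics: a cell fails the RMP check iff `rmp > rmp_max` and
#' the Rs check iff `r_s > rs_max`; values exactly at a threshold pass.
#'
#' @param cell_id Cell identifier.
#' @param rmp Baseline resting membrane potential (mV).
#' @param r_s Uncompensated series resistance (MOhm).
#' @param thresholds A [qc_thresholds()].
#' @return List of class `qc_result`: `cell_id`, `rmp`, `r_s`, `passed`,
#'   `failed_checks` (character vector of `"rmp"` / `"rs"` tags).
#' @export
assess_cell_qc <- function(cell_id, rmp, r_s,
                           thresholds = qc_thresholds()) {
  stopifnot(is.finite(rmp), is.finite(r_s))
  failed <- character(0)
  if (rmp > thresholds$rmp_max) failed <- c(failed, "rmp")
  if (r_s > thresholds$rs_max) failed <- c(failed, "rs")
  structure(list(cell_id = cell_id, rmp = rmp, r_s = r_s,
                 passed = length(failed) == 0L, failed_checks = failed),
            class = "qc_result")
}

#' Firing-pattern and physiology-index classification
#'
#' Inclusion requires co-expression of a regular-spiking firing pattern and
#' a physiology index below the gate. "Regular spiking" is operationalized
#' (the source criterion is qualitative) as the absence of an initial
#' doublet — the first interspike interval on the reference sweep (the
#' lowest current at least `ref_above_rheobase` pA above rheobase with at
#' least three spikes) must be at least `isi_ratio_min` times the median
#' interspike interval — and the absence of sub-floor spike peaks at
#' currents up to `block_current_factor` times rheobase. Both knobs are
#' configurable.
#'
#' @param fi An [compute_fi_curve()] result (supplies per-sweep spike
#'   times and currents).
#' @param subfloor_by_current Integer vector, per-sweep count of sub-floor
#'   spike candidates (from the detector), aligned with `fi$currents`;
#'   `NULL` skips the block check.
#' @param phys_index Physiology-index score of the cell.
#' @param rheobase Rheobase (pA) for the reference-sweep rule.
#' @param thresholds A [qc_thresholds()].
#' @param isi_ratio_min,ref_above_rheobase,block_current_factor
#'   Configuration of the regular-spiking surrogate.
#' @return List: `regular_spiking`, `included`, `first_isi_ratio`.
#' @export
classify_cell <- function(fi, subfloor_by_current = NULL, phys_index,
                          rheobase, thresholds = qc_thresholds(),
                          isi_ratio_min = 0.5, ref_above_rheobase = 50,
                          block_current_factor = 2) {
  regular <- TRUE
  first_isi_ratio <- NA_real_
  if (!is.na(rheobase)) {
    ref <- which(fi$currents >= rheobase + ref_above_rheobase &
                   vapply(fi$spike_times, length, integer(1)) >= 3L)
    if (length(ref)) {
      isi <- diff(fi$spike_times[[ref[1]]])
      first_isi_ratio <- isi[1] / median(isi)
      if (first_isi_ratio < isi_ratio_min) regular <- FALSE
    }
    if (!is.null(subfloor_by_current)) {
      low <- fi$currents <= block_current_factor * rheobase
      if (any(subfloor_by_current[low] > 0)) regular <- FALSE
    }
  }
  list(regular_spiking = regular,
       included = regular && phys_index < thresholds$physiology_index_max,
       first_isi_ratio = first_isi_ratio)
}

#' Run all QC gates over a feature table
#'
#' @param features data.frame with columns `cell_id`, `rmp_mV`, `r_s_MOhm`,
#'   `physiology_index`, `regular_spiking`.
#' @param thresholds A [qc_thresholds()].
#' @return data.frame, one row per cell: the inputs plus `passed` and
#'   `failed_checks` (comma-separated tags; the audit log of exclusions).
#' @export
qc_table <- function(features, thresholds = qc_thresholds()) {
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    r <- assess_cell_qc(f$cell_id, f$rmp_mV, f$r_s_MOhm, thresholds)
    failed <- r$failed_checks
    if (!is.na(f$physiology_index) &&
        f$physiology_index >= thresholds$physiology_index_max) {
      failed <- c(failed, "physiology_index")
    }
    if (!is.null(f$regular_spiking) && !isTRUE(f$regular_spiking)) {
      failed <- c(failed, "firing_pattern")
    }
    data.frame(cell_id = f$cell_id, rmp = f$rmp_mV, r_s = f$r_s_MOhm,
               physiology_index = f$physiology_index,
               regular_spiking = isTRUE(f$regular_spiking),
               passed = length(failed) == 0L,
               failed_checks = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
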