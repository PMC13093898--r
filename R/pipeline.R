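#' Extract all current-clamp features for one cell
#'
#' Runs the full intrinsic-property chain on a cell's three current-clamp
#' recordings: f-I curve (gain, maximum rate, total spike output,
#' block flag), first-spike waveform features from the lowest suprathreshold
#' f-I sweep, rheobase and latency, passive properties, and the physiology
#' index.
#'
#' @param recs Named list of recordings for the cell (`fi_steps`,
#'   `rheobase_steps`, `hyperpolarizing_steps`).
#' @param dvdt_threshold,peak_floor Spike detector settings.
#' @param index_config Physiology-index configuration
#'   (see [physiology_index()]).
#' @return One-row data.frame of features (columns `rmp_mV`, `r_in_MOhm`,
#'   `tc_ms`, `c_in_pF`, `sag_ratio`, `threshold_mV`, `peak_mV`,
#'   `amplitude_mV`, `half_width_ms`, `max_rise_slope`, `max_decay_slope`,
#'   `gain_Hz_pA`, `max_frequency_Hz`, `current_at_max_pA`,
#'   `total_spike_output`, `block_detected`, `rheobase_pA`, `latency_ms`,
#'   `physiology_index`, `regular_spiking`).
#' @export
extract_cc_features <- function(recs, dvdt_threshold = 10, peak_floor = -10,
                                index_config = default_physiology_index_config()) {
  fi_rec <- recs$fi_steps
  fi <- compute_fi_curve(fi_rec, dvdt_threshold, peak_floor)
  rheo <- rheobase_and_latency(recs$rheobase_steps, dvdt_threshold, peak_floor)
  pas <- passive_properties(recs$hyperpolarizing_steps)

  # first-spike features from the lowest f-I sweep that fired
  amps <- vapply(fi_rec$sweeps, function(s) s$command$amplitude, numeric(1))
  ord <- order(amps)
  spk_feats <- structure(list(no_spike = TRUE), class = "spike_features")
  subfloor <- integer(length(ord))
  for (j in seq_along(ord)) {
    sw <- fi_rec$sweeps[[ord[j]]]
    spk <- detect_spikes(sw, dvdt_threshold, peak_floor)
    subfloor[j] <- attr(spk, "n_subfloor")
    if (isTRUE(spk_feats$no_spike) && nrow(spk) > 0L) {
      spk_feats <- first_spike_features(sw, spk, dvdt_threshold)
    }
  }

  feats <- list(rmp_mV = pas$rmp, r_in_MOhm = pas$r_in, tc_ms = pas$tc,
                c_in_pF = pas$c_in, sag_ratio = pas$sag_ratio)
  pi_score <- physiology_index(feats, index_config)
  cls <- classify_cell(fi, subfloor_by_current = subfloor,
                       phys_index = pi_score, rheobase = rheo$rheobase)

  data.frame(
    cell_id = fi_rec$cell_id, group_label = fi_rec$group_label,
    rmp_mV = pas$rmp, r_in_MOhm = pas$r_in, tc_ms = pas$tc,
    c_in_pF = pas$c_in, sag_ratio = pas$sag_ratio,
    threshold_mV = if (isTRUE(spk_feats$no_spike)) NA_real_ else spk_feats$threshold,
    peak_mV = if (isTRUE(spk_feats$no_spike)) NA_real_ else spk_feats$peak,
    amplitude_mV = if (isTRUE(spk_feats$no_spike)) NA_real_ else spk_feats$amplitude,
    half_width_ms = if (isTRUE(spk_feats$no_spike)) NA_real_ else spk_feats$half_width,
    max_rise_slope = if (isTRUE(spk_feats$no_spike)) NA_real_ else spk_feats$max_rise_slope,
    max_decay_slope = if (isTRUE(spk_feats$no_spike)) NA_real_ else spk_feats$max_decay_slope,
    gain_Hz_pA = fi$gain, max_frequency_Hz = fi$max_frequency,
    current_at_max_pA = fi$current_at_max,
    total_spike_output = fi$total_spike_output,
    block_detected = fi$block_detected,
    rheobase_pA = rheo$rheobase, latency_ms = rheo$latency_ms,
    physiology_index = pi_score, regular_spiking = cls$regular_spiking,
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param design A [cohort_design()] to simulate, or `NULL` when reading
#'   fixtures from `input_dir`.
#' @param input_dir Directory of fixture recordings written by
#'   [make_fixtures()]; ignored when `design` is given.
#' @param settings [detection_settings()] for the sEPSC stage.
#' @param criteria [noise_criteria()] for event rejection.
#' @param thresholds [qc_thresholds()].
#' @param stats [stats_config()].
#' @param out_dir Output directory for the CSV artifacts (`NULL` = return
#'   tables only).
#' @param seed Master seed recorded in the provenance of every output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, input_dir = NULL,
                            settings = detection_settings(),
                            criteria = noise_criteria(),
                            thresholds = qc_thresholds(),
                            stats = stats_config(),
                            out_dir = NULL, seed = 1) {
  if (is.null(design) && is.null(input_dir)) {
    stop("pipeline needs either a cohort design or an input directory")
  }
  if (!is.null(input_dir) && is.null(design) && !dir.exists(input_dir)) {
    stop("startup error: input directory does not exist: ", input_dir)
  }
  structure(list(design = design, input_dir = input_dir,
                 settings = settings, criteria = criteria,
                 thresholds = thresholds, stats = stats,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

read_fixture_cohort <- function(dir) {
  manifests <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  manifests <- manifests[basename(manifests) != "design.json"]
  cells <- list()
  for (mf in manifests) {
    rec <- read_recording(mf)
    cid <- rec$cell_id
    if (is.null(cells[[cid]])) {
      cells[[cid]] <- list(cell_id = cid, group_label = rec$group_label,
                           recordings = list())
    }
    cells[[cid]]$recordings[[rec$protocol_tag]] <- rec
  }
  list(cells = cells, ground_truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the stage order of the study: simulate (or ingest) -> extract
#' current-clamp features -> detect sEPSCs -> quality control -> group
#' comparison. Deterministic given the configuration seed; every written
#' artifact carries the seed and a configuration fingerprint in
#' `provenance.json`.
#'
#' @param config A [pipeline_config()].
#' @return List of tables: `features`, `events`, `sweep_summaries`, `qc`,
#'   `comparisons` (scalar features), `omnibus`, `fi_comparisons`
#'   (permutation tests per pair), `fi_curves` (per-cell frequency matrix),
#'   `ground_truth` (when simulated), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$design)) {
    generate_cohort(config$design)
  } else {
    read_fixture_cohort(config$input_dir)
  }

  stage <- "extract"
  feats <- list()
  sepsc_rows <- list()
  events <- list()
  sweep_sum <- list()
  curves <- list()
  for (cell in cohort$cells) {
    res <- tryCatch({
      f <- extract_cc_features(cell$recordings)
      s <- analyze_sepsc_recording(cell$recordings$sepsc, config$settings,
                                   config$criteria)
      list(f = f, s = s)
    }, error = function(e) {
      stop("stage '", stage, "' failed for cell ", cell$cell_id, ": ",
           conditionMessage(e))
    })
    f <- res$f
    f$sepsc_frequency_Hz <- res$s$cell_summary$sepsc_frequency
    f$sepsc_amplitude_pA <- res$s$cell_summary$sepsc_amplitude
    f$sepsc_decay_ms <- res$s$cell_summary$sepsc_decay_tc
    f$r_s_MOhm <- res$s$cell_summary$r_s
    feats[[cell$cell_id]] <- f
    ev <- res$s$events
    if (nrow(ev)) ev$cell_id <- cell$cell_id
    events[[cell$cell_id]] <- ev
    ss <- res$s$sweep_summaries
    ss$cell_id <- cell$cell_id
    sweep_sum[[cell$cell_id]] <- ss
    fi <- compute_fi_curve(cell$recordings$fi_steps)
    curves[[cell$cell_id]] <- stats::setNames(fi$frequencies,
                                              as.character(fi$currents))
  }
  features <- do.call(rbind, c(feats, list(make.row.names = FALSE)))

  stage <- "qc"
  qc <- qc_table(features, config$thresholds)

  stage <- "compare"
  passed <- qc$cell_id[qc$passed]
  feature_names <- c("gain_Hz_pA", "max_frequency_Hz", "total_spike_output",
                     "threshold_mV", "amplitude_mV", "half_width_ms",
                     "max_rise_slope", "max_decay_slope", "rheobase_pA",
                     "latency_ms", "rmp_mV", "r_in_MOhm", "tc_ms", "c_in_pF",
                     "sag_ratio", "sepsc_frequency_Hz", "sepsc_amplitude_pA",
                     "sepsc_decay_ms")
  summary_tables <- build_summary_table(features, qc, feature_names,
                                        config$stats)

  curve_mat <- do.call(rbind, curves[passed])
  groups <- features$group_label[match(passed, features$cell_id)]
  curves_by_group <- lapply(split(seq_along(passed), groups),
                            function(i) curve_mat[i, , drop = FALSE])
  pairs <- utils::combn(c("control", "PAE_saline", "PAE_NBOH"), 2)
  fi_cmp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    compare_fi_curves(curves_by_group, pairs[, k], config$stats)
  }))

  provenance <- list(
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config_fingerprint = paste0("cells=",
      if (!is.null(config$design)) config$design$cells_per_group else "fixture",
      ";policy=", config$stats$policy, ";corr=", config$stats$correction,
      ";thr=", config$settings$threshold))

  out <- list(features = features,
              events = do.call(rbind, c(events, list(make.row.names = FALSE))),
              sweep_summaries = do.call(rbind, c(sweep_sum, list(make.row.names = FALSE))),
              qc = qc,
              comparisons = summary_tables$table,
              omnibus = summary_tables$omnibus,
              fi_comparisons = fi_cmp,
              fi_curves = curve_mat,
              ground_truth = cohort$ground_truth,
              provenance = provenance)

  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    for (nm in c("features", "events", "sweep_summaries", "qc",
                 "comparisons", "fi_comparisons")) {
      data.table::fwrite(out[[nm]], file.path(config$out_dir,
                                              paste0(nm, ".csv")))
    }
    jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Plot group-mean f-I curves with SEM ribbons
#'
#' @param fi_curves Per-cell frequency matrix from [run_pipeline()].
#' @param groups Group label per row.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_fi_curves <- function(fi_curves, groups) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fi_curves requires ggplot2")
  }
  currents <- as.numeric(colnames(fi_curves))
  dfs <- lapply(split(seq_along(groups), groups), function(i) {
    m <- fi_curves[i, , drop = FALSE]
    data.frame(group = groups[i[1]], current = currents,
               mean = colMeans(m),
               sem = apply(m, 2, sd) / sqrt(nrow(m)))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = current, y = mean, colour = group,
                                   fill = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Injected current (pA)", y = "Firing frequency (Hz)") +
    ggplot2::theme_minimal()
}
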