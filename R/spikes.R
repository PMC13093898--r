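#' Detect action potentials in a current-clamp sweep
#'
#' Candidate spikes are local voltage maxima preceded by an upward crossing
#' of the rise-slope criterion: dV/dt (central differences, mV/ms) rising
#' through `dvdt_threshold`. Each crossing is assigned to exactly one peak
#' (the first local maximum at or after the crossing); candidates must
#' rise at least `height_min` mV from the crossing to the peak (guards
#' against slope-criterion hits from measurement noise); candidates whose
#' peak voltage fails to reach `peak_floor` are not counted. Candidates
#' that rise at least `subfloor_height_min` mV yet peak below the floor are
#' the signature of depolarization block; their count is reported so
#' downstream classification can flag it (small sub-floor noise bumps are
#' ignored entirely).
#'
#' @param sw A current-clamp [sweep()].
#' @param dvdt_threshold Rise-slope criterion (mV/ms); default 10.
#' @param peak_floor Minimum peak voltage for a counted spike (mV);
#'   default -10.
#' @param height_min Minimum crossing-to-peak rise (mV) for a candidate.
#' @param subfloor_height_min Minimum rise (mV) for a sub-floor candidate
#'   to be reported as a blocked-spike stub.
#' @return data.frame with one row per counted spike: `threshold_index`,
#'   `threshold_time` (s), `peak_index`, `peak_time` (s), `peak_value`
#'   (mV). Attribute `n_subfloor` counts candidates discarded by the peak
#'   floor.
#' @export
detect_spikes <- function(sw, dvdt_threshold = 10, peak_floor = -10,
                          height_min = 2, subfloor_height_min = 15) {
  if (identical(sw$clamp_mode, "voltage_clamp")) {
    stop("mode error: spike detection requires a current-clamp sweep")
  }
  v <- sw$samples
  n <- length(v)
  sr <- sw$sampling_rate
  dt_ms <- 1000 / sr
  empty <- data.frame(threshold_index = integer(0), threshold_time = numeric(0),
                      peak_index = integer(0), peak_time = numeric(0),
                      peak_value = numeric(0))
  attr(empty, "n_subfloor") <- 0L
  if (n < 3L) return(empty)

  dvdt <- c(NA_real_, (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms), NA_real_)
  above <- dvdt >= dvdt_threshold
  above[is.na(above)] <- FALSE
  crossings <- which(above & !c(FALSE, above[-n]))
  if (!length(crossings)) return(empty)

  # local maxima: v[i] > v[i-1] and v[i] >= v[i+1]
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  max_idx <- which(is_max)
  if (!length(max_idx)) return(empty)

  # first local maximum at or after each crossing
  pos <- findInterval(crossings - 1L, max_idx) + 1L
  keep <- pos <= length(max_idx)
  crossings <- crossings[keep]
  peaks <- max_idx[pos[keep]]
  if (!length(crossings)) return(empty)

  # one spike per peak: keep the earliest crossing assigned to each peak
  first_of_peak <- !duplicated(peaks)
  crossings <- crossings[first_of_peak]
  peaks <- peaks[first_of_peak]

  # prominence guard: a candidate must actually rise from the crossing
  height <- v[peaks] - v[crossings]
  keep <- height >= height_min
  crossings <- crossings[keep]
  peaks <- peaks[keep]
  height <- height[keep]
  if (!length(crossings)) return(empty)

  sub <- v[peaks] < peak_floor
  out <- data.frame(threshold_index = crossings,
                    threshold_time = (crossings - 1) / sr,
                    peak_index = peaks,
                    peak_time = (peaks - 1) / sr,
                    peak_value = v[peaks])[!sub, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_subfloor") <- sum(sub & height >= subfloor_height_min)
  out
}

#' Waveform features of the first spike
#'
#' Computes the study's spike-waveform feature set on the first detected
#' spike of a sweep: threshold (voltage at the first sample of the rising
#' phase where dV/dt reaches the criterion), peak, amplitude (peak minus
#' threshold), half-width (time between the two crossings of
#' threshold + amplitude/2, linearly interpolated between samples), and the
#' maximum rise and decay slopes of dV/dt over the spike extent. dV/dt is
#' computed by central differences in mV/ms.
#'
#' @param sw A current-clamp [sweep()].
#' @param spikes Output of [detect_spikes()] on the same sweep.
#' @param dvdt_threshold Rise-slope criterion used for the threshold (mV/ms).
#' @return List of class `spike_features` with fields `threshold`,
#'   `threshold_time`, `peak`, `amplitude`, `half_width`,
#'   `max_rise_slope`, `max_decay_slope`; or a list with
#'   `no_spike = TRUE` when `spikes` is empty.
#' @export
first_spike_features <- function(sw, spikes, dvdt_threshold = 10) {
  if (is.null(spikes) || nrow(spikes) == 0L) {
    return(structure(list(no_spike = TRUE), class = "spike_features"))
  }
  v <- sw$samples
  n <- length(v)
  sr <- sw$sampling_rate
  dt_ms <- 1000 / sr
  i_th <- spikes$threshold_index[1]
  i_pk <- spikes$peak_index[1]
  dvdt <- c(NA_real_, (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms), NA_real_)

  threshold <- v[i_th]
  peak <- v[i_pk]
  amplitude <- peak - threshold
  half <- threshold + amplitude / 2

  # spike extent: until the voltage first returns below threshold after the
  # peak, or 10 ms, or the next spike's threshold, whichever is earliest
  lim <- min(n, i_pk + round(10 / dt_ms))
  if (nrow(spikes) > 1L) lim <- min(lim, spikes$threshold_index[2] - 1L)
  below <- which(v[(i_pk + 1L):lim] < threshold)
  i_end <- if (length(below)) i_pk + below[1] else lim

  # half-maximum crossings, linearly interpolated
  up_seg <- i_th:i_pk
  iu <- up_seg[which(v[up_seg] >= half)[1]]
  t_up <- if (iu == i_th || v[iu] == v[iu - 1L]) iu - 1 else {
    (iu - 2) + (half - v[iu - 1L]) / (v[iu] - v[iu - 1L])
  }
  down_seg <- i_pk:i_end
  id <- down_seg[which(v[down_seg] <= half)[1]]
  t_dn <- if (is.na(id)) i_end - 1 else if (v[id] == v[id - 1L]) id - 1 else {
    (id - 2) + (half - v[id - 1L]) / (v[id] - v[id - 1L])
  }
  half_width <- (t_dn - t_up) * dt_ms

  rise_rng <- i_th:i_pk
  fall_rng <- i_pk:i_end
  structure(list(
    no_spike = FALSE,
    threshold = threshold,
    threshold_time = (i_th - 1) / sr,
    peak = peak,
    amplitude = amplitude,
    half_width = half_width,
    max_rise_slope = max(dvdt[rise_rng], na.rm = TRUE),
    max_decay_slope = min(dvdt[fall_rng], na.rm = TRUE)
  ), class = "spike_features")
}
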