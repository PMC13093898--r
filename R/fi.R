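#' f-I curve, gain, maximum rate and total spike output
#'
#' Counts spikes per sweep of an f-I step protocol (a 1-s step makes the
#' count numerically equal to the frequency in Hz), then summarizes the
#' curve the way the study does: the gain is the ordinary least-squares
#' slope of frequency on current from the 0-pA sweep up to the injection at
#' which the maximum frequency was attained (ties resolved to the lowest
#' such current), and the total spike output is the spike sum over the same
#' range. Sub-floor peaks are never counted; a sweep above the
#' maximum-frequency current that both fires less than the maximum and
#' contains sub-floor peaks raises the advisory depolarization-block flag.
#'
#' @param rec A current-clamp [recording()] with `protocol_tag`
#'   `"fi_steps"`, sweeps at increasing step amplitudes including 0 pA.
#' @param dvdt_threshold,peak_floor Spike detector settings
#'   (see [detect_spikes()]).
#' @return List of class `fi_curve`: `currents` (pA), `frequencies` (Hz),
#'   `gain` (Hz/pA), `max_frequency`, `current_at_max`,
#'   `total_spike_output`, `block_detected`, plus `spike_times` (list of
#'   per-sweep spike threshold times).
#' @export
compute_fi_curve <- function(rec, dvdt_threshold = 10, peak_floor = -10) {
  if (rec$clamp_mode != "current_clamp") {
    stop("mode error: f-I analysis requires a current-clamp recording")
  }
  amps <- vapply(rec$sweeps, function(s) s$command$amplitude, numeric(1))
  ord <- order(amps)
  sweeps <- rec$sweeps[ord]
  amps <- amps[ord]
  if (!any(amps == 0)) {
    stop("missing 0 pA sweep: the gain regression range is undefined")
  }
  counts <- integer(length(sweeps))
  subfloor <- integer(length(sweeps))
  spike_times <- vector("list", length(sweeps))
  for (k in seq_along(sweeps)) {
    s <- sweeps[[k]]
    spk <- detect_spikes(s, dvdt_threshold, peak_floor)
    on <- s$command$onset
    off <- on + s$command$duration
    in_step <- spk$threshold_time >= on & spk$threshold_time < off
    counts[k] <- sum(in_step)
    subfloor[k] <- attr(spk, "n_subfloor")
    spike_times[[k]] <- spk$threshold_time[in_step]
  }
  dur <- sweeps[[1]]$command$duration
  freqs <- counts / dur

  max_f <- max(freqs)
  i_max <- which(freqs == max_f)[1]  # lowest current attaining the maximum
  rng <- 1:i_max
  gain <- if (length(rng) >= 2 && stats::var(amps[rng]) > 0) {
    unname(coef(lm(freqs[rng] ~ amps[rng]))[2])
  } else 0
  block <- any(freqs[-rng] < max_f & subfloor[-rng] > 0)

  structure(list(currents = amps, frequencies = freqs, gain = gain,
                 max_frequency = max_f, current_at_max = amps[i_max],
                 total_spike_output = sum(counts[rng]),
                 block_detected = isTRUE(block),
                 spike_times = spike_times),
            class = "fi_curve")
}

#' Rheobase and latency to first spike
#'
#' Scans the fine-step (2-s) depolarizing protocol for the smallest step
#' amplitude whose sweep contains at least one detected spike; latency is
#' measured on that sweep from the command onset to the first spike's
#' threshold crossing. When the protocol was repeated (amplitudes restart
#' at a lower value), each monotone-increasing run is treated as one
#' repetition and the per-repetition rheobase and latency are averaged.
#'
#' @param rec A current-clamp [recording()] with `protocol_tag`
#'   `"rheobase_steps"`.
#' @param dvdt_threshold,peak_floor Spike detector settings.
#' @return List of class `rheobase_result`: `reached` (logical),
#'   `rheobase` (pA), `latency_ms`, and `per_repetition` (data.frame).
#'   When no sweep spikes, `reached` is `FALSE` and the estimates are `NA`.
#' @export
rheobase_and_latency <- function(rec, dvdt_threshold = 10, peak_floor = -10) {
  if (rec$clamp_mode != "current_clamp") {
    stop("mode error: rheobase analysis requires a current-clamp recording")
  }
  amps <- vapply(rec$sweeps, function(s) s$command$amplitude, numeric(1))
  # split into repetitions at every non-increase of the amplitude sequence
  rep_id <- cumsum(c(TRUE, diff(amps) <= 0))
  reps <- split(seq_along(amps), rep_id)
  rows <- list()
  for (r in seq_along(reps)) {
    idx <- reps[[r]]
    if (is.unsorted(amps[idx], strictly = TRUE)) {
      stop("step amplitudes must be strictly increasing within a repetition")
    }
    rheo <- NA_real_
    lat <- NA_real_
    for (i in idx) {
      s <- rec$sweeps[[i]]
      spk <- detect_spikes(s, dvdt_threshold, peak_floor)
      on <- s$command$onset
      off <- on + s$command$duration
      spk <- spk[spk$threshold_time >= on & spk$threshold_time < off, , drop = FALSE]
      if (nrow(spk) > 0L) {
        rheo <- amps[i]
        lat <- (spk$threshold_time[1] - on) * 1000
        break
      }
    }
    rows[[r]] <- data.frame(repetition = r, rheobase = rheo, latency_ms = lat)
  }
  per_rep <- do.call(rbind, rows)
  ok <- !is.na(per_rep$rheobase)
  if (!any(ok)) {
    return(structure(list(reached = FALSE, rheobase = NA_real_,
                          latency_ms = NA_real_, per_repetition = per_rep),
                     class = "rheobase_result"))
  }
  structure(list(reached = TRUE,
                 rheobase = mean(per_rep$rheobase[ok]),
                 latency_ms = mean(per_rep$latency_ms[ok]),
                 per_repetition = per_rep),
            class = "rheobase_result")
}
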