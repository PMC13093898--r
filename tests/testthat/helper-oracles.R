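# Independent brute-force oracles and closed-form references used by the
# tests. These deliberately re-implement the written semantics with naive
# per-sample scans, independent of the package's vectorized/compiled paths.

# Closed-form passive step response with the delayed sag relaxation.
# t_s: time from step onset (s); returns deflection from the bias (mV).
rc_step_deflection <- function(t_s, r_m, c_m, amp_pa, sag_frac = 0,
                               sag_tau_ms = 120, sag_delay_ms = NULL) {
  tau <- r_m * c_m / 1000                      # ms
  sag_delay_ms <- if (is.null(sag_delay_ms)) 5 * tau else sag_delay_ms
  t_ms <- t_s * 1000
  d_ss <- r_m * amp_pa / 1000                  # mV
  u <- d_ss * (1 - exp(-t_ms / tau))
  z <- ifelse(t_ms > sag_delay_ms & amp_pa < 0 & sag_frac > 0,
              sag_frac * d_ss * (1 - exp(-(t_ms - sag_delay_ms) / sag_tau_ms)),
              0)
  u - z
}

# Exhaustive spike-detection oracle: per-sample scan for the
# crossing-then-first-local-maximum pattern with the prominence and
# peak-floor rules.
oracle_detect_spikes <- function(v, sr, dvdt_threshold = 10, peak_floor = -10,
                                 height_min = 2, subfloor_height_min = 15) {
  n <- length(v)
  dt_ms <- 1000 / sr
  dvdt <- rep(NA_real_, n)
  for (i in 2:(n - 1)) dvdt[i] <- (v[i + 1] - v[i - 1]) / (2 * dt_ms)
  rows <- list()
  n_subfloor <- 0L
  last_peak <- -1L
  i <- 2L
  while (i <= n - 1L) {
    crossed <- !is.na(dvdt[i]) && dvdt[i] >= dvdt_threshold &&
      (is.na(dvdt[i - 1]) || dvdt[i - 1] < dvdt_threshold)
    if (crossed) {
      j <- max(i, 2L)
      pk <- NA_integer_
      while (j <= n - 1L) {
        if (v[j] > v[j - 1] && v[j] >= v[j + 1]) { pk <- j; break }
        j <- j + 1L
      }
      if (!is.na(pk) && pk != last_peak && v[pk] - v[i] >= height_min) {
        if (v[pk] < peak_floor) {
          if (v[pk] - v[i] >= subfloor_height_min) n_subfloor <- n_subfloor + 1L
        } else {
          rows[[length(rows) + 1L]] <- c(i, pk)
        }
        last_peak <- pk
      } else if (!is.na(pk)) {
        last_peak <- max(last_peak, pk)
      }
    }
    i <- i + 1L
  }
  out <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(threshold_index = m[, 1], threshold_time = (m[, 1] - 1) / sr,
               peak_index = m[, 2], peak_time = (m[, 2] - 1) / sr,
               peak_value = v[m[, 2]])
  } else {
    data.frame(threshold_index = integer(0), threshold_time = numeric(0),
               peak_index = integer(0), peak_time = numeric(0),
               peak_value = numeric(0))
  }
  attr(out, "n_subfloor") <- n_subfloor
  out
}

# Exhaustive sEPSC detection oracle implementing the same written
# semantics as detect_events, with naive per-sample scans.
oracle_detect_events <- function(x, baseline, sr, settings) {
  n <- length(x)
  thr <- baseline - settings$threshold
  w_lmp <- as.integer(round(settings$local_max_period / 1000 * sr))
  w_search <- as.integer(round(settings$search_period / 1000 * sr))
  w_base <- max(1L, as.integer(round(settings$baseline_average_window / 1000 * sr)))

  peaks <- integer(0)
  for (i in which(x < thr)) {
    lo <- max(1L, i - w_lmp)
    hi <- min(n, i + w_lmp)
    strictly_before <- lo > i - 1L || all(x[i] < x[lo:(i - 1L)])
    leq_after <- hi < i + 1L || all(x[i] <= x[(i + 1L):hi])
    if (strictly_before && leq_after) peaks <- c(peaks, i)
  }

  onsets <- integer(length(peaks))
  prev_pk <- 0L
  for (e in seq_along(peaks)) {
    pk <- peaks[e]
    lo <- max(1L, pk - w_search, prev_pk + 1L)
    onset <- NA_integer_
    for (j in pk:lo) {            # walk back to the last return to baseline
      if (x[j] >= baseline[j]) { onset <- j; break }
    }
    if (is.na(onset)) onset <- lo + which.max(x[lo:pk]) - 1L
    onsets[e] <- onset
    prev_pk <- pk
  }
  amp <- numeric(length(peaks))
  for (e in seq_along(peaks)) {
    b <- mean(x[max(1L, onsets[e] - w_base):(onsets[e] - 1L)])
    amp[e] <- b - x[peaks[e]]
  }
  data.frame(onset_index = onsets, peak_index = peaks, amplitude = amp)
}

# Greedy onset-matching of detected to true events within a tolerance (s).
match_events <- function(detected_onsets, true_onsets, tol = 0.003) {
  used <- rep(FALSE, length(true_onsets))
  tp <- 0L
  for (t in detected_onsets) {
    d <- abs(true_onsets - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(recall = tp / length(true_onsets), precision = tp / length(detected_onsets))
}

# A sweep with n_spikes stereotyped spikes pasted on a flat baseline,
# built directly from samples (no simulator involvement).
make_spike_sweep <- function(n_spikes, amp_pa, sr = 20000, dur = 1.4,
                             onset = 0.2, step_dur = 1,
                             v_base = -65, v_th = -48, v_pk = 12,
                             rise_ms = 0.4, fall_ms = 1.2, v_reset = -58) {
  n <- round(dur * sr)
  v <- rep(v_base, n)
  dt_ms <- 1000 / sr
  n_r <- round(rise_ms / dt_ms)
  n_f <- round(fall_ms / dt_ms)
  wave <- c(v_th + (v_pk - v_th) * (1 - cos(pi * dt_ms * seq_len(n_r) / rise_ms)) / 2,
            v_reset + (v_pk - v_reset) * (1 + cos(pi * dt_ms * seq_len(n_f) / fall_ms)) / 2)
  n_pre <- round(3 / dt_ms)  # 3-ms approach ramp keeps dV/dt < 10 mV/ms
  if (n_spikes > 0) {
    times <- onset + (seq_len(n_spikes) - 0.5) * step_dur / n_spikes
    for (ts in times) {
      i0 <- round(ts * sr) + 1L
      pr <- (i0 - n_pre):(i0 - 1L)
      v[pr] <- v_base + (v_th - v_base) * seq_along(pr) / (n_pre + 1)
      v[i0] <- v_th
      idx <- i0 + seq_along(wave)
      v[idx[idx <= n]] <- wave[seq_len(sum(idx <= n))]
      # gentle return ramp to baseline keeps dV/dt below the criterion
      j0 <- i0 + length(wave) + 1L
      ramp <- j0:min(n, j0 + round(2 / dt_ms))
      if (length(ramp) > 1) {
        v[ramp] <- v_reset + (v_base - v_reset) * seq_along(ramp) / length(ramp)
      }
    }
  }
  sweep(v, sr, step_command(amp_pa, onset, step_dur, 0))
}

# Bi-exponential kernel trace with events at given onsets/amplitudes on a
# flat (or supplied) background, for detector tests.
make_event_trace <- function(n, sr, onsets_s, amps, tau_rise = 0.5,
                             tau_decay = 8, background = numeric(n)) {
  x <- background
  dt_ms <- 1000 / sr
  t <- seq(0, tau_decay * 8, by = dt_ms)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  t_pk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  k <- -k / (exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise))
  for (e in seq_along(onsets_s)) {
    i0 <- round(onsets_s[e] * sr) + 1L
    idx <- i0:min(n, i0 + length(k) - 1L)
    x[idx] <- x[idx] + amps[e] * k[seq_along(idx)]
  }
  x
}
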