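#' Membrane parameters for the synthetic neuron
#'
#' Ground-truth parameters of the simulated cell. The membrane is a leaky
#' integrator (time constant `r_m * c_m`) biased so that the pre-step
#' potential sits at `bias_mv` (the study bias of -65 mV). Spikes are
#' stereotyped waveforms pasted at threshold crossings: a half-cosine rise
#' from `spike_threshold` to `ap_peak` over `ap_rise_ms` followed by a
#' half-cosine fall to `reset` over `ap_fall_ms`, so that every dV/dt-based
#' waveform feature has a closed-form designed value (see
#' [ap_waveform_design()]). Sag is modelled as an Ih-like relaxation that
#' recovers a fraction `sag_conductance` of the steady-state hyperpolarizing
#' deflection with time constant `sag_tau_ms`, activating `sag_delay_ms`
#' after step onset (default five membrane time constants, i.e. after the
#' passive charge is essentially complete) so that the peak deflection and
#' the late plateau relate exactly by `1 - sag_conductance`.
#'
#' For f-I protocols the cell can either fire through its integrate-and-fire
#' dynamics (`fi_mode = "lif"`) or pace a designed linear rate code
#' (`fi_mode = "designed"`): rate `fi_gain * (I - fi_rheobase)` capped at
#' `fi_max_rate`, which gives the cohort generator exact control over the
#' f-I gain that group effects multiply.
#'
#' @param r_m Membrane resistance (MOhm).
#' @param c_m Membrane capacitance (pF).
#' @param e_l Resting potential before bias (mV).
#' @param bias_mv Pre-step potential the holding bias maintains (mV).
#' @param spike_threshold Spike initiation voltage (mV); `Inf` disables
#'   spiking (pure passive membrane).
#' @param reset Post-spike reset voltage (mV).
#' @param refractory_ms Absolute refractory period (ms).
#' @param sag_conductance Fraction of the steady-state deflection recovered
#'   by the sag component (0 disables sag).
#' @param sag_tau_ms Sag relaxation time constant (ms).
#' @param sag_delay_ms Sag activation delay after step onset (ms);
#'   `NULL` = 5 membrane time constants.
#' @param noise_sd Additive Gaussian measurement noise (mV).
#' @param ap_peak,ap_rise_ms,ap_fall_ms Spike waveform design: peak voltage
#'   (mV), rise and fall durations (ms).
#' @param fi_mode `"lif"` or `"designed"` (see above).
#' @param fi_gain Designed f-I gain (Hz/pA), designed mode only.
#' @param fi_rheobase Designed rheobase (pA); `NULL` = the analytic LIF
#'   value `(spike_threshold - bias_mv) / r_m * 1000`.
#' @param fi_max_rate Designed maximum firing rate (Hz).
#' @return A list of class `membrane_params`.
#' @export
membrane_params <- function(r_m = 150, c_m = 150, e_l = -70, bias_mv = -65,
                            spike_threshold = -45, reset = -58,
                            refractory_ms = 3,
                            sag_conductance = 0.12, sag_tau_ms = 120,
                            sag_delay_ms = NULL, noise_sd = 0.2,
                            ap_peak = 20, ap_rise_ms = 0.4, ap_fall_ms = 1.2,
                            fi_mode = c("lif", "designed"),
                            fi_gain = 0.2, fi_rheobase = NULL,
                            fi_max_rate = 40) {
  fi_mode <- match.arg(fi_mode)
  stopifnot(r_m > 0, c_m > 0, sag_conductance >= 0, sag_conductance < 1,
            noise_sd >= 0, ap_rise_ms > 0, ap_fall_ms > 0)
  p <- list(r_m = r_m, c_m = c_m, e_l = e_l, bias_mv = bias_mv,
            spike_threshold = spike_threshold, reset = reset,
            refractory_ms = refractory_ms,
            sag_conductance = sag_conductance, sag_tau_ms = sag_tau_ms,
            sag_delay_ms = sag_delay_ms, noise_sd = noise_sd,
            ap_peak = ap_peak, ap_rise_ms = ap_rise_ms,
            ap_fall_ms = ap_fall_ms, fi_mode = fi_mode, fi_gain = fi_gain,
            fi_rheobase = fi_rheobase, fi_max_rate = fi_max_rate)
  class(p) <- "membrane_params"
  p
}

tau_m_ms <- function(p) p$r_m * p$c_m / 1000

#' Designed values of the stereotyped spike waveform
#'
#' Closed-form features of the pasted spike: threshold, peak, amplitude,
#' maximum rise and decay slopes of the half-cosine segments, and the
#' half-width (time between the two crossings of threshold + amplitude/2).
#'
#' @param p A [membrane_params()].
#' @return Named list of designed feature values.
#' @export
ap_waveform_design <- function(p) {
  a <- p$ap_peak - p$spike_threshold
  half <- p$spike_threshold + a / 2
  fall_amp <- p$ap_peak - p$reset
  # fall: v(t) = reset + fall_amp * (1 + cos(pi t / Tf)) / 2
  t_half_fall <- p$ap_fall_ms / pi * acos(2 * (half - p$reset) / fall_amp - 1)
  list(threshold = p$spike_threshold, peak = p$ap_peak, amplitude = a,
       max_rise_slope = a * pi / (2 * p$ap_rise_ms),
       max_decay_slope = -fall_amp * pi / (2 * p$ap_fall_ms),
       half_width = p$ap_rise_ms / 2 + t_half_fall)
}

# Spike waveform samples at interval dt_ms, starting one sample after the
# threshold crossing and ending at the reset voltage.
ap_waveform_samples <- function(p, dt_ms) {
  n_r <- max(1L, round(p$ap_rise_ms / dt_ms))
  n_f <- max(1L, round(p$ap_fall_ms / dt_ms))
  t_r <- dt_ms * seq_len(n_r)
  t_f <- dt_ms * seq_len(n_f)
  rise <- p$spike_threshold +
    (p$ap_peak - p$spike_threshold) * (1 - cos(pi * t_r / p$ap_rise_ms)) / 2
  fall <- p$reset + (p$ap_peak - p$reset) * (1 + cos(pi * t_f / p$ap_fall_ms)) / 2
  c(rise, fall)
}

#' Current-clamp step protocol description
#'
#' @param tag Protocol tag (`"fi_steps"`, `"rheobase_steps"`,
#'   `"hyperpolarizing_steps"`).
#' @param amplitudes Step amplitudes in pA, one sweep per entry.
#' @param duration Step duration (s).
#' @param pre,post Baseline before/after the step (s); at least 0.2 s of
#'   pre-step baseline is required so the 100-ms baseline window exists.
#' @param sampling_rate Sampling rate (Hz).
#' @return A list of class `cc_protocol`.
#' @export
cc_protocol <- function(tag, amplitudes, duration, pre = 0.2, post = 0.2,
                        sampling_rate = 20000) {
  tag <- match.arg(tag, c("fi_steps", "rheobase_steps", "hyperpolarizing_steps"))
  if (pre < 0.2) stop("protocol missing baseline: pre-step baseline must be >= 0.2 s")
  if (duration <= 0) stop("non-positive step duration")
  structure(list(tag = tag, amplitudes = amplitudes, duration = duration,
                 pre = pre, post = post, sampling_rate = sampling_rate),
            class = "cc_protocol")
}

#' @rdname cc_protocol
#' @param max_pa,step_pa f-I protocol range: steps `0, step_pa, ..., max_pa`
#'   (the study protocol: 1-s injections, 50-pA steps up to 400 pA).
#' @export
fi_protocol <- function(max_pa = 400, step_pa = 50, duration = 1,
                        pre = 0.2, post = 0.3, sampling_rate = 20000) {
  cc_protocol("fi_steps", seq(0, max_pa, by = step_pa), duration, pre, post,
              sampling_rate)
}

#' @rdname cc_protocol
#' @export
rheobase_protocol <- function(amplitudes, duration = 2, pre = 0.2, post = 0.2,
                              sampling_rate = 20000) {
  cc_protocol("rheobase_steps", amplitudes, duration, pre, post, sampling_rate)
}

#' @rdname cc_protocol
#' @param amplitude Hyperpolarizing step amplitude (pA, negative).
#' @param n_sweeps Number of repeated sweeps.
#' @export
hyperpolarizing_protocol <- function(amplitude = -20, n_sweeps = 30,
                                     duration = 1, pre = 0.3, post = 0.3,
                                     sampling_rate = 20000) {
  cc_protocol("hyperpolarizing_steps", rep(amplitude, n_sweeps), duration,
              pre, post, sampling_rate)
}

#' Simulate a current-clamp recording
#'
#' Integrates the leaky integrate-and-fire membrane of `params` through the
#' step protocol by forward Euler at the sampling interval, pastes the
#' stereotyped spike waveform at threshold crossings, applies the delayed
#' sag relaxation during hyperpolarizing steps, and adds Gaussian
#' measurement noise. Deterministic given `(params, protocol, seed)`.
#'
#' @param params A [membrane_params()].
#' @param protocol A [cc_protocol()].
#' @param seed Integer seed for the measurement noise.
#' @param cell_id,group_label Metadata for the returned recording.
#' @return A current-clamp [recording()]. The true pasted-spike times per
#'   sweep are attached as attribute `"true_spikes"` (list of numeric
#'   vectors, seconds of the threshold crossing).
#' @export
simulate_current_clamp <- function(params, protocol, seed = 1,
                                   cell_id = "sim_cell",
                                   group_label = "control") {
  stopifnot(inherits(params, "membrane_params"), inherits(protocol, "cc_protocol"))
  sr <- protocol$sampling_rate
  dt_ms <- 1000 / sr
  n_pre <- round(protocol$pre * sr)
  n_step <- round(protocol$duration * sr)
  n_post <- round(protocol$post * sr)
  n <- n_pre + n_step + n_post
  step_idx <- (n_pre + 1L):(n_pre + n_step)
  wave <- ap_waveform_samples(params, dt_ms)
  sag_delay <- params$sag_delay_ms %||% (5 * tau_m_ms(params))
  designed <- identical(params$fi_mode, "designed") &&
    identical(protocol$tag, "fi_steps")

  sweeps <- vector("list", length(protocol$amplitudes))
  true_spikes <- vector("list", length(protocol$amplitudes))
  noise <- with_seed(seed, matrix(rnorm(n * length(protocol$amplitudes),
                                        sd = params$noise_sd), nrow = n))
  for (k in seq_along(protocol$amplitudes)) {
    amp <- protocol$amplitudes[k]
    i_pa <- numeric(n)
    i_pa[step_idx] <- amp
    if (designed) {
      v <- designed_fi_sweep(params, amp, n, n_pre, n_step, dt_ms, wave)
      spk_t <- attr(v, "spike_times")
    } else {
      z_target <- numeric(n)
      if (amp < 0 && params$sag_conductance > 0) {
        i_sag0 <- n_pre + 1L + round(sag_delay / dt_ms)
        if (i_sag0 <= n_pre + n_step) {
          z_target[i_sag0:(n_pre + n_step)] <-
            params$sag_conductance * params$r_m * amp / 1000
        }
      }
      out <- lif_integrate(i_pa, dt_ms, params$r_m, params$c_m,
                           params$bias_mv, params$spike_threshold,
                           params$reset, params$refractory_ms, wave,
                           params$sag_tau_ms, z_target)
      v <- out$v
      spk_t <- (out$spike_index - 1) / sr
    }
    v <- v + noise[, k]
    sweeps[[k]] <- sweep(v, sr,
                         step_command(amp, protocol$pre, protocol$duration, 0),
                         sweep_index = k)
    true_spikes[[k]] <- spk_t
  }
  rec <- recording(sweeps, "current_clamp", cell_id, group_label,
                   holding_level = params$bias_mv,
                   protocol_tag = protocol$tag)
  attr(rec, "true_spikes") <- true_spikes
  rec
}

# Designed-rate f-I sweep: passive clamped subthreshold trace with evenly
# paced stereotyped spikes at rate fi_gain * (I - fi_rheobase), capped at
# fi_max_rate. Returns voltage vector with attribute spike_times (s).
designed_fi_sweep <- function(p, amp, n, n_pre, n_step, dt_ms, wave) {
  sr <- 1000 / dt_ms
  tau <- tau_m_ms(p)
  rheo <- p$fi_rheobase %||% ((p$spike_threshold - p$bias_mv) / p$r_m * 1000)
  v_inf <- p$bias_mv + p$r_m * amp / 1000
  v_cap <- p$spike_threshold - 2  # between spikes the membrane stays subthreshold
  t_ms <- (seq_len(n) - 1) * dt_ms
  on_ms <- n_pre * dt_ms
  off_ms <- (n_pre + n_step) * dt_ms
  v <- rep(p$bias_mv, n)
  in_step <- t_ms >= on_ms & t_ms < off_ms
  v[in_step] <- pmin(v_cap,
                     v_inf + (p$bias_mv - v_inf) * exp(-(t_ms[in_step] - on_ms) / tau))
  after <- t_ms >= off_ms
  v_off <- min(v_cap, v_inf + (p$bias_mv - v_inf) * exp(-(off_ms - on_ms) / tau))
  v[after] <- p$bias_mv + (v_off - p$bias_mv) * exp(-(t_ms[after] - off_ms) / tau)

  rate <- if (amp > rheo) min(p$fi_max_rate, p$fi_gain * (amp - rheo)) else 0
  dur_s <- n_step / sr
  n_spk <- round(rate * dur_s)
  spike_times <- numeric(0)
  if (n_spk > 0) {
    spike_times <- (n_pre / sr) + (seq_len(n_spk) - 0.5) * dur_s / n_spk
    n_ramp <- max(2L, round(2 / dt_ms))  # 2-ms ramps keep inter-spike dV/dt < 10 mV/ms
    for (ts in spike_times) {
      i0 <- round(ts * sr) + 1L
      if (i0 > n) next
      if (i0 > n_ramp + 1L) {
        pr <- (i0 - n_ramp):(i0 - 1L)
        v[pr] <- v[i0 - n_ramp] +
          (p$spike_threshold - v[i0 - n_ramp]) * seq_along(pr) / (n_ramp + 1L)
      }
      v[i0] <- p$spike_threshold
      idx <- i0 + seq_along(wave)
      idx <- idx[idx <= n]
      v[idx] <- wave[seq_along(idx)]
      j0 <- i0 + length(wave) + 1L
      if (j0 <= n) {
        jr <- j0:min(n, j0 + n_ramp - 1L)
        v[jr] <- p$reset + (v[min(n, j0 + n_ramp)] - p$reset) *
          seq_along(jr) / n_ramp
      }
    }
  }
  attr(v, "spike_times") <- spike_times
  v
}

#' Synaptic (sEPSC) generator parameters
#'
#' Ground truth for the voltage-clamp simulation: a Poisson train of
#' inward bi-exponential events with lognormal amplitudes, superimposed on
#' a slowly drifting sinusoidal baseline with Gaussian noise.
#'
#' @param event_rate Poisson event rate (Hz) over the analysis window.
#' @param amp_mean Mean event amplitude (pA, magnitude of the inward peak).
#' @param amp_cv Coefficient of variation of the lognormal amplitude law
#'   (0 = all events identical).
#' @param tau_rise,tau_decay Kernel time constants (ms); must satisfy
#'   `tau_decay > tau_rise > 0`.
#' @param noise_sd Gaussian current noise (pA).
#' @param drift_amplitude Sinusoidal baseline drift amplitude (pA).
#' @param drift_period Drift period (s).
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(event_rate = 5, amp_mean = 20, amp_cv = 0.3,
                           tau_rise = 0.5, tau_decay = 8, noise_sd = 2,
                           drift_amplitude = 20, drift_period = 10) {
  stopifnot(event_rate >= 0, amp_mean > 0, tau_decay > tau_rise,
            tau_rise > 0, noise_sd >= 0)
  structure(list(event_rate = event_rate, amp_mean = amp_mean,
                 amp_cv = amp_cv, tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period),
            class = "synapse_params")
}

# Bi-exponential kernel samples, peak-normalized to -1, at interval dt_ms.
epsc_kernel <- function(tau_rise, tau_decay, dt_ms, span_factor = 8) {
  t <- seq(0, tau_decay * span_factor, by = dt_ms)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  t_pk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise)
  list(samples = -k / norm, peak_offset_ms = t_pk)
}

#' Simulate voltage-clamp sEPSC sweeps
#'
#' Each sweep is 30 s at the given sampling rate and starts with the
#' response to a -5 mV / 250 ms test pulse (onset 10 ms): a capacitive peak
#' of `-5 mV / rs_mohm` relaxing to the steady state
#' `-5 mV / (rs_mohm + rin_mohm)`. Spontaneous events are a Poisson train
#' over the post-test-pulse analysis window (1-30 s), each a negative
#' bi-exponential kernel peak-normalized to its drawn amplitude, on a
#' sinusoidal drifting baseline with Gaussian noise.
#'
#' @param params A [synapse_params()].
#' @param n_sweeps Number of sweeps.
#' @param seed Integer seed.
#' @param rs_mohm,rin_mohm True series and input resistance (MOhm) shaping
#'   the test-pulse response.
#' @param tp_tau_ms Test-pulse relaxation time constant (ms).
#' @param sweep_s,sampling_rate Sweep length (s) and sampling rate (Hz).
#' @param cell_id,group_label Recording metadata.
#' @return List with elements `recording` (a voltage-clamp [recording()])
#'   and `events` (data.frame of true events: `sweep_index`, `onset_time`,
#'   `peak_time`, `amplitude`, sorted by onset within sweep).
#' @export
simulate_sepsc_sweeps <- function(params, n_sweeps, seed = 1,
                                  rs_mohm = 12, rin_mohm = 150,
                                  tp_tau_ms = 1.5, sweep_s = 30,
                                  sampling_rate = 20000,
                                  cell_id = "sim_cell",
                                  group_label = "control") {
  stopifnot(inherits(params, "synapse_params"), n_sweeps >= 1)
  sr <- sampling_rate
  dt_ms <- 1000 / sr
  n <- round(sweep_s * sr)
  tp_onset <- 0.01
  tp_dur <- 0.25
  i_on <- round(tp_onset * sr) + 1L
  i_off <- round((tp_onset + tp_dur) * sr)

  # test-pulse current template (pA), identical across sweeps
  tp <- numeric(n)
  i_ss <- -5000 / (rs_mohm + rin_mohm)
  i_pk <- -5000 / rs_mohm
  t_in <- (0:(i_off - i_on)) * dt_ms
  tp[i_on:i_off] <- i_ss + (i_pk - i_ss) * exp(-t_in / tp_tau_ms)
  post_idx <- (i_off + 1L):min(n, i_off + round(20 / dt_ms))
  tp[post_idx] <- (-i_pk) * exp(-(seq_along(post_idx) - 1) * dt_ms / tp_tau_ms)

  kern <- epsc_kernel(params$tau_rise, params$tau_decay, dt_ms)
  win0 <- 1  # analysis window start (s): the first second holds the test pulse
  usable <- sweep_s - win0

  sweeps <- vector("list", n_sweeps)
  ev_list <- vector("list", n_sweeps)
  sdlog <- sqrt(log(1 + params$amp_cv^2))
  with_seed(seed, {
    for (k in seq_len(n_sweeps)) {
      x <- tp + rnorm(n, sd = params$noise_sd)
      if (params$drift_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        x <- x + params$drift_amplitude *
          sin(2 * pi * (seq_len(n) - 1) / (params$drift_period * sr) + phase)
      }
      n_ev <- rpois(1, params$event_rate * usable)
      onsets <- sort(runif(n_ev, win0, sweep_s))
      amps <- if (n_ev == 0) numeric(0)
              else if (params$amp_cv > 0) {
                rlnorm(n_ev, meanlog = log(params$amp_mean) - sdlog^2 / 2,
                       sdlog = sdlog)
              } else rep(params$amp_mean, n_ev)
      for (e in seq_len(n_ev)) {
        i0 <- round(onsets[e] * sr) + 1L
        idx <- i0:min(n, i0 + length(kern$samples) - 1L)
        x[idx] <- x[idx] + amps[e] * kern$samples[seq_along(idx)]
      }
      sweeps[[k]] <- sweep(x, sr,
                           step_command(-5, tp_onset, tp_dur, -70),
                           sweep_index = k)
      ev_list[[k]] <- data.frame(sweep_index = rep(k, n_ev),
                                 onset_time = onsets,
                                 peak_time = onsets + kern$peak_offset_ms / 1000,
                                 amplitude = amps)
    }
  })
  rec <- recording(sweeps, "voltage_clamp", cell_id, group_label,
                   holding_level = -70, protocol_tag = "sepsc")
  list(recording = rec, events = do.call(rbind, ev_list))
}
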