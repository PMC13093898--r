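#' Resting membrane potential
#'
#' Mean of the 100 ms of baseline immediately preceding the command onset.
#'
#' @param sw A current-clamp [sweep()] with at least 100 ms of pre-step
#'   baseline.
#' @return Resting potential (mV).
#' @export
resting_membrane_potential <- function(sw) {
  sr <- sw$sampling_rate
  n_base <- round(0.1 * sr)
  i_on <- round(sw$command$onset * sr)  # last pre-step sample (0-based onset)
  if (i_on < n_base) {
    stop("insufficient baseline: need >= 100 ms before the command onset")
  }
  mean(sw$samples[(i_on - n_base + 1L):i_on])
}

# Average sweeps point-wise per step amplitude. Returns a list per
# amplitude: amplitude, trace, onset/offset sample indices, sampling rate.
averaged_step_traces <- function(rec) {
  amps <- vapply(rec$sweeps, function(s) s$command$amplitude, numeric(1))
  lapply(split(seq_along(amps), amps), function(idx) {
    s1 <- rec$sweeps[[idx[1]]]
    len <- vapply(rec$sweeps[idx], function(s) length(s$samples), integer(1))
    if (length(unique(len)) != 1L) {
      stop("sweeps at one step amplitude differ in length; cannot average")
    }
    tr <- rowMeans(vapply(rec$sweeps[idx], `[[`, numeric(len[1]), "samples"))
    sr <- s1$sampling_rate
    list(amplitude = s1$command$amplitude, trace = tr, sampling_rate = sr,
         i_on = round(s1$command$onset * sr),      # last pre-step sample
         i_off = round((s1$command$onset + s1$command$duration) * sr))
  })
}

step_baseline <- function(tr) {
  n_base <- round(0.1 * tr$sampling_rate)
  if (tr$i_on < n_base) stop("insufficient baseline: need >= 100 ms before onset")
  mean(tr$trace[(tr$i_on - n_base + 1L):tr$i_on])
}

# 2-ms moving average; the "maximum response" extremum is taken on this
# lightly filtered trace so residual noise does not bias it outward. The
# charging curve and sag peak are orders of magnitude slower than 2 ms, so
# the smoothing bias is negligible.
smooth_for_extremum <- function(x, sampling_rate) {
  k <- max(1L, round(0.002 * sampling_rate))
  if (k < 2L) return(x)
  pad <- c(rep(x[1], k), x, rep(x[length(x)], k))
  sm <- as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))
  sm[(k + 1L):(k + length(x))]
}

#' Input resistance from hyperpolarizing steps
#'
#' Sweeps are averaged point-wise per step amplitude before measurement
#' (reducing the noise bias on the extremum); for each amplitude the
#' maximum response is the extremum of the averaged trace during the step,
#' measured relative to the mean of the 100 ms before onset, and
#' `Rin = deltaV / I`. Several amplitudes are combined by the mean of the
#' per-amplitude estimates.
#'
#' @param rec A current-clamp [recording()] of hyperpolarizing steps.
#' @return Input resistance (MOhm), with per-amplitude detail in attribute
#'   `"per_amplitude"`.
#' @export
input_resistance <- function(rec) {
  trs <- averaged_step_traces(rec)
  per <- vapply(trs, function(tr) {
    if (tr$amplitude == 0) stop("zero-amplitude step: input resistance undefined")
    base <- step_baseline(tr)
    seg <- smooth_for_extremum(tr$trace[(tr$i_on + 1L):tr$i_off],
                               tr$sampling_rate)
    dv <- seg[which.max(abs(seg - base))] - base
    dv / tr$amplitude * 1000  # mV/pA -> GOhm -> MOhm
  }, numeric(1))
  structure(mean(per), per_amplitude = per)
}

#' Membrane time constant
#'
#' Fits a single exponential, `v(t) = v_ss + (v_0 - v_ss) exp(-t / tau)`,
#' to the averaged voltage trace from the start of the current injection to
#' the peak voltage deflection, by Levenberg-Marquardt least squares with
#' tau bounded in (0.1, 200] ms. Several amplitudes are combined by the
#' mean of the per-amplitude fits.
#'
#' @param rec A current-clamp [recording()] of hyperpolarizing steps.
#' @return Fitted time constant (ms); attribute `"per_amplitude"` carries
#'   the per-amplitude fits.
#' @export
membrane_time_constant <- function(rec) {
  trs <- averaged_step_traces(rec)
  per <- vapply(trs, function(tr) {
    base <- step_baseline(tr)
    seg <- tr$trace[(tr$i_on + 1L):tr$i_off]
    sm <- smooth_for_extremum(seg, tr$sampling_rate)
    i_pk <- which.max(abs(sm - base))
    if (i_pk < 5L) stop("fit failure: fewer than 5 samples before the peak deflection")
    t_ms <- (seq_len(i_pk) - 1) * 1000 / tr$sampling_rate
    y <- seg[seq_len(i_pk)]
    v_ss0 <- y[i_pk]
    # start tau at the 63% rise time of the smoothed charging curve
    i63 <- which(abs(sm[seq_len(i_pk)] - base) >=
                   0.632 * abs(sm[i_pk] - base))[1]
    tau0 <- min(150, max(0.5, (i63 - 1) * 1000 / tr$sampling_rate))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ v_ss + (v0 - v_ss) * exp(-t_ms / tau),
        start = list(v_ss = v_ss0, v0 = base, tau = tau0),
        lower = c(-200, -200, 0.1), upper = c(100, 100, 200),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      stop("fit failure: exponential fit did not converge (amplitude ",
           tr$amplitude, " pA)")
    }
    unname(coef(fit)["tau"])
  }, numeric(1))
  structure(mean(per), per_amplitude = per)
}

#' Input capacitance from the time constant and input resistance
#'
#' `Cin = TC / Rin`; ms / MOhm = nF, reported in pF.
#'
#' @param tc_ms Membrane time constant (ms).
#' @param r_in_mohm Input resistance (MOhm).
#' @return Input capacitance (pF).
#' @export
input_capacitance <- function(tc_ms, r_in_mohm) {
  if (!is.finite(tc_ms) || tc_ms <= 0) stop("time constant must be > 0")
  if (!is.finite(r_in_mohm) || r_in_mohm <= 0) stop("input resistance must be > 0")
  tc_ms / r_in_mohm * 1000
}

#' Sag ratio
#'
#' Maximum response amplitude divided by the mean response amplitude of the
#' last 50 ms of the current injection, both measured on the averaged trace
#' relative to the 100-ms pre-step baseline. A ratio above 1 reports the
#' Ih-mediated sag.
#'
#' @param rec A current-clamp [recording()] of hyperpolarizing steps with
#'   step duration of at least 150 ms.
#' @return Sag ratio (dimensionless); attribute `"per_amplitude"`.
#' @export
sag_ratio <- function(rec) {
  trs <- averaged_step_traces(rec)
  per <- vapply(trs, function(tr) {
    sr <- tr$sampling_rate
    if ((tr$i_off - tr$i_on) / sr < 0.15) {
      stop("step too short: sag ratio needs a step of >= 150 ms")
    }
    base <- step_baseline(tr)
    seg <- tr$trace[(tr$i_on + 1L):tr$i_off]
    peak_amp <- max(abs(smooth_for_extremum(seg, sr) - base))
    n50 <- round(0.05 * sr)
    late_amp <- abs(mean(seg[(length(seg) - n50 + 1L):length(seg)]) - base)
    peak_amp / late_amp
  }, numeric(1))
  structure(mean(per), per_amplitude = per)
}

#' Composite physiology index
#'
#' A configurable weighted combination of extracted features used as a
#' cell-classification gate (cells with score below 5 are retained as
#' putative intratelencephalic pyramidal neurons). The exact formula in the
#' source literature is not reproduced here; the default configuration is a
#' documented placeholder with the same contractual use (the `< 5` gate),
#' and any weighting can be supplied.
#'
#' @param features Named list or one-row data.frame of feature values.
#' @param config List with element `terms`: each term a list with `feature`
#'   (name), `weight`, and optional `center` and `scale` applied as
#'   `weight * (x - center) / scale`; plus optional scalar `offset`.
#' @return Numeric score.
#' @export
physiology_index <- function(features, config = default_physiology_index_config()) {
  if (is.data.frame(features)) features <- as.list(features)
  score <- config$offset %||% 0
  for (term in config$terms) {
    x <- features[[term$feature]]
    if (is.null(x) || length(x) != 1L || is.na(x)) {
      stop("physiology index config references missing feature '",
           term$feature, "'")
    }
    score <- score + term$weight * (x - (term$center %||% 0)) / (term$scale %||% 1)
  }
  score
}

#' @rdname physiology_index
#' @export
default_physiology_index_config <- function() {
  # Placeholder weighting (non-authoritative): penalizes strong sag and
  # very fast membranes, the qualitative signature of non-IT cells. Typical
  # regular-spiking pyramidal cells score well below the gate of 5.
  list(offset = 0,
       terms = list(
         list(feature = "sag_ratio", weight = 2, center = 1, scale = 0.25),
         list(feature = "tc_ms", weight = -1, center = 40, scale = 20)
       ))
}

#' Assemble the passive-property set for one cell
#'
#' Convenience wrapper running every passive measurement on a
#' hyperpolarizing-step recording and enforcing the `Cin = TC / Rin`
#' identity.
#'
#' @param rec A current-clamp [recording()] of hyperpolarizing steps.
#' @return List of class `passive_properties`: `rmp`, `r_in`, `tc`, `c_in`,
#'   `sag_ratio`.
#' @export
passive_properties <- function(rec) {
  rmp <- mean(vapply(rec$sweeps, resting_membrane_potential, numeric(1)))
  r_in <- as.numeric(input_resistance(rec))
  tc <- as.numeric(membrane_time_constant(rec))
  structure(list(rmp = rmp, r_in = r_in, tc = tc,
                 c_in = input_capacitance(tc, r_in),
                 sag_ratio = as.numeric(sag_ratio(rec))),
            class = "passive_properties")
}
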