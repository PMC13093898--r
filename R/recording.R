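#' Step command metadata
#'
#' Describes the rectangular command applied during a sweep: a step of
#' `amplitude` (pA in current clamp, mV in voltage clamp) starting `onset`
#' seconds after sweep start and lasting `duration` seconds, on top of
#' `baseline_level`. Sample `i` (0-based) corresponds to time
#' `i / sampling_rate`; the step occupies the half-open interval
#' `[onset, onset + duration)`.
#'
#' @param amplitude Step amplitude relative to baseline (pA or mV).
#' @param onset Step onset in seconds from sweep start.
#' @param duration Step duration in seconds.
#' @param baseline_level Holding level outside the step (pA or mV).
#' @return An object of class `step_command`.
#' @export
step_command <- function(amplitude, onset, duration, baseline_level = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (!is.numeric(onset) || onset < 0) stop("step onset must be >= 0")
  if (!is.numeric(duration) || duration <= 0) stop("step duration must be > 0")
  structure(
    list(amplitude = amplitude, onset = onset, duration = duration,
         baseline_level = baseline_level),
    class = "step_command"
  )
}

#' A single episodic sweep
#'
#' One uniformly sampled trace (membrane potential in mV for current clamp,
#' membrane current in pA for voltage clamp) together with the command step
#' that was applied while it was acquired.
#'
#' @param samples Numeric vector of signal values.
#' @param sampling_rate Sampling rate in Hz.
#' @param command A [step_command()].
#' @param sweep_index Integer position of the sweep within its recording.
#' @return An object of class `sweep`.
#' @export
sweep <- function(samples, sampling_rate, command, sweep_index = 1L) {
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         command = command,
         sweep_index = as.integer(sweep_index)),
    class = "sweep"
  )
}

sweep_duration <- function(sw) length(sw$samples) / sw$sampling_rate

#' An episodic recording from one cell
#'
#' An ordered set of sweeps sharing a sampling rate and clamp mode, plus the
#' metadata the analysis needs: which protocol was run, which experimental
#' arm the cell belongs to, and the holding level.
#'
#' @param sweeps List of [sweep()] objects.
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param cell_id Character cell identifier.
#' @param group_label One of `"control"`, `"PAE_saline"`, `"PAE_NBOH"`.
#' @param holding_level Holding potential (mV, voltage clamp) or bias
#'   current context (pA, current clamp).
#' @param protocol_tag One of `"fi_steps"`, `"rheobase_steps"`,
#'   `"hyperpolarizing_steps"`, `"sepsc"`.
#' @return An object of class `recording`.
#' @export
recording <- function(sweeps, clamp_mode, cell_id, group_label,
                      holding_level = NA_real_, protocol_tag) {
  clamp_mode <- match.arg(clamp_mode, c("current_clamp", "voltage_clamp"))
  group_label <- match.arg(group_label, c("control", "PAE_saline", "PAE_NBOH"))
  protocol_tag <- match.arg(protocol_tag,
                            c("fi_steps", "rheobase_steps",
                              "hyperpolarizing_steps", "sepsc"))
  rec <- structure(
    list(sweeps = sweeps, clamp_mode = clamp_mode, cell_id = cell_id,
         group_label = group_label, holding_level = holding_level,
         protocol_tag = protocol_tag),
    class = "recording"
  )
  viol <- validate_recording(rec)
  if (length(viol) > 0L) {
    stop("invalid recording: ", paste(viol, collapse = "; "))
  }
  rec
}

#' Validate a recording against its structural invariants
#'
#' Checks every type invariant (positive uniform sampling rate, non-empty
#' finite samples, command fitting inside the sweep, legal labels) and
#' returns human-readable violation messages rather than raising, so that a
#' batch ingest can report all problems at once.
#'
#' @param rec A `recording` (or any list shaped like one).
#' @return Character vector of violations; empty when the recording is valid.
#' @export
validate_recording <- function(rec) {
  v <- character()
  if (!length(rec$sweeps)) {
    return("recording has no sweeps")
  }
  if (!rec$clamp_mode %in% c("current_clamp", "voltage_clamp")) {
    v <- c(v, sprintf("clamp_mode '%s' is not current_clamp/voltage_clamp",
                      rec$clamp_mode))
  }
  if (!rec$group_label %in% c("control", "PAE_saline", "PAE_NBOH")) {
    v <- c(v, sprintf("group_label '%s' is not a study arm", rec$group_label))
  }
  rates <- vapply(rec$sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(rates)) > 1L) {
    v <- c(v, "non-uniform sampling: sweeps have mixed sampling rates")
  }
  for (i in seq_along(rec$sweeps)) {
    s <- rec$sweeps[[i]]
    if (!is.numeric(s$sampling_rate) || s$sampling_rate <= 0) {
      v <- c(v, sprintf("sweep %d: sampling_rate must be > 0", i))
      next
    }
    if (!length(s$samples)) {
      v <- c(v, sprintf("sweep %d: samples empty", i))
      next
    }
    if (!all(is.finite(s$samples))) {
      v <- c(v, sprintf("sweep %d: samples contain non-finite values", i))
    }
    cmd <- s$command
    if (is.null(cmd)) {
      v <- c(v, sprintf("sweep %d: command metadata missing", i))
    } else {
      if (cmd$onset < 0) {
        v <- c(v, sprintf("sweep %d: command onset < 0", i))
      }
      if (cmd$onset + cmd$duration > sweep_duration(s) + 1e-12) {
        v <- c(v, sprintf("sweep %d: command onset + duration exceeds sweep length", i))
      }
    }
  }
  v
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> cell %s [%s]  %s, %s\n", x$cell_id, x$group_label,
              x$protocol_tag, x$clamp_mode))
  cat(sprintf("  %d sweeps @ %g kHz, %.3g s each\n", length(x$sweeps),
              x$sweeps[[1]]$sampling_rate / 1000,
              sweep_duration(x$sweeps[[1]])))
  invisible(x)
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep %d> %d samples @ %g Hz, step %+g from %gs for %gs\n",
              x$sweep_index, length(x$samples), x$sampling_rate,
              x$command$amplitude, x$command$onset, x$command$duration))
  invisible(x)
}
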