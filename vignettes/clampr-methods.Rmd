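---
title: "Models and methods behind clampr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clampr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampr)
```

clampr re-implements, as tested and reusable code, the two analysis chains
of a whole-cell patch-clamp study of prefrontal layer-5 pyramidal neurons
in a prenatal-alcohol-exposure (PAE) mouse model with a psychedelic
(25CN-NBOH) treatment arm: intrinsic-excitability and passive-membrane
feature extraction from current-clamp step protocols, and spontaneous
excitatory postsynaptic current (sEPSC) detection from 30-s voltage-clamp
sweeps, followed by quality control and a three-arm group comparison.
Because the original recordings are not publicly deposited, the package
pairs every analysis stage with a seeded synthetic-recording generator
with known ground truth, so that each estimator is validated by parameter
recovery rather than by comparison to irreproducible numbers.

## The signal model

All analyses operate on episodic sweeps: uniformly sampled traces
(nominally 20 kHz) with known rectangular command steps. Sample `i`
(0-based) sits at time `i / sampling_rate`; a step occupies the half-open
interval `[onset, onset + duration)`. Command metadata is mandatory —
steps are never inferred from the recorded trace, because every estimator
below assumes the commanded current or voltage is known exactly.

## Intrinsic excitability (current clamp)

**Spike detection.** A spike candidate is an upward crossing of the rise
slope dV/dt through 10 mV/ms (central differences, mV/ms), assigned to the
first subsequent local voltage maximum. Candidates must rise at least 2 mV
from the crossing to the peak — without this prominence guard, wideband
measurement noise (0.2 mV at 20 kHz gives dV/dt noise of ~3 mV/ms)
produces spurious crossings on any segment whose underlying slope exceeds
a few mV/ms. Candidates peaking below −10 mV are never counted; those that
nonetheless rose ≥ 15 mV are reported separately as blocked-spike stubs,
the signature of depolarization block.

**Waveform features** are measured on the first spike of a sweep:
threshold (voltage at the first rising sample with dV/dt ≥ 10 mV/ms), peak,
amplitude (peak − threshold), half-width (time between the two crossings
of threshold + amplitude/2, linearly interpolated between samples — the
interpolation rule is a package choice), and the extrema of dV/dt over the
spike extent for the maximum rise and decay slopes.

**f–I curve.** Firing frequency is the spike count per 1-s step. The gain
is the ordinary least-squares slope of frequency on current from the 0-pA
sweep up to the injection at which the maximum frequency is attained (ties
broken to the lowest such current, making the rule deterministic); the
total spike output is the spike sum over the same range, so appending
sweeps above that current changes neither. The 0-pA point is included in
the regression; some laboratories start at the first suprathreshold step,
which would change gain values systematically.

**Rheobase and latency** come from the fine-step (2-s) protocol: the
smallest amplitude whose sweep contains a spike, and the onset-to-first-
threshold-crossing interval on that sweep. Repetitions are combined by the
mean, a package choice (the combiner is rarely stated in methods
sections).

## Passive membrane properties

From small hyperpolarizing steps, sweeps are averaged point-wise per step
amplitude *before* measurement; averaging first reduces the outward bias
that noise puts on any extremum-based measure. The input resistance is the
maximum voltage deflection during the step (relative to the 100-ms
pre-step baseline mean) divided by the injected current; the membrane time
constant is a bounded Levenberg–Marquardt single-exponential fit from step
onset to the peak deflection (tau in (0.1, 200] ms); the input capacitance
is the exact identity Cin = TC/Rin (ms/MΩ = nF); and the sag ratio is the
peak deflection over the mean deflection of the last 50 ms of the step.

One numerical choice matters here: the "maximum response" is taken on a
2-ms moving average of the averaged trace. The unfiltered extremum of even
a 30-sweep average is biased outward by the expected maximum of ~20,000
residual noise samples (about 4 standard errors), which at a 1.6–4 mV
deflection is a 4–9% error in Rin; the 2-ms filter removes this bias while
being two orders of magnitude faster than the membrane charge, so it does
not clip the true peak. The sag ratio is baseline-relative throughout and
therefore invariant to any constant offset of the sweep.

The physiology index used as a cell-classification gate is a weighted
combination of features whose exact published form lives in prior
literature not reproduced here; clampr ships it as a pluggable
configuration (`default_physiology_index_config()` is an explicitly
non-authoritative placeholder combining sag and time-constant terms), and
the only contractual use is the inclusion gate `score < 5`.

## sEPSC detection (voltage clamp)

Each 30-s sweep starts with a −5 mV / 250 ms test pulse; the first second
of every sweep is discarded and the remaining 29 s analyzed, so frequency
is events per 29 s. The test pulse is used for monitoring: series
resistance from the peak transient (Rs = |command| / |peak|) and input
resistance from the steady state of the last 50 ms of the pulse.

Detection follows the published settings of the commercial detector used
in the field (negative peaks, 5-ms local maximum period, 30-ms decay
search period, 8-pA threshold, 10-ms search period, 1-ms averaged
baseline, curved baseline and threshold), whose internal semantics are not
published. clampr's concrete semantics are:

* The **curved baseline** is a running median over ten decay search
  periods (computed on a 1-ms decimated grid), smoothed by a 51-ms moving
  average and interpolated back — it tracks drifts with periods of seconds
  while being insensitive to the 10–30 ms events themselves. The detection
  threshold is this curve minus 8 pA.
* An **event peak** is a below-threshold sample that is the signal minimum
  within ± the local maximum period (earliest sample on exact ties). This
  single rule both finds peaks and implements the merge semantics: two
  troughs closer than the period yield one event, the most negative
  extremum winning. It also finds events that arrive while the trace is
  still below threshold on the tail of a preceding event — a crossing-only
  reading misses those entirely and caps recall near 0.88 at 5 Hz, below
  any useful quality bar.
* The **onset** is found by walking back from the peak (at most one search
  period, never past the previous peak) to the last sample at or above the
  baseline curve; if the trace stays below baseline throughout, the onset
  is the intervening signal maximum. The per-event baseline current is the
  1-ms mean before the onset, and the amplitude is that baseline minus the
  peak value, which makes amplitudes invariant to constant offsets.
* The blinded manual rejection of the original workflow is replaced by an
  automated surrogate with configurable kinetic criteria: 10–90% rise time
  in [0.1, 5] ms, a per-event log-linear decay fit in [1, 50] ms, and
  amplitudes between the detection threshold and ten times it. The rise is
  measured on a 5-sample smoothed segment as the ascent above the foot of
  the final rise (the depth minimum over the 3 ms before the 90% crossing),
  so a summated pair of events is judged by its own flank rather than the
  whole complex; the decay fit is truncated at the following event's
  onset for the same reason. One-sample artifacts smear into flat-topped
  pulses whose rise measures ~0 and whose decay cannot be fit, so the
  criteria reject them. This is a documented stand-in, not a claim of
  equivalence to a human analyst.

Per-sweep statistics mirror the study: frequency = accepted events / 29 s;
amplitude averaged within the sweep; the decay time constant from a
single-exponential fit to the averaged event (events aligned at their
peaks — alignment is a package choice — from 2 ms pre-peak to one decay
search period post-peak, each baseline-subtracted). Two to three sweeps
per cell are combined by the mean of per-sweep summaries.

## Quality control

Cells are excluded when the baseline resting potential is more depolarized
than −50 mV or the uncompensated series resistance exceeds 35 MΩ — both
strict inequalities, so boundary values pass — and included only when they
co-express a regular-spiking pattern and a physiology index below 5.
"Regular spiking" is not operationalized in the source literature; clampr
uses a documented, configurable surrogate: no initial doublet (first
interspike interval at least half the median interval on the lowest sweep
at least 50 pA above rheobase with ≥ 3 spikes) and no blocked-spike stubs
at currents up to twice rheobase.

## Group statistics

Every scalar feature is compared across the three arms by a Kruskal–Wallis
omnibus test followed by three pairwise contrasts. The default pairwise
scheme is the `auto` policy — Welch's t when Shapiro–Wilk rejects
normality in neither group, Mann–Whitney otherwise — with Holm adjustment
within the three contrasts of a feature; Dunn's rank contrasts after
Kruskal–Wallis are available (`correction = "dunn_kw"`, implemented with
tie correction since no installed package provides them). The exact
per-panel test choices of the original study are not in its available
text, so these defaults are documented as the package's own policy, not
asserted as the study's. f–I curves are compared by a cell-level
permutation test on the maximum absolute difference of group mean
frequencies across the current grid (max-T); the statistic is symmetric in
the two groups and the permutation stream is seeded, so p-values are
reproducible and invariant to group relabeling. Under the global null the
per-contrast type-I error is ~5% and the Holm-corrected family-wise error
stays at or below 5% (both verified by simulation in the test suite).

## The synthetic cohort

The generator exists so that every stage above is testable offline with
known truth; it emulates the study's design, not its biology in detail.

* **Membrane**: a leaky integrate-and-fire neuron (R·C time constant),
  integrated by forward Euler at the 50-µs sampling interval; the
  passive-limit tests hold the simulated trace to within 0.1% of the
  closed-form step response. The membrane is biased to −65 mV before each
  step, as in the study protocol.
* **Spikes** are pasted stereotypes: a half-cosine rise from threshold to
  peak and a half-cosine fall to reset, so threshold, amplitude, maximum
  slopes and half-width all have closed-form designed values
  (`ap_waveform_design()`), making waveform-feature tests exact by
  construction rather than dependent on a biophysical model.
* **Sag** is an Ih-like relaxation recovering a fraction of the
  steady-state deflection with its own time constant, activating five
  membrane time constants after step onset. The delay makes the
  plateau-to-peak relation exactly 1 − sag_conductance (the measured sag
  ratio is 1/(1 − s) to better than 1%); without it the sag state charges
  during the passive rise and no simple designed value exists.
* **f–I protocols** can fire through the integrate-and-fire dynamics or
  pace a designed linear rate code (`rate = gain × (I − rheobase)`, capped
  at a maximum rate). The cohort generator uses the designed mode so that
  group effect multipliers act on the gain exactly.
* **sEPSC sweeps**: Poisson event trains (over the 29-s analysis window)
  of negative bi-exponential kernels peak-normalized to lognormal
  amplitudes, on a sinusoidal drifting baseline with white Gaussian noise,
  preceded by the test-pulse current response. The drift exercises the
  curved-baseline handling; the lognormal law exercises amplitude
  averaging.
* **Three arms**: cell-level parameters are lognormal draws around typical
  layer-5 pyramidal values (documented in `cohort_base_params()`; the
  source study reports no such distributions, so these are explicit
  choices) scaled by per-arm multipliers. The defaults
  (`default_group_effects()`) are qualitative stand-ins for the directions
  the study reports, not published magnitudes: PAE+saline reduces the
  sEPSC rate (×0.6), f–I gain (×0.7) and maximum rate (×0.75), broadens
  spikes (×1.15) and slows the sEPSC decay (×1.2); PAE+NBOH restores the
  rate (×0.95), maximum rate (×0.95) and decay (×1.0) while gain (×0.8)
  and half-width (×1.08) recover only partially. Every multiplier is
  overridable in `cohort_design()`.

What passing tests on this cohort do **not** show: the generator has white
(not 1/f or synaptically colored) noise, stereotyped spikes rather than
conductance dynamics, no series-resistance filtering of event kinetics, no
temperature or animal-level structure, and sinusoidal rather than
irregular drift. Recovery results on it validate the estimators'
correctness, not their robustness to every pathology of real recordings.

## Problem sizes and determinism

The shipped checks use 50-cell recovery sweeps, 500 randomized
detector-oracle traces, 20-sweep detection-quality runs, 1000–2000
simulated null replicates for calibration, and a 12-cells-per-arm cohort
for the end-to-end comparison — sizes at which every Monte-Carlo margin in
the assertions is several standard errors wide. All randomness flows from
explicit integer seeds (the package restores the caller's RNG state), and
rerunning any pipeline configuration reproduces its tables bit for bit.

## Known limitations

ABF files are not read directly (no reader is bundled); recordings arrive
through the documented JSON + CSV fixture format, to which ABF can be
converted externally. The detector semantics are a faithful concretization
of published settings, not a reverse-engineered copy of the commercial
tool. The physiology index is a placeholder configuration. Animal-level
nesting is carried through identifiers but not modeled; all tests treat
cells as independent units, as the comparison layer does.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  design = cohort_design(cells_per_group = 12, seed = 1),
  stats = stats_config(permutations = 5000, seed = 1),
  out_dir = "clampr_out")
res <- run_pipeline(cfg)
subset(res$comparisons, feature == "sepsc_frequency_Hz")
plot_fi_curves(res$fi_curves,
               res$features$group_label[res$qc$passed])
```
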