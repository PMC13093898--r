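hyp_recording <- function(r_m = 150, c_m = 100, amp = -10, n_sweeps = 1,
                          noise = 0, sag = 0, sag_tau = 120, dur = 1,
                          seed = 1) {
  mp <- membrane_params(r_m = r_m, c_m = c_m, spike_threshold = Inf,
                        sag_conductance = sag, sag_tau_ms = sag_tau,
                        noise_sd = noise)
  simulate_current_clamp(
    mp, hyperpolarizing_protocol(amp, n_sweeps, duration = dur,
                                 pre = 0.3, post = 0.2),
    seed = seed)
}

test_that("resting potential is the 100-ms pre-step mean", {
  sw <- sweep(rep(-65, 20000), 20000, step_command(-10, 0.5, 0.4))
  expect_equal(resting_membrane_potential(sw), -65)
  set.seed(31)
  sw_noisy <- sweep(-65 + rnorm(20000, sd = 0.5), 20000,
                    step_command(-10, 0.5, 0.4))
  # estimator of a 2000-sample mean: SE = 0.5/sqrt(2000)
  expect_lt(abs(resting_membrane_potential(sw_noisy) + 65),
            3 * 0.5 / sqrt(2000))
  short <- sweep(rep(-65, 2000), 20000, step_command(-10, 0.05, 0.04))
  expect_error(resting_membrane_potential(short), "insufficient baseline")
})

test_that("input resistance follows Ohm's law on the noiseless membrane", {
  rec <- hyp_recording(r_m = 150, amp = -10)
  expect_equal(as.numeric(input_resistance(rec)), 150, tolerance = 0.01)
})

test_that("a zero-amplitude step is rejected", {
  rec <- hyp_recording()
  rec$sweeps[[1]]$command$amplitude <- 0
  expect_error(input_resistance(rec), "zero-amplitude")
})

test_that("input resistance is recovered within 2% from 30 noisy sweeps", {
  rec <- hyp_recording(r_m = 120, amp = -20, n_sweeps = 30, noise = 0.2,
                       seed = 21)
  expect_lt(abs(as.numeric(input_resistance(rec)) - 120) / 120, 0.02)
})

test_that("the membrane time constant fit recovers tau", {
  # noiseless: tau = 150 MOhm * 120 pF = 18 ms
  rec <- hyp_recording(r_m = 150, c_m = 120, amp = -20)
  expect_equal(as.numeric(membrane_time_constant(rec)), 18,
               tolerance = 0.005)
  # noisy, 30 sweeps: within 5%
  rec_n <- hyp_recording(r_m = 150, c_m = 120, amp = -20, n_sweeps = 30,
                         noise = 0.2, seed = 8)
  expect_lt(abs(as.numeric(membrane_time_constant(rec_n)) - 18) / 18, 0.05)
  # with sag the pre-peak window is still a clean single exponential
  rec_s <- hyp_recording(r_m = 150, c_m = 120, amp = -20, sag = 0.2)
  expect_lt(abs(as.numeric(membrane_time_constant(rec_s)) - 18) / 18, 0.10)
})

test_that("input capacitance is TC/Rin with ms/MOhm -> pF units", {
  expect_equal(input_capacitance(18, 120), 150)
  expect_equal(input_capacitance(20, 100), 200)
  expect_error(input_capacitance(18, 0), "input resistance")
  expect_error(input_capacitance(-1, 100), "time constant")
})

test_that("the Cin = TC/Rin identity holds exactly for emitted properties", {
  rec <- hyp_recording(r_m = 140, c_m = 160, amp = -20, n_sweeps = 5,
                       noise = 0.2, seed = 3)
  p <- passive_properties(rec)
  expect_identical(p$c_in, p$tc / p$r_in * 1000)
})

test_that("sag ratio on a constructed piecewise trace is peak over late amplitude", {
  sr <- 20000
  n <- round(1.6 * sr)
  v <- rep(-65, n)
  i_on <- round(0.3 * sr); i_off <- round(1.3 * sr)
  v[(i_on + 1):i_off] <- -73                       # late level: amplitude 8
  v[(i_on + round(0.05 * sr)):(i_on + round(0.25 * sr))] <- -75  # peak: 10
  rec <- recording(list(sweep(v, sr, step_command(-20, 0.3, 1))),
                   "current_clamp", "c", "control",
                   protocol_tag = "hyperpolarizing_steps")
  expect_equal(as.numeric(sag_ratio(rec)), 10 / 8, tolerance = 0.005)
})

test_that("a pure RC membrane has sag ratio 1 and the generator sag gives 1/(1-s)", {
  rec <- hyp_recording(r_m = 150, c_m = 100, amp = -20, dur = 1)  # 7+ tau
  expect_equal(as.numeric(sag_ratio(rec)), 1, tolerance = 0.002)
  rec_s <- hyp_recording(r_m = 150, c_m = 100, amp = -20, sag = 0.2,
                         dur = 1.5)
  expect_equal(as.numeric(sag_ratio(rec_s)), 1.25, tolerance = 0.0125)
})

test_that("sag ratio is invariant to a constant offset and needs a 150-ms step", {
  rec <- hyp_recording(r_m = 150, c_m = 100, amp = -20, sag = 0.15,
                       n_sweeps = 3, noise = 0.2, seed = 5)
  s0 <- as.numeric(sag_ratio(rec))
  rec_off <- rec
  for (k in seq_along(rec_off$sweeps)) {
    rec_off$sweeps[[k]]$samples <- rec_off$sweeps[[k]]$samples + 7
  }
  expect_equal(as.numeric(sag_ratio(rec_off)), s0, tolerance = 1e-12)

  short <- hyp_recording(dur = 0.1)
  expect_error(sag_ratio(short), "step too short")
})

test_that("the physiology index is the configured weighted combination", {
  feats <- list(sag_ratio = 1.4, tc_ms = 25, r_in_MOhm = 150)
  zero_cfg <- list(terms = list(list(feature = "sag_ratio", weight = 0)))
  expect_equal(physiology_index(feats, zero_cfg), 0)

  cfg <- list(offset = 0.5, terms = list(
    list(feature = "sag_ratio", weight = 2, center = 1, scale = 0.2),
    list(feature = "r_in_MOhm", weight = -1, center = 100, scale = 50)))
  expect_equal(physiology_index(feats, cfg),
               0.5 + 2 * (1.4 - 1) / 0.2 - (150 - 100) / 50)

  bad <- list(terms = list(list(feature = "absent_feature", weight = 1)))
  expect_error(physiology_index(feats, bad), "absent_feature")
})
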