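test_that("the first second (test pulse) is split from the 29-s analysis segment", {
  sr <- 20000
  sw <- sweep(rnorm(30 * sr, sd = 0.1), sr, step_command(-5, 0.01, 0.25, -70))
  parts <- strip_test_pulse(sw)
  expect_equal(length(parts$analysis$samples), 580000L)
  expect_equal(parts$analysis$t0, 1)
  # analysis segment plus the discarded first second account for every sample
  expect_equal(length(parts$analysis$samples) + sr, length(sw$samples))

  short <- sweep(rnorm(1.2 * sr), sr, step_command(-5, 0.01, 0.25, -70))
  expect_error(strip_test_pulse(short), "1.5 s")
})

test_that("the curved baseline is flat on a flat trace and tracks slow drift", {
  sr <- 20000
  n <- 10 * sr
  st <- detection_settings()
  expect_lt(max(abs(estimate_curved_baseline(rep(0, n), sr, st))), 0.1)

  t <- (seq_len(n) - 1) / sr
  drift <- 20 * sin(2 * pi * t / 10)
  expect_lt(max(abs(estimate_curved_baseline(drift, sr, st) - drift)), 1)
})

test_that("events do not drag the curved baseline", {
  sr <- 20000
  n <- 10 * sr
  t <- (seq_len(n) - 1) / sr
  drift <- 20 * sin(2 * pi * t / 10)
  set.seed(9)
  onsets <- sort(runif(50, 0.5, 9.5))
  x <- make_event_trace(n, sr, onsets, rep(20, 50), background = drift)
  base <- estimate_curved_baseline(x, sr, detection_settings())
  event_free <- rep(TRUE, n)
  for (o in onsets) {
    event_free[round(o * sr):(round(o * sr) + round(0.06 * sr))] <- FALSE
  }
  expect_lt(max(abs(base - drift)[event_free]), 2)
})

test_that("a segment shorter than the filter window is rejected", {
  expect_error(estimate_curved_baseline(rep(0, 1000), 20000,
                                        detection_settings()),
               "filter window")
})

test_that("noiseless detection finds each injected kernel once, at its amplitude", {
  sr <- 20000
  n <- 10 * sr
  onsets <- seq(0.5, 9.5, by = 1)
  x <- make_event_trace(n, sr, onsets, rep(20, 10))
  base <- estimate_curved_baseline(x, sr, detection_settings())
  ev <- detect_events(x, base, sr)
  expect_equal(nrow(ev), 10L)
  expect_lt(max(abs(ev$onset_time - onsets)), 0.001)
  expect_lt(max(abs(ev$amplitude - 20)), 0.5)

  flat <- detect_events(rep(0, n), rep(0, n), sr)
  expect_equal(nrow(flat), 0L)
})

test_that("kernels closer than the local maximum period merge into one event", {
  sr <- 20000
  n <- 2 * sr
  x <- make_event_trace(n, sr, c(1.000, 1.003), c(15, 25))
  base <- rep(0, n)
  ev <- detect_events(x, base, sr)
  expect_equal(nrow(ev), 1L)
  # the merged peak is the most negative extremum of the pair
  expect_equal(x[ev$peak_index], min(x))
  want <- oracle_detect_events(x, base, sr, detection_settings())
  expect_equal(ev$peak_index, want$peak_index)
  expect_equal(ev$onset_index, want$onset_index)
})

test_that("detector output equals the exhaustive oracle on randomized micro-traces", {
  set.seed(77)
  sr <- 20000
  for (i in 1:60) {
    n <- 2 * sr
    st <- detection_settings(
      threshold = runif(1, 4, 15),
      local_max_period = runif(1, 2, 8),
      search_period = runif(1, 5, 15),
      decay_search_period = 30)
    n_ev <- rpois(1, 2 * runif(1, 2, 12))
    x <- make_event_trace(n, sr, sort(runif(n_ev, 0.05, 1.9)),
                          runif(n_ev, 10, 40),
                          background = rnorm(n, sd = runif(1, 0.5, 2.5)))
    base <- rep(0, n)
    got <- detect_events(x, base, sr, st)
    want <- oracle_detect_events(x, base, sr, st)
    expect_equal(got$peak_index, want$peak_index)
    expect_equal(got$onset_index, want$onset_index)
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-9)
  }
})

test_that("raising the threshold never increases the event count", {
  sr <- 20000
  n <- 4 * sr
  set.seed(13)
  x <- make_event_trace(n, sr, sort(runif(20, 0.1, 3.8)), runif(20, 8, 35),
                        background = rnorm(n, sd = 2))
  base <- estimate_curved_baseline(x, sr, detection_settings())
  counts <- vapply(c(4, 6, 8, 10, 14), function(thr) {
    nrow(detect_events(x, base, sr, detection_settings(threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("amplitudes are invariant to a constant offset of the whole segment", {
  sr <- 20000
  n <- 6 * sr
  set.seed(14)
  x <- make_event_trace(n, sr, sort(runif(25, 0.1, 5.8)), runif(25, 10, 30),
                        background = rnorm(n, sd = 2))
  st <- detection_settings()
  ev1 <- detect_events(x, estimate_curved_baseline(x, sr, st), sr, st)
  x2 <- x + 50
  ev2 <- detect_events(x2, estimate_curved_baseline(x2, sr, st), sr, st)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_lt(max(abs(ev1$amplitude - ev2$amplitude)), 0.1)
})

test_that("noise rejection keeps physiological events and drops artifacts", {
  sr <- 20000
  n <- 10 * sr
  onsets <- seq(0.5, 9.5, by = 1)
  x <- make_event_trace(n, sr, onsets, rep(20, 10))
  base <- rep(0, n)
  st <- detection_settings()
  ev <- reject_noise_events(detect_events(x, base, sr, st), x, sr, st)
  expect_true(all(ev$accepted))

  # a one-sample square artifact fails the kinetic criteria
  xa <- x
  xa[4 * sr] <- xa[4 * sr] - 30
  eva <- reject_noise_events(detect_events(xa, base, sr, st), xa, sr, st)
  art <- which.min(abs(eva$peak_index - 4 * sr))
  expect_false(eva$accepted[art])
  expect_true(eva$rejection_reason[art] %in% c("rise_time", "decay_fit_failure"))
  expect_equal(sum(eva$accepted), 10L)

  # disabling the criteria accepts everything
  ev_off <- reject_noise_events(detect_events(xa, base, sr, st), xa, sr, st,
                                noise_criteria(enabled = FALSE))
  expect_true(all(ev_off$accepted))
})

test_that("per-sweep statistics use the 29-s denominator and the averaged event", {
  sr <- 20000
  n <- 29 * sr
  onsets <- seq(0.25, 28.9, length.out = 58)
  x <- make_event_trace(n, sr, onsets, rep(20, 58), tau_decay = 6)
  st <- detection_settings()
  ev <- reject_noise_events(detect_events(x, rep(0, n), sr, st), x, sr, st)
  s <- summarize_sweep(ev, x, sr, st)
  expect_equal(s$n_events, 58L)
  expect_equal(s$frequency, 2.0, tolerance = 1e-9)
  expect_equal(s$decay_tc, 6, tolerance = 0.12)       # 2%
  expect_equal(s$mean_amplitude, 20, tolerance = 0.5)

  empty <- summarize_sweep(ev[0, ], x, sr, st)
  expect_equal(empty$frequency, 0)
  expect_true(is.na(empty$decay_tc))
})

test_that("decay time constant is recovered within 10% under noise", {
  sp <- synapse_params(event_rate = 5, amp_mean = 20, amp_cv = 0.3,
                       tau_decay = 8, noise_sd = 2)
  sim <- simulate_sepsc_sweeps(sp, 2, seed = 33)
  res <- analyze_sepsc_recording(sim$recording)
  expect_lt(abs(mean(res$sweep_summaries$decay_tc) - 8) / 8, 0.10)
})

test_that("the test pulse yields Rs and Rin by the stated decomposition", {
  sr <- 20000
  # constructed pulse response: hold 0, peak -500 pA, steady -50 pA
  n <- round(0.3 * sr)
  seg <- numeric(n)
  i_on <- round(0.01 * sr)
  i_off <- round(0.26 * sr)
  t <- (0:(i_off - i_on - 1)) / sr * 1000
  seg[(i_on + 1):i_off] <- -50 + (-500 + 50) * exp(-t / 1.5)
  tp <- list(samples = seg, sampling_rate = sr,
             command = step_command(-5, 0.01, 0.25, -70))
  stats <- test_pulse_monitor(tp)
  expect_equal(stats$r_s, 10, tolerance = 0.01)
  expect_equal(stats$r_in, 100 - stats$r_s, tolerance = 0.5)

  flat <- list(samples = numeric(n), sampling_rate = sr,
               command = step_command(-5, 0.01, 0.25, -70))
  expect_error(test_pulse_monitor(flat), "no detectable transient")
})

test_that("test-pulse monitoring recovers the generator's Rs and Rin within 10%", {
  sp <- synapse_params(noise_sd = 2)
  sim <- simulate_sepsc_sweeps(sp, 3, seed = 19, rs_mohm = 12, rin_mohm = 150)
  res <- analyze_sepsc_recording(sim$recording)
  expect_lt(abs(mean(res$test_pulse$r_s) - 12) / 12, 0.10)
  expect_lt(abs(mean(res$test_pulse$r_in) - 150) / 150, 0.10)
})
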