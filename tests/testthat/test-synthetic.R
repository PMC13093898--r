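test_that("passive membrane obeys Ohm's law at steady state", {
  mp <- membrane_params(r_m = 150, c_m = 100, spike_threshold = Inf,
                        sag_conductance = 0, noise_sd = 0)
  rec <- simulate_current_clamp(mp, hyperpolarizing_protocol(-10, 1, duration = 1))
  v <- rec$sweeps[[1]]$samples
  sr <- rec$sweeps[[1]]$sampling_rate
  expect_equal(mean(v[1:round(0.25 * sr)]), -65, tolerance = 1e-9)
  # late in the 1-s step: deflection -10 pA * 150 MOhm = -1.5 mV
  expect_equal(v[round(1.29 * sr)], -66.5, tolerance = 1e-3)
})

test_that("sag produces a late plateau of (1 - sag_conductance) times the peak", {
  mp <- membrane_params(r_m = 150, c_m = 100, spike_threshold = Inf,
                        sag_conductance = 0.2, sag_tau_ms = 120, noise_sd = 0)
  rec <- simulate_current_clamp(
    mp, hyperpolarizing_protocol(-20, 1, duration = 1.5, pre = 0.3, post = 0.3))
  v <- rec$sweeps[[1]]$samples
  sr <- rec$sweeps[[1]]$sampling_rate
  base <- mean(v[1:round(0.3 * sr)])
  step_idx <- (round(0.3 * sr) + 1):round(1.8 * sr)
  peak <- min(v[step_idx]) - base
  late <- mean(v[(round(1.75 * sr)):round(1.8 * sr)]) - base
  expect_equal(late / peak, 0.8, tolerance = 0.01)
})

test_that("Euler integration matches the closed-form step response within 0.1%", {
  for (sag in c(0, 0.2)) {
    mp <- membrane_params(r_m = 120, c_m = 180, spike_threshold = Inf,
                          sag_conductance = sag, sag_tau_ms = 100,
                          noise_sd = 0)
    rec <- simulate_current_clamp(
      mp, hyperpolarizing_protocol(-20, 1, duration = 1, pre = 0.3, post = 0.2))
    sw <- rec$sweeps[[1]]
    sr <- sw$sampling_rate
    i_on <- round(0.3 * sr)
    idx <- (i_on + 1):round(1.3 * sr)
    t_s <- (idx - 1 - i_on) / sr
    expected <- -65 + rc_step_deflection(t_s, 120, 180, -20, sag_frac = sag,
                                         sag_tau_ms = 100)
    d_ss <- abs(120 * -20 / 1000)
    expect_lt(max(abs(sw$samples[idx] - expected)) / d_ss, 0.001)
  }
})

test_that("simulation is a pure function of parameters and seed", {
  mp <- membrane_params()
  a <- simulate_current_clamp(mp, fi_protocol(max_pa = 100), seed = 5)
  b <- simulate_current_clamp(mp, fi_protocol(max_pa = 100), seed = 5)
  d <- simulate_current_clamp(mp, fi_protocol(max_pa = 100), seed = 6)
  expect_identical(lapply(a$sweeps, `[[`, "samples"),
                   lapply(b$sweeps, `[[`, "samples"))
  expect_false(identical(a$sweeps[[1]]$samples, d$sweeps[[1]]$samples))

  sp <- synapse_params()
  s1 <- simulate_sepsc_sweeps(sp, 2, seed = 3)
  s2 <- simulate_sepsc_sweeps(sp, 2, seed = 3)
  expect_identical(s1$recording$sweeps[[2]]$samples,
                   s2$recording$sweeps[[2]]$samples)
  expect_identical(s1$events, s2$events)
})

test_that("protocol preconditions are enforced", {
  expect_error(cc_protocol("fi_steps", 0, duration = 1, pre = 0.1),
               "missing baseline")
  expect_error(cc_protocol("fi_steps", 0, duration = 0), "non-positive step")
})

test_that("quiet synapse simulation gives a flat post-pulse trace at baseline", {
  sp <- synapse_params(event_rate = 0, noise_sd = 0, drift_amplitude = 0)
  sim <- simulate_sepsc_sweeps(sp, 1, seed = 1)
  sw <- sim$recording$sweeps[[1]]
  post <- sw$samples[(round(1 * sw$sampling_rate) + 1):length(sw$samples)]
  expect_lt(max(abs(post)), 1e-9)
  expect_equal(nrow(sim$events), 0L)
})

test_that("every kernel peaks at exactly its drawn amplitude before noise", {
  sp <- synapse_params(event_rate = 3, amp_mean = 20, amp_cv = 0,
                       noise_sd = 0, drift_amplitude = 0)
  sim <- simulate_sepsc_sweeps(sp, 1, seed = 11)
  x <- sim$recording$sweeps[[1]]$samples
  sr <- sim$recording$sweeps[[1]]$sampling_rate
  tr <- sim$events
  iso <- which(c(Inf, diff(tr$onset_time)) > 0.1 &
                 c(diff(tr$onset_time), Inf) > 0.1)
  expect_gt(length(iso), 5)
  for (i in iso) {
    pk_idx <- round(tr$peak_time[i] * sr) + 1L
    expect_equal(min(x[(pk_idx - 10):(pk_idx + 10)]), -20, tolerance = 1e-3)
  }
})

test_that("event counts follow the Poisson law over the 29-s usable window", {
  sp <- synapse_params(event_rate = 5, noise_sd = 0, drift_amplitude = 0)
  counts <- vapply(1:200, function(k) {
    nrow(simulate_sepsc_sweeps(sp, 1, seed = 5000 + k)$events)
  }, numeric(1))
  # mean 5 * 29 = 145, SE = sqrt(145/200)
  expect_lt(abs(mean(counts) - 145), 3 * sqrt(145 / 200))
})

test_that("cohort generation is deterministic and produces the declared counts", {
  dsn <- cohort_design(cells_per_group = 2, seed = 4, n_hyp_sweeps = 2,
                       sepsc_sweeps = 1)
  a <- generate_cohort(dsn)
  b <- generate_cohort(dsn)
  expect_equal(length(a$cells), 6L)
  expect_equal(sum(vapply(a$cells, function(c) length(c$recordings),
                          integer(1))), 24L)
  expect_equal(nrow(a$ground_truth), 6L)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$cells[[3]]$recordings$sepsc$sweeps[[1]]$samples,
                   b$cells[[3]]$recordings$sepsc$sweeps[[1]]$samples)
})

test_that("group effect multipliers scale the drawn parameters in expectation", {
  base <- cohort_base_params()
  eff <- default_group_effects()
  draw <- function(group, n) {
    vapply(seq_len(n), function(i) {
      clampr:::draw_cell_params(base, eff[[group]], seed = 7000 + i)$synapse$event_rate
    }, numeric(1))
  }
  ctrl <- draw("control", 50)
  pae <- draw("PAE_saline", 50)
  ratio <- mean(pae) / mean(ctrl)
  # multiplier 0.6; lognormal CV 0.25 over 50 cells -> SE of the ratio ~ 0.03
  expect_lt(abs(ratio - 0.6), 0.09)
})
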