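#' Default per-group effect multipliers
#'
#' Qualitative stand-ins for the direction pattern of the study arms:
#' prenatal alcohol exposure with saline (`PAE_saline`) lowers sEPSC rate,
#' f-I gain and maximum rate, broadens spikes and slows the sEPSC decay;
#' the psychedelic-treated arm (`PAE_NBOH`) largely restores synaptic drive
#' and maximum firing while gain remains reduced. The literature the design
#' emulates reports directions, not magnitudes, so all multipliers are
#' overridable.
#'
#' @return Named list (one entry per arm) of multiplier lists with fields
#'   `event_rate`, `amp_mean`, `fi_gain`, `fi_max_rate`, `half_width`,
#'   `tau_decay`.
#' @export
default_group_effects <- function() {
  list(
    control    = list(event_rate = 1,    amp_mean = 1, fi_gain = 1,
                      fi_max_rate = 1,    half_width = 1,    tau_decay = 1),
    PAE_saline = list(event_rate = 0.6,  amp_mean = 1, fi_gain = 0.7,
                      fi_max_rate = 0.75, half_width = 1.15, tau_decay = 1.2),
    PAE_NBOH   = list(event_rate = 0.95, amp_mean = 1, fi_gain = 0.8,
                      fi_max_rate = 0.95, half_width = 1.08, tau_decay = 1)
  )
}

#' Base distributions for synthetic cells
#'
#' Means and coefficients of variation of the lognormal cell-level
#' parameter draws, loosely centred on typical layer-5 pyramidal values.
#'
#' @return Named list of distribution parameters.
#' @export
cohort_base_params <- function() {
  list(r_m_mean = 150, r_m_cv = 0.18,
       c_m_mean = 150, c_m_cv = 0.15,
       sag_conductance = 0.12, sag_tau_ms = 120,
       noise_sd_mv = 0.2,
       fi_gain_mean = 0.2, fi_gain_cv = 0.1,
       fi_max_rate_mean = 40, fi_max_rate_cv = 0.1,
       ap_rise_ms = 0.4, ap_fall_ms = 1.2,
       event_rate_mean = 5, event_rate_cv = 0.25,
       amp_mean = 20, amp_mean_cv = 0.15, amp_cv = 0.3,
       tau_rise = 0.5, tau_decay_mean = 8, tau_decay_cv = 0.1,
       noise_sd_pa = 2, drift_amplitude = 20, drift_period = 10,
       rs_mean = 15, rs_sd = 3)
}

#' Cohort design
#'
#' Describes a three-arm synthetic cohort: how many cells per group, the
#' per-group effect multipliers, the base parameter distributions, and the
#' per-cell protocol sizes.
#'
#' @param cells_per_group Cells per study arm (>= 1).
#' @param seed Integer master seed; every random draw derives from it.
#' @param group_effects Per-group multipliers, as [default_group_effects()].
#' @param base Base distributions, as [cohort_base_params()].
#' @param n_hyp_sweeps Hyperpolarizing sweeps per cell.
#' @param sepsc_sweeps Candidate sEPSC sweep counts per cell (the study
#'   analyzed two to three per cell; one count is drawn per cell).
#' @param fi_max_pa,fi_step_pa f-I protocol range and step.
#' @param rheo_step_pa Rheobase protocol step size (pA, in 5-10).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(cells_per_group = 12, seed = 1,
                          group_effects = default_group_effects(),
                          base = cohort_base_params(),
                          n_hyp_sweeps = 30, sepsc_sweeps = c(2, 3),
                          fi_max_pa = 400, fi_step_pa = 50,
                          rheo_step_pa = 5) {
  stopifnot(cells_per_group >= 1)
  for (g in names(group_effects)) {
    if (any(unlist(group_effects[[g]]) <= 0)) {
      stop("group effect multipliers must be > 0")
    }
  }
  structure(list(cells_per_group = cells_per_group, seed = seed,
                 group_effects = group_effects, base = base,
                 n_hyp_sweeps = n_hyp_sweeps, sepsc_sweeps = sepsc_sweeps,
                 fi_max_pa = fi_max_pa, fi_step_pa = fi_step_pa,
                 rheo_step_pa = rheo_step_pa),
            class = "cohort_design")
}

# Draw one cell's ground-truth parameters (membrane + synapse + Rs) for a
# group, applying the group's multipliers. Lognormal draws with the stated
# mean and CV.
draw_cell_params <- function(base, eff, seed) {
  rln <- function(mean, cv) {
    if (cv <= 0) return(mean)
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(1, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, {
    r_m <- rln(base$r_m_mean, base$r_m_cv)
    c_m <- rln(base$c_m_mean, base$c_m_cv)
    fi_gain <- rln(base$fi_gain_mean, base$fi_gain_cv) * eff$fi_gain
    fi_max <- rln(base$fi_max_rate_mean, base$fi_max_rate_cv) * eff$fi_max_rate
    event_rate <- rln(base$event_rate_mean, base$event_rate_cv) * eff$event_rate
    amp_mean <- rln(base$amp_mean, base$amp_mean_cv) * eff$amp_mean
    tau_decay <- rln(base$tau_decay_mean, base$tau_decay_cv) * eff$tau_decay
    rs <- min(30, max(6, rnorm(1, base$rs_mean, base$rs_sd)))
    mp <- membrane_params(
      r_m = r_m, c_m = c_m,
      sag_conductance = base$sag_conductance, sag_tau_ms = base$sag_tau_ms,
      noise_sd = base$noise_sd_mv,
      ap_rise_ms = base$ap_rise_ms * eff$half_width,
      ap_fall_ms = base$ap_fall_ms * eff$half_width,
      fi_mode = "designed", fi_gain = fi_gain, fi_max_rate = fi_max)
    sp <- synapse_params(event_rate = event_rate, amp_mean = amp_mean,
                         amp_cv = base$amp_cv, tau_rise = base$tau_rise,
                         tau_decay = tau_decay, noise_sd = base$noise_sd_pa,
                         drift_amplitude = base$drift_amplitude,
                         drift_period = base$drift_period)
    list(membrane = mp, synapse = sp, rs_mohm = rs)
  })
}

#' Simulate all four recordings of one cell
#'
#' Runs the f-I, rheobase, hyperpolarizing and sEPSC protocols for a single
#' cell with the given ground-truth parameters.
#'
#' @param mp A [membrane_params()].
#' @param sp A [synapse_params()].
#' @param rs_mohm True series resistance (MOhm) for the test pulse.
#' @param cell_id,group_label Metadata.
#' @param seed Integer seed.
#' @param design A [cohort_design()] supplying protocol sizes.
#' @param n_sepsc_sweeps Number of sEPSC sweeps for this cell.
#' @return List with `recordings` (named list: `fi_steps`,
#'   `rheobase_steps`, `hyperpolarizing_steps`, `sepsc`) and `sepsc_truth`
#'   (true event table).
#' @export
simulate_cell <- function(mp, sp, rs_mohm, cell_id, group_label, seed,
                          design = cohort_design(), n_sepsc_sweeps = 3) {
  rheo_true <- (mp$spike_threshold - mp$bias_mv) / mp$r_m * 1000
  step <- design$rheo_step_pa
  rheo_amps <- seq(floor(0.85 * rheo_true / step) * step,
                   ceiling(1.25 * rheo_true / step) * step, by = step)
  recs <- list(
    fi_steps = simulate_current_clamp(
      mp, fi_protocol(design$fi_max_pa, design$fi_step_pa),
      seed = child_seed(seed, 1), cell_id = cell_id,
      group_label = group_label),
    rheobase_steps = simulate_current_clamp(
      mp, rheobase_protocol(rheo_amps),
      seed = child_seed(seed, 2), cell_id = cell_id,
      group_label = group_label),
    hyperpolarizing_steps = simulate_current_clamp(
      mp, hyperpolarizing_protocol(n_sweeps = design$n_hyp_sweeps),
      seed = child_seed(seed, 3), cell_id = cell_id,
      group_label = group_label)
  )
  sepsc <- simulate_sepsc_sweeps(sp, n_sweeps = n_sepsc_sweeps,
                                 seed = child_seed(seed, 4),
                                 rs_mohm = rs_mohm, rin_mohm = mp$r_m,
                                 cell_id = cell_id,
                                 group_label = group_label)
  recs$sepsc <- sepsc$recording
  list(recordings = recs, sepsc_truth = sepsc$events)
}

#' Generate a seeded three-arm synthetic cohort
#'
#' Draws per-cell ground-truth parameters from the base distributions
#' scaled by the group effect multipliers, then simulates the four study
#' protocols for every cell. Deterministic given the design seed.
#'
#' @param design A [cohort_design()].
#' @return List with `cells` (named list per cell: `cell_id`,
#'   `group_label`, `params`, `recordings`, `sepsc_truth`) and
#'   `ground_truth` (one data.frame row per cell with every true
#'   parameter).
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- names(design$group_effects)
  cells <- list()
  gt <- list()
  idx <- 0L
  for (g in groups) {
    for (k in seq_len(design$cells_per_group)) {
      idx <- idx + 1L
      cell_id <- sprintf("%s_%02d", g, k)
      par_seed <- child_seed(design$seed, idx)
      pars <- draw_cell_params(design$base, design$group_effects[[g]],
                               par_seed)
      n_sepsc <- with_seed(child_seed(par_seed, 99),
                           sample(design$sepsc_sweeps, 1))
      sim <- simulate_cell(pars$membrane, pars$synapse, pars$rs_mohm,
                           cell_id, g, seed = child_seed(design$seed, 1000L + idx),
                           design = design, n_sepsc_sweeps = n_sepsc)
      mp <- pars$membrane
      cells[[cell_id]] <- list(cell_id = cell_id, group_label = g,
                               params = pars,
                               recordings = sim$recordings,
                               sepsc_truth = sim$sepsc_truth)
      gt[[cell_id]] <- data.frame(
        cell_id = cell_id, group_label = g,
        r_m = mp$r_m, c_m = mp$c_m, tau_m_ms = tau_m_ms(mp),
        sag_conductance = mp$sag_conductance,
        spike_threshold = mp$spike_threshold,
        rheobase_analytic = (mp$spike_threshold - mp$bias_mv) / mp$r_m * 1000,
        fi_gain = mp$fi_gain, fi_max_rate = mp$fi_max_rate,
        ap_rise_ms = mp$ap_rise_ms, ap_fall_ms = mp$ap_fall_ms,
        event_rate = pars$synapse$event_rate,
        amp_mean = pars$synapse$amp_mean,
        tau_decay = pars$synapse$tau_decay,
        rs_mohm = pars$rs_mohm,
        n_sepsc_sweeps = n_sepsc,
        stringsAsFactors = FALSE)
    }
  }
  list(cells = cells, ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))))
}

#' Write a packaged fixture cohort to disk
#'
#' Generates a seeded cohort at one of two scales and writes every
#' recording in the portable fixture format plus the ground-truth table
#' (`ground_truth.csv`) and the design seed (`design.json`).
#'
#' @param scale `"tiny"` (3 cells/group, 2 sEPSC sweeps, 8 hyperpolarizing
#'   sweeps; suitable for quick checks) or `"default"` (12 cells/group, the
#'   study-sized cohort).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The cohort (as [generate_cohort()]), invisibly; files are the
#'   side effect.
#' @export
make_fixtures <- function(scale = c("tiny", "default"), dir, seed = 1) {
  scale <- match.arg(scale)
  design <- if (scale == "tiny") {
    cohort_design(cells_per_group = 3, seed = seed, n_hyp_sweeps = 8,
                  sepsc_sweeps = 2)
  } else {
    cohort_design(cells_per_group = 12, seed = seed)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(design)
  for (cell in cohort$cells) {
    for (tag in names(cell$recordings)) {
      write_recording(cell$recordings[[tag]],
                      file.path(dir, paste0(cell$cell_id, "_", tag)))
    }
  }
  data.table::fwrite(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  jsonlite::write_json(list(scale = scale, seed = seed,
                            cells_per_group = design$cells_per_group),
                       file.path(dir, "design.json"), auto_unbox = TRUE)
  invisible(cohort)
}
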