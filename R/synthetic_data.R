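# Seeded generator for synthetic single-cell calcium-imaging datasets with
# the statistical structure the analysis assumes: several independent
# experiments, log-spaced ATP concentrations, tens of cells per condition,
# experiment-to-experiment baseline and scale variability, injected outlier
# cells, vehicle artifacts, and a concentration-dependent transition from
# brief transients to prolonged responses above ~1e-4 M.

#' Default two-peak amplitude dose-response model
#'
#' The generating model for peak amplitude: the rodent
#' \{P2Y1, P2Y4, P2X7\} ensemble with coefficients (1.8, -1.4, 0.6)
#' multiplied by a non-specific high-dose suppression term
#' `1 - 0.4 * Hill(L; 5e-3 M, 3)` that reproduces the drop in amplitude at
#' the highest (10 mM) dose. On an 11-point log grid over 1e-9..1e-2 M this
#' curve has exactly two interior peaks: one sub-micromolar, one above
#' 1e-4 M.
#'
#' @param species catalog species tag for the ensemble part.
#' @return a function `f(concentration) -> amplitude`, carrying a
#'   `"manifest"` attribute describing the generating parameters.
#' @export
two_peak_amplitude_model <- function(species = "rodent") {
  ens <- ensemble_model(basis_set(c("P2Y1", "P2Y4", "P2X7"), species),
                        coefficients = c(1.8, -1.4, 0.6))
  k_ns <- 5e-3; h_ns <- 3; s_ns <- 0.4
  f <- function(concentration) {
    ensemble_response(concentration, ens) *
      (1 - s_ns * hill_response(concentration, k_ns, h_ns))
  }
  attr(f, "manifest") <- list(
    type = "two_peak",
    basis = ens$basis$receptor, species = species,
    coefficients = as.list(ens$coefficients),
    nonspecific_suppression = list(k_half_M = k_ns, hill = h_ns,
                                   fraction = s_ns))
  f
}

#' Default duration (FWHM) dose-response model
#'
#' Width at half maximum versus ATP concentration: a brief ~10 s transient
#' at low doses switching to a prolonged ~100 s response above ~1e-4 M,
#' following a steep Hill dependence (K half 6e-4 M, h = 4) as observed for
#' P2X7-driven prolongation.
#'
#' @param base_s,max_s transient and added prolonged duration (seconds).
#' @param k_half,hill_coeff Hill parameters of the transition.
#' @return a function `f(concentration) -> FWHM seconds` with a
#'   `"manifest"` attribute.
#' @export
duration_dose_model <- function(base_s = 10, max_s = 90, k_half = 6e-4,
                                hill_coeff = 4) {
  f <- function(concentration) {
    base_s + max_s * hill_response(concentration, k_half, hill_coeff)
  }
  attr(f, "manifest") <- list(type = "hill_plus_offset", base_s = base_s,
                              max_s = max_s, k_half_M = k_half,
                              hill = hill_coeff)
  f
}

# coerce a model argument (function, ensemble_model, hill_fit, or
# list(k_half, hill_coeff[, offset])) to a response function of concentration
.as_response_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "ensemble_model")) {
    return(function(concentration) ensemble_response(concentration, model))
  }
  if (inherits(model, "hill_fit") ||
      (is.list(model) && all(c("k_half", "hill_coeff") %in% names(model)))) {
    beta <- if (!is.null(model$offset) && is.finite(model$offset))
      model$offset else 0
    return(function(concentration) {
      hill_response(concentration, model$k_half, model$hill_coeff) + beta
    })
  }
  abort_param("cannot interpret `model` as a dose-response model")
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic dataset generator.
#' Defaults state the emulated study design: 8 independent experiments,
#' 11 log-spaced ATP concentrations over 1e-9..1e-2 M plus vehicle, 11-55
#' cells per condition, 0.5 s sampling over 300 s, per-experiment baseline
#' fluorescence spanning 23-78 FU with ~17% within-experiment cell-to-cell
#' variation, and 10% (high dose) to 25% (low dose) outlier cells.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param concentrations molar ATP concentrations (increasing, > 0).
#' @param n_experiments number of independent experiments.
#' @param cells_per_condition integer range `c(min, max)`.
#' @param sampling_interval seconds between frames.
#' @param trace_duration total trace length (s).
#' @param stimulus_time agonist application time (s).
#' @param baseline_fu_range range of per-experiment mean baseline (FU).
#' @param baseline_cv cell-to-cell baseline coefficient of variation.
#' @param noise_fu additive Gaussian fluorescence noise SD (FU).
#' @param outlier_fraction `c(high_dose, low_dose)` fraction of injected
#'   outlier cells, interpolated in log-concentration.
#' @param outlier_high_range,outlier_low_range amplitude multiplier ranges
#'   for hyper-responding and non-responding outlier cells; both land the
#'   cell outside the mean +/- 2 SD band of the clean population.
#' @param outlier_high_prob probability an outlier is a hyper-responder
#'   (otherwise a non-responder).
#' @param vehicle_response_prob probability a vehicle cell shows a small
#'   mechanical-artifact response.
#' @param vehicle_amplitude amplitude of that artifact.
#' @param amplitude_model amplitude dose-response model (function,
#'   `ensemble_model`, or Hill parameter list).
#' @param duration_model FWHM dose-response model.
#' @param amplitude_scale overall scale from model units to (F/F0)-1.
#' @param cell_amp_cv cell-to-cell amplitude coefficient of variation
#'   (amplitude is the most variable metric in this kind of data).
#' @param amp_dur_coupling decay rate `b` of the injected exponential
#'   amplitude-duration law `duration = d0 exp(-b amplitude)` applied below
#'   `coupling_max_conc`; produces the negative single-cell correlation of
#'   brief transients.
#' @param coupling_max_conc upper concentration bound of the coupling
#'   regime (the negative correlation is lost at high, P2X7-type doses).
#' @param duration_jitter_sd SD of the log-normal cell-level duration
#'   jitter.
#' @param experiment_scale_sd SD of the log-normal per-experiment
#'   amplitude scale factor.
#' @param rise_tau rise time constant of the transient pulse (s).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              concentrations = 10^seq(-9, -2, length.out = 11),
                              n_experiments = 8L,
                              cells_per_condition = c(11L, 55L),
                              sampling_interval = 0.5,
                              trace_duration = 300,
                              stimulus_time = 20,
                              baseline_fu_range = c(23, 78),
                              baseline_cv = 0.17,
                              noise_fu = 1.5,
                              outlier_fraction = c(0.10, 0.25),
                              outlier_high_range = c(3, 6),
                              outlier_low_range = c(0, 0.25),
                              outlier_high_prob = 0.7,
                              vehicle_response_prob = 0.2,
                              vehicle_amplitude = 0.05,
                              amplitude_model = two_peak_amplitude_model(),
                              duration_model = duration_dose_model(),
                              amplitude_scale = 2,
                              cell_amp_cv = 0.45,
                              amp_dur_coupling = 0.6,
                              coupling_max_conc = 1e-4,
                              duration_jitter_sd = 0.15,
                              experiment_scale_sd = 0.15,
                              rise_tau = 2) {
  cfg <- as.list(environment())
  if (!is.numeric(seed) || length(seed) != 1L) abort_param("seed must be one integer")
  if (is.unsorted(concentrations, strictly = TRUE) || any(concentrations <= 0)) {
    abort_param("concentrations must be strictly increasing and positive")
  }
  if (n_experiments < 1L) abort_param("n_experiments must be >= 1")
  if (length(cells_per_condition) != 2L || any(cells_per_condition < 1L) ||
      cells_per_condition[1L] > cells_per_condition[2L]) {
    abort_param("cells_per_condition must be an increasing positive range")
  }
  if (sampling_interval <= 0 || trace_duration <= stimulus_time) {
    abort_param("invalid sampling_interval/trace_duration/stimulus_time")
  }
  if (any(outlier_fraction < 0) || any(outlier_fraction > 1)) {
    abort_param("outlier_fraction entries must be in [0, 1]")
  }
  cfg$amplitude_fun <- .as_response_fun(amplitude_model)
  cfg$duration_fun <- .as_response_fun(duration_model)
  cfg$fwhm_lut <- .fwhm_lookup(rise_tau)
  class(cfg) <- "simulation_config"
  cfg
}

# monotone lookup table tau_d -> FWHM, inverted by log-log interpolation;
# avoids per-cell root finding. Interpolation error < 0.2% on the grid used.
.fwhm_lookup <- function(tau_r, tau_max = 3000, n = 200L) {
  taus <- exp(seq(log(tau_r * 1.02), log(tau_max), length.out = n))
  fw <- vapply(taus, function(td) .pulse_fwhm(tau_r, td), numeric(1))
  list(log_fwhm = log(fw), log_tau = log(taus))
}

.tau_d_from_lut <- function(target, lut) {
  lf <- log(max(target, exp(lut$log_fwhm[1L])))
  lf <- min(lf, lut$log_fwhm[length(lut$log_fwhm)])
  exp(stats::approx(lut$log_fwhm, lut$log_tau, xout = lf)$y)
}

# deterministic 32-bit substream seed from (master seed, counter); keeps
# per-cell reproducibility independent of generation order
.sub_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 65521 * 99991 + counter * 7919) %% 2147483629) + 1L
}

# unit-peak double-exponential pulse on post-stimulus time s >= 0
.pulse <- function(s, tau_r, tau_d) {
  t_pk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  g_pk <- exp(-t_pk / tau_d) - exp(-t_pk / tau_r)
  out <- numeric(length(s))
  pos <- s >= 0
  out[pos] <- (exp(-s[pos] / tau_d) - exp(-s[pos] / tau_r)) / g_pk
  out
}

# FWHM of the unit-peak pulse, by root finding on the closed form
.pulse_fwhm <- function(tau_r, tau_d) {
  t_pk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  f <- function(s) .pulse(s, tau_r, tau_d) - 0.5
  up <- stats::uniroot(f, c(0, t_pk), tol = 1e-10)$root
  hi <- t_pk * 2
  while (f(hi) > 0) hi <- hi * 2
  down <- stats::uniroot(f, c(t_pk, hi), tol = 1e-10)$root
  down - up
}

# decay tau giving a target FWHM at fixed rise tau
.tau_d_for_fwhm <- function(target, tau_r) {
  g <- function(td) .pulse_fwhm(tau_r, td) - target
  lo <- tau_r * 1.001
  if (g(lo) > 0) return(lo)  # target narrower than achievable; clamp
  hi <- max(4 * target, 4 * tau_r)
  while (g(hi) < 0) hi <- hi * 2
  stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
}

#' Generate noisy dose-response points from a model
#'
#' `response = model(concentration) + N(0, noise_sd)`, reproducible per
#' seed. Useful as fixtures for fit-recovery tests.
#'
#' @param model dose-response model (function, `ensemble_model`, `hill_fit`
#'   or `list(k_half, hill_coeff[, offset])`).
#' @param concentrations molar concentrations.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed optional integer seed.
#' @return data frame with `concentration`, `response`.
#' @export
generate_dose_response <- function(model, concentrations, noise_sd = 0,
                                   seed = NULL) {
  if (noise_sd < 0) abort_param("noise_sd must be >= 0")
  f <- .as_response_fun(model)
  if (!is.null(seed)) set.seed(seed)
  mu <- f(concentrations)
  eps <- if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  data.frame(concentration = concentrations, response = mu + eps)
}

# core single-trace synthesis; all randomness must be seeded by the caller
.make_trace <- function(concentration, amplitude, fwhm, f0, config,
                        cell_id, experiment_id) {
  t <- seq(0, config$trace_duration, by = config$sampling_interval)
  s <- t - config$stimulus_time
  f <- rep(f0, length(t))
  if (amplitude > 0) {
    tau_d <- if (!is.null(config$fwhm_lut)) {
      .tau_d_from_lut(fwhm, config$fwhm_lut)
    } else {
      .tau_d_for_fwhm(fwhm, config$rise_tau)
    }
    f <- f0 * (1 + amplitude * .pulse(s, config$rise_tau, tau_d))
  }
  if (config$noise_fu > 0) {
    f <- f + stats::rnorm(length(t), 0, config$noise_fu)
  }
  f <- pmax(f, 0.05)
  calcium_trace(time = t, fluorescence = f,
                stimulus_time = config$stimulus_time,
                cell_id = cell_id, experiment_id = experiment_id,
                concentration = concentration)
}

#' Generate one synthetic single-cell calcium trace
#'
#' Baseline segment at a drawn F0, then a double-exponential transient
#' whose peak (F/F0)-1 follows the configured amplitude model (with
#' cell-level jitter, floored at 0) and whose FWHM is calibrated to the
#' configured duration model; additive Gaussian fluorescence noise on top.
#' Below `coupling_max_conc` the cell's amplitude and duration jitters are
#' anti-correlated (shared latent draw), reproducing the negative
#' amplitude-duration correlation of brief transients.
#'
#' @param concentration ATP concentration (molar; 0 for vehicle).
#' @param config a [simulation_config()].
#' @param seed integer seed for this cell's substream.
#' @param cell_id,experiment_id identifiers.
#' @param f0 baseline fluorescence (FU); drawn around `f0_mean` when `NULL`.
#' @param f0_mean experiment-level mean baseline (FU).
#' @param scale extra amplitude scale factor (per-experiment variability).
#' @param outlier inject this cell as an amplitude outlier.
#' @return a `calcium_trace`.
#' @export
generate_trace <- function(concentration, config = simulation_config(),
                           seed = 1L, cell_id = "cell1",
                           experiment_id = "exp1", f0 = NULL,
                           f0_mean = mean(config$baseline_fu_range),
                           scale = 1, outlier = FALSE) {
  set.seed(seed)
  z <- stats::rnorm(1)
  z2 <- stats::rnorm(1)
  u_veh <- stats::runif(1)
  u_out <- stats::runif(1)
  fac_hi <- stats::runif(1, config$outlier_high_range[1L],
                         config$outlier_high_range[2L])
  fac_lo <- stats::runif(1, config$outlier_low_range[1L],
                         config$outlier_low_range[2L])
  if (is.null(f0)) {
    f0 <- f0_mean * exp(stats::rnorm(1, 0, config$baseline_cv))
  }
  if (concentration > 0) {
    base <- config$amplitude_scale * scale * config$amplitude_fun(concentration)
    amplitude <- max(0, base * (1 + config$cell_amp_cv * z))
    if (outlier) {
      amplitude <- amplitude *
        (if (u_out < config$outlier_high_prob) fac_hi else fac_lo)
    }
    d0 <- config$duration_fun(concentration)
    jit <- exp(config$duration_jitter_sd * z2)
    fwhm <- if (concentration < config$coupling_max_conc) {
      # exponential amplitude-duration law of brief transients: cells that
      # rise higher return faster; lost above the P2X7 threshold
      d0 * exp(-config$amp_dur_coupling * amplitude) * jit
    } else {
      d0 * jit
    }
  } else {
    amplitude <- if (u_veh < config$vehicle_response_prob) {
      max(0, config$vehicle_amplitude * (1 + config$cell_amp_cv * z))
    } else 0
    fwhm <- 8 * exp(config$duration_jitter_sd * z2)
  }
  .make_trace(concentration, amplitude, fwhm, f0, config, cell_id,
              experiment_id)
}

#' Generate a full multi-experiment synthetic dataset
#'
#' Emulates the study design end to end: per experiment, a vehicle
#' condition plus every configured ATP concentration, each with a drawn
#' number of cells; per-experiment baseline level and amplitude scale;
#' per-condition injected outlier cells (amplitude multiplied by
#' `outlier_scale`, landing outside the mean +/- 2 SD band); deterministic
#' per-cell substreams so output is byte-identical for identical
#' config + seed.
#'
#' @param config a [simulation_config()].
#' @return list of class `experiment_set`: `traces` (long data frame:
#'   `experiment_id, cell_id, concentration_M, time_s, fluorescence`),
#'   `stimuli` (`experiment_id, stimulus_time_s`), and `manifest` (every
#'   generating parameter, including per-cell ground truth).
#' @export
generate_experiment_set <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  concs <- c(0, config$concentrations)
  lc <- log10(range(config$concentrations))
  n_t <- length(seq(0, config$trace_duration, by = config$sampling_interval))
  col_eid <- list(); col_cid <- list(); col_conc <- list()
  col_time <- list(); col_f <- list()
  truth <- list()
  stimuli <- list()
  for (e in seq_len(config$n_experiments)) {
    eid <- sprintf("exp%02d", e)
    set.seed(.sub_seed(config$seed, e * 1000000))
    f0_mean <- stats::runif(1, config$baseline_fu_range[1L],
                            config$baseline_fu_range[2L])
    scale_e <- exp(stats::rnorm(1, 0, config$experiment_scale_sd))
    n_cells <- sample(seq(config$cells_per_condition[1L],
                          config$cells_per_condition[2L]),
                      length(concs), replace = TRUE)
    stimuli[[e]] <- data.frame(experiment_id = eid,
                               stimulus_time_s = config$stimulus_time,
                               stringsAsFactors = FALSE)
    for (ci in seq_along(concs)) {
      conc <- concs[ci]
      nc <- n_cells[ci]
      # outlier fraction interpolated in log10 concentration:
      # high fraction at the low end, low fraction at the high end
      frac <- if (conc == 0) 0 else {
        w <- (log10(conc) - lc[1L]) / (lc[2L] - lc[1L])
        config$outlier_fraction[2L] +
          (config$outlier_fraction[1L] - config$outlier_fraction[2L]) * w
      }
      set.seed(.sub_seed(config$seed, e * 1000000 + ci * 10000))
      n_out <- round(frac * nc)
      out_idx <- if (n_out > 0) sample(nc, n_out) else integer(0)
      for (j in seq_len(nc)) {
        cid <- sprintf("%s_c%02d_cell%03d", eid, ci, j)
        cell_seed <- .sub_seed(config$seed, e * 1000000 + ci * 10000 + j)
        tr <- generate_trace(conc, config, seed = cell_seed, cell_id = cid,
                             experiment_id = eid, f0_mean = f0_mean,
                             scale = scale_e, outlier = j %in% out_idx)
        k <- length(col_eid) + 1L
        col_eid[[k]] <- rep(eid, n_t)
        col_cid[[k]] <- rep(cid, n_t)
        col_conc[[k]] <- rep(conc, n_t)
        col_time[[k]] <- tr$time
        col_f[[k]] <- round(tr$fluorescence, 4)
        truth[[length(truth) + 1L]] <- data.frame(
          experiment_id = eid, cell_id = cid, concentration_M = conc,
          injected_outlier = j %in% out_idx,
          stringsAsFactors = FALSE)
      }
    }
  }
  traces <- data.frame(
    experiment_id = unlist(col_eid), cell_id = unlist(col_cid),
    concentration_M = unlist(col_conc), time_s = unlist(col_time),
    fluorescence = unlist(col_f), stringsAsFactors = FALSE)
  manifest <- list(
    seed = config$seed,
    n_experiments = config$n_experiments,
    concentrations = config$concentrations,
    cells_per_condition = config$cells_per_condition,
    sampling_interval_s = config$sampling_interval,
    trace_duration_s = config$trace_duration,
    stimulus_time_s = config$stimulus_time,
    baseline_fu_range = config$baseline_fu_range,
    noise_fu = config$noise_fu,
    outlier_fraction = config$outlier_fraction,
    outlier_high_range = config$outlier_high_range,
    outlier_low_range = config$outlier_low_range,
    outlier_high_prob = config$outlier_high_prob,
    amplitude_scale = config$amplitude_scale,
    cell_amp_cv = config$cell_amp_cv,
    amp_dur_coupling = config$amp_dur_coupling,
    experiment_scale_sd = config$experiment_scale_sd,
    amplitude_model = attr(config$amplitude_model, "manifest"),
    duration_model = attr(config$duration_model, "manifest"),
    note = paste("Synthetic dataset; variance components are stated",
                 "emulation choices, not measured values."),
    cells = do.call(rbind, truth)
  )
  structure(list(traces = traces,
                 stimuli = do.call(rbind, stimuli),
                 manifest = manifest),
            class = "experiment_set")
}

#' Write an experiment set to disk
#'
#' Emits `traces.csv`, `stimuli.csv` and `manifest.json` (ground truth)
#' into `dir` in the dialects the readers expect.
#'
#' @param x an `experiment_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_set <- function(x, dir) {
  stopifnot(inherits(x, "experiment_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(x$stimuli, file.path(dir, "stimuli.csv"),
                   row.names = FALSE)
  js <- jsonlite::toJSON(x$manifest, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  writeLines(js, file.path(dir, "manifest.json"))
  invisible(dir)
}
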