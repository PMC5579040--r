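#' Ground-truth specification for synthetic recordings
#'
#' Defaults encode the reported experimental world: baseline ratios inside the
#' printed 1.0-1.3 operating band, equal AVP/VIP baselines with a +0.03
#' day-over-night offset, KCC-blocker (VU) ratio increases of 0.18 (AVP) and
#' 0.27 (VIP), NKCC1-blocker (bumetanide) effects of +0.04 (AVP) and -0.04
#' (VIP), minutes-long agonist-puff transients, and full occlusion of a
#' second chloride-uptake step under prior blockade.
#'
#' @param calibration Forward sensor model, a [calibration_fit()].
#' @param baseline_r Named numeric, baseline ratio per phase.
#' @param day_night_offset Kept for documentation; the offset is already in
#'   `baseline_r`.
#' @param drug_effects Named list: per drug either a scalar ratio change or a
#'   named vector by neuron type.
#' @param transient Puff-transient parameters: `amplitude` (ratio units),
#'   `tau_rise_s`, `tau_decay_s`.
#' @param washin_tau_s Bath-drug wash-in time constant (s).
#' @param slice_random_effect_sd SD of the per-slice additive ratio offset.
#' @param drug_effect_slice_sd SD of the per-slice jitter on each drug's
#'   plateau amplitude (ratio units); emulates the between-slice effect
#'   heterogeneity visible in published summary error bars and matches
#'   the slice random-effect magnitude used for the clustered-inference
#'   null world.
#' @param occlusion_factor Amplitude multiplier for a bath step beginning
#'   while another bath drug is present (0 = fully occluded).
#' @param egaba_true_mV True reversal potential for ramp simulations.
#' @param egaba_shift_mV True depolarising shift applied by the blocker in
#'   paired ramp simulations.
#' @return Object of class `truth_spec`.
#' @export
truth_spec <- function(calibration = reference_calibration(),
                       baseline_r = c(day = 1.15, night = 1.12),
                       day_night_offset = 0.03,
                       drug_effects = list(
                         bath_VU = c(AVP = 0.18, VIP = 0.27),
                         bath_bumetanide = c(AVP = 0.04, VIP = -0.04)),
                       transient = list(amplitude = 0.10, tau_rise_s = 10,
                                        tau_decay_s = 120),
                       washin_tau_s = 180,
                       slice_random_effect_sd = 0.03,
                       drug_effect_slice_sd = 0.03,
                       occlusion_factor = 0,
                       egaba_true_mV = -47,
                       egaba_shift_mV = 23) {
  structure(list(calibration = calibration, baseline_r = baseline_r,
                 day_night_offset = day_night_offset,
                 drug_effects = drug_effects, transient = transient,
                 washin_tau_s = washin_tau_s,
                 slice_random_effect_sd = slice_random_effect_sd,
                 drug_effect_slice_sd = drug_effect_slice_sd,
                 occlusion_factor = occlusion_factor,
                 egaba_true_mV = egaba_true_mV,
                 egaba_shift_mV = egaba_shift_mV),
            class = "truth_spec")
}

#' Noise specification for synthetic recordings
#'
#' Channel noise is shot-noise-like: Gaussian with SD `a + b * sqrt(I)` at
#' clean intensity I. Intensities are scaled so a 100 ms exposure of the
#' 500 nm channel yields ~1000 camera units, giving a ratio noise SD of
#' roughly 0.5-1% per sample at defaults.
#'
#' @param a,b Noise-model coefficients (camera units).
#' @param intensity_500 Clean 500 nm intensity at the 100 ms reference
#'   exposure.
#' @param background_level Named vector, additive background per channel.
#' @param ramp_current_noise_pA Current noise for ramp simulations.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(a = 0.5, b = 0.15, intensity_500 = 1000,
                       background_level = c(f436 = 60, f500 = 60),
                       ramp_current_noise_pA = 5) {
  structure(list(a = a, b = b, intensity_500 = intensity_500,
                 background_level = background_level,
                 ramp_current_noise_pA = ramp_current_noise_pA),
            class = "noise_spec")
}

#' Photoinactivation drift specification
#'
#' Drift acts on the 500 nm channel (the chloride-sensitive YFP accumulates
#' in an inactivated state), depressing it by a saturating-exponential
#' factor so the ratio rises by `amplitude_per_100ms * exposure/100` at
#' saturation. Amplitude scaling with exposure reproduces the
#' exposure-dependent trend the correction pipeline removes.
#'
#' @param amplitude_per_100ms Fractional ratio rise at saturation for a
#'   100 ms exposure.
#' @param tau_s Drift time constant (s).
#' @param exposure_set_ms Exposures cycled across slices (acquisition range
#'   20-200 ms).
#' @return Object of class `drift_spec`.
#' @export
drift_spec <- function(amplitude_per_100ms = 0.05, tau_s = 300,
                       exposure_set_ms = c(50, 100, 200)) {
  structure(list(amplitude_per_100ms = amplitude_per_100ms, tau_s = tau_s,
                 exposure_set_ms = exposure_set_ms),
            class = "drift_spec")
}

#' Full simulation configuration
#'
#' @param seed Integer master seed; every random draw descends from it
#'   through per-(slice, roi) substreams, so outputs are bit-reproducible
#'   and adding ROIs never perturbs existing ones.
#' @param n_slices Slices per condition.
#' @param rois_per_slice Signal ROIs per slice (a background ROI is added).
#' @param sampling_interval_s 2 or 5 s.
#' @param duration_s Recording length (s).
#' @param conditions List of [condition()] objects; default the four
#'   neuron-type x phase combinations in bicarbonate buffer.
#' @param events Data frame (`kind`, `onset_s`, optional `offset_s`) applied
#'   to every slice; default one KCC-blocker bath application at 600 s.
#' @param truth,noise,drift Component specifications.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_slices = 10L, rois_per_slice = 4L,
                       sampling_interval_s = 5, duration_s = 1800,
                       conditions = NULL,
                       events = data.frame(kind = "bath_VU", onset_s = 600,
                                           offset_s = NA_real_),
                       truth = truth_spec(), noise = noise_spec(),
                       drift = drift_spec()) {
  if (is.null(conditions)) {
    conditions <- list(condition("AVP", "day"), condition("AVP", "night"),
                       condition("VIP", "day"), condition("VIP", "night"))
  }
  if (!sampling_interval_s %in% c(2, 5))
    warning("typical sampling intervals are 2 or 5 s")
  if (!"offset_s" %in% names(events)) events$offset_s <- NA_real_
  structure(list(seed = as.integer(seed), n_slices = as.integer(n_slices),
                 rois_per_slice = as.integer(rois_per_slice),
                 sampling_interval_s = sampling_interval_s,
                 duration_s = duration_s, conditions = conditions,
                 events = events, truth = truth, noise = noise, drift = drift),
            class = "sim_config")
}

# Deterministic substream seed for (slice index, roi index); stays inside
# 32-bit integer range. roi index 0 is the background ROI.
.substream_seed <- function(seed, slice_i, roi_j) {
  as.integer((as.numeric(seed) * 48271 + slice_i * 100003 + roi_j * 1009 + 7) %%
               2147483647)
}

.event_r_component <- function(events, time_s, truth, neuron_type,
                               effect_jitter = NULL) {
  r <- numeric(length(time_s))
  if (is.null(events) || !nrow(events)) return(r)
  ev <- events[order(events$onset_s), , drop = FALSE]
  if (anyDuplicated(paste(ev$kind, ev$onset_s)))
    stop("overlapping incompatible events: duplicated kind at one onset",
         call. = FALSE)
  bath_active_until <- -Inf
  for (k in seq_len(nrow(ev))) {
    kind <- ev$kind[k]
    onset <- ev$onset_s[k]
    offset <- if ("offset_s" %in% names(ev)) ev$offset_s[k] else NA_real_
    dt <- time_s - onset
    if (startsWith(kind, "bath")) {
      eff <- truth$drug_effects[[kind]]
      if (is.null(eff))
        stop(sprintf("no true effect specified for drug '%s'", kind), call. = FALSE)
      amp <- if (length(eff) > 1L) unname(eff[[neuron_type]]) else unname(eff)
      if (!is.null(effect_jitter) && !is.null(effect_jitter[[kind]]))
        amp <- amp + effect_jitter[[kind]]
      if (onset < bath_active_until) amp <- amp * truth$occlusion_factor
      step <- ifelse(dt >= 0, amp * (1 - exp(-dt / truth$washin_tau_s)), 0)
      if (!is.na(offset)) {
        washed <- time_s > offset
        plateau <- amp * (1 - exp(-(offset - onset) / truth$washin_tau_s))
        step[washed] <- plateau * exp(-(time_s[washed] - offset) / truth$washin_tau_s)
        bath_active_until <- max(bath_active_until, offset)
      } else {
        bath_active_until <- Inf
      }
      r <- r + step
    } else { # puff transient: difference of exponentials, normalised to peak
      tr <- truth$transient
      shape <- ifelse(dt >= 0,
                      exp(-dt / tr$tau_decay_s) - exp(-dt / tr$tau_rise_s), 0)
      t_peak <- log(tr$tau_decay_s / tr$tau_rise_s) /
        (1 / tr$tau_rise_s - 1 / tr$tau_decay_s)
      peak <- exp(-t_peak / tr$tau_decay_s) - exp(-t_peak / tr$tau_rise_s)
      r <- r + tr$amplitude * shape / peak
    }
  }
  r
}

#' Simulate a true chloride trajectory
#'
#' Drug effects are specified in ratio units (the study's reporting
#' currency), composed additively on the baseline ratio — bath drugs as
#' saturating wash-in steps, puffs as fast-rise/slow-decay transients — and
#' the summed ratio trajectory is routed through the inverse calibration to
#' yield the underlying chloride concentration. A bath step starting while a
#' previous bath drug is still present is scaled by the occlusion factor.
#'
#' @param truth A [truth_spec()].
#' @param events Event data frame (`kind`, `onset_s`, optional `offset_s`).
#' @param time_s Time base (s).
#' @param cond A [condition()] (selects baseline and per-neuron-type
#'   effects).
#' @param slice_effect Additive per-slice ratio offset (default 0).
#' @param effect_jitter Optional named list (by drug) of per-slice additive
#'   amplitude jitters.
#' @return List with `cl_mM` and `r_true` vectors over `time_s`.
#' @export
simulate_cl_trajectory <- function(truth, events, time_s, cond,
                                   slice_effect = 0, effect_jitter = NULL) {
  r0 <- unname(truth$baseline_r[[cond$phase]])
  r_true <- r0 + slice_effect +
    .event_r_component(events, time_s, truth, cond$neuron_type, effect_jitter)
  cl <- inverse_model(truth$calibration, r_true)
  if (any(!is.finite(cl)))
    stop("trajectory leaves the invertible calibration range", call. = FALSE)
  list(cl_mM = as.numeric(cl), r_true = r_true)
}

#' Render a chloride trajectory into a two-channel fluorescence trace
#'
#' The clean 500 nm intensity scales with exposure; photoinactivation
#' divides it by `1 + d(t)` with `d(t) = D (1 - exp(-t/tau))`, so the
#' rendered ratio rises by exactly the factor `1 + d(t)` (drift lives in the
#' 500 nm channel, as expected for YFP inactivation). Per-channel background
#' is added, then shot-noise-like Gaussian noise. With drift and noise
#' disabled and the background subtracted, the pipeline ratio equals the
#' forward-model ratio to numerical precision.
#'
#' @param cl_mM True chloride trajectory.
#' @param time_s Time base (s).
#' @param calibration Forward model, a [calibration_fit()].
#' @param drift A [drift_spec()] (or `NULL` for none).
#' @param noise A [noise_spec()] (or `NULL` for none).
#' @param exposure_ms 500 nm exposure for this slice.
#' @param slice_id,roi_id Identifiers.
#' @param slice_effect Additive ratio offset shared by the slice's ROIs.
#' @param rng_seed Integer seed for this trace's noise substream.
#' @return List with `trace` (the signal [roi_trace()]) and `background`
#'   (the matching background [roi_trace()] drawn with an independent
#'   substream derived from `rng_seed`).
#' @export
render_fluorescence <- function(cl_mM, time_s, calibration, drift, noise,
                                exposure_ms, slice_id = "s1", roi_id = "roi1",
                                slice_effect = 0, rng_seed = 1L) {
  r_true <- forward_model(calibration, cl_mM) + slice_effect
  base_i500 <- if (is.null(noise)) 1000 else noise$intensity_500
  f500_clean <- rep(base_i500 * exposure_ms / 100, length(time_s))
  f436_clean <- r_true * f500_clean
  if (!is.null(drift)) {
    d <- drift$amplitude_per_100ms * (exposure_ms / 100) *
      (1 - exp(-time_s / drift$tau_s))
    f500_clean <- f500_clean / (1 + d)
  }
  bg <- if (is.null(noise)) c(f436 = 0, f500 = 0) else noise$background_level
  f436 <- f436_clean + bg[["f436"]]
  f500 <- f500_clean + bg[["f500"]]
  bg436 <- rep(bg[["f436"]], length(time_s))
  bg500 <- rep(bg[["f500"]], length(time_s))
  if (!is.null(noise)) {
    withr_seed <- function(seed, code) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
        suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
      set.seed(seed)
      code()
    }
    n <- length(time_s)
    draws <- withr_seed(rng_seed, function() {
      list(e436 = stats::rnorm(n, 0, noise$a + noise$b * sqrt(pmax(f436, 0))),
           e500 = stats::rnorm(n, 0, noise$a + noise$b * sqrt(pmax(f500, 0))),
           b436 = stats::rnorm(n, 0, noise$a + noise$b * sqrt(bg436)),
           b500 = stats::rnorm(n, 0, noise$a + noise$b * sqrt(bg500)))
    })
    f436 <- pmax(f436 + draws$e436, 0)
    f500 <- pmax(f500 + draws$e500, 0)
    bg436 <- pmax(bg436 + draws$b436, 0)
    bg500 <- pmax(bg500 + draws$b500, 0)
  }
  list(trace = roi_trace(slice_id, roi_id, time_s, f436, f500, exposure_ms),
       background = roi_trace(slice_id, "background", time_s, bg436, bg500,
                              exposure_ms, is_background = TRUE))
}

#' Simulate a complete multi-slice dataset
#'
#' Generates `n_slices` recordings per condition with per-slice exposure
#' assignment (cycled through the drift spec's exposure set), per-slice
#' random ratio offsets, shared events, and a ground-truth sidecar recording
#' every generated parameter. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `traces.csv`,
#'   `manifest.json` and `truth.json` there (created if missing).
#' @return List with `recordings` (named list of [slice_recording()]),
#'   `truth` (per-slice ground-truth list), and `paths` (when `dir` given).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  time_s <- seq(0, config$duration_s, by = config$sampling_interval_s)
  recordings <- list()
  truth_sidecar <- list(seed = config$seed,
                        baseline_r = as.list(config$truth$baseline_r),
                        drug_effects = config$truth$drug_effects,
                        slice_random_effect_sd = config$truth$slice_random_effect_sd,
                        washin_tau_s = config$truth$washin_tau_s,
                        occlusion_factor = config$truth$occlusion_factor,
                        drift = list(amplitude_per_100ms = config$drift$amplitude_per_100ms,
                                     tau_s = config$drift$tau_s),
                        slices = list())
  slice_i <- 0L
  for (cond in config$conditions) {
    for (k in seq_len(config$n_slices)) {
      slice_i <- slice_i + 1L
      sid <- sprintf("%s_%s_%s_s%02d", cond$neuron_type, cond$phase,
                     substr(cond$buffer, 1, 4), k)
      exposure_set <- if (is.null(config$drift)) 100 else config$drift$exposure_set_ms
      exposure <- exposure_set[(slice_i - 1L) %% length(exposure_set) + 1L]
      seed_slice <- .substream_seed(config$seed, slice_i, 0L)
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed_slice)
      slice_effect <- stats::rnorm(1, 0, config$truth$slice_random_effect_sd)
      bath_kinds <- unique(config$events$kind[startsWith(config$events$kind, "bath")])
      effect_jitter <- NULL
      if (length(bath_kinds) && config$truth$drug_effect_slice_sd > 0) {
        effect_jitter <- as.list(stats::setNames(
          stats::rnorm(length(bath_kinds), 0, config$truth$drug_effect_slice_sd),
          bath_kinds))
      }
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      traj <- simulate_cl_trajectory(config$truth, config$events, time_s,
                                     cond, slice_effect = 0,
                                     effect_jitter = effect_jitter)
      traces <- list()
      bg <- NULL
      for (j in seq_len(config$rois_per_slice)) {
        rendered <- render_fluorescence(
          traj$cl_mM, time_s, config$truth$calibration, config$drift,
          config$noise, exposure, slice_id = sid,
          roi_id = sprintf("roi%02d", j), slice_effect = slice_effect,
          rng_seed = .substream_seed(config$seed, slice_i, j))
        traces[[length(traces) + 1L]] <- rendered$trace
        if (j == 1L) bg <- rendered$background
      }
      traces[[length(traces) + 1L]] <- bg
      recordings[[sid]] <- slice_recording(sid, cond, traces, config$events)
      truth_sidecar$slices[[sid]] <- list(
        condition = list(neuron_type = cond$neuron_type, phase = cond$phase,
                         buffer = cond$buffer),
        slice_effect = slice_effect, effect_jitter = effect_jitter,
        exposure500_ms = exposure,
        baseline_r = unname(config$truth$baseline_r[[cond$phase]]))
    }
  }
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(traces = file.path(dir, "traces.csv"),
                  manifest = file.path(dir, "manifest.json"),
                  truth = file.path(dir, "truth.json"))
    write_traces(recordings, paths$traces)
    write_manifest(recordings, paths$manifest)
    jsonlite::write_json(truth_sidecar, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(recordings = recordings, truth = truth_sidecar, paths = paths)
}

#' Window-estimand of a simulated drug effect
#'
#' The drug's plateau amplitude is approached with a finite wash-in time
#' constant, so the baseline/response-window contrast of the *noiseless*
#' trajectory — the estimand that an unbiased pipeline recovers — is
#' slightly below the plateau amplitude (about 1.8\% below for the default
#' 180 s wash-in and the default windows). Recovery oracles should compare
#' estimates against this value, not against the raw plateau.
#'
#' @param truth A [truth_spec()].
#' @param events Event data frame.
#' @param cond A [condition()].
#' @param time_s Recording time base.
#' @param event_kind Which event to evaluate.
#' @param spec A [window_spec()].
#' @return The expected window delta of the ratio (numeric scalar).
#' @export
expected_window_delta <- function(truth, events, cond, time_s,
                                  event_kind = events$kind[1],
                                  spec = window_spec()) {
  traj <- simulate_cl_trajectory(truth, events, time_s, cond)
  rt <- ratio_trace("truth", "truth", time_s, traj$r_true, 100)
  ev <- events[events$kind == event_kind, , drop = FALSE][1, , drop = FALSE]
  rec <- quantify_bath_effect(rt, ev, spec, cond)
  rec$delta_r
}

#' Simulate calibration points
#'
#' Steady-state ratios on the forward curve plus Gaussian noise, one point
#' per slice per concentration level.
#'
#' @param fit Generating [calibration_fit()].
#' @param cl_levels Concentration levels (mM), at least 5.
#' @param noise_sd Gaussian SD on the ratio.
#' @param n_slices Replicate slices.
#' @param seed Integer seed.
#' @return Data frame with `cl_mM`, `steady_r`, `slice_id`.
#' @export
simulate_calibration <- function(fit, cl_levels = calibration_levels(),
                                 noise_sd = 0.02, n_slices = 6L, seed = 1L) {
  if (length(cl_levels) < 5L)
    stop("need at least 5 concentration levels", call. = FALSE)
  grid <- expand.grid(slice = seq_len(n_slices), cl_mM = cl_levels)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  r <- forward_model(fit, grid$cl_mM) + stats::rnorm(nrow(grid), 0, noise_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  data.frame(cl_mM = grid$cl_mM, steady_r = r,
             slice_id = sprintf("cal%02d", grid$slice),
             stringsAsFactors = FALSE)
}

#' Simulate a voltage-ramp current pair
#'
#' GABA sweep: agonist conductance times driving force plus leak plus noise;
#' control sweep: leak plus independent noise. Leak is linear,
#' `g_leak * (V - e_leak)`.
#'
#' @param egaba_true_mV True reversal potential; must lie inside the command
#'   span.
#' @param conductance_nS Agonist conductance (nS, = pA/mV).
#' @param noise_pA Gaussian current noise SD per sample.
#' @param seed Integer seed (`NULL` for noiseless draw order independence).
#' @param v_range Command span (mV), default -80 to -20 (about 60 mV).
#' @param n_points Samples along the ramp (400 ms at 5 kHz would be 2000;
#'   200 keeps fixtures light and is plenty for a line fit).
#' @param g_leak_nS,e_leak_mV Leak parameters.
#' @param sweep_id Identifier.
#' @return A [ramp_pair()].
#' @export
simulate_ramp <- function(egaba_true_mV, conductance_nS = 1.5, noise_pA = 5,
                          seed = 1L, v_range = c(-80, -20), n_points = 200L,
                          g_leak_nS = 2, e_leak_mV = -65, sweep_id = "sweep") {
  if (egaba_true_mV <= v_range[1] || egaba_true_mV >= v_range[2])
    stop(sprintf("true reversal %.1f mV outside command span [%g, %g] mV",
                 egaba_true_mV, v_range[1], v_range[2]), call. = FALSE)
  v <- seq(v_range[1], v_range[2], length.out = n_points)
  leak <- g_leak_nS * (v - e_leak_mV)
  e1 <- e2 <- numeric(n_points)
  if (noise_pA > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    e1 <- stats::rnorm(n_points, 0, noise_pA)
    e2 <- stats::rnorm(n_points, 0, noise_pA)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  ramp_pair(v, conductance_nS * (v - egaba_true_mV) + leak + e1, leak + e2,
            sweep_id = sweep_id)
}
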