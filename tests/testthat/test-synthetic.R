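test_that("trajectories compose baseline, wash-in steps, and transients", {
  t <- seq(0, 1800, by = 5)
  tr <- truth_spec()
  cond <- condition("VIP", "day")

  none <- simulate_cl_trajectory(tr, empty_events(), t, cond)
  expect_equal(diff(range(none$r_true)), 0)
  expect_equal(forward_model(tr$calibration, none$cl_mM[1]),
               tr$baseline_r[["day"]], tolerance = 1e-9)

  ev <- data.frame(kind = "bath_VU", onset_s = 300, offset_s = NA_real_)
  traj <- simulate_cl_trajectory(tr, ev, t, cond)
  plateau_r <- forward_model(tr$calibration, traj$cl_mM[t == 1800])
  expect_equal(plateau_r, tr$baseline_r[["day"]] + 0.27, tolerance = 0.001)

  # occlusion: a second chloride-uptake step under prior blockade adds nothing
  ev2 <- data.frame(kind = c("bath_bumetanide", "bath_VU"),
                    onset_s = c(300, 1200), offset_s = NA_real_)
  occ <- simulate_cl_trajectory(tr, ev2, t, condition("AVP", "night"))
  expect_equal(occ$r_true[t == 1150], occ$r_true[t == 1800], tolerance = 1e-3)

  expect_error(simulate_cl_trajectory(
    tr, data.frame(kind = c("bath_VU", "bath_VU"), onset_s = c(300, 300),
                   offset_s = NA_real_), t, cond), "overlapping")
})

test_that("rendering is the identity under the pipeline when clean", {
  t <- seq(0, 900, by = 5)
  cal <- reference_calibration()
  cl <- inverse_model(cal, rep(1.15, length(t)))
  rend <- render_fluorescence(cl, t, cal, drift = NULL, noise = NULL,
                              exposure_ms = 100)
  ratio <- compute_ratio(subtract_background(rend$trace, rend$background))
  expect_lt(max(abs(ratio$r_cl - 1.15)), 1e-9)
})

test_that("drift raises late-trace ratios and scales with exposure", {
  t <- seq(0, 1800, by = 5)
  cal <- reference_calibration()
  cl <- inverse_model(cal, rep(1.15, length(t)))
  steady <- sapply(c(50, 100, 200), function(ex) {
    rend <- render_fluorescence(cl, t, cal, drift = drift_spec(), noise = NULL,
                                exposure_ms = ex)
    r <- compute_ratio(subtract_background(rend$trace, rend$background))
    expect_gt(mean(r$r_cl[t > 1500]), mean(r$r_cl[t < 100]))  # rising drift
    mean(r$r_cl[t > 1500])
  })
  expect_true(all(diff(steady) > 0))  # steady level grows with exposure
})

test_that("datasets are deterministic given the seed and structurally correct", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 7, n_slices = 2, rois_per_slice = 3,
                    duration_s = 900)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in c("traces.csv", "manifest.json", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  recs <- read_traces(file.path(d1, "traces.csv"),
                      read_manifest(file.path(d1, "manifest.json")))
  expect_length(recs, 8L)  # 4 conditions x 2 slices
  expect_length(recs[[1]]$traces, 4L)  # 3 signal ROIs + background
  # per-condition ROI counts match the configuration
  conds <- table(vapply(recs, function(r) condition_label(r$condition),
                        character(1)))
  expect_true(all(conds == 2L))
})

test_that("substreams make existing ROIs invariant to adding more ROIs", {
  base <- sim_config(seed = 11, n_slices = 1, rois_per_slice = 2,
                     conditions = list(condition("AVP", "day")),
                     duration_s = 600)
  more <- sim_config(seed = 11, n_slices = 1, rois_per_slice = 4,
                     conditions = list(condition("AVP", "day")),
                     duration_s = 600)
  s1 <- simulate_dataset(base)$recordings[[1]]
  s2 <- simulate_dataset(more)$recordings[[1]]
  expect_identical(s1$traces[[1]]$f436, s2$traces[[1]]$f436)
  expect_identical(s1$traces[[2]]$f500, s2$traces[[2]]$f500)
})

test_that("the truth sidecar tracks every generated parameter", {
  cfg <- sim_config(seed = 3, n_slices = 2, rois_per_slice = 2,
                    conditions = list(condition("VIP", "night")),
                    duration_s = 900)
  sim <- simulate_dataset(cfg)
  expect_named(sim$truth$slices, names(sim$recordings))
  s <- sim$truth$slices[[1]]
  expect_true(is.finite(s$slice_effect))
  expect_true(is.finite(s$effect_jitter$bath_VU))
  expect_true(s$exposure500_ms %in% drift_spec()$exposure_set_ms)
  expect_identical(sim$truth$drug_effects$bath_VU[["VIP"]], 0.27)
})

test_that("simulated calibration points sit on the curve when noiseless", {
  cal <- reference_calibration()
  pts0 <- simulate_calibration(cal, noise_sd = 0, n_slices = 2, seed = 1)
  expect_equal(pts0$steady_r, forward_model(cal, pts0$cl_mM), tolerance = 1e-12)
  pts <- simulate_calibration(cal, noise_sd = 0.02, n_slices = 6, seed = 2)
  fit <- fit_calibration(pts)
  se <- sqrt(diag(fit$covariance))
  expect_lt(abs(fit$kd_mM - cal$kd_mM), 3 * se[1])
  expect_error(simulate_calibration(cal, cl_levels = c(0, 123)), "at least 5")
})

test_that("ramp simulation honours its domain constraints", {
  expect_error(simulate_ramp(-100), "outside command span")
  p <- simulate_ramp(-47, noise_pA = 0)
  expect_equal(estimate_egaba(subtract_ramp(p))$e_gaba_mV, -47,
               tolerance = 1e-9)
})

test_that("the full pipeline recovers each condition's drug effect within 2 robust SE", {
  cfg <- sim_config(seed = 2718, n_slices = 10, rois_per_slice = 4,
                    conditions = list(condition("AVP", "day"),
                                      condition("VIP", "day")))
  sim <- simulate_dataset(cfg)
  ratios <- preprocess_dataset(sim$recordings)
  eff <- build_effects_table(sim$recordings, ratios, "bath_VU")
  time_s <- seq(0, cfg$duration_s, by = cfg$sampling_interval_s)
  fit <- fit_gee(eff, terms = "neuron_type")
  t_avp <- expected_window_delta(cfg$truth, cfg$events, condition("AVP", "day"),
                                 time_s)
  t_vip <- expected_window_delta(cfg$truth, cfg$events, condition("VIP", "day"),
                                 time_s)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - t_avp),
            2 * fit$robust_se[["(Intercept)"]])
  expect_lt(abs(fit$coefficients[["neuron_typeVIP"]] - (t_vip - t_avp)),
            2 * fit$robust_se[["neuron_typeVIP"]])
})
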