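test_that("background subtraction is per-channel and flags degenerate samples", {
  t <- seq(0, 95, by = 5)
  sig <- roi_trace("s1", "r1", t, rep(600, 20), rep(500, 20), 100)
  bg <- roi_trace("s1", "bg", t, rep(100, 20), rep(100, 20), 100,
                  is_background = TRUE)
  out <- subtract_background(sig, bg)
  expect_equal(out$f436, rep(500, 20))
  expect_equal(out$f500, rep(400, 20))
  expect_identical(attr(out, "n_flagged"), 0L)

  # trace == background: all flagged
  self <- bg
  self$is_background <- FALSE
  out2 <- subtract_background(self, bg)
  expect_identical(attr(out2, "n_flagged"), 20L)
  expect_true(all(is.na(out2$f436)))

  expect_error(subtract_background(sig, sig), "not flagged")
  bg_short <- roi_trace("s1", "bg", t[1:10], rep(1, 10), rep(1, 10), 100,
                        is_background = TRUE)
  expect_error(subtract_background(sig, bg_short), "time base")
})

test_that("compute_ratio handles equality, the operating band, and zeros", {
  t <- seq(0, 95, by = 5)
  bg <- roi_trace("s1", "bg", t, rep(0.0, 20) + 1e-9, rep(1e-9, 20), 100,
                  is_background = TRUE)
  mk <- function(f436, f500) {
    tr <- roi_trace("s1", "r1", t, f436, f500, 100)
    compute_ratio(subtract_background(tr, bg))
  }
  expect_equal(mk(rep(500, 20), rep(500, 20))$r_cl, rep(1, 20),
               tolerance = 1e-8)
  # 600/500 = 1.2, inside the indicator's typical 1.0-1.3 operating band
  expect_equal(mk(rep(600, 20), rep(500, 20))$r_cl, rep(1.2, 20),
               tolerance = 1e-8)
  f500 <- rep(500, 20); f500[7] <- 0
  r <- mk(rep(600, 20), f500)
  expect_true(is.na(r$r_cl[7]))
  expect_identical(sum(is.na(r$r_cl)), 1L)
  expect_identical(r$n_flagged, 1L)
  expect_identical(r$corrections, c("background", "ratio"))
  # ratio requires prior background subtraction
  tr <- roi_trace("s1", "r1", t, rep(1, 20), rep(1, 20), 100)
  expect_error(compute_ratio(tr), "background subtraction first")
})

test_that("drift fit recovers exponential parameters", {
  t <- seq(0, 1500, by = 5)
  # flat trace: amplitude ~ 0, level preserved
  flat <- fit_drift(make_ratio(rep(1.1, length(t))))
  expect_lt(abs(flat$amplitude_A), 1e-8)
  expect_equal(flat$offset_B, 1.1, tolerance = 1e-8)

  # pure noiseless drift: parameters to 1e-6 relative
  r <- 1.05 + 0.05 * (1 - exp(-t / 300))
  m <- fit_drift(make_ratio(r))
  expect_equal(m$amplitude_A, 0.05, tolerance = 1e-6)
  expect_equal(m$tau_s, 300, tolerance = 1e-6)
  expect_equal(m$offset_B, 1.05, tolerance = 1e-6)

  # drift + masked bath step: parameters still recovered
  step <- ifelse(t >= 600, 0.24, 0)
  rt <- make_ratio(r + step)
  mask <- event_mask(t, data.frame(kind = "bath_VU", onset_s = 600,
                                   offset_s = NA_real_))
  m2 <- fit_drift(rt, mask)
  expect_equal(m2$amplitude_A, 0.05, tolerance = 1e-3)
  expect_equal(m2$tau_s, 300, tolerance = 1e-3)

  expect_error(fit_drift(make_ratio(rep(1, 10))), "unmasked samples")
})

test_that("event masking distinguishes bath (to end) from puff (guarded) events", {
  t <- seq(0, 1500, by = 5)
  ev <- data.frame(kind = c("bath_VU", "puff_isoguvacine"),
                   onset_s = c(1000, 200), offset_s = c(NA_real_, NA_real_))
  mask <- event_mask(t, ev)
  expect_true(all(mask[t >= 940]))          # bath: masked to trace end
  expect_true(all(mask[t >= 140 & t <= 800]))  # puff: -60 to +600
  expect_false(any(mask[t > 800 & t < 940]))
})

test_that("drift correction flattens drift and passes steps through unbiased", {
  t <- seq(0, 1500, by = 5)
  r <- 1.05 + 0.05 * (1 - exp(-t / 300))
  rt <- make_ratio(r)
  m <- fit_drift(rt)
  corr <- correct_drift(rt, m)
  # flatness: |fitted linear slope| < 1e-6 ratio/s
  slope <- unname(coef(lm(corr$r_cl ~ t))[2])
  expect_lt(abs(slope), 1e-6)
  expect_equal(mean(corr$r_cl), 1.05, tolerance = 1e-6)
  expect_identical(corr$corrections, c("background", "ratio", "drift"))

  # A = 0 model is the identity in both modes
  m0 <- m; m0$amplitude_A <- 0
  expect_equal(correct_drift(rt, m0)$r_cl, rt$r_cl)
  expect_equal(correct_drift(rt, m0, mode = "subtract")$r_cl, rt$r_cl)

  # model/trace mismatch
  other <- make_ratio(r, roi_id = "roi9")
  expect_error(correct_drift(other, m), "roi9")

  # generator-rendered drift + embedded step of 0.24: amplitude preserved
  ev <- data.frame(kind = "bath_VU", onset_s = 600, offset_s = NA_real_)
  traj_r <- 1.05 + ifelse(t >= 600, 0.24 * (1 - exp(-(t - 600) / 1e-9)), 0)
  drift_gain <- 1 + 0.05 * (1 - exp(-t / 300))
  rt2 <- make_ratio(traj_r * drift_gain)
  m2 <- fit_drift(rt2, event_mask(t, ev))
  corr2 <- correct_drift(rt2, m2)
  delta <- mean(corr2$r_cl[t >= 1200 & t <= 1500]) -
    mean(corr2$r_cl[t >= 420 & t <= 590])
  expect_equal(delta, 0.24, tolerance = 0.005)
})

test_that("exposure adjustment estimates per-condition slopes and normalises to 100 ms", {
  set.seed(7)
  exposures <- rep(c(50, 100, 150, 200), each = 6)
  mk <- function(slope, base) {
    data.frame(exposure500_ms = exposures,
               steady_r = base + slope * (exposures - 100) +
                 rnorm(length(exposures), 0, 0.01))
  }
  b1 <- cbind(mk(5e-4, 1.10), condition = "AVP.day.bicarbonate")
  b2 <- cbind(mk(-2e-4, 1.15), condition = "VIP.day.bicarbonate")
  adj <- fit_exposure_adjustment(rbind(b1, b2))
  expect_named(adj, c("AVP.day.bicarbonate", "VIP.day.bicarbonate"))
  a1 <- adj[["AVP.day.bicarbonate"]]
  a2 <- adj[["VIP.day.bicarbonate"]]
  expect_lt(abs(a1$slope - 5e-4), 2 * a1$slope_se)
  expect_lt(abs(a2$slope + 2e-4), 2 * a2$slope_se)

  # all-identical exposures: unidentifiable unless identity is opted into
  one <- data.frame(exposure500_ms = 100, steady_r = 1.1,
                    condition = "c")[rep(1, 5), ]
  expect_error(fit_exposure_adjustment(one), "unidentifiable")
  expect_warning(adj0 <- fit_exposure_adjustment(one, allow_identity = TRUE),
                 "identity")
  expect_identical(adj0[["c"]]$slope, 0)

  # application: reference exposure is the identity; arithmetic elsewhere
  rt <- make_ratio(rep(1.2, 40), exposure = 200)
  a <- structure(list(condition = "AVP.day.bicarbonate", slope = 5e-4,
                      slope_se = 1e-5, reference_ms = 100, n = 24),
                 class = "exposure_adjustment")
  out <- apply_exposure_adjustment(rt, a, "AVP.day.bicarbonate")
  expect_equal(out$r_cl, rep(1.2 - 0.05, 40))
  rt100 <- make_ratio(rep(1.2, 40), exposure = 100)
  expect_equal(apply_exposure_adjustment(rt100, a, "AVP.day.bicarbonate")$r_cl,
               rt100$r_cl)
  expect_error(apply_exposure_adjustment(rt, a, "VIP.day.bicarbonate"),
               "condition")
})

test_that("adjusted multi-exposure baselines keep no residual exposure trend", {
  set.seed(11)
  exposures <- rep(c(50, 100, 200), each = 8)
  base <- data.frame(exposure500_ms = exposures,
                     steady_r = 1.1 + 4e-4 * (exposures - 100) +
                       rnorm(length(exposures), 0, 0.01),
                     condition = "AVP.day.bicarbonate")
  adj <- fit_exposure_adjustment(base)[[1]]
  corrected <- base$steady_r - adj$slope * (base$exposure500_ms - 100)
  fit <- summary(lm(corrected ~ base$exposure500_ms))$coefficients
  ci <- fit[2, 1] + c(-2, 2) * fit[2, 2]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("full preprocess chain is the identity on clean synthetic input", {
  cfg <- sim_config(seed = 5, n_slices = 1, rois_per_slice = 2,
                    conditions = list(condition("AVP", "day")),
                    events = empty_events(), noise = NULL, drift = NULL,
                    duration_s = 900)
  sim <- simulate_dataset(cfg)
  out <- preprocess_recording(sim$recordings[[1]])
  truth_r <- sim$truth$slices[[1]]$baseline_r + sim$truth$slices[[1]]$slice_effect
  for (r in out) {
    expect_lt(max(abs(r$r_cl - truth_r)), 1e-9)
    expect_identical(r$corrections, c("background", "ratio", "drift"))
  }
})
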