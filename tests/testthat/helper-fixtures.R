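# Shared fixtures, all built in code.

ref_cal <- function() reference_calibration()

# Deterministic two-slice recording set: 2 signal ROIs + background each.
make_recordings <- function(n_slices = 2L, n_samples = 10L, dt = 5) {
  time_s <- seq(0, by = dt, length.out = n_samples)
  recs <- list()
  for (i in seq_len(n_slices)) {
    sid <- sprintf("s%d", i)
    traces <- list(
      roi_trace(sid, "roi1", time_s, 600 + i + time_s / 100, rep(500 + i, n_samples), 100),
      roi_trace(sid, "roi2", time_s, 550 - i + time_s / 50, rep(480, n_samples), 100),
      roi_trace(sid, "bg", time_s, rep(40 + i, n_samples), rep(50, n_samples), 100,
                is_background = TRUE))
    recs[[sid]] <- slice_recording(
      sid, condition(if (i %% 2) "AVP" else "VIP", "day"), traces,
      data.frame(kind = "bath_VU", onset_s = 20, offset_s = NA_real_))
  }
  recs
}

# Ratio trace built directly in ratio space.
make_ratio <- function(r, dt = 5, slice_id = "s1", roi_id = "roi1",
                       exposure = 100) {
  time_s <- seq(0, by = dt, length.out = length(r))
  ratio_trace(slice_id, roi_id, time_s, r, exposure,
              corrections = c("background", "ratio"))
}

# Per-ROI effect table with known structure for GEE tests; the layout and
# draw order are frozen because test-inference.R asserts oracle values
# computed from this exact fixture with an independent GEE implementation.
make_gee_fixture <- function() {
  set.seed(42)
  rois <- c(3, 5, 4, 6, 2, 4, 5, 3)
  do.call(rbind, lapply(seq_len(8), function(i) {
    nt <- ifelse(i %% 2 == 0, "VIP", "AVP")
    ph <- ifelse(i <= 4, "day", "night")
    b <- rnorm(1, 0, 0.03)
    data.frame(slice_id = sprintf("s%d", i), neuron_type = nt, phase = ph,
               delta_r = 0.2 + 0.1 * (nt == "VIP") - 0.02 * (ph == "night") +
                 b + rnorm(rois[i], 0, 0.02))
  }))
}
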