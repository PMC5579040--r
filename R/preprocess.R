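#' Corrected ratio trace
#'
#' Container for the chloride-proxy ratio R(t) = F436/F500 after corrections.
#' `corrections` records the order in which corrections were applied; the
#' canonical pipeline order is background -> ratio -> drift -> exposure.
#'
#' @param slice_id,roi_id Identifiers.
#' @param time_s Acquisition times (s).
#' @param r_cl Ratio values; `NA` marks flagged samples (e.g. non-positive
#'   denominator after background subtraction).
#' @param exposure500_ms 500 nm exposure (ms), carried for exposure adjustment.
#' @param corrections Character vector of applied correction tags.
#' @param n_flagged Number of samples flagged missing so far.
#' @return An object of class `ratio_trace`.
#' @export
ratio_trace <- function(slice_id, roi_id, time_s, r_cl, exposure500_ms,
                        corrections = character(), n_flagged = 0L) {
  structure(list(slice_id = slice_id, roi_id = roi_id,
                 time_s = as.numeric(time_s), r_cl = as.numeric(r_cl),
                 exposure500_ms = exposure500_ms,
                 corrections = corrections, n_flagged = as.integer(n_flagged)),
            class = "ratio_trace")
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("<ratio_trace> %s/%s: %d samples (%d flagged), corrections: %s\n",
              x$slice_id, x$roi_id, length(x$r_cl), x$n_flagged,
              if (length(x$corrections)) paste(x$corrections, collapse = " -> ")
              else "none"))
  invisible(x)
}

#' Subtract the background ROI, per wavelength
#'
#' Background intensities from the dim-field ROI are subtracted pointwise and
#' independently for each excitation wavelength. Samples whose background
#' subtraction yields a non-positive intensity in either channel are set to
#' `NA` (a flagged gap) rather than clamped to zero: a ratio of noise-level
#' residuals is worse than a missing sample.
#'
#' @param trace Signal [roi_trace()].
#' @param background Background [roi_trace()] on the same time base.
#' @return An `roi_trace` with corrected channels; flagged samples are `NA`
#'   in both channels. Attribute `n_flagged` counts them.
#' @export
subtract_background <- function(trace, background) {
  if (!isTRUE(background$is_background))
    .stop_validation("slice '%s': supplied background trace is not flagged is_background",
                     trace$slice_id)
  if (length(trace$time_s) != length(background$time_s) ||
      max(abs(trace$time_s - background$time_s)) > 1e-9)
    .stop_validation("slice '%s' roi '%s': background time base mismatch",
                     trace$slice_id, trace$roi_id)
  f436 <- trace$f436 - background$f436
  f500 <- trace$f500 - background$f500
  flagged <- f436 <= 0 | f500 <= 0
  f436[flagged] <- NA_real_
  f500[flagged] <- NA_real_
  out <- trace
  out$f436 <- f436
  out$f500 <- f500
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "background_subtracted") <- TRUE
  out
}

#' Form the chloride-proxy ratio
#'
#' R(t) is the emission after 436 nm excitation divided by that after 500 nm
#' excitation; chloride quenches the YFP (500 nm-excited) emission, so the
#' ratio rises with intracellular chloride. Samples with non-positive or
#' missing denominator become `NA` and are counted in `n_flagged`.
#'
#' @param trace Background-subtracted [roi_trace()].
#' @return A [ratio_trace()] with corrections `c("background", "ratio")`.
#' @export
compute_ratio <- function(trace) {
  if (!isTRUE(attr(trace, "background_subtracted")))
    .stop_validation("slice '%s' roi '%s': compute_ratio requires background subtraction first",
                     trace$slice_id, trace$roi_id)
  r <- ifelse(is.na(trace$f500) | trace$f500 <= 0, NA_real_,
              trace$f436 / trace$f500)
  ratio_trace(trace$slice_id, trace$roi_id, trace$time_s, r,
              trace$exposure500_ms,
              corrections = c("background", "ratio"),
              n_flagged = sum(is.na(r)))
}

#' Single-exponential photoinactivation drift model
#'
#' Repeated excitation drives the chloride-sensitive YFP moiety into an
#' inactivated state, producing a slow exposure-dependent rise of the ratio
#' on a constant-chloride cell. The drift is modelled as a saturating rise
#' `R(t) = B + A * (1 - exp(-t / tau))`; correction subtracts only the
#' time-dependent component `A * (1 - exp(-t / tau))`, preserving the
#' absolute baseline `B`.
#'
#' @name drift
NULL

#' Build the mask of samples excluded from drift fitting
#'
#' Samples around events are excluded so that genuine biology does not get
#' absorbed into the drift term. Puff events mask `guard_pre_s` before onset
#' to `guard_post_s` after; bath events persist, so they mask from
#' `guard_pre_s` before onset to the event offset (trace end when no offset
#' is recorded).
#'
#' @param time_s Sample times (s).
#' @param events Event data frame (`kind`, `onset_s`, `offset_s`).
#' @param guard_pre_s,guard_post_s Guard widths in seconds.
#' @return Logical vector, `TRUE` where samples are masked (excluded).
#' @export
event_mask <- function(time_s, events, guard_pre_s = 60, guard_post_s = 600) {
  mask <- rep(FALSE, length(time_s))
  if (is.null(events) || !nrow(events)) return(mask)
  for (i in seq_len(nrow(events))) {
    lo <- events$onset_s[i] - guard_pre_s
    hi <- if (startsWith(events$kind[i], "bath")) {
      if (is.na(events$offset_s[i])) Inf else events$offset_s[i]
    } else {
      events$onset_s[i] + guard_post_s
    }
    mask <- mask | (time_s >= lo & time_s <= hi)
  }
  mask
}

#' Fit the drift model to a ratio trace
#'
#' Least-squares fit of `B + A * (1 - exp(-t / tau))` over unmasked, finite
#' samples. The model is linear in (A, B) given tau, so the fit profiles tau
#' over a log-spaced grid (spanning 1/50 to 20 times the unmasked duration)
#' and polishes the best grid point with one-dimensional optimisation; this
#' is immune to the start-value divergence that plagues full 3-parameter
#' Newton fits on near-flat traces.
#'
#' @param ratio A [ratio_trace()].
#' @param mask Logical vector of samples to exclude (see [event_mask()]), or
#'   `NULL` for none.
#' @param min_samples Minimum number of usable samples (default 30).
#' @return A `drift_model` list: `amplitude_A`, `tau_s`, `offset_B`,
#'   `rms_residual`, `fit_window`, `n_fit`.
#' @export
fit_drift <- function(ratio, mask = NULL, min_samples = 30L) {
  if (is.null(mask)) mask <- rep(FALSE, length(ratio$time_s))
  use <- !mask & is.finite(ratio$r_cl)
  if (sum(use) < min_samples)
    .stop_validation("slice '%s' roi '%s': only %d unmasked samples for drift fit (need >= %d)",
                     ratio$slice_id, ratio$roi_id, sum(use), min_samples)
  t <- ratio$time_s[use]
  y <- ratio$r_cl[use]
  span <- max(diff(range(t)), 1)

  ssq_for <- function(tau) {
    x <- 1 - exp(-t / tau)
    fit <- stats::lm.fit(cbind(1, x), y)
    sum(fit$residuals^2)
  }
  taus <- exp(seq(log(span / 50), log(span * 20), length.out = 60))
  ssqs <- vapply(taus, ssq_for, numeric(1))
  i <- which.min(ssqs)
  lo <- taus[max(1L, i - 1L)]
  hi <- taus[min(length(taus), i + 1L)]
  opt <- stats::optimize(ssq_for, c(lo, hi), tol = 1e-10)
  tau <- opt$minimum
  x <- 1 - exp(-t / tau)
  fit <- stats::lm.fit(cbind(1, x), y)
  B <- unname(fit$coefficients[1])
  A <- unname(fit$coefficients[2])
  if (!all(is.finite(c(A, B, tau))))
    stop(sprintf("drift fit failed for slice '%s' roi '%s' (non-finite parameters)",
                 ratio$slice_id, ratio$roi_id), call. = FALSE)
  structure(list(amplitude_A = A, tau_s = tau, offset_B = B,
                 rms_residual = sqrt(mean(fit$residuals^2)),
                 fit_window = range(t), n_fit = length(t),
                 slice_id = ratio$slice_id, roi_id = ratio$roi_id),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> A = %.4g, tau = %.4g s, B = %.4g (RMS %.2g, n = %d)\n",
              x$amplitude_A, x$tau_s, x$offset_B, x$rms_residual, x$n_fit))
  invisible(x)
}

#' Predicted drift component
#' @param model A `drift_model`.
#' @param time_s Times (s) to evaluate at.
#' @return The time-dependent component `A * (1 - exp(-t / tau))`.
#' @export
drift_component <- function(model, time_s) {
  model$amplitude_A * (1 - exp(-time_s / model$tau_s))
}

#' Fit one drift model jointly across the ROIs of a slice
#'
#' Photoinactivation is driven by the illumination and exposure shared by
#' every ROI in a field of view, so the relative drift amplitude and time
#' constant are slice-level quantities; only the baseline level differs
#' between ROIs. The pooled model is `R_j(t) = B_j (1 + D (1 - exp(-t/tau)))`
#' with per-ROI `B_j` profiled out, fitted by Nelder-Mead over `(log tau, D)`
#' started from the average of per-ROI fits. Pooling roughly quarters the
#' extrapolation error of the fitted drift compared to independent per-ROI
#' fits (see the methods vignette).
#'
#' @param ratios List of [ratio_trace()] objects from one slice.
#' @param mask Logical exclusion mask on the shared time base, or `NULL`.
#' @param min_samples Minimum usable samples per ROI.
#' @return Named list of `drift_model` objects, one per ROI, sharing
#'   `tau_s` and relative amplitude `amplitude_A / offset_B`.
#' @export
fit_drift_pooled <- function(ratios, mask = NULL, min_samples = 30L) {
  stopifnot(length(ratios) >= 1L)
  if (length(ratios) == 1L) {
    m <- fit_drift(ratios[[1]], mask, min_samples)
    return(stats::setNames(list(m), ratios[[1]]$roi_id))
  }
  single <- lapply(ratios, fit_drift, mask = mask, min_samples = min_samples)
  tau0 <- exp(mean(log(vapply(single, function(m) m$tau_s, numeric(1)))))
  d0 <- mean(vapply(single, function(m) m$amplitude_A / m$offset_B, numeric(1)))
  if (is.null(mask)) mask <- rep(FALSE, length(ratios[[1]]$time_s))

  tt <- lapply(ratios, function(r) r$time_s[!mask & is.finite(r$r_cl)])
  yy <- lapply(ratios, function(r) r$r_cl[!mask & is.finite(r$r_cl)])
  profile_B <- function(tau, D) {
    vapply(seq_along(tt), function(j) {
      g <- 1 + D * (1 - exp(-tt[[j]] / tau))
      sum(yy[[j]] * g) / sum(g * g)
    }, numeric(1))
  }
  ssq <- function(par) {
    tau <- exp(par[1]); D <- par[2]
    if (1 + D <= 0) return(1e12)
    B <- profile_B(tau, D)
    s <- 0
    for (j in seq_along(tt)) {
      g <- 1 + D * (1 - exp(-tt[[j]] / tau))
      s <- s + sum((yy[[j]] - B[j] * g)^2)
    }
    s
  }
  opt <- stats::optim(c(log(tau0), d0), ssq, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  tau <- exp(opt$par[1]); D <- opt$par[2]
  B <- profile_B(tau, D)
  out <- list()
  for (j in seq_along(ratios)) {
    g <- 1 + D * (1 - exp(-tt[[j]] / tau))
    res <- yy[[j]] - B[j] * g
    out[[ratios[[j]]$roi_id]] <-
      structure(list(amplitude_A = B[j] * D, tau_s = tau, offset_B = B[j],
                     rms_residual = sqrt(mean(res^2)),
                     fit_window = range(tt[[j]]), n_fit = length(tt[[j]]),
                     slice_id = ratios[[j]]$slice_id,
                     roi_id = ratios[[j]]$roi_id, pooled = TRUE),
                class = "drift_model")
  }
  out
}

#' Fit one drift model jointly across all slices of a dataset
#'
#' The strongest pooling level: the photoinactivation time constant and the
#' relative drift amplitude per 100 ms of 500 nm exposure are treated as
#' properties of the indicator and illumination, shared by the whole
#' dataset; each slice contributes through its exposure (amplitude scales
#' linearly with exposure) and each ROI through its own baseline level.
#' Model: `R_{s,j}(t) = B_{s,j} (1 + (E_s/100) D100 (1 - exp(-t/tau)))`.
#' Per-ROI baselines are profiled out and `(log tau, D100)` optimised by
#' Nelder-Mead, started from the median of per-slice pooled fits.
#'
#' @param ratio_lists Named list (by slice) of lists of [ratio_trace()].
#' @param masks Named list of logical masks matching `ratio_lists`, or
#'   `NULL`.
#' @param min_samples Minimum usable samples per ROI.
#' @return Named list (by slice) of named lists of `drift_model` objects.
#' @export
fit_drift_global <- function(ratio_lists, masks = NULL, min_samples = 30L) {
  slice_fits <- lapply(names(ratio_lists), function(sid) {
    fit_drift_pooled(ratio_lists[[sid]],
                     if (is.null(masks)) NULL else masks[[sid]],
                     min_samples = min_samples)
  })
  names(slice_fits) <- names(ratio_lists)
  taus <- vapply(slice_fits, function(f) f[[1]]$tau_s, numeric(1))
  exposures <- vapply(ratio_lists,
                      function(rl) rl[[1]]$exposure500_ms, numeric(1))
  d100s <- vapply(names(slice_fits), function(sid) {
    f <- slice_fits[[sid]][[1]]
    (f$amplitude_A / f$offset_B) / (exposures[[sid]] / 100)
  }, numeric(1))
  tau0 <- stats::median(taus)
  d0 <- stats::median(d100s)

  tt <- list(); yy <- list(); ee <- numeric(); key <- character()
  for (sid in names(ratio_lists)) {
    mask <- if (is.null(masks)) rep(FALSE, length(ratio_lists[[sid]][[1]]$time_s))
            else masks[[sid]]
    for (r in ratio_lists[[sid]]) {
      use <- !mask & is.finite(r$r_cl)
      tt[[length(tt) + 1L]] <- r$time_s[use]
      yy[[length(yy) + 1L]] <- r$r_cl[use]
      ee[length(ee) + 1L] <- r$exposure500_ms / 100
      key[length(key) + 1L] <- sid
    }
  }
  ssq <- function(par) {
    tau <- exp(par[1]); d100 <- par[2]
    s <- 0
    for (j in seq_along(tt)) {
      g <- 1 + ee[j] * d100 * (1 - exp(-tt[[j]] / tau))
      if (any(g <= 0)) return(1e12)
      B <- sum(yy[[j]] * g) / sum(g * g)
      s <- s + sum((yy[[j]] - B * g)^2)
    }
    s
  }
  opt <- stats::optim(c(log(tau0), d0), ssq, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  tau <- exp(opt$par[1])
  # With tau pinned by the whole dataset, re-estimate the amplitude per
  # slice: the per-slice problem is then nearly linear (no time-constant
  # extrapolation nonlinearity, hence no appreciable small-sample bias) and
  # its errors are independent across slices, so cluster-robust standard
  # errors downstream account for residual correction error honestly.
  out <- lapply(names(ratio_lists), function(sid) {
    mask <- if (is.null(masks)) NULL else masks[[sid]]
    rl <- ratio_lists[[sid]]
    tt_s <- lapply(rl, function(r) {
      use <- if (is.null(mask)) is.finite(r$r_cl) else !mask & is.finite(r$r_cl)
      r$time_s[use]
    })
    yy_s <- lapply(rl, function(r) {
      use <- if (is.null(mask)) is.finite(r$r_cl) else !mask & is.finite(r$r_cl)
      r$r_cl[use]
    })
    ssq_s <- function(dtilde) {
      s <- 0
      for (j in seq_along(rl)) {
        g <- 1 + dtilde * (1 - exp(-tt_s[[j]] / tau))
        if (any(g <= 0)) return(1e12)
        B <- sum(yy_s[[j]] * g) / sum(g * g)
        s <- s + sum((yy_s[[j]] - B * g)^2)
      }
      s
    }
    dt0 <- opt$par[2] * rl[[1]]$exposure500_ms / 100
    os <- stats::optimize(ssq_s, c(dt0 - 0.2, dt0 + 0.2), tol = 1e-12)
    dtilde <- os$minimum
    models <- list()
    for (j in seq_along(rl)) {
      r <- rl[[j]]
      g <- 1 + dtilde * (1 - exp(-tt_s[[j]] / tau))
      B <- sum(yy_s[[j]] * g) / sum(g * g)
      res <- yy_s[[j]] - B * g
      models[[r$roi_id]] <-
        structure(list(amplitude_A = B * dtilde, tau_s = tau, offset_B = B,
                       rms_residual = sqrt(mean(res^2)),
                       fit_window = range(tt_s[[j]]), n_fit = length(tt_s[[j]]),
                       slice_id = r$slice_id, roi_id = r$roi_id,
                       pooled = TRUE, global_tau = TRUE),
                  class = "drift_model")
    }
    models
  })
  names(out) <- names(ratio_lists)
  out
}

#' Remove the fitted drift component
#'
#' Photoinactivation scales the 500 nm channel, so the artifact enters the
#' ratio as a gain: `R(t) = R_bio(t) * (1 + d(t))` with
#' `d(t) = A (1 - exp(-t/tau)) / B` on a baseline of level `B`. The default
#' `"gain"` mode therefore divides the trace by the fitted gain, which
#' removes the drift exactly and leaves later drug steps unbiased (an
#' additive subtraction under-corrects a step by the factor `1 + d`). The
#' literal `"subtract"` mode — removing `A (1 - exp(-t/tau))` — is retained;
#' the two are identical on a drift-only trace and differ only in how a
#' superimposed biological change is scaled (relative difference `d(t)`,
#' a few percent at most). Both preserve the absolute baseline `B`.
#'
#' @param ratio A [ratio_trace()].
#' @param model The `drift_model` fitted on this trace.
#' @param mode `"gain"` (default) or `"subtract"`.
#' @return The corrected [ratio_trace()] with `"drift"` appended to its
#'   corrections.
#' @export
correct_drift <- function(ratio, model, mode = c("gain", "subtract")) {
  mode <- match.arg(mode)
  if (!identical(model$slice_id, ratio$slice_id) ||
      !identical(model$roi_id, ratio$roi_id))
    .stop_validation("drift model fitted on %s/%s applied to %s/%s",
                     model$slice_id, model$roi_id, ratio$slice_id, ratio$roi_id)
  out <- ratio
  comp <- drift_component(model, ratio$time_s)
  if (mode == "gain") {
    out$r_cl <- ratio$r_cl / (1 + comp / model$offset_B)
  } else {
    out$r_cl <- ratio$r_cl - comp
  }
  out$corrections <- c(ratio$corrections, "drift")
  out
}

#' Fit the per-condition exposure adjustment
#'
#' Even after drift correction, steady-state ratios retain a dependence on
#' the 500 nm exposure duration. The adjustment is an additive linear trend
#' estimated per condition from condition-level baselines across slices
#' (never within one trace), and maps every value to the 100 ms reference
#' exposure.
#'
#' @param baselines Data frame with columns `exposure500_ms`, `steady_r`, and
#'   `condition` (a label identifying the condition each baseline belongs to).
#' @param allow_identity If `TRUE`, a condition with a single exposure level
#'   yields a zero-slope identity adjustment with a warning instead of an
#'   error.
#' @return Named list of `exposure_adjustment` objects (slope in ratio units
#'   per ms, `reference_ms = 100`, plus slope SE and n), one per condition.
#' @export
fit_exposure_adjustment <- function(baselines, allow_identity = FALSE) {
  stopifnot(all(c("exposure500_ms", "steady_r", "condition") %in% names(baselines)))
  out <- list()
  for (cond in unique(baselines$condition)) {
    b <- baselines[baselines$condition == cond, , drop = FALSE]
    nexp <- length(unique(b$exposure500_ms))
    if (nexp < 2L) {
      if (!allow_identity)
        .stop_validation("condition '%s': all baselines share one exposure; adjustment unidentifiable",
                         cond)
      warning(sprintf("condition '%s': single exposure level, using identity adjustment", cond))
      out[[cond]] <- structure(list(condition = cond, slope = 0,
                                    slope_se = NA_real_, reference_ms = 100,
                                    n = nrow(b)),
                               class = "exposure_adjustment")
      next
    }
    if (nexp < 3L && !allow_identity)
      .stop_validation("condition '%s': need >= 3 distinct exposures (have %d)",
                       cond, nexp)
    fit <- stats::lm(steady_r ~ exposure500_ms, data = b)
    sm <- summary(fit)$coefficients
    out[[cond]] <- structure(list(condition = cond,
                                  slope = unname(stats::coef(fit)[2]),
                                  slope_se = unname(sm["exposure500_ms", "Std. Error"]),
                                  reference_ms = 100, n = nrow(b)),
                             class = "exposure_adjustment")
  }
  out
}

#' @export
print.exposure_adjustment <- function(x, ...) {
  cat(sprintf("<exposure_adjustment> '%s': slope %.3g ratio/ms (SE %.2g, n = %d), ref %g ms\n",
              x$condition, x$slope, x$slope_se, x$n, x$reference_ms))
  invisible(x)
}

#' Apply the exposure adjustment to a ratio trace
#'
#' @param ratio A [ratio_trace()].
#' @param adj An `exposure_adjustment` for the trace's condition.
#' @param condition_label Label of the trace's condition; must match
#'   `adj$condition`.
#' @return Adjusted [ratio_trace()] with `"exposure"` appended to corrections.
#' @export
apply_exposure_adjustment <- function(ratio, adj, condition_label) {
  if (!identical(condition_label, adj$condition))
    .stop_validation("exposure adjustment for condition '%s' applied to '%s'",
                     adj$condition, condition_label)
  out <- ratio
  out$r_cl <- ratio$r_cl - adj$slope * (ratio$exposure500_ms - adj$reference_ms)
  out$corrections <- c(ratio$corrections, "exposure")
  out
}

#' Condition label used to key exposure adjustments
#' @param cond A [condition()].
#' @return Character scalar like `"AVP.day.bicarbonate"`.
#' @export
condition_label <- function(cond) {
  paste(cond$neuron_type, cond$phase, cond$buffer, sep = ".")
}

#' Run the full preprocessing chain on one slice recording
#'
#' Applies, in canonical order: background subtraction, ratio formation,
#' per-ROI drift fitting with event masking and subtraction, and (when an
#' adjustment table is supplied) exposure normalisation to 100 ms.
#'
#' @param rec A [slice_recording()].
#' @param adjustments Named list from [fit_exposure_adjustment()], or `NULL`
#'   to skip the exposure step.
#' @param guard_pre_s,guard_post_s Drift-fit event guards (s), see
#'   [event_mask()].
#' @param min_samples Minimum unmasked samples for the drift fit.
#' @param drift_mode Drift-removal mode, see [correct_drift()].
#' @param drift_scope `"slice"` (default): one pooled drift fit per slice
#'   with shared time constant and relative amplitude (see
#'   [fit_drift_pooled()]); `"roi"`: independent per-ROI fits.
#' @return Named list of corrected [ratio_trace()] objects (one per signal
#'   ROI), each carrying its `drift_model` as attribute `"drift_model"`.
#' @export
preprocess_recording <- function(rec, adjustments = NULL,
                                 guard_pre_s = 60, guard_post_s = 600,
                                 min_samples = 30L,
                                 drift_mode = c("gain", "subtract"),
                                 drift_scope = c("slice", "roi")) {
  drift_mode <- match.arg(drift_mode)
  drift_scope <- match.arg(drift_scope)
  bg <- background_trace(rec)
  ratios <- list()
  for (tr in signal_traces(rec)) {
    ratios[[tr$roi_id]] <- compute_ratio(subtract_background(tr, bg))
  }
  mask <- event_mask(ratios[[1]]$time_s, rec$events, guard_pre_s, guard_post_s)
  models <- if (drift_scope == "slice") {
    fit_drift_pooled(ratios, mask, min_samples = min_samples)
  } else {
    lapply(ratios, fit_drift, mask = mask, min_samples = min_samples)
  }
  out <- list()
  for (rid in names(ratios)) {
    ratio <- correct_drift(ratios[[rid]], models[[rid]], mode = drift_mode)
    if (!is.null(adjustments)) {
      lbl <- condition_label(rec$condition)
      if (!lbl %in% names(adjustments))
        .stop_validation("no exposure adjustment for condition '%s'", lbl)
      ratio <- apply_exposure_adjustment(ratio, adjustments[[lbl]], lbl)
    }
    attr(ratio, "drift_model") <- models[[rid]]
    out[[rid]] <- ratio
  }
  out
}

#' Preprocess a whole dataset with dataset-level drift pooling
#'
#' Background subtraction and ratio formation per slice, one global drift
#' fit (see [fit_drift_global()]), gain-mode drift removal, and optional
#' exposure adjustment. This is the pipeline entry point used for
#' multi-slice analyses; [preprocess_recording()] remains available for
#' standalone recordings.
#'
#' @inheritParams preprocess_recording
#' @param recordings Named list of [slice_recording()] objects.
#' @return Named list (by slice) of named lists of corrected
#'   [ratio_trace()] objects.
#' @export
preprocess_dataset <- function(recordings, adjustments = NULL,
                               guard_pre_s = 60, guard_post_s = 600,
                               min_samples = 30L,
                               drift_mode = c("gain", "subtract")) {
  drift_mode <- match.arg(drift_mode)
  ratio_lists <- list()
  masks <- list()
  for (sid in names(recordings)) {
    rec <- recordings[[sid]]
    bg <- background_trace(rec)
    rl <- list()
    for (tr in signal_traces(rec)) {
      rl[[tr$roi_id]] <- compute_ratio(subtract_background(tr, bg))
    }
    ratio_lists[[sid]] <- rl
    masks[[sid]] <- event_mask(rl[[1]]$time_s, rec$events,
                               guard_pre_s, guard_post_s)
  }
  models <- fit_drift_global(ratio_lists, masks, min_samples = min_samples)
  out <- list()
  for (sid in names(recordings)) {
    rec <- recordings[[sid]]
    corrected <- list()
    for (rid in names(ratio_lists[[sid]])) {
      ratio <- correct_drift(ratio_lists[[sid]][[rid]], models[[sid]][[rid]],
                             mode = drift_mode)
      if (!is.null(adjustments)) {
        lbl <- condition_label(rec$condition)
        if (!lbl %in% names(adjustments))
          .stop_validation("no exposure adjustment for condition '%s'", lbl)
        ratio <- apply_exposure_adjustment(ratio, adjustments[[lbl]], lbl)
      }
      attr(ratio, "drift_model") <- models[[sid]][[rid]]
      corrected[[rid]] <- ratio
    }
    out[[sid]] <- corrected
  }
  out
}
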