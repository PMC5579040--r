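#' Four-parameter sigmoid calibration of the chloride indicator
#'
#' The steady-state ratio R is related to chloride concentration C (mM) by a
#' Hill-type dose-response curve
#' \deqn{R(C) = R_{max} + \frac{R_{min} - R_{max}}{1 + (C/K_d)^p}}
#' which rises from `r_min` at C = 0 to `r_max` at saturating chloride
#' (chloride quenches the 500 nm-excited YFP emission, so F436/F500 grows
#' with C). Its exact algebraic inverse is
#' \deqn{C(R) = K_d \left(\frac{R_{min} - R}{R - R_{max}}\right)^{1/p}.}
#' Note the sign convention: the numerator of the forward form must be
#' `r_min - r_max` for the pair to be mutually consistent and for R(0) to
#' equal `r_min`; see the methods vignette for the full derivation.
#'
#' @param kd_mM Half-saturation constant (mM), > 0.
#' @param r_min Asymptote at 0 chloride.
#' @param r_max Asymptote at saturating chloride; must exceed `r_min`.
#' @param hill_p Hill coefficient, > 0.
#' @param covariance Optional 4x4 covariance of (kd, r_min, r_max, p).
#' @param n_points Number of calibration points behind the fit.
#' @return Object of class `calibration_fit`.
#' @examples
#' cal <- calibration_fit(kd_mM = 108.8, r_min = 0.98, r_max = 2.92,
#'                        hill_p = 2.91)
#' forward_model(cal, 22.7)   # ~ 1.00, bottom of the operating band
#' inverse_model(cal, 1.0)    # ~ 22.7 mM resting chloride
#' @export
calibration_fit <- function(kd_mM, r_min, r_max, hill_p,
                            covariance = NULL, n_points = NA_integer_) {
  if (!is.finite(kd_mM) || kd_mM <= 0) stop("kd_mM must be > 0", call. = FALSE)
  if (!is.finite(hill_p) || hill_p <= 0) stop("hill_p must be > 0", call. = FALSE)
  if (!(r_max > r_min)) stop("r_max must exceed r_min", call. = FALSE)
  structure(list(kd_mM = kd_mM, r_min = r_min, r_max = r_max, hill_p = hill_p,
                 covariance = covariance, n_points = n_points),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> Kd = %.4g mM, Rmin = %.4g, Rmax = %.4g, p = %.4g",
              x$kd_mM, x$r_min, x$r_max, x$hill_p))
  if (!is.na(x$n_points)) cat(sprintf(" (n = %d points)", x$n_points))
  cat("\n")
  invisible(x)
}

#' @rdname calibration_fit
#' @param fit A `calibration_fit`.
#' @param cl_mM Chloride concentration(s), mM, >= 0.
#' @export
forward_model <- function(fit, cl_mM) {
  if (any(cl_mM < 0, na.rm = TRUE))
    stop("negative chloride concentration", call. = FALSE)
  fit$r_max + (fit$r_min - fit$r_max) / (1 + (cl_mM / fit$kd_mM)^fit$hill_p)
}

#' @rdname calibration_fit
#' @param r_cl Ratio value(s). Values at or below `r_min` return 0 (floor
#'   flag); values at or above `r_max` return `NA` (ceiling flag). Flags are
#'   attached as attribute `"flags"` when any sample is out of range.
#' @export
inverse_model <- function(fit, r_cl) {
  out <- rep(NA_real_, length(r_cl))
  flags <- rep("ok", length(r_cl))
  floor_i <- !is.na(r_cl) & r_cl <= fit$r_min
  ceil_i <- !is.na(r_cl) & r_cl >= fit$r_max
  ok <- !is.na(r_cl) & !floor_i & !ceil_i
  out[floor_i] <- 0
  flags[floor_i] <- "floor"
  flags[ceil_i] <- "ceiling"
  flags[is.na(r_cl)] <- "missing"
  out[ok] <- fit$kd_mM *
    ((fit$r_min - r_cl[ok]) / (r_cl[ok] - fit$r_max))^(1 / fit$hill_p)
  if (any(flags != "ok")) attr(out, "flags") <- flags
  out
}

#' Convert a ratio change into a chloride-concentration change
#'
#' Because the calibration is non-linear, a ratio change is converted by
#' differencing the inverse model at the two endpoints rather than by a
#' local slope. Endpoints outside the open interval (r_min, r_max) yield
#' `NA` with a flag attribute.
#'
#' @param fit A [calibration_fit()].
#' @param baseline_r Ratio before the intervention.
#' @param delta_r Ratio change.
#' @return Concentration change in mM (same sign as `delta_r`).
#' @examples
#' cal <- calibration_fit(108.8, 0.98, 2.92, 2.91)
#' delta_cl(cal, baseline_r = 1.05, delta_r = 0.27)  # ~ 29 mM
#' delta_cl(cal, baseline_r = 1.20, delta_r = 0.18)  # ~ 15 mM
#' @export
delta_cl <- function(fit, baseline_r, delta_r) {
  ends <- c(baseline_r, baseline_r + delta_r)
  if (any(ends <= fit$r_min | ends >= fit$r_max)) {
    out <- NA_real_
    attr(out, "flags") <- "out_of_range"
    return(out)
  }
  inverse_model(fit, ends[2]) - inverse_model(fit, ends[1])
}

# Residual function for the calibration fit, parameterised on the log scale
# for kd and p so box constraints are implicit.
.cal_resid <- function(par, cl, r) {
  kd <- exp(par[1]); p <- exp(par[4])
  rmin <- par[2]; rmax <- par[3]
  pred <- rmax + (rmin - rmax) / (1 + (cl / kd)^p)
  r - pred
}

#' Fit the sigmoid calibration to (concentration, ratio) points
#'
#' Nonlinear least squares with multi-start initialisation: asymptotes from
#' the observed extremes, Kd from the concentration nearest the mid-range
#' ratio, p = 1, followed by jittered restarts. Parameters are optimised on
#' a log scale for Kd and p, keeping them positive; fits with p outside
#' (0.5, 10) or with inverted asymptotes are rejected.
#'
#' @param points Data frame with columns `cl_mM`, `steady_r` (and optionally
#'   `slice_id`, kept for diagnostics).
#' @param init Optional named list overriding starting values
#'   (`kd_mM`, `r_min`, `r_max`, `hill_p`).
#' @param n_restarts Number of jittered restarts after the deterministic
#'   start (default 8).
#' @return A [calibration_fit()] with parameter covariance (from the Jacobian
#'   at the optimum) and residual diagnostics in attributes `"rms"` and
#'   `"sensitivity_note"`.
#' @export
fit_calibration <- function(points, init = NULL, n_restarts = 8L) {
  stopifnot(all(c("cl_mM", "steady_r") %in% names(points)))
  cl <- points$cl_mM
  r <- points$steady_r
  if (any(!is.finite(cl)) || any(!is.finite(r)))
    stop("non-finite calibration points", call. = FALSE)
  if (any(r <= 0)) stop("steady_r must be positive", call. = FALSE)
  ncl <- length(unique(cl))
  if (ncl < 5L)
    stop(sprintf("calibration unidentifiable: %d distinct concentrations (need >= 5)", ncl),
         call. = FALSE)

  rmin0 <- min(r) - 0.01 * diff(range(r))
  rmax0 <- max(r) + 0.01 * diff(range(r))
  mid_r <- (rmin0 + rmax0) / 2
  kd0 <- cl[which.min(abs(r - mid_r))]
  if (kd0 <= 0) kd0 <- stats::median(cl[cl > 0])
  p0 <- 1
  if (!is.null(init)) {
    if (!is.null(init$kd_mM)) kd0 <- init$kd_mM
    if (!is.null(init$r_min)) rmin0 <- init$r_min
    if (!is.null(init$r_max)) rmax0 <- init$r_max
    if (!is.null(init$hill_p)) p0 <- init$hill_p
  }

  obj <- function(par) sum(.cal_resid(par, cl, r)^2)
  starts <- list(c(log(kd0), rmin0, rmax0, log(p0)))
  # deterministic jitters; no RNG so the fit itself is reproducible
  jit <- expand.grid(k = c(0.5, 1, 2), p = c(0.5, 1, 2, 4))
  for (i in seq_len(min(n_restarts + 3L, nrow(jit)))) {
    starts[[length(starts) + 1L]] <-
      c(log(kd0 * jit$k[i]), rmin0, rmax0, log(p0 * jit$p[i]))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with BFGS for tight convergence on smooth problems
    fit <- tryCatch(
      stats::optim(fit$par, obj, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15)),
      error = function(e) fit)
    p_hat <- exp(fit$par[4])
    if (p_hat <= 0.5 || p_hat >= 10) next
    if (fit$par[3] <= fit$par[2]) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("calibration fit failed to converge from any start", call. = FALSE)

  par <- best$par
  kd <- exp(par[1]); rmin <- par[2]; rmax <- par[3]; p <- exp(par[4])
  n <- length(r)
  dof <- n - 4L
  rms <- sqrt(best$value / n)
  # covariance on the natural scale via numeric Jacobian + delta method
  covariance <- NULL
  if (dof > 0) {
    theta <- c(kd, rmin, rmax, p)
    pred_fun <- function(th) {
      th[3] + (th[2] - th[3]) / (1 + (cl / th[1])^th[4])
    }
    J <- matrix(0, n, 4)
    h <- pmax(abs(theta), 1e-4) * 1e-6
    for (j in 1:4) {
      tp <- theta; tp[j] <- tp[j] + h[j]
      tm <- theta; tm[j] <- tm[j] - h[j]
      J[, j] <- (pred_fun(tp) - pred_fun(tm)) / (2 * h[j])
    }
    s2 <- best$value / dof
    JtJ <- crossprod(J)
    covariance <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
    if (!is.null(covariance))
      dimnames(covariance) <- list(c("kd_mM", "r_min", "r_max", "hill_p"),
                                   c("kd_mM", "r_min", "r_max", "hill_p"))
  }
  out <- calibration_fit(kd, rmin, rmax, p, covariance = covariance,
                         n_points = n)
  attr(out, "rms") <- rms
  # the inverse model's sensitivity d[Cl]/dR diverges as R -> r_min+: a fixed
  # ratio uncertainty maps to unbounded concentration uncertainty near the
  # bottom of the operating band
  attr(out, "sensitivity_note") <-
    "d[Cl]/dR grows without bound as R approaches r_min; concentration estimates near the floor carry large uncertainty"
  out
}

#' Serialize / load a calibration fit as JSON
#' @param fit A [calibration_fit()].
#' @param path JSON path.
#' @export
write_calibration <- function(fit, path) {
  obj <- list(kd_mM = fit$kd_mM, r_min = fit$r_min, r_max = fit$r_max,
              hill_p = fit$hill_p, n_points = fit$n_points,
              rms = attr(fit, "rms"))
  if (!is.null(fit$covariance))
    obj$covariance <- unname(apply(fit$covariance, 1, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covr <- NULL
  if (!is.null(obj$covariance)) {
    covr <- matrix(unlist(obj$covariance), 4, 4, byrow = TRUE)
    dimnames(covr) <- list(c("kd_mM", "r_min", "r_max", "hill_p"),
                           c("kd_mM", "r_min", "r_max", "hill_p"))
  }
  fit <- calibration_fit(obj$kd_mM, obj$r_min, obj$r_max, obj$hill_p,
                         covariance = covr,
                         n_points = if (is.null(obj$n_points)) NA_integer_ else obj$n_points)
  if (!is.null(obj$rms)) attr(fit, "rms") <- obj$rms
  fit
}

#' Read calibration points from CSV
#' @param path CSV with columns `cl_mM`, `steady_r` and optionally `slice_id`.
#' @return Validated data frame.
#' @export
read_calibration_points <- function(path) {
  if (!file.exists(path))
    stop(sprintf("calibration file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("cl_mM", "steady_r"), names(df))
  if (length(missing))
    .stop_validation("calibration CSV missing column(s): %s",
                     paste(missing, collapse = ", "))
  df
}

#' Published calibration constants for this indicator
#'
#' Convenience constructor with published constants for this indicator in
#' brain-slice recordings (Kd = 108.8 mM, Rmin = 0.98, Rmax = 2.92, p = 2.91).
#' These are dataset-specific: calibrations should normally be refitted.
#'
#' @return A [calibration_fit()].
#' @export
reference_calibration <- function() {
  calibration_fit(kd_mM = 108.8, r_min = 0.98, r_max = 2.92, hill_p = 2.91)
}

#' The chloride concentrations of the standard calibration solution series
#' @return Numeric vector of mM values.
#' @export
calibration_levels <- function() c(0, 4, 20, 40, 60, 80, 123)
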