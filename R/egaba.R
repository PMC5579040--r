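#' Voltage-ramp current pair
#'
#' Currents recorded during a ~400 ms voltage ramp (spanning roughly 60 mV),
#' once during a GABA puff and once without agonist. The control trace
#' captures leak and intrinsic currents; subtracting it isolates the
#' GABA-A-mediated component whose zero crossing is the reversal potential.
#'
#' @param command_mV Strictly monotone command-voltage sequence (mV).
#' @param i_gaba_pA Current during the GABA puff (pA).
#' @param i_control_pA Current without GABA (pA).
#' @param sweep_id Optional identifier.
#' @return Object of class `ramp_pair`.
#' @export
ramp_pair <- function(command_mV, i_gaba_pA, i_control_pA, sweep_id = "sweep") {
  n <- length(command_mV)
  if (length(i_gaba_pA) != n || length(i_control_pA) != n)
    stop("ramp traces must share the command length", call. = FALSE)
  d <- diff(command_mV)
  if (!(all(d > 0) || all(d < 0)))
    stop("command voltage must be strictly monotone", call. = FALSE)
  structure(list(command_mV = as.numeric(command_mV),
                 i_gaba_pA = as.numeric(i_gaba_pA),
                 i_control_pA = as.numeric(i_control_pA),
                 sweep_id = as.character(sweep_id)),
            class = "ramp_pair")
}

#' Subtract the control ramp from the GABA ramp
#' @param pair A [ramp_pair()].
#' @return Data frame with `command_mV` and the difference current `i_pA`.
#' @export
subtract_ramp <- function(pair) {
  data.frame(command_mV = pair$command_mV,
             i_pA = pair$i_gaba_pA - pair$i_control_pA)
}

#' Estimate the GABA reversal potential from a subtracted ramp I-V
#'
#' The coarse zero crossing of a 5-point moving average of the difference
#' current locates the reversal; a straight line is then fitted to the raw
#' difference current within `window_mV` of that crossing and the reversal
#' potential is read off as the x-intercept. No series-resistance or
#' junction-potential correction is applied.
#'
#' @param diff_iv Data frame from [subtract_ramp()].
#' @param window_mV Half-width of the fit window around the coarse crossing
#'   (default 10 mV; GABA-A difference currents rectify away from reversal,
#'   so a narrow window limits bias).
#' @return Object of class `egaba_estimate`: `e_gaba_mV`, `slope_nS`,
#'   `fit_window_mV`, `r_squared`, `n_fit`.
#' @export
estimate_egaba <- function(diff_iv, window_mV = 10) {
  v <- diff_iv$command_mV
  i <- diff_iv$i_pA
  if (any(!is.finite(v)) || any(!is.finite(i)))
    stop("non-finite samples in difference I-V", call. = FALSE)
  sm <- .movavg5(i)
  sgn <- sign(sm)
  nz <- which(sgn != 0)
  crossings <- nz[which(diff(sgn[nz]) != 0)]
  if (!length(crossings))
    stop("reversal outside ramp: difference current does not cross zero",
         call. = FALSE)
  # Noise produces runs of adjacent sign flips around the one true reversal;
  # crossings within one fit-window width of each other belong to the same
  # reversal. Only well-separated crossing clusters are genuinely ambiguous.
  vc <- sort(v[crossings])
  cluster_id <- cumsum(c(1, diff(vc) > window_mV))
  if (max(cluster_id) > 1L) {
    reps <- vapply(split(vc, cluster_id), stats::median, numeric(1))
    stop(sprintf("multiple zero crossings at command voltages: %s mV",
                 paste(round(reps, 1), collapse = ", ")), call. = FALSE)
  }
  v0 <- stats::median(vc)
  sel <- abs(v - v0) <= window_mV
  if (sum(sel) < 3L)
    stop("fewer than 3 samples inside the fit window", call. = FALSE)
  fit <- stats::lm(i[sel] ~ v[sel])
  b <- unname(stats::coef(fit))
  if (b[2] <= 0)
    stop("non-positive conductance in fit window: not a valid agonist response",
         call. = FALSE)
  e <- -b[1] / b[2]
  if (e < min(v) || e > max(v))
    stop("fitted reversal lies outside the command range", call. = FALSE)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((i[sel] - mean(i[sel]))^2)
  structure(list(e_gaba_mV = e, slope_nS = b[2], # pA/mV == nS
                 fit_window_mV = c(v0 - window_mV, v0 + window_mV),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_fit = sum(sel)),
            class = "egaba_estimate")
}

.movavg5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  out <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  out <- as.numeric(out)
  # shrink the window at the edges instead of dropping samples
  out[1] <- mean(x[1:3]); out[2] <- mean(x[1:4])
  out[n - 1] <- mean(x[(n - 3):n]); out[n] <- mean(x[(n - 2):n])
  out
}

#' @export
print.egaba_estimate <- function(x, ...) {
  cat(sprintf("<egaba_estimate> E = %.2f mV, g = %.3g nS, R2 = %.4f (n = %d in [%g, %g] mV)\n",
              x$e_gaba_mV, x$slope_nS, x$r_squared, x$n_fit,
              x$fit_window_mV[1], x$fit_window_mV[2]))
  invisible(x)
}

# CODATA constants
.GAS_R <- 8.314462618      # J / (mol K)
.FARADAY <- 96485.33212    # C / mol

#' Chloride Nernst potential and passive distribution
#'
#' For the monovalent anion the equilibrium potential is
#' \deqn{E_{Cl} = \frac{RT}{F}\,\ln\frac{[Cl]_{in}}{[Cl]_{out}}}
#' in mV. `passive_cl` inverts the relation: the internal concentration at
#' which chloride would be passively distributed for a given membrane
#' potential. Default temperature is the 34 C bath temperature.
#'
#' @param cl_out_mM,cl_in_mM External / internal chloride (mM), > 0.
#' @param temperature_C Temperature in Celsius (default 34).
#' @return `nernst_cl`: potential in mV. `passive_cl`: concentration in mM.
#' @examples
#' nernst_cl(cl_out_mM = 122, cl_in_mM = 12.2)    # ~ -60.9 mV at 34 C
#' passive_cl(cl_out_mM = 122, v_m_mV = -45)      # ~ 22.3 mM
#' @export
nernst_cl <- function(cl_out_mM, cl_in_mM, temperature_C = 34) {
  if (cl_out_mM <= 0 || cl_in_mM <= 0)
    stop("concentrations must be positive", call. = FALSE)
  rt_f <- .GAS_R * (temperature_C + 273.15) / .FARADAY * 1000  # mV
  rt_f * log(cl_in_mM / cl_out_mM)
}

#' @rdname nernst_cl
#' @param v_m_mV Membrane potential (mV).
#' @export
passive_cl <- function(cl_out_mM, v_m_mV, temperature_C = 34) {
  if (cl_out_mM <= 0)
    stop("concentrations must be positive", call. = FALSE)
  rt_f <- .GAS_R * (temperature_C + 273.15) / .FARADAY * 1000
  cl_out_mM * exp(v_m_mV / rt_f)
}

#' Read voltage-ramp pairs from CSV
#'
#' Schema: `sweep_id, command_mV, i_gaba_pA, i_control_pA`, one row per
#' command-voltage sample.
#'
#' @param path CSV path.
#' @return Named list of [ramp_pair()] objects keyed by sweep_id.
#' @export
read_ramps <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ramp file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sweep_id", "command_mV", "i_gaba_pA", "i_control_pA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stop_validation("ramp CSV missing column(s): %s",
                     paste(missing, collapse = ", "))
  out <- list()
  for (sw in unique(df$sweep_id)) {
    s <- df[df$sweep_id == sw, , drop = FALSE]
    out[[as.character(sw)]] <- ramp_pair(s$command_mV, s$i_gaba_pA,
                                         s$i_control_pA, sweep_id = sw)
  }
  out
}

#' @rdname read_ramps
#' @param pairs Named list of [ramp_pair()] objects.
#' @export
write_ramps <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(sweep_id = p$sweep_id, command_mV = p$command_mV,
               i_gaba_pA = p$i_gaba_pA, i_control_pA = p$i_control_pA,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  .write_csv_lossless(df, path, c("command_mV", "i_gaba_pA", "i_control_pA"))
}
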