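# Tonic (steady-state) analysis: parameter sweeps, oscillation detection and
# localisation of the Hopf boundary in the 5HT -> GABA(LHA) coupling.

#' Detect slow oscillations in a simulated time series
#'
#' Classifies a trajectory as oscillatory when the peak-to-trough excursion
#' of the serotonergic rate over the analysis window exceeds a threshold.
#' The period is estimated as the mean interval between successive maxima of
#' the serotonergic rate (at least three maxima are required; maxima are
#' local peaks in the upper half of the excursion, so integrator ripple is
#' ignored).
#'
#' @param ts a `drn_sim`, or any data frame with columns `time_s` and
#'   `f_5HT_Hz`.
#' @param amplitude_threshold peak-to-trough threshold, Hz.  The default
#'   0.05 Hz sits well above integrator noise and well below the
#'   oscillation amplitudes the circuit produces.
#' @param transient initial time span to discard, s.
#' @param min_window minimum analysis window after the transient, s.
#' @return An object of class `oscillation_summary`: list with `oscillatory`
#'   (logical), `amplitude` (peak-to-trough of the serotonergic rate, Hz) and
#'   `period` (s, `NA` if non-oscillatory or fewer than 3 maxima).
#' @examples
#' tt <- seq(0, 1200, by = 0.1)
#' synth <- data.frame(time_s = tt, f_5HT_Hz = 5 + sin(2 * pi * tt / 120))
#' detect_oscillation(synth)
#' @export
detect_oscillation <- function(ts, amplitude_threshold = 0.05,
                               transient = 0, min_window = 1000) {
  if (!all(c("time_s", "f_5HT_Hz") %in% names(ts)))
    stop("'ts' must have columns time_s and f_5HT_Hz")
  keep <- ts$time_s >= transient
  tt <- ts$time_s[keep]; x <- ts$f_5HT_Hz[keep]
  if (length(tt) < 3 || (max(tt) - min(tt)) < min_window)
    stop(sprintf("analysis window too short: need >= %g s beyond the transient",
                 min_window))
  amplitude <- max(x) - min(x)
  oscillatory <- amplitude > amplitude_threshold
  period <- NA_real_
  if (oscillatory) {
    pk <- which(diff(sign(diff(x))) == -2) + 1L
    pk <- pk[x[pk] > min(x) + 0.5 * amplitude]
    if (length(pk) >= 3) period <- mean(diff(tt[pk]))
  }
  structure(list(oscillatory = oscillatory, amplitude = amplitude,
                 period = period),
            class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  if (x$oscillatory)
    cat(sprintf("oscillatory: peak-to-trough %.3f Hz, period %s\n",
                x$amplitude,
                if (is.na(x$period)) "not resolved" else
                  sprintf("%.1f s", x$period)))
  else
    cat(sprintf("non-oscillatory (peak-to-trough %.3g Hz)\n", x$amplitude))
  invisible(x)
}

# Simulation-based oscillation classification for one parameter point.
# Starts near (1% off) the analytic fixed point and compares the rate
# excursion in two consecutive windows: a limit cycle keeps (or grows) its
# excursion, a stable focus rings down.  This makes the classification
# robust close to the Hopf point, where absolute amplitudes decay or grow
# on >1000 s timescales.
classify_oscillation <- function(circuit, ss = steady_state(circuit),
                                 window = 1000, dt = 0.01,
                                 amplitude_threshold = 0.05) {
  init <- ss$currents * 1.01 + 1e-3
  sim <- integrate_circuit(circuit, horizon = 3 * window, dt = dt,
                           init = init, record_every = 10L)
  x <- sim$f_5HT_Hz; tt <- sim$time_s
  amp_in <- function(a, b) {
    xi <- x[tt >= a & tt < b]
    max(xi) - min(xi)
  }
  a1 <- amp_in(window, 2 * window)
  a2 <- amp_in(2 * window, 3 * window)
  osc <- a2 > amplitude_threshold && a2 > 0.9 * a1
  summ <- if (osc) {
    detect_oscillation(sim, amplitude_threshold, transient = 2 * window,
                       min_window = window)
  } else {
    structure(list(oscillatory = FALSE, amplitude = a2, period = NA_real_),
              class = "oscillation_summary")
  }
  summ$oscillatory <- osc
  summ
}

#' Sweep a connection strength
#'
#' For each value on the grid the connection strength is set, the analytic
#' fixed point and its stability are computed, and --- where the fixed point
#' is linearly unstable --- the circuit is integrated for 2000 s from a
#' slightly perturbed fixed point, the first 1000 s are discarded, and the
#' oscillation envelope (minimum/maximum serotonergic rate) and period are
#' recorded.
#'
#' @param circuit a [drn_circuit].
#' @param name one of the twelve connection names (see [connections()]).
#' @param grid strictly increasing numeric vector of nonnegative connection
#'   strengths, pA/Hz.
#' @return An object of class `drn_sweep`: a data frame with columns
#'   `param_value`, `f_5HT`, `f_GABA_DRN`, `f_Ox`, `f_GABA_LHA` (the
#'   fixed-point rates, Hz), `stable`, `env_min_5HT`, `env_max_5HT` and
#'   `period_s` (`NA` where stable).  Rows where the computation fails carry
#'   `NA` and the error message in the `errors` attribute.
#' @examples
#' \donttest{
#' sw <- sweep_parameter(default_circuit(), "Ox_to_GABA_LHA", 0:6)
#' }
#' @export
sweep_parameter <- function(circuit, name, grid) {
  stopifnot(inherits(circuit, "drn_circuit"))
  if (!name %in% ALL_CONNECTIONS)
    stop(sprintf("unknown connection '%s'", name))
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("grid values must be finite and nonnegative")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  n <- length(grid)
  out <- data.frame(param_value = grid, f_5HT = NA_real_,
                    f_GABA_DRN = NA_real_, f_Ox = NA_real_,
                    f_GABA_LHA = NA_real_, stable = NA,
                    env_min_5HT = NA_real_, env_max_5HT = NA_real_,
                    period_s = NA_real_)
  errors <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      ci <- set_parameter(circuit, stats::setNames(grid[i], paste0("J.", name)))
      ss <- steady_state(ci)
      row <- c(ss$rates, stable = ss$stable, env_min = NA_real_,
               env_max = NA_real_, period = NA_real_)
      if (!ss$stable) {
        sim <- integrate_circuit(ci, horizon = 2000, dt = 0.01,
                                 init = ss$currents * 1.01 + 1e-3,
                                 record_every = 10L)
        w <- sim$time_s >= 1000
        row["env_min"] <- min(sim$f_5HT_Hz[w])
        row["env_max"] <- max(sim$f_5HT_Hz[w])
        det <- detect_oscillation(sim, transient = 1000)
        row["period"] <- det$period
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      out[i, 2:5] <- res[1:4]
      out$stable[i] <- as.logical(res["stable"])
      out$env_min_5HT[i] <- res["env_min"]
      out$env_max_5HT[i] <- res["env_max"]
      out$period_s[i] <- res["period"]
    }
  }
  structure(out, class = c("drn_sweep", "data.frame"),
            parameter = paste0("J.", name), errors = errors)
}

#' @export
plot.drn_sweep <- function(x, ...) {
  graphics::matplot(x$param_value, as.matrix(x[, 2:5]), type = "l", lty = 1,
                    xlab = paste(attr(x, "parameter"), "(pA/Hz)"),
                    ylab = "steady-state rate (Hz)", ...)
  if (any(!x$stable, na.rm = TRUE)) {
    graphics::lines(x$param_value, x$env_min_5HT, lty = 2)
    graphics::lines(x$param_value, x$env_max_5HT, lty = 2)
  }
  graphics::legend("topright", legend = c(POPULATIONS, "5HT envelope"),
                   lty = c(1, 1, 1, 1, 2), col = c(1:4, 1), bty = "n")
  invisible(x)
}

#' Locate the oscillation (Hopf) boundary
#'
#' Bisects the serotonin-to-LHA-GABA connection strength for the point where
#' the fixed point loses linear stability, i.e. where the largest real part
#' of the slow-current Jacobian's eigenvalues crosses zero.  Linear
#' stability is the primary criterion; a simulation-based oscillation
#' classification at the two endpoints serves as an independent cross-check
#' and the two criteria must agree there.
#'
#' @param circuit a [drn_circuit].
#' @param lo,hi bracket of `J.5HT_to_GABA_LHA` values, pA/Hz; the stability
#'   flag must differ between them.
#' @param tol bisection tolerance, pA/Hz (default `1e-3`, resolving the
#'   boundary to its third decimal).
#' @param cross_check run the simulation-based cross-check at the endpoints
#'   (default `TRUE`).
#' @return The critical strength `J*`, pA/Hz, with attribute `iterations`.
#' @examples
#' \donttest{
#' oscillation_boundary(default_circuit(), 0, 6)  # about 0.805 pA/Hz
#' }
#' @export
oscillation_boundary <- function(circuit, lo = 0, hi = 6, tol = 1e-3,
                                 cross_check = TRUE) {
  stopifnot(inherits(circuit, "drn_circuit"), lo < hi, tol > 0)
  at <- function(j) steady_state(
    set_parameter(circuit, c(J.5HT_to_GABA_LHA = j)))
  ss_lo <- at(lo); ss_hi <- at(hi)
  if (ss_lo$stable == ss_hi$stable)
    stop(sprintf(paste("no stability change in [%g, %g]:",
                       "both endpoints are %s"), lo, hi,
         if (ss_lo$stable) "stable" else "unstable"))
  if (cross_check) {
    for (ep in list(list(j = lo, ss = ss_lo), list(j = hi, ss = ss_hi))) {
      ci <- set_parameter(circuit, c(J.5HT_to_GABA_LHA = ep$j))
      osc <- classify_oscillation(ci, ep$ss)$oscillatory
      if (osc == ep$ss$stable)
        stop(sprintf(paste("stability flag and simulated oscillation",
                           "disagree at J = %g (eigenvalues say %s,",
                           "simulation says %s)"), ep$j,
             if (ep$ss$stable) "stable" else "oscillatory",
             if (osc) "oscillatory" else "quiescent"))
    }
  }
  iter <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (at(mid)$stable == ss_lo$stable) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  structure((lo + hi) / 2, iterations = iter)
}
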