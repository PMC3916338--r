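# RK2 time integration of the slow-current dynamics.

#' Describe a pulse stimulation protocol
#'
#' @param targets character subset of `c("5HT", "Ox")`: the principal
#'   populations whose drive receives the stimulus current.
#' @param amplitude pulse amplitude, pA (finite; the standard protocol uses
#'   150 pA, calibrated to double the serotonergic rate).
#' @param onset pulse onset, s (nonnegative).
#' @param duration pulse duration, s (positive; standard 0.5 s, a
#'   behavioural timescale).
#' @return An object of class `stim_protocol`.
#' @examples
#' stimulus_protocol("5HT", amplitude = 150, onset = 1, duration = 0.5)
#' @export
stimulus_protocol <- function(targets, amplitude = 150, onset = 0,
                              duration = 0.5) {
  if (!length(targets) || !all(targets %in% c("5HT", "Ox")))
    stop("'targets' must be a nonempty subset of c(\"5HT\", \"Ox\")")
  if (!is.finite(amplitude)) stop("'amplitude' must be finite")
  if (!is.finite(onset) || onset < 0) stop("'onset' must be >= 0")
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  structure(list(targets = unique(targets), amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "stim_protocol")
}

#' Integrate the circuit dynamics
#'
#' Advances the eight slow receptor currents with the explicit-midpoint
#' second-order Runge-Kutta scheme (default time step 10 ms; halving the step
#' does not change the results materially), re-resolving the four population
#' rates algebraically at every stage.  The fast GABAergic synapses are
#' always at their instantaneous steady states.
#'
#' @param circuit a [drn_circuit].
#' @param horizon total simulated time, s (positive).
#' @param dt time step, s; must not exceed one tenth of the smallest dynamic
#'   time constant.
#' @param init initial slow-current state: `"fixed_point"` (the analytic
#'   steady-state currents), `"zero"`, or a named numeric vector of 8
#'   nonnegative currents (pA).
#' @param protocol `NULL` or a [stimulus_protocol].
#' @param record_every record every `record_every`-th step (the final state
#'   is always recorded).
#' @return An object of class `drn_sim`: a data frame with columns `time_s`,
#'   rate columns `f_<population>_Hz`, drive columns `I_Local_<population>_pA`
#'   and one current column `I_<connection>_pA` per dynamic connection, with
#'   the circuit, protocol and step size attached as attributes.
#' @examples
#' sim <- integrate_circuit(default_circuit(), horizon = 30,
#'                          protocol = stimulus_protocol("5HT", onset = 1))
#' @export
integrate_circuit <- function(circuit, horizon, dt = 0.01,
                              init = "fixed_point", protocol = NULL,
                              record_every = 1L) {
  stopifnot(inherits(circuit, "drn_circuit"))
  if (!is.finite(horizon) || horizon <= 0) stop("'horizon' must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (dt > min(circuit$tau) / 10)
    stop(sprintf(paste("'dt' = %g s is too coarse for the fastest dynamic",
                       "time constant (%g s); need dt <= tau/10"),
         dt, min(circuit$tau)))
  if (is.character(init)) {
    init <- match.arg(init, c("fixed_point", "zero"))
    init <- if (init == "zero") zero_currents() else
      steady_state(circuit)$currents
  }
  init <- check_slow(init)
  if (any(init < 0)) stop("initial slow currents must be nonnegative")
  if (!is.null(protocol) && !inherits(protocol, "stim_protocol"))
    stop("'protocol' must be NULL or a stimulus_protocol")
  aS <- aO <- 0; onset <- 0; dur <- 0
  if (!is.null(protocol)) {
    if ("5HT" %in% protocol$targets) aS <- protocol$amplitude
    if ("Ox" %in% protocol$targets) aO <- protocol$amplitude
    onset <- protocol$onset; dur <- protocol$duration
  }
  m <- rk2_integrate_cpp(unname(init), unname(circuit$g), unname(circuit$I0),
                         unname(circuit$I_bg),
                         unname(circuit$J[DYN_CONNECTIONS$name]),
                         unname(circuit$tau),
                         unname(dyn_sign_vector(circuit)),
                         unname(circuit$J[INST_CONNECTIONS$name]),
                         aS, aO, onset, dur, horizon, dt,
                         as.integer(record_every))
  df <- as.data.frame(m)
  names(df) <- c("time_s", paste0("f_", POPULATIONS, "_Hz"),
                 paste0("I_Local_", POPULATIONS, "_pA"),
                 paste0("I_", DYN_CONNECTIONS$name, "_pA"))
  structure(df, class = c("drn_sim", "data.frame"),
            circuit = circuit, protocol = protocol, dt = dt)
}

#' Simulate a circuit
#'
#' Method for the [stats::simulate()] generic.  The model is deterministic,
#' so repeated simulations with the same arguments are identical; `nsim` and
#' `seed` are accepted for interface compatibility and `seed` is applied (it
#' has no effect on the trajectory).
#'
#' @param object a [drn_circuit].
#' @param nsim number of trajectories (returned as a list if `nsim > 1`).
#' @param seed optional RNG seed, passed to [set.seed()].
#' @param ... passed on to [integrate_circuit()] (`horizon`, `dt`, `init`,
#'   `protocol`, `record_every`).
#' @return A `drn_sim` (or a list of them if `nsim > 1`).
#' @export
simulate.drn_circuit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(nsim), function(i) integrate_circuit(object, ...))
  if (nsim == 1) sims[[1]] else sims
}

terminal_rates <- function(sim) {
  n <- nrow(sim)
  r <- as.numeric(sim[n, paste0("f_", POPULATIONS, "_Hz")])
  stats::setNames(r, POPULATIONS)
}

rate_matrix <- function(sim) {
  as.matrix(sim[, paste0("f_", POPULATIONS, "_Hz")])
}

#' @export
`[.drn_sim` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.drn_sim <- function(x, ...) {
  cat(sprintf("DRN-LHA simulation: %d samples over %.4g s (dt = %g s)\n",
              nrow(x), x$time_s[nrow(x)], attr(x, "dt")))
  prot <- attr(x, "protocol")
  if (!is.null(prot))
    cat(sprintf("stimulus: %g pA on %s at t = %g s for %g s\n",
                prot$amplitude, paste(prot$targets, collapse = "+"),
                prot$onset, prot$duration))
  fin <- terminal_rates(x)
  cat("terminal rates (Hz):",
      paste(sprintf("%s = %.3f", names(fin), fin), collapse = ", "), "\n")
  invisible(x)
}

#' Plot population rate trajectories
#'
#' @param x a `drn_sim`.
#' @param populations which populations to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.drn_sim <- function(x, populations = POPULATIONS, ...) {
  cols <- paste0("f_", populations, "_Hz")
  graphics::matplot(x$time_s, as.matrix(x[, cols, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "firing rate (Hz)",
                    ...)
  graphics::legend("topright", legend = populations, lty = 1,
                   col = seq_along(populations), bty = "n")
  invisible(x)
}
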