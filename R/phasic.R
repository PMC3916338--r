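# Phasic (pulse-stimulation) experiments with fast/slow receptor-timescale
# variants, and scalar transient metrics.

#' Receptor-timescale variants
#'
#' The DRN-to-LHA and LHA-to-DRN projections act through both slow
#' G-protein-coupled receptors (seconds to a minute) and fast ligand-gated
#' channels (5-HT_3A-like, tens of milliseconds).  A variant is a set of
#' time-constant overrides applied to dynamic connections; fast and slow
#' variants are always simulated separately, never mixed.
#'
#' Presets (resolved relative to the stimulated population by
#' [run_pulse()]):
#' \describe{
#'   \item{`slow`}{no overrides --- the default metabotropic time constants.}
#'   \item{`fast` with a serotonergic pulse}{`tau.5HT_to_Ox` and
#'     `tau.5HT_to_GABA_LHA` set to `tau_fast` (default 0.05 s, a
#'     ligand-gated-channel scale).}
#'   \item{`fast` with an orexinergic pulse}{`tau.Ox_to_5HT` set to 5 s (the
#'     fast direct Ox-to-5HT timescale; the slow alternative is the default
#'     60 s).}
#' }
#'
#' @param overrides named numeric vector of time constants, s; names are
#'   dynamic connection names.
#' @return An object of class `timescale_variant`.
#' @export
timescale_variant <- function(overrides) {
  if (length(overrides)) {
    if (is.null(names(overrides)) ||
        any(!names(overrides) %in% DYN_CONNECTIONS$name))
      stop("overrides must be named after dynamic connections")
    if (any(!is.finite(overrides)) || any(overrides <= 0))
      stop("time-constant overrides must be positive")
  }
  structure(list(overrides = overrides), class = "timescale_variant")
}

resolve_variant <- function(variant, target, tau_fast) {
  if (inherits(variant, "timescale_variant")) return(variant)
  variant <- match.arg(variant, c("slow", "fast"))
  if (variant == "slow") return(timescale_variant(numeric(0)))
  if (target == "5HT") {
    timescale_variant(c(`5HT_to_Ox` = tau_fast,
                        `5HT_to_GABA_LHA` = tau_fast))
  } else {
    timescale_variant(c(Ox_to_5HT = 5))
  }
}

apply_variant <- function(circuit, variant) {
  ov <- variant$overrides
  if (!length(ov)) return(circuit)
  set_parameter(circuit, stats::setNames(ov, paste0("tau.", names(ov))))
}

#' Run a pulse-stimulation experiment
#'
#' Starts the circuit at its stable fixed point, applies a square current
#' pulse to the drive of one principal population, integrates through the
#' transient and scalarizes the response with [phasic_metrics()].
#'
#' @param circuit a [drn_circuit]; its fixed point must be stable.
#' @param target `"5HT"` or `"Ox"`.
#' @param variant `"slow"`, `"fast"`, or a [timescale_variant] of explicit
#'   time-constant overrides.
#' @param amplitude pulse amplitude, pA.
#' @param duration pulse duration, s.
#' @param onset pulse onset, s.
#' @param horizon total simulated time, s; by default 60 s, extended to
#'   600 s when a time constant of 60 s participates in the relaxation.
#' @param dt time step, s; by default 10 ms, refined to a tenth of the
#'   fastest time constant when a fast variant requires it.
#' @param tau_fast the fast ligand-gated timescale used by the `"fast"`
#'   preset for serotonergic connections, s.
#' @return An object of class `drn_pulse`: list with `sim` (a `drn_sim`),
#'   `metrics` (see [phasic_metrics()]), `target`, `variant` and `circuit`
#'   (with the variant applied).
#' @examples
#' pl <- run_pulse(default_circuit(), "5HT")
#' pl$metrics["5HT", "fold"]  # about 2
#' @export
run_pulse <- function(circuit, target = c("5HT", "Ox"), variant = "slow",
                      amplitude = 150, duration = 0.5, onset = 1,
                      horizon = NULL, dt = NULL, tau_fast = 0.05) {
  stopifnot(inherits(circuit, "drn_circuit"))
  target <- match.arg(target)
  variant <- resolve_variant(variant, target, tau_fast)
  circuit <- apply_variant(circuit, variant)
  ss <- steady_state(circuit)
  if (!ss$stable)
    stop("pulse experiments require a stable baseline fixed point")
  if (is.null(horizon))
    horizon <- if (max(circuit$tau) >= 60) 600 else 60
  if (is.null(dt)) dt <- min(0.01, min(circuit$tau) / 10)
  prot <- stimulus_protocol(target, amplitude = amplitude, onset = onset,
                            duration = duration)
  sim <- integrate_circuit(circuit, horizon = horizon, dt = dt,
                           init = ss$currents, protocol = prot)
  metrics <- phasic_metrics(sim, onset = onset, duration = duration)
  structure(list(sim = sim, metrics = metrics, target = target,
                 variant = variant, circuit = circuit),
            class = "drn_pulse")
}

#' Scalar transient metrics of a pulse response
#'
#' For every population: the baseline rate (immediately before onset), the
#' peak rate during the stimulus, the fold change (peak over baseline), the
#' post-stimulus trough, and the post-stimulus rebound peak.
#'
#' @param ts a `drn_sim` (or data frame with `time_s` and rate columns
#'   `f_<population>_Hz`).
#' @param onset stimulus onset, s.
#' @param duration stimulus duration, s.
#' @return Data frame with one row per population and columns `baseline_Hz`,
#'   `peak_Hz`, `fold`, `trough_Hz`, `rebound_Hz`.
#' @export
phasic_metrics <- function(ts, onset, duration) {
  cols <- paste0("f_", POPULATIONS, "_Hz")
  if (!all(c("time_s", cols) %in% names(ts)))
    stop("'ts' must have time_s and the four rate columns")
  tt <- ts$time_s
  if (min(tt) >= onset || max(tt) <= onset + duration)
    stop("time series must span the pre-onset baseline and the post-offset",
         " relaxation")
  pre <- max(which(tt < onset))
  during <- tt >= onset & tt <= onset + duration
  after <- tt > onset + duration
  out <- data.frame(baseline_Hz = numeric(4), peak_Hz = numeric(4),
                    fold = numeric(4), trough_Hz = numeric(4),
                    rebound_Hz = numeric(4), row.names = POPULATIONS)
  for (p in seq_along(POPULATIONS)) {
    x <- ts[[cols[p]]]
    base <- x[pre]
    out$baseline_Hz[p] <- base
    out$peak_Hz[p] <- max(x[during])
    out$fold[p] <- if (base > 0) out$peak_Hz[p] / base else NA_real_
    out$trough_Hz[p] <- min(x[after])
    out$rebound_Hz[p] <- max(x[after])
  }
  out
}

#' @export
print.drn_pulse <- function(x, digits = 3, ...) {
  ov <- x$variant$overrides
  cat(sprintf("Pulse experiment on %s (%s)\n", x$target,
              if (length(ov)) paste0("tau overrides: ",
                paste(sprintf("%s = %g s", names(ov), ov), collapse = ", "))
              else "default slow timescales"))
  print(round(x$metrics, digits))
  invisible(x)
}
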