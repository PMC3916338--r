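# Scenario generation: default parameters, the parameter constraints, the
# background-current calibration procedure, and seeded perturbed parameter
# sets for robustness testing.

#' Baseline rate targets
#'
#' In-vivo baseline firing rates used to calibrate the background currents:
#' about 5 Hz for the serotonergic, orexinergic and LHA GABAergic
#' populations and about 15 Hz for the DRN GABAergic population.
#'
#' @param `5HT`,GABA_DRN,Ox,GABA_LHA target rates, Hz (positive).
#' @return Named numeric of length 4.
#' @export
baseline_targets <- function(`5HT` = 5, GABA_DRN = 15, Ox = 5, GABA_LHA = 5) {
  out <- c(`5HT` = `5HT`, GABA_DRN = GABA_DRN, Ox = Ox, GABA_LHA = GABA_LHA)
  if (any(!is.finite(out)) || any(out <= 0))
    stop("baseline targets must be finite and positive")
  out
}

#' Check the circuit's parameter constraints
#'
#' The parameter set ties several strengths and time constants together:
#' (i) `tau.5HT_to_GABA_LHA = tau.5HT_to_Ox`;
#' (ii) `tau.Ox_to_GABA_LHA = tau.Ox_auto`;
#' (iii) `J.5HT_to_GABA_LHA = J.5HT_to_Ox`;
#' (iv) `J.Ox_to_GABA_LHA = J.Ox_auto`, waived while the very weak
#' orexin-to-LHA-GABA connection is pinned at (approximately) zero;
#' (v) `J.GABA_LHA_self = J.GABA_DRN_self`.
#'
#' @param circuit a [drn_circuit].
#' @param tol equality tolerance.
#' @return An object of class `constraint_report`: data frame with columns
#'   `constraint`, `description`, `holds`, `waived`; a constraint is
#'   satisfied when it holds or is waived.
#' @export
check_constraints <- function(circuit, tol = 1e-9) {
  stopifnot(inherits(circuit, "drn_circuit"))
  J <- circuit$J; tau <- circuit$tau
  eq <- function(a, b) abs(a - b) <= tol
  out <- data.frame(
    constraint = c("i", "ii", "iii", "iv", "v"),
    description = c(
      "tau.5HT_to_GABA_LHA = tau.5HT_to_Ox",
      "tau.Ox_to_GABA_LHA = tau.Ox_auto",
      "J.5HT_to_GABA_LHA = J.5HT_to_Ox",
      "J.Ox_to_GABA_LHA = J.Ox_auto (waived while J.Ox_to_GABA_LHA ~ 0)",
      "J.GABA_LHA_self = J.GABA_DRN_self"),
    holds = c(
      eq(tau["5HT_to_GABA_LHA"], tau["5HT_to_Ox"]),
      eq(tau["Ox_to_GABA_LHA"], tau["Ox_auto"]),
      eq(J["5HT_to_GABA_LHA"], J["5HT_to_Ox"]),
      eq(J["Ox_to_GABA_LHA"], J["Ox_auto"]),
      eq(J["GABA_LHA_self"], J["GABA_DRN_self"])),
    waived = c(FALSE, FALSE, FALSE, J["Ox_to_GABA_LHA"] <= tol, FALSE)
  )
  structure(out, class = c("constraint_report", "data.frame"))
}

#' @export
print.constraint_report <- function(x, ...) {
  status <- ifelse(x$holds, "pass", ifelse(x$waived, "waived", "FAIL"))
  print(data.frame(constraint = x$constraint, status = status,
                   description = x$description), row.names = FALSE)
  invisible(x)
}

constraints_satisfied <- function(report) all(report$holds | report$waived)

#' Calibrate background currents to baseline rate targets
#'
#' Emulates the parameter-selection procedure for the free background
#' currents: on the all-active branch the fixed-point equations are linear,
#' so the background current that places the circuit exactly at the target
#' rates is `I_bg = f/g + I0 - (signed synaptic sum at the targets)`.
#' The calibrated circuit's steady state is verified to reproduce the
#' targets to `1e-6` Hz.
#'
#' @param circuit a [drn_circuit] (its `J`, `g`, `I0` and signs are used).
#' @param targets named numeric of target rates, Hz ([baseline_targets()]).
#' @param apply if `TRUE` return the calibrated circuit instead of the
#'   current vector.
#' @return Named numeric of background currents, pA (or the calibrated
#'   circuit when `apply = TRUE`).
#' @examples
#' calibrate_background(default_circuit())
#' @export
calibrate_background <- function(circuit, targets = baseline_targets(),
                                 apply = FALSE) {
  stopifnot(inherits(circuit, "drn_circuit"))
  targets <- named_vec(targets, POPULATIONS, "targets")
  if (any(!is.finite(targets)) || any(targets <= 0))
    stop("targets must be finite and positive (all populations active)")
  M <- signed_matrix(circuit)
  bg <- targets / circuit$g + circuit$I0 - as.vector(M %*% targets)
  names(bg) <- POPULATIONS
  cal <- set_parameter(circuit, stats::setNames(bg, paste0("Ibg.", POPULATIONS)))
  ss <- steady_state(cal)
  if (max(abs(ss$rates - targets)) > 1e-6)
    stop("targets not reproduced on the all-active branch; ",
         "requested baseline is infeasible for these parameters")
  if (apply) cal else bg
}

#' Generate a perturbed parameter set
#'
#' Draws an independent multiplicative factor, uniform on
#' `[1 - relative_scale, 1 + relative_scale]`, for every connection
#' strength, time constant and f-I slope, then re-imposes the tied-parameter
#' constraints (copying the master value of each tied pair; constraint (iv)
#' only when the orexin-to-LHA-GABA coupling is nonzero) and re-calibrates
#' the background currents to the baseline targets.  Re-calibration keeps
#' perturbed circuits comparable at identical baselines, isolating
#' connectivity effects.
#'
#' @param circuit a [drn_circuit].
#' @param relative_scale perturbation half-width, in `[0, 0.5]`.
#' @param seed integer RNG seed (reproducible; same seed, same circuit).
#' @param targets baseline targets for the re-calibration.
#' @return A perturbed [drn_circuit].
#' @export
perturb_circuit <- function(circuit, relative_scale, seed,
                            targets = baseline_targets()) {
  stopifnot(inherits(circuit, "drn_circuit"))
  if (!is.finite(relative_scale) || relative_scale < 0 || relative_scale > 0.5)
    stop("'relative_scale' must be in [0, 0.5]")
  if (relative_scale == 0) return(circuit)
  if (!missing(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  fac <- function(n) stats::runif(n, 1 - relative_scale, 1 + relative_scale)
  circuit$J <- circuit$J * fac(length(circuit$J))
  circuit$tau <- circuit$tau * fac(length(circuit$tau))
  circuit$g <- circuit$g * fac(length(circuit$g))
  # re-impose tied parameters from their master values
  circuit$tau["5HT_to_GABA_LHA"] <- circuit$tau["5HT_to_Ox"]
  circuit$tau["Ox_to_GABA_LHA"] <- circuit$tau["Ox_auto"]
  circuit$J["5HT_to_GABA_LHA"] <- circuit$J["5HT_to_Ox"]
  if (circuit$J["Ox_to_GABA_LHA"] > 0)  # (iv) only with a nonzero coupling
    circuit$J["Ox_to_GABA_LHA"] <- circuit$J["Ox_auto"]
  circuit$J["GABA_LHA_self"] <- circuit$J["GABA_DRN_self"]
  circuit <- drn_circuit(circuit$g, circuit$I0, circuit$I_bg, circuit$J,
                         circuit$tau, circuit$sign_5HT_to_GABA_LHA)
  calibrate_background(circuit, targets, apply = TRUE)
}
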