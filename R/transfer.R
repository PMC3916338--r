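# Threshold-linear transfer, drive assembly and slow-current kinetics.

#' Threshold-linear f-I transfer function
#'
#' Population firing rate as a threshold-linear ("rectified linear") function
#' of total input current: `g * (I_total - I_0)` when the drive exceeds the
#' threshold, zero otherwise.  Vectorized over `I_total`.
#'
#' @param g f-I slope, Hz/pA (positive).
#' @param I_total total local input current, pA.
#' @param I_0 current threshold, pA.
#' @return Firing rate(s), Hz; never negative.
#' @examples
#' rate_transfer(0.033, 151.47, 0.13)
#' @export
rate_transfer <- function(g, I_total, I_0) {
  if (any(!is.finite(g)) || any(!is.finite(I_total)) || any(!is.finite(I_0)))
    stop("non-finite input to rate_transfer()")
  if (any(g <= 0)) stop("'g' must be positive")
  pmax(0, g * (I_total - I_0))
}

# zero slow-current state, in canonical order
zero_currents <- function() {
  stats::setNames(numeric(8), DYN_CONNECTIONS$name)
}

check_slow <- function(slow) {
  slow <- named_vec(slow, DYN_CONNECTIONS$name, "slow currents")
  if (any(!is.finite(slow))) stop("non-finite slow currents")
  slow
}

# stimulus amplitudes per population at an instant: named c(`5HT`=, Ox=)
stim_now_vec <- function(stim) {
  out <- c(`5HT` = 0, Ox = 0)
  if (is.null(stim)) return(out)
  if (is.null(names(stim)) || any(!names(stim) %in% c("5HT", "Ox")))
    stop("stimulus currents may only target the 5HT and Ox populations")
  out[names(stim)] <- stim
  if (any(!is.finite(out))) stop("non-finite stimulus amplitude")
  out
}

#' Assemble per-population local drives
#'
#' The local input to each population is its background current plus the
#' signed sum of its three afferent currents (self-feedback plus two others),
#' plus any stimulus current on the principal (5HT/Ox) populations.  Slow
#' receptor currents enter at their instantaneous state values; the fast
#' GABAergic currents are `J * f_presynaptic` with the supplied GABA rates.
#'
#' @param circuit a [drn_circuit].
#' @param slow named numeric of the 8 slow currents, pA (nonnegative).
#' @param gaba_rates named numeric `c(GABA_DRN=, GABA_LHA=)`, Hz.
#' @param stim `NULL` or named numeric of instantaneous stimulus amplitudes
#'   (pA) for `5HT` and/or `Ox`.
#' @return Named numeric of local drives `I_Local` per population, pA.
#' @export
assemble_drive <- function(circuit, slow, gaba_rates, stim = NULL) {
  stopifnot(inherits(circuit, "drn_circuit"))
  slow <- check_slow(slow)
  if (any(slow < 0)) stop("slow currents must be nonnegative")
  gaba_rates <- named_vec(gaba_rates, c("GABA_DRN", "GABA_LHA"), "gaba_rates")
  if (any(!is.finite(gaba_rates)) || any(gaba_rates < 0))
    stop("GABA rates must be finite and nonnegative")
  st <- stim_now_vec(stim)
  s <- dyn_sign_vector(circuit)
  drive <- circuit$I_bg
  for (k in seq_len(nrow(DYN_CONNECTIONS))) {
    tgt <- DYN_CONNECTIONS$target[k]
    drive[tgt] <- drive[tgt] + s[k] * slow[k]
  }
  for (k in seq_len(nrow(INST_CONNECTIONS))) {
    tgt <- INST_CONNECTIONS$target[k]
    drive[tgt] <- drive[tgt] -
      circuit$J[INST_CONNECTIONS$name[k]] * gaba_rates[INST_CONNECTIONS$source[k]]
  }
  drive["5HT"] <- drive["5HT"] + st["5HT"]
  drive["Ox"]  <- drive["Ox"]  + st["Ox"]
  drive
}

#' Resolve instantaneous rates given the slow currents
#'
#' The fast GABAergic synapses are assumed to reach their steady state
#' instantaneously, which makes the four rates an algebraic function of the
#' eight slow currents.  Each GABAergic population satisfies
#' `f = g * [X - J_self * f - I0]_+` where `X` collects its slow afferents;
#' on the active branch this has the closed form
#' `f = g * (X - I0) / (1 + g * J_self)` (the subthreshold branch gives 0;
#' the solution is unique because `g * J_self > -1`).  The two principal
#' populations' rates then follow directly from the transfer function.
#'
#' @inheritParams assemble_drive
#' @return A list with `rates` (named, Hz) and `drives` (named, pA).
#' @export
instantaneous_rates <- function(circuit, slow, stim = NULL) {
  stopifnot(inherits(circuit, "drn_circuit"))
  slow <- check_slow(slow)
  if (any(slow < 0)) stop("slow currents must be nonnegative")
  st <- stim_now_vec(stim)
  s <- dyn_sign_vector(circuit)
  g <- circuit$g; I0 <- circuit$I0; J <- circuit$J

  # slow-afferent part of each GABA population's drive
  XD <- circuit$I_bg["GABA_DRN"] +
    s["5HT_to_GABA_DRN"] * slow["5HT_to_GABA_DRN"] +
    s["Ox_to_GABA_DRN"] * slow["Ox_to_GABA_DRN"]
  XL <- circuit$I_bg["GABA_LHA"] +
    s["5HT_to_GABA_LHA"] * slow["5HT_to_GABA_LHA"] +
    s["Ox_to_GABA_LHA"] * slow["Ox_to_GABA_LHA"]
  fD <- if (XD > I0["GABA_DRN"]) {
    g["GABA_DRN"] * (XD - I0["GABA_DRN"]) /
      (1 + g["GABA_DRN"] * J["GABA_DRN_self"])
  } else 0
  fL <- if (XL > I0["GABA_LHA"]) {
    g["GABA_LHA"] * (XL - I0["GABA_LHA"]) /
      (1 + g["GABA_LHA"] * J["GABA_LHA_self"])
  } else 0
  gaba <- c(GABA_DRN = unname(fD), GABA_LHA = unname(fL))
  drives <- assemble_drive(circuit, slow, gaba, stim)
  rates <- c(rate_transfer(g["5HT"], drives["5HT"], I0["5HT"]),
             gaba["GABA_DRN"],
             rate_transfer(g["Ox"], drives["Ox"], I0["Ox"]),
             gaba["GABA_LHA"])
  names(rates) <- POPULATIONS
  list(rates = rates, drives = drives)
}

#' Time derivatives of the slow receptor currents
#'
#' Each slow current relaxes to `J * f_presynaptic` with first-order
#' kinetics: `dI/dt = (-I + J * f_src) / tau`.
#'
#' @param circuit a [drn_circuit].
#' @param slow named numeric of the 8 slow currents, pA.
#' @param rates named numeric of the 4 population rates, Hz.
#' @return Named numeric of derivatives, pA/s, one per dynamic connection.
#' @export
slow_current_derivs <- function(circuit, slow, rates) {
  stopifnot(inherits(circuit, "drn_circuit"))
  slow <- check_slow(slow)
  rates <- named_vec(rates, POPULATIONS, "rates")
  J <- circuit$J[DYN_CONNECTIONS$name]
  (-slow + J * rates[DYN_CONNECTIONS$source]) / circuit$tau
}
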