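# Analytic fixed points of the piecewise-linear circuit and their linear
# stability in the 8-dimensional slow-current state space.

#' Analytic steady state of the circuit
#'
#' Solves the piecewise-linear fixed-point system exactly.  On a candidate
#' "active set" (the populations assumed above threshold) the fixed point
#' satisfies the linear system `f = g * (I_bg + M f - I0)` restricted to the
#' active populations, where `M` is the signed connectivity matrix; clamped
#' populations have `f = 0`.  All sixteen candidate sets are searched
#' (smallest first, so the rectified branch wins in degenerate cases) and a
#' branch is accepted only if it is self-consistent:
#' every active population has drive above threshold and every clamped one
#' has drive at or below threshold.  The slow currents at the fixed point are
#' `I = J * f_source`.  Stability is read from the eigenvalues of the 8x8
#' Jacobian of the slow-current dynamics (with the rates eliminated
#' algebraically, respecting the active branch): the fixed point is stable
#' iff all real parts are negative.
#'
#' @param circuit a [drn_circuit].
#' @param simulate_check if `TRUE` and the fixed point is stable, additionally
#'   integrate the circuit from a perturbed initial condition and verify that
#'   the simulation relaxes back to the analytic fixed point (within
#'   `1e-3` Hz); an error is raised on disagreement.
#' @return An object of class `drn_steady`: a list with `rates` (Hz),
#'   `drives` (pA), `currents` (the 8 slow currents, pA), `active` (logical
#'   per population), `stable` (logical), `eigenvalues` (complex, length 8)
#'   and `max_re` (largest real part, 1/s).
#' @examples
#' steady_state(default_circuit())
#' @export
steady_state <- function(circuit, simulate_check = FALSE) {
  stopifnot(inherits(circuit, "drn_circuit"))
  M <- signed_matrix(circuit)
  g <- circuit$g; I0 <- circuit$I0; Ibg <- circuit$I_bg
  sets <- active_set_candidates()
  outcomes <- character(0)
  sol <- NULL
  for (act in sets) {
    f <- stats::setNames(numeric(4), POPULATIONS)
    if (any(act)) {
      A <- diag(sum(act)) - diag(g[act], sum(act)) %*% M[act, act, drop = FALSE]
      fa <- try(solve(A, g[act] * (Ibg[act] - I0[act])), silent = TRUE)
      if (inherits(fa, "try-error")) {
        outcomes <- c(outcomes, sprintf("{%s}: singular",
                                        paste(POPULATIONS[act], collapse = ",")))
        next
      }
      f[act] <- fa
    }
    drive <- Ibg + as.vector(M %*% f)
    # active populations must be strictly above threshold; rates exactly at
    # zero are classified on the clamped branch (conservative at the
    # rectification boundary)
    ok <- all(f[act] > 1e-9) &&
      all(drive[act] > I0[act] - 1e-9) &&
      all(drive[!act] <= I0[!act] + 1e-9)
    if (ok) { sol <- list(f = pmax(f, 0), drive = drive, active = act); break }
    outcomes <- c(outcomes, sprintf("{%s}: inconsistent",
                                    paste(POPULATIONS[act], collapse = ",")))
  }
  if (is.null(sol))
    stop("no self-consistent active set found; branch outcomes: ",
         paste(outcomes, collapse = "; "))
  f <- sol$f
  currents <- circuit$J[DYN_CONNECTIONS$name] * f[DYN_CONNECTIONS$source]
  names(currents) <- DYN_CONNECTIONS$name
  Jac <- slow_jacobian(circuit, sol$active)
  ev <- eigen(Jac, only.values = TRUE)$values
  max_re <- max(Re(ev))
  out <- structure(list(rates = f, drives = sol$drive, currents = currents,
                        active = stats::setNames(sol$active, POPULATIONS),
                        stable = max_re < 0, eigenvalues = ev,
                        max_re = max_re, circuit = circuit),
                   class = "drn_steady")
  if (simulate_check && out$stable) {
    horizon <- max(600, 20 * max(circuit$tau))
    ts <- integrate_circuit(circuit, horizon = horizon, dt = 0.01,
                            init = currents * 0.99 + 1e-3)
    fin <- terminal_rates(ts)
    if (max(abs(fin - f)) > 1e-3)
      stop(sprintf(paste("analytic and simulated fixed points disagree:",
                         "max |diff| = %.3g Hz"), max(abs(fin - f))))
  }
  out
}

# All subsets of the 4 populations, smallest first.  With the excitatory
# orexin autoreceptor loop above unit gain (g * J_auto > 1) a spurious
# self-sustaining all-active fixed point can coexist with a quiescent one;
# preferring smaller active sets returns the rectified (physical) branch in
# such degenerate cases, and for non-degenerate parameters only one branch
# is self-consistent anyway.
active_set_candidates <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  grid <- as.matrix(grid)
  ord <- order(rowSums(grid))
  lapply(ord, function(i) as.logical(grid[i, ]))
}

# Jacobian of dI/dt = (-I + J * f_src(I)) / tau on a given active branch.
# The rates are piecewise-linear in the slow currents; the 4x8 sensitivity
# A = df/dI is assembled from the closed-form GABA solve and the principal
# transfer functions, with clamped populations contributing zero rows.
slow_jacobian <- function(circuit, active) {
  g <- circuit$g; J <- circuit$J
  s <- dyn_sign_vector(circuit)
  dn <- DYN_CONNECTIONS$name
  A <- matrix(0, 4, 8, dimnames = list(POPULATIONS, dn))
  aD <- if (active[2]) {
    g["GABA_DRN"] / (1 + g["GABA_DRN"] * J["GABA_DRN_self"])
  } else 0
  aL <- if (active[4]) {
    g["GABA_LHA"] / (1 + g["GABA_LHA"] * J["GABA_LHA_self"])
  } else 0
  A["GABA_DRN", "5HT_to_GABA_DRN"] <- aD * s["5HT_to_GABA_DRN"]
  A["GABA_DRN", "Ox_to_GABA_DRN"]  <- aD * s["Ox_to_GABA_DRN"]
  A["GABA_LHA", "5HT_to_GABA_LHA"] <- aL * s["5HT_to_GABA_LHA"]
  A["GABA_LHA", "Ox_to_GABA_LHA"]  <- aL * s["Ox_to_GABA_LHA"]
  if (active[1]) {
    A["5HT", "5HT_auto"]  <- g["5HT"] * s["5HT_auto"]
    A["5HT", "Ox_to_5HT"] <- g["5HT"] * s["Ox_to_5HT"]
    A["5HT", ] <- A["5HT", ] - g["5HT"] * J["GABA_DRN_to_5HT"] * A["GABA_DRN", ]
  }
  if (active[3]) {
    A["Ox", "Ox_auto"]   <- g["Ox"] * s["Ox_auto"]
    A["Ox", "5HT_to_Ox"] <- g["Ox"] * s["5HT_to_Ox"]
    A["Ox", ] <- A["Ox", ] - g["Ox"] * J["GABA_LHA_to_Ox"] * A["GABA_LHA", ]
  }
  Jd <- J[dn]
  src <- DYN_CONNECTIONS$source
  Jac <- matrix(0, 8, 8, dimnames = list(dn, dn))
  for (i in 1:8)
    Jac[i, ] <- (Jd[i] * A[src[i], ] - (seq_len(8) == i)) / circuit$tau[i]
  Jac
}

#' @export
print.drn_steady <- function(x, digits = 4, ...) {
  cat("Fixed point of the DRN-LHA circuit",
      if (x$stable) "(stable)" else "(unstable)", "\n")
  df <- data.frame(rate_Hz = round(x$rates, digits),
                   drive_pA = round(x$drives, digits),
                   active = x$active)
  print(df)
  cat(sprintf("largest eigenvalue real part: %.4g 1/s\n", x$max_re))
  invisible(x)
}
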