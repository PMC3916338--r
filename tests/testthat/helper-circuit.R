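# Shared fixtures and independent oracles.

# Independent fixed-point oracle: builds the signed connectivity matrix from
# first principles and solves the all-active linear system
#   f = g * (I_bg + M f - I0)
# directly.  Kept free of package internals (only the parameter values are
# taken from the circuit object) so it can arbitrate the package's own
# steady-state solver.
oracle_fixed_point <- function(circuit, active = rep(TRUE, 4)) {
  g <- circuit$g; I0 <- circuit$I0; Ibg <- circuit$I_bg
  J <- circuit$J; s <- circuit$sign_5HT_to_GABA_LHA
  M <- rbind(
    c(-J[["5HT_auto"]], -J[["GABA_DRN_to_5HT"]], J[["Ox_to_5HT"]], 0),
    c(J[["5HT_to_GABA_DRN"]], -J[["GABA_DRN_self"]], J[["Ox_to_GABA_DRN"]], 0),
    c(-J[["5HT_to_Ox"]], 0, J[["Ox_auto"]], -J[["GABA_LHA_to_Ox"]]),
    c(s * J[["5HT_to_GABA_LHA"]], 0, J[["Ox_to_GABA_LHA"]],
      -J[["GABA_LHA_self"]]))
  f <- numeric(4)
  A <- diag(sum(active)) -
    diag(g[active], sum(active)) %*% M[active, active, drop = FALSE]
  f[active] <- solve(A, g[active] * (Ibg[active] - I0[active]))
  names(f) <- c("5HT", "GABA_DRN", "Ox", "GABA_LHA")
  f
}

# terminal rates of a simulation
last_rates <- function(sim) {
  n <- nrow(sim)
  r <- as.numeric(sim[n, c("f_5HT_Hz", "f_GABA_DRN_Hz", "f_Ox_Hz",
                           "f_GABA_LHA_Hz")])
  stats::setNames(r, c("5HT", "GABA_DRN", "Ox", "GABA_LHA"))
}

with_J <- function(circuit, name, value) {
  set_parameter(circuit, stats::setNames(value, paste0("J.", name)))
}
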