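# Circuit data model: four populations, twelve connections.
#
# Population order used everywhere: 5HT, GABA_DRN, Ox, GABA_LHA.
# Connections split by receptor class: eight slow (metabotropic or otherwise
# dynamically filtered) currents that form the ODE state, and four fast
# ionotropic GABA_A synapses treated as instantaneous.

POPULATIONS <- c("5HT", "GABA_DRN", "Ox", "GABA_LHA")

# dynamic (filtered) connections, in canonical state-vector order
DYN_CONNECTIONS <- data.frame(
  name   = c("5HT_auto", "Ox_to_5HT", "5HT_to_GABA_DRN", "Ox_to_GABA_DRN",
             "Ox_auto", "5HT_to_Ox", "Ox_to_GABA_LHA", "5HT_to_GABA_LHA"),
  source = c("5HT", "Ox", "5HT", "Ox", "Ox", "5HT", "Ox", "5HT"),
  target = c("5HT", "5HT", "GABA_DRN", "GABA_DRN", "Ox", "Ox",
             "GABA_LHA", "GABA_LHA"),
  # + excitatory, - inhibitory; 5HT_to_GABA_LHA is the experimentally
  # undetermined sign and is stored on the circuit object itself
  sign   = c(-1, +1, +1, +1, +1, -1, +1, NA),
  stringsAsFactors = FALSE
)

# instantaneous GABA_A-mediated connections (~4 ms, slaved to their inputs)
INST_CONNECTIONS <- data.frame(
  name   = c("GABA_DRN_to_5HT", "GABA_DRN_self", "GABA_LHA_to_Ox",
             "GABA_LHA_self"),
  source = c("GABA_DRN", "GABA_DRN", "GABA_LHA", "GABA_LHA"),
  target = c("5HT", "GABA_DRN", "Ox", "GABA_LHA"),
  sign   = c(-1, -1, -1, -1),
  stringsAsFactors = FALSE
)

ALL_CONNECTIONS <- c(DYN_CONNECTIONS$name, INST_CONNECTIONS$name)

dyn_sign_vector <- function(circuit) {
  s <- DYN_CONNECTIONS$sign
  s[DYN_CONNECTIONS$name == "5HT_to_GABA_LHA"] <- circuit$sign_5HT_to_GABA_LHA
  names(s) <- DYN_CONNECTIONS$name
  s
}

#' Construct a DRN-LHA circuit parameter set
#'
#' Builds the complete parameterization of the four-population mean-field
#' firing-rate circuit: dorsal raphe serotonergic (`5HT`) and GABAergic
#' (`GABA_DRN`) populations, and lateral hypothalamic orexinergic (`Ox`) and
#' GABAergic (`GABA_LHA`) populations.  Each population has a threshold-linear
#' f-I curve with slope `g` (Hz/pA), threshold `I0` (pA) and a constant
#' background current `I_bg` (pA).  The twelve connections carry strengths `J`
#' (pA/Hz); the eight non-GABAergic connections are dynamically filtered with
#' time constants `tau` (s) while the four GABA_A-mediated synapses are
#' instantaneous.
#'
#' @param g named numeric of length 4 (names `5HT`, `GABA_DRN`, `Ox`,
#'   `GABA_LHA`): f-I slopes in Hz/pA, all positive.
#' @param I0 named numeric of length 4: current thresholds in pA,
#'   nonnegative.
#' @param I_bg named numeric of length 4: background currents in pA.
#' @param J named numeric of length 12: connection strengths in pA/Hz,
#'   nonnegative (signs are fixed by receptor identity, except the
#'   experimentally undetermined serotonin-to-LHA-GABA sign below).
#' @param tau named numeric of length 8: time constants in s for the dynamic
#'   connections, all positive.
#' @param sign_5HT_to_GABA_LHA `+1` (excitatory, the default and the
#'   physiologically favoured case) or `-1` (inhibitory) for the
#'   serotonin-to-LHA-GABAergic connection.
#' @return An object of class `drn_circuit`: a list with elements `g`, `I0`,
#'   `I_bg`, `J`, `tau`, `sign_5HT_to_GABA_LHA`.
#' @seealso [default_circuit()] for the standard parameter set,
#'   [connections()] for the connection table, [steady_state()],
#'   [simulate.drn_circuit()].
#' @export
drn_circuit <- function(g, I0, I_bg, J, tau, sign_5HT_to_GABA_LHA = +1) {
  g    <- named_vec(g,   POPULATIONS,        "g")
  I0   <- named_vec(I0,  POPULATIONS,        "I0")
  I_bg <- named_vec(I_bg, POPULATIONS,       "I_bg")
  J    <- named_vec(J,   ALL_CONNECTIONS,    "J")
  tau  <- named_vec(tau, DYN_CONNECTIONS$name, "tau")
  if (any(!is.finite(g)) || any(g <= 0))
    stop("f-I slopes 'g' must be finite and positive")
  if (any(!is.finite(I0)) || any(I0 < 0))
    stop("thresholds 'I0' must be finite and nonnegative")
  if (any(!is.finite(I_bg)))
    stop("background currents must be finite")
  if (any(!is.finite(J)) || any(J < 0))
    stop("connection strengths 'J' must be finite and nonnegative",
         " (signs are carried separately)")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("time constants 'tau' must be finite and positive")
  if (!sign_5HT_to_GABA_LHA %in% c(-1, 1))
    stop("'sign_5HT_to_GABA_LHA' must be +1 or -1")
  structure(list(g = g, I0 = I0, I_bg = I_bg, J = J, tau = tau,
                 sign_5HT_to_GABA_LHA = sign_5HT_to_GABA_LHA),
            class = "drn_circuit")
}

named_vec <- function(x, nm, what) {
  if (length(x) != length(nm))
    stop(sprintf("'%s' must have length %d", what, length(nm)))
  if (is.null(names(x))) {
    names(x) <- nm
  } else if (!setequal(names(x), nm)) {
    bad <- setdiff(names(x), nm)
    stop(sprintf("unknown %s name(s): %s", what, paste(bad, collapse = ", ")))
  }
  x[nm]
}

#' Default circuit parameter set
#'
#' Returns the standard parameterization of the DRN-LHA circuit, with
#' connection strengths derived from published receptor-current amplitudes
#' divided by the in-vivo baseline rates of the presynaptic populations, time
#' constants from GIRK-current or firing-rate-relaxation measurements, and
#' background currents chosen so that baseline rates are close to their
#' in-vivo values (about 5 Hz for the serotonergic, orexinergic and LHA
#' GABAergic populations and about 15 Hz for the DRN GABAergic population).
#' The orexin-to-LHA-GABA strength defaults to 0 (a very weak connection).
#'
#' @return A [drn_circuit] object.
#' @examples
#' circ <- default_circuit()
#' steady_state(circ)
#' @export
default_circuit <- function() {
  drn_circuit(
    g    = c(`5HT` = 0.033, GABA_DRN = 0.061, Ox = 0.205, GABA_LHA = 0.195),
    I0   = c(`5HT` = 0.13,  GABA_DRN = 0,     Ox = 0,     GABA_LHA = 0),
    I_bg = c(`5HT` = 231.47, GABA_DRN = 246,  Ox = 617.6, GABA_LHA = 20.9),
    J    = c(`5HT_auto` = 16, Ox_to_5HT = 15, `5HT_to_GABA_DRN` = 10,
             Ox_to_GABA_DRN = 5, Ox_auto = 6, `5HT_to_Ox` = 6,
             Ox_to_GABA_LHA = 0, `5HT_to_GABA_LHA` = 6,
             GABA_DRN_to_5HT = 5, GABA_DRN_self = 5, GABA_LHA_to_Ox = 118,
             GABA_LHA_self = 5),
    tau  = c(`5HT_auto` = 1, Ox_to_5HT = 60, `5HT_to_GABA_DRN` = 60,
             Ox_to_GABA_DRN = 5, Ox_auto = 10, `5HT_to_Ox` = 2,
             Ox_to_GABA_LHA = 10, `5HT_to_GABA_LHA` = 2),
    sign_5HT_to_GABA_LHA = +1
  )
}

#' Connection table of a circuit
#'
#' @param circuit a [drn_circuit].
#' @return A data frame with one row per connection: `connection`, `source`,
#'   `target`, `kinetics` (`"dynamic"` or `"instantaneous"`), `sign`,
#'   `J` (pA/Hz) and `tau` (s; `NA` for instantaneous synapses).
#' @export
connections <- function(circuit) {
  stopifnot(inherits(circuit, "drn_circuit"))
  dyn <- data.frame(connection = DYN_CONNECTIONS$name,
                    source = DYN_CONNECTIONS$source,
                    target = DYN_CONNECTIONS$target,
                    kinetics = "dynamic",
                    sign = unname(dyn_sign_vector(circuit)),
                    J = unname(circuit$J[DYN_CONNECTIONS$name]),
                    tau = unname(circuit$tau),
                    stringsAsFactors = FALSE)
  inst <- data.frame(connection = INST_CONNECTIONS$name,
                     source = INST_CONNECTIONS$source,
                     target = INST_CONNECTIONS$target,
                     kinetics = "instantaneous",
                     sign = INST_CONNECTIONS$sign,
                     J = unname(circuit$J[INST_CONNECTIONS$name]),
                     tau = NA_real_,
                     stringsAsFactors = FALSE)
  rbind(dyn, inst)
}

# Signed connectivity matrix M[target, source] (pA/Hz), so that at a fixed
# point the local drive is I_bg + M %*% f.
signed_matrix <- function(circuit) {
  M <- matrix(0, 4, 4, dimnames = list(POPULATIONS, POPULATIONS))
  conn <- connections(circuit)
  for (k in seq_len(nrow(conn)))
    M[conn$target[k], conn$source[k]] <- conn$sign[k] * conn$J[k]
  M
}

#' Flat parameter keys of a circuit
#'
#' Every circuit parameter is addressable by a dotted key, the same keys used
#' by the plain-text configuration files ([read_circuit_config()]):
#' `g.<population>`, `I0.<population>`, `Ibg.<population>`,
#' `J.<connection>`, `tau.<dynamic connection>` and `sign.5HT_to_GABA_LHA`.
#'
#' @return Character vector of all valid keys, in canonical order.
#' @export
parameter_keys <- function() {
  c(paste0("g.", POPULATIONS), paste0("I0.", POPULATIONS),
    paste0("Ibg.", POPULATIONS), paste0("J.", ALL_CONNECTIONS),
    paste0("tau.", DYN_CONNECTIONS$name), "sign.5HT_to_GABA_LHA")
}

#' Modify circuit parameters by key
#'
#' @param circuit a [drn_circuit].
#' @param values named numeric vector; names are dotted keys as listed by
#'   [parameter_keys()].
#' @return The modified, revalidated circuit.
#' @examples
#' weak <- set_parameter(default_circuit(), c(J.5HT_to_GABA_LHA = 0.4))
#' @export
set_parameter <- function(circuit, values) {
  stopifnot(inherits(circuit, "drn_circuit"))
  if (length(values) == 0) return(circuit)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be a fully named numeric vector")
  for (key in names(values)) {
    v <- unname(values[[key]])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("unknown parameter key '%s'", key))
    field <- parts[1]; id <- parts[2]
    ok <- switch(field,
      g    = id %in% POPULATIONS,
      I0   = id %in% POPULATIONS,
      Ibg  = id %in% POPULATIONS,
      J    = id %in% ALL_CONNECTIONS,
      tau  = id %in% DYN_CONNECTIONS$name,
      sign = id == "5HT_to_GABA_LHA",
      FALSE)
    if (!isTRUE(ok))
      stop(sprintf("unknown parameter key '%s'", key))
    switch(field,
      g    = circuit$g[id]   <- v,
      I0   = circuit$I0[id]  <- v,
      Ibg  = circuit$I_bg[id] <- v,
      J    = circuit$J[id]   <- v,
      tau  = circuit$tau[id] <- v,
      sign = circuit$sign_5HT_to_GABA_LHA <- v)
  }
  drn_circuit(circuit$g, circuit$I0, circuit$I_bg, circuit$J, circuit$tau,
              circuit$sign_5HT_to_GABA_LHA)
}

#' @export
coef.drn_circuit <- function(object, ...) {
  keys <- parameter_keys()
  vals <- c(object$g, object$I0, object$I_bg, object$J, object$tau,
            object$sign_5HT_to_GABA_LHA)
  names(vals) <- keys
  vals
}

#' @export
print.drn_circuit <- function(x, ...) {
  cat("DRN-LHA mean-field circuit (4 populations, 12 connections)\n")
  pops <- data.frame(g_Hz_per_pA = x$g, I0_pA = x$I0, I_bg_pA = x$I_bg)
  print(pops)
  cat("5HT -> GABA_LHA connection is",
      if (x$sign_5HT_to_GABA_LHA > 0) "excitatory" else "inhibitory", "\n")
  invisible(x)
}

#' @export
summary.drn_circuit <- function(object, ...) {
  print(object)
  cat("\nConnections:\n")
  print(connections(object), row.names = FALSE)
  ss <- tryCatch(steady_state(object), error = function(e) NULL)
  if (!is.null(ss)) {
    cat("\nSteady state:\n")
    print(ss)
  }
  invisible(object)
}

#' Knockout scenarios
#'
#' Emulates an in-model knockout by zeroing connection strengths.  The
#' `remove_Ox` scenario zeroes all four orexin-sourced connections (the model
#' analogue of an orexin-peptide knockout); `remove_Ox_autoreceptor` zeroes
#' only the excitatory Ox_2 autoreceptor self-feedback, which is the
#' manipulation that abolishes the slow-oscillation regime.
#'
#' @param circuit a [drn_circuit].
#' @param scenario `"remove_Ox"`, `"remove_Ox_autoreceptor"`, or a character
#'   vector of connection names to zero (possibly empty).
#' @return The modified circuit.
#' @examples
#' ko <- knockout(default_circuit(), "remove_Ox")
#' steady_state(ko)$rates["5HT"]  # serotonergic tone surviving Ox loss
#' @export
knockout <- function(circuit, scenario) {
  stopifnot(inherits(circuit, "drn_circuit"))
  conns <- if (identical(scenario, "remove_Ox")) {
    DYN_CONNECTIONS$name[DYN_CONNECTIONS$source == "Ox"]
  } else if (identical(scenario, "remove_Ox_autoreceptor")) {
    "Ox_auto"
  } else if (is.character(scenario)) {
    if (length(scenario) && any(!scenario %in% ALL_CONNECTIONS))
      stop("unknown scenario or connection name(s): ",
           paste(setdiff(scenario, ALL_CONNECTIONS), collapse = ", "))
    scenario
  } else stop("invalid 'scenario'")
  circuit$J[conns] <- 0
  circuit
}
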