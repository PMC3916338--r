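# Plain-text serialization: flat key-value parameter files, time-series CSV
# and sweep TSV.

format_num <- function(x) sprintf("%.15g", x)

#' Write circuit parameters to a key-value file
#'
#' One `key = value` line per parameter, dotted keys as in
#' [parameter_keys()], in canonical order.  The format round-trips: reading
#' a written file and writing it again is byte-identical.
#'
#' @param circuit a [drn_circuit].
#' @param path output file path.
#' @param header optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_circuit_config <- function(circuit, path, header = NULL) {
  stopifnot(inherits(circuit, "drn_circuit"))
  vals <- coef(circuit)
  lines <- c(if (length(header)) paste("#", header),
             paste(names(vals), "=", format_num(vals)))
  writeLines(lines, path)
  invisible(path)
}

#' Read circuit parameters from a key-value file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored.  Unknown keys are rejected (naming the key); keys missing from
#' the file are filled from the default parameter set with a notice on
#' standard error.
#'
#' @param path input file path.
#' @return A [drn_circuit].
#' @export
read_circuit_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- numeric(0)
  for (i in keep) {
    m <- regmatches(lines[i],
                    regexec("^\\s*([A-Za-z0-9._]+)\\s*=\\s*(\\S+)\\s*$",
                            lines[i]))[[1]]
    if (length(m) != 3)
      stop(sprintf("%s:%d: cannot parse line '%s'", path, i, lines[i]))
    key <- m[2]
    if (!key %in% parameter_keys())
      stop(sprintf("%s:%d: unknown parameter key '%s'", path, i, key))
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v))
      stop(sprintf("%s:%d: value for '%s' is not numeric", path, i, key))
    vals[key] <- v
  }
  missing <- setdiff(parameter_keys(), names(vals))
  if (length(missing) && length(vals))
    message(sprintf("%d key(s) missing from '%s'; using defaults for: %s",
                    length(missing), path, paste(missing, collapse = ", ")))
  set_parameter(default_circuit(), vals)
}

#' Write a simulated time series as CSV
#'
#' Columns `time_s`, `f_5HT_Hz`, `f_GABA_DRN_Hz`, `f_Ox_Hz`, `f_GABA_LHA_Hz`
#' and, optionally, the per-connection slow currents.  Rates are written at
#' 6 decimals and currents at 3 (beyond integrator accuracy, stable diffs).
#'
#' @param sim a `drn_sim`.
#' @param path output file path.
#' @param currents include the slow-current columns.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sim, path, currents = FALSE) {
  cols <- c("time_s", paste0("f_", POPULATIONS, "_Hz"))
  fmt <- c("%.6g", rep("%.6f", 4))
  if (currents) {
    cols <- c(cols, paste0("I_", DYN_CONNECTIONS$name, "_pA"))
    fmt <- c(fmt, rep("%.3f", 8))
  }
  body <- vapply(seq_len(nrow(sim)), function(i) {
    paste(sprintf(fmt, as.numeric(sim[i, cols])), collapse = ",")
  }, character(1))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Read a time-series CSV written by [write_timeseries()]
#'
#' @param path input file path.
#' @return A data frame.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a sweep result as TSV
#'
#' @param sweep a `drn_sweep` from [sweep_parameter()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
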