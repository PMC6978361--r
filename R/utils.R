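# Classed conditions so callers and tests can distinguish configuration,
# parse, validation and domain failures.
stop_ndr <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ndrscreen_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_ndr <- function(msg, class = "ndrscreen_warning") {
  warning(structure(
    class = c(class, "ndrscreen_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# log-normal multiplier with mean 1 and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
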