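#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a classed condition so tests can assert on error class.
#' @noRd
ems_stop <- function(msg, class = "emsloc_error", ...) {
  stop(structure(
    class = c(class, "emsloc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, class = "emsloc_validation_error") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    ems_stop(sprintf("'%s' must be a single number", name), class)
  if (x < lower || x > upper)
    ems_stop(sprintf("'%s' = %s outside [%s, %s]", name, format(x),
                     format(lower), format(upper)), class)
  if (integer && x != round(x))
    ems_stop(sprintf("'%s' must be an integer", name), class)
  invisible(x)
}

#' @noRd
check_proportion <- function(x, name) {
  check_number(x, name, lower = 0, upper = 1)
}

#' Derive a child seed from a master seed and a stream index.
#'
#' Keeps derived seeds inside the 32-bit signed integer range. The same
#' (seed, stream) pair always yields the same child, and distinct streams
#' yield distinct children for any seed below ~2e9.
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 97L + stream * 1009L) %% 2147483629)
}
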