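# Internal validation helpers. All user-facing constructors validate eagerly
# and signal classed conditions so callers (and tests) can distinguish
# validation failures from resolution and numerical errors.

stop_validation <- function(msg, fields = character()) {
  stop(structure(
    class = c("dfp_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), fields = fields)
  ))
}

stop_resolution <- function(msg, keys = character()) {
  stop(structure(
    class = c("dfp_resolution_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), keys = keys)
  ))
}

stop_numerical <- function(msg) {
  stop(structure(
    class = c("dfp_numerical_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Collect per-field violations, then fail once listing every offending path.
check_fields <- function(checks, context) {
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    stop_validation(
      sprintf("%s: invalid field(s): %s", context, paste(bad, collapse = ", ")),
      fields = bad
    )
  }
  invisible(TRUE)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_pos1 <- function(x) is_num1(x) && x > 0
is_nonneg1 <- function(x) is_num1(x) && x >= 0
is_frac1 <- function(x) is_num1(x) && x >= 0 && x <= 1
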