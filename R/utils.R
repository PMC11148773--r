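#' @keywords internal
"_PACKAGE"

# Shared argument checks. All user-facing validation errors are classed so the
# CLI can map them to exit code 2.

stop_invalid <- function(msg, class = "gicoreg_invalid_input", ...) {
  stop(structure(
    class = c(class, "gicoreg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, len = 1L) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_invalid(sprintf("`%s` must be numeric and non-missing", name))
  }
  if (!is.null(len) && length(x) != len) {
    stop_invalid(sprintf("`%s` must have length %d", name, len))
  }
  if (any(x < lower) || any(x > upper)) {
    stop_invalid(sprintf("`%s` must lie in [%s, %s]", name,
                         format(lower), format(upper)))
  }
  if (integer && any(x != round(x))) {
    stop_invalid(sprintf("`%s` must be integer-valued", name))
  }
  invisible(x)
}

# deterministic sub-seed derivation; keeps results independent across stages
# while reproducible from one user seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}
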