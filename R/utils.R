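#' @keywords internal
"_PACKAGE"

# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_isohet <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_isohet(msg)
}

# Undefined-result convention: operations whose value does not exist for the
# given input (all-missing sample, singleton population, ...) return NA_real_
# with a warning rather than erroring, so vectorised callers can proceed.
undefined_result <- function(msg) {
  warning(msg, call. = FALSE)
  NA_real_
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
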