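# Internal helpers shared across modules.

#' Round half-up to a number of decimal places
#'
#' Monetary arithmetic in this package is rounded half-up to cents on
#' output (base R's `round()` rounds half-to-even, which is unsuitable
#' for reproducible money arithmetic).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, i.e. cents).
#' @return `x` rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Validate a named probability; errors name the offending field.
check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort("'%s' must be a probability in [0, 1] (got %s)",
          field, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort("'%s' must be non-negative (got %s)",
          field, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != trunc(x))) {
    abort("'%s' must be a non-negative integer count (got %s)",
          field, paste(format(x), collapse = ", "))
  }
  invisible(as.integer(x))
}

# The four per-protocol strategy groups, in canonical order.
strategy_groups <- function() {
  c("multifaceted", "unifaceted", "pfh_control", "nfh")
}
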