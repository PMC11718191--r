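## Internal helpers shared across modules.

# Scalar, finite, numeric check with a contextual error message.
check_scalar <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside its admissible range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

# Percent coefficient of variation with the n-1 sample standard deviation.
cv_pct <- function(x) {
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  100 * stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
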