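# Small internal helpers shared across modules.

# Sample skewness (m3 / m2^1.5); NA-safe.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

stopifnot_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector of length %d", name, len))
  }
  lo_ok <- if (strict_min) all(x > min) else all(x >= min)
  if (!lo_ok || !all(x <= max)) {
    abort(sprintf(
      "`%s` must be %s %s and <= %s", name,
      if (strict_min) ">" else ">=", format(min), format(max)
    ))
  }
  invisible(x)
}

# Evaluate `expr` under a locally-set RNG seed when `seed` is non-NULL,
# leaving the caller's RNG stream untouched; otherwise use the current stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
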