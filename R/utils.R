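# internal helpers shared across modules

# reported hydration levels are integer percent, half up (42.86 -> 43)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("'%s' must be a single non-missing number", name)
  }
  if (!allow_inf && !is.finite(x)) {
    stop_invalid("'%s' must be finite", name)
  }
  if (x < lower || x > upper) {
    stop_invalid("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x))
  }
  invisible(x)
}
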