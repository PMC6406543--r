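#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr %>%
#' @importFrom tibble tibble as_tibble
NULL

# internal: stop with a classed condition so tests can assert on class
stop_stratmir <- function(msg, class = "stratmir_error") {
  abort(msg, class = c(class, "stratmir_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_stratmir(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_stratmir(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}

# derive a per-stage 32-bit seed from a global seed and a stage label,
# so stage randomness is independent of stage execution order
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
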