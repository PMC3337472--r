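# Internal helpers: argument checking, conditions, rounding.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
abort_validation <- function(msg) {
  stop(errorCondition(msg,
    class = c("mosaicsat_validation_error", "mosaicsat_error", "error", "condition")
  ))
}

#' @keywords internal
abort_degenerate <- function(msg) {
  stop(errorCondition(msg,
    class = c("mosaicsat_degenerate_error", "mosaicsat_error", "error", "condition")
  ))
}

warn_mosaicsat <- function(msg, class = "mosaicsat_warning") {
  warning(warningCondition(msg,
    class = c(class, "mosaicsat_warning", "warning", "condition")
  ))
}

# Round half away from zero (manuscript-style presentation rounding, as
# opposed to base round()'s round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                integerish = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_validation(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (x < min) abort_validation(sprintf("`%s` must be >= %s (got %s)", name, min, x))
  if (x > max) abort_validation(sprintf("`%s` must be <= %s (got %s)", name, max, x))
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_validation(sprintf("`%s` must be a whole number (got %s)", name, x))
  }
  invisible(x)
}

check_probability <- function(x, name, allow_null = FALSE) {
  check_scalar_number(x, name, min = 0, max = 1, allow_null = allow_null)
}

# Run code with the global RNG state restored afterwards, seeded locally.
with_seed <- function(seed, code) {
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
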