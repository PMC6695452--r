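#' Internal assertion helpers
#'
#' Small guard functions used across the package to validate user input.
#' They stop with the offending argument name in the message.
#' @noRd
stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  stop_if(lo_bad || hi_bad,
          sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

#' Derive a reproducible child seed from a master seed
#'
#' A Lehmer-style step keeps every derived seed a valid 32-bit integer, so
#' independent components (sessions, neurons, bootstrap replicates) can each
#' get their own stream from one user-facing seed.
#' @noRd
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2L)) s <- (s * 48271 + index * 2654435761) %% m
  as.integer(s %% (m - 1)) + 1L
}

#' Run an expression under a local seed (global RNG state untouched)
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
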