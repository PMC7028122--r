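#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global random stream seeded at \code{seed},
#' restoring the caller's \code{.Random.seed} afterwards so that package
#' functions never perturb user-level randomness.
#'
#' @param seed integer seed (may be NULL, in which case the expression is
#'   evaluated on the current stream and reproducibility is not guaranteed).
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic arithmetic hash used to give each simulated session its own
#' named stream. Kept strictly below 2^31 so the result is a valid R seed.
#'
#' @param seed master integer seed.
#' @param ... integer offsets identifying the stream (participant index, run
#'   index, ...).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h)
}

# shared argument checks ------------------------------------------------------

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
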