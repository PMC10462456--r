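#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.005 -> 0.01),
#' the convention used for the survey's reported indices, rather than the
#' IEEE banker's rounding of [base::round()].
#'
#' @param x Numeric vector (non-negative values expected).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.855, 2) # 0.86, where round(0.855, 2) gives 0.85 or 0.86
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards values like 0.285 stored as 0.28499999...
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
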