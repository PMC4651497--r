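#' @keywords internal
#' @useDynLib surequant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps every derived seed a valid 32-bit
# integer no matter how large `i` gets.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 7919) %% 2147483587L) + 1L
}

#' Round half away from zero
#'
#' Table-style rounding: 3.85 -> 3.9, -3.85 -> -3.9. `base::round()` rounds half
#' to even, which does not reproduce the conventions used in printed cohort
#' tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(3.85, 1)  # 3.9
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  # the 1e-9 guard absorbs binary representation error in values like 38.5
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)
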