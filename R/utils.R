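# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random stream. A `NULL` seed evaluates the
#' expression in the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Wrap phase angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # map the representative -pi back to +pi so the interval is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Analytic signal via the Hilbert transform
#'
#' FFT-based construction: negative frequencies are zeroed, positive
#' frequencies doubled, DC and (for even lengths) Nyquist left untouched.
#'
#' @param x real-valued numeric vector.
#' @return complex vector `x + i * H(x)` of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 2L) stop("analytic_signal() needs at least 2 samples")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in input")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Deterministic child seeds for nested generation, kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
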