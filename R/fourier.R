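#' Truncated Fourier representation of a stance-aligned curve
#'
#' A curve f(t) on t in \[0, T\] is represented as
#' \deqn{f(t) \approx a_0 + \sum_{k=1}^{K} a_k \cos(2\pi k t/T) +
#'       b_k \sin(2\pi k t/T)}
#' with K harmonics (default 15, i.e. 31 real coefficients). The stance
#' duration T is carried alongside the coefficients: the coefficients
#' describe shape on normalized time, T restores the physical time base.
#'
#' @param a0 Constant term.
#' @param a,b Cosine/sine coefficient vectors, each of length `K`.
#' @param duration_s Stance duration T the curve was fitted over (s).
#' @return An object of class `fourier_coefficients`.
#' @export
fourier_coefficients <- function(a0, a, b, duration_s) {
  stopifnot(length(a) == length(b), length(a) >= 1, duration_s > 0,
            is.finite(a0), all(is.finite(a)), all(is.finite(b)))
  structure(list(a0 = a0, a = as.numeric(a), b = as.numeric(b),
                 K = length(a), duration_s = duration_s),
            class = "fourier_coefficients")
}

#' Fit a truncated Fourier series to a curve
#'
#' Least-squares fit on the (possibly non-uniform) time grid; on uniform
#' grids this coincides with FFT bin extraction but stays valid after
#' resampling or cropping.
#'
#' @param values Curve samples.
#' @param times Sample times in seconds, spanning \[0, T\].
#' @param K Number of harmonics (default 15).
#' @param period Fundamental period T; defaults to the last sample time.
#' @return A [fourier_coefficients()] object with `duration_s = period`.
#' @export
#' @examples
#' t <- seq(0, 0.25, length.out = 201)
#' fc <- fit_fourier(cos(2 * pi * 3 * t / 0.25), t, K = 15)
#' round(fc$a[3], 6)  # the third cosine harmonic
fit_fourier <- function(values, times, K = 15, period = NULL) {
  stopifnot(length(values) == length(times), K >= 1)
  if (is.null(period)) period <- tail(times, 1)
  stopifnot(period > 0)
  n <- length(values)
  if (n < 2 * K + 1)
    stop("need at least 2K+1 = ", 2 * K + 1, " samples to fit ", K,
         " harmonics (got ", n, ")", call. = FALSE)
  w <- 2 * pi * outer(times / period, seq_len(K))
  X <- cbind(1, cos(w), sin(w))
  beta <- qr.coef(qr(X), values)
  if (anyNA(beta))
    stop("rank-deficient Fourier design matrix", call. = FALSE)
  fourier_coefficients(beta[1], beta[2:(K + 1)], beta[(K + 2):(2 * K + 1)],
                       duration_s = period)
}

#' Evaluate a truncated Fourier series on a normalized grid
#'
#' @param coeffs A [fourier_coefficients()] object.
#' @param grid Normalized times in \[0, 1\] (fractions of stance).
#' @return Curve values at `grid * duration_s`.
#' @export
eval_fourier <- function(coeffs, grid) {
  stopifnot(inherits(coeffs, "fourier_coefficients"))
  if (length(grid) == 0L) return(numeric(0))
  if (any(grid < -1e-12 | grid > 1 + 1e-12))
    stop("grid must lie in [0, 1]", call. = FALSE)
  w <- 2 * pi * outer(grid, seq_len(coeffs$K))
  as.numeric(coeffs$a0 + cos(w) %*% coeffs$a + sin(w) %*% coeffs$b)
}

#' Flatten Fourier coefficients to a vector (and back)
#'
#' The flat layout is `(a0, a1..aK, b1..bK)`, length `2K + 1`. The ordering
#' is fixed and round-trips exactly; `duration_s` is not part of the vector
#' and must be supplied when unflattening.
#'
#' @param coeffs A [fourier_coefficients()] object.
#' @return `coefficient_vector()`: numeric vector of length `2K + 1`.
#' @export
coefficient_vector <- function(coeffs) {
  stopifnot(inherits(coeffs, "fourier_coefficients"))
  c(coeffs$a0, coeffs$a, coeffs$b)
}

#' @rdname coefficient_vector
#' @param v Flat coefficient vector of odd length `2K + 1`.
#' @param duration_s Stance duration to attach.
#' @export
vector_to_coefficients <- function(v, duration_s) {
  n <- length(v)
  if (n < 3L || n %% 2L != 1L)
    stop("coefficient vector must have odd length >= 3", call. = FALSE)
  K <- (n - 1L) / 2L
  fourier_coefficients(v[1], v[2:(K + 1)], v[(K + 2):n],
                       duration_s = duration_s)
}

#' Fit the Fourier representation of a stance or envelope curve
#'
#' Convenience wrapper around [fit_fourier()] using the curve's own time
#' base.
#'
#' @param curve A `stance_curve` or `envelope_curve`.
#' @param K Number of harmonics.
#' @return A [fourier_coefficients()] object.
#' @export
fit_curve_fourier <- function(curve, K = 15) {
  fit_fourier(curve$values, curve$times, K = K)
}
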