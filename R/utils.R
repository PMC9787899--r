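# Internal helpers shared across modules.

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding at
# both ends so short stance windows do not show start-up transients.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 20L)
  if (padlen < 1L) return(as.numeric(signal::filtfilt(b, a, x)))
  pre  <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(padlen + 1L):(padlen + n)]
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Greatest common divisor, for reducing resampling ratios.
gcd <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# Linear interpolation of a curve at arbitrary times (no extrapolation).
interp_curve <- function(times, values, at) {
  stats::approx(times, values, xout = at, rule = 1)$y
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
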