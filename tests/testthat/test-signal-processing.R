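test_that("force low-pass passes DC unchanged and is linear", {
  rec <- force_recording(rep(800, 500), rate = 1000)
  out <- filter_force(rec)
  expect_equal(out$samples, rep(800, 500), tolerance = 1e-8)

  x <- sin(2 * pi * 20 * (0:999) / 1000) + 0.3
  f1 <- filter_force(force_recording(x, 1000))$samples
  f3 <- filter_force(force_recording(3 * x, 1000))$samples
  expect_equal(f3, 3 * f1, tolerance = 1e-10)
})

test_that("force low-pass attenuates the stopband as a 4th-order Butterworth", {
  # 300 Hz on 1000 Hz data is deep in the stopband of a 60 Hz cut-off
  x <- sin(2 * pi * 300 * (0:1999) / 1000)
  y <- filter_force(force_recording(x, 1000))$samples
  expect_lt(max(abs(y[500:1500])), 0.01)
  # in the passband-to-transition region the measured zero-phase gain
  # matches the designed digital response squared
  x2 <- sin(2 * pi * 100 * (0:3999) / 1000)
  y2 <- filter_force(force_recording(x2, 1000))$samples
  bf <- signal::butter(4, 60 / 500, type = "low")
  w <- 2 * pi * 100 / 1000     # transfer function evaluated on the circle
  H <- Mod(sum(bf$b * exp(-1i * w * (0:4))) /
             sum(bf$a * exp(-1i * w * (0:4))))
  expect_equal(max(abs(y2[1500:2500])), H^2, tolerance = 0.02)
  expect_error(filter_force(force_recording(rep(1, 10), rate = 100)),
               "twice the low-pass cut-off")
})

test_that("stance segmentation finds maximal runs above 20 N", {
  # trapezoid rising 0 -> 800 -> 0 N
  x <- c(rep(0, 100), seq(0, 800, length.out = 126),
         rep(800, 100), seq(800, 0, length.out = 126), rep(0, 100))
  rec <- force_recording(x, 1000)
  iv <- segment_stances(rec)
  expect_equal(nrow(iv), 1L)
  expect_true(all(x[iv$start:iv$end] > 20))
  expect_true(x[iv$start - 1] <= 20 && x[iv$end + 1] <= 20)

  expect_equal(nrow(segment_stances(force_recording(rep(0, 100), 1000))), 0L)

  bump <- c(seq(0, 900, length.out = 150), seq(900, 0, length.out = 150))
  two <- force_recording(c(rep(0, 50), bump, rep(0, 200), bump, rep(0, 50)),
                         1000)
  iv2 <- segment_stances(two)
  expect_equal(nrow(iv2), 2L)
  expect_lt(iv2$end[1], iv2$start[2])
})

test_that("samples exactly at the threshold are excluded and short runs dropped", {
  x <- rep(0, 300)
  x[100:110] <- 20          # exactly at threshold: not stance
  expect_equal(nrow(segment_stances(force_recording(x, 1000))), 0L)
  x[100:110] <- 21          # above, but 11 ms < 80 ms minimum: dropped
  expect_equal(nrow(segment_stances(force_recording(x, 1000))), 0L)
  x[100:200] <- 21          # 101 ms: kept
  expect_equal(nrow(segment_stances(force_recording(x, 1000))), 1L)
})

test_that("segmentation matches a naive per-sample scan on random signals", {
  naive_scan <- function(x, thr, min_n) {
    runs <- list(); start <- NA
    for (i in seq_along(x)) {
      if (x[i] > thr && is.na(start)) start <- i
      if ((x[i] <= thr || i == length(x)) && !is.na(start)) {
        end <- if (x[i] <= thr) i - 1L else i
        if (end - start + 1L >= min_n) runs[[length(runs) + 1L]] <- c(start, end)
        start <- NA
      }
    }
    if (!length(runs)) return(data.frame(start = integer(), end = integer()))
    m <- do.call(rbind, runs)
    data.frame(start = m[, 1], end = m[, 2])
  }
  cfg <- processing_config()
  set.seed(7)
  for (i in 1:200) {
    knots <- runif(8, 0, 60)
    x <- approx(seq(0, 1, length.out = 8), knots,
                xout = seq(0, 1, length.out = 400))$y
    rec <- force_recording(x, 1000)
    got <- segment_stances(rec, cfg)
    want <- naive_scan(x, cfg$stance_threshold_n,
                       ceiling(cfg$min_stance_s * 1000))
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("body-weight normalization divides by weight exactly once", {
  cv <- stance_curve(c(0, 800, 1600, 400, 0), seq(0, 0.2, by = 0.05))
  norm <- normalize_stance(cv, 800)
  expect_equal(max(norm$values), 2.0)
  expect_true(norm$normalized)
  expect_error(normalize_stance(norm, 800), "already normalized")
  expect_error(normalize_stance(cv, 0), "positive")
  zero <- normalize_stance(stance_curve(c(0, 0), c(0, 0.1)), 700)
  expect_equal(zero$values, c(0, 0))
})

test_that("envelope of a rectified sine settles near 2/pi", {
  fs <- 44100
  t <- seq(0, 0.5, by = 1 / fs)
  rec <- sound_recording(sin(2 * pi * 1000 * t), fs, "Mic1")
  env <- suppressMessages(compute_envelope(rec))
  expect_equal(env$rate, 20000)
  mid <- env$values[4000:6000]
  expect_equal(mean(mid), 2 / pi, tolerance = 0.05)
  # negative excursions from filtering are bounded by 1% of the peak
  expect_gt(min(env$values), -0.01 * max(env$values))

  zero <- suppressMessages(compute_envelope(
    sound_recording(rep(0, 4410), fs, "Mic2")))
  expect_equal(max(abs(zero$values)), 0)
  empty <- compute_envelope(sound_recording(numeric(0), fs, "Mic3"))
  expect_length(empty$values, 0)
})

test_that("envelope segmentation maps stance windows through the rate ratio", {
  env <- list(values = seq_len(10000) / 10000, rate = 20000, mic_id = "Mic1")
  seg <- segment_envelope(env, data.frame(start = 101, end = 351),
                          force_rate = 1000)
  expect_equal(length(seg$values), 5001)           # samples 2001..7001
  expect_equal(seg$values[1], env$values[2001])
  expect_equal(seg$times[1], 0)
  seg0 <- segment_envelope(env, data.frame(start = 1, end = 100), 1000)
  expect_equal(seg0$values[1], env$values[1])
  expect_error(segment_envelope(env, data.frame(start = 450, end = 600),
                                1000), "outside")
  # round trip: the segment is exactly the windowed original
  expect_equal(seg$values, env$values[2001:7001])
})

test_that("foot contact angle classification uses closed printed boundaries", {
  expect_equal(classify_fca(8.0), "rearfoot")
  expect_equal(classify_fca(-1.6), "forefoot")
  expect_equal(classify_fca(0), "midfoot")
  expect_equal(classify_fca(c(10, 7.99, -1.59, -2)),
               c("rearfoot", "midfoot", "midfoot", "forefoot"))
  expect_error(classify_fca(NaN), "finite")
})
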