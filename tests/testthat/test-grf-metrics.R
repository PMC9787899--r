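# Curve constructors used throughout: a two-bump rearfoot-like curve and a
# single-bump forefoot-like curve, both on a 1 ms grid.
two_bump <- function(imp = 1.5, t_imp = 0.034, stance = 0.25) {
  t <- seq(0, stance, by = 0.001)
  v <- 2.3 * exp(-0.5 * ((t - 0.42 * stance) / (0.16 * stance))^2) +
    imp * 0.75 * exp(-0.5 * ((t - t_imp) / 0.006)^2)
  stance_curve(v, t, normalized = TRUE)
}
one_bump <- function(stance = 0.25) {
  t <- seq(0, stance, by = 0.001)
  stance_curve(2.3 * exp(-0.5 * ((t - 0.42 * stance) / (0.16 * stance))^2),
               t, normalized = TRUE)
}

test_that("the impact peak is the local maximum within the first 50 ms", {
  cv <- two_bump(imp = 2.0, t_imp = 0.034)
  ip <- find_impact_peak(cv)
  expect_lt(abs(ip$time_s - 0.034), 0.0015)
  expect_equal(ip$value_xbw, max(cv$values[cv$times <= 0.05]),
               tolerance = 1e-9)
  # monotone rise in the window: no impact peak
  expect_null(find_impact_peak(one_bump()))
  # a local max just beyond 50 ms does not qualify
  expect_null(find_impact_peak(two_bump(imp = 2.0, t_imp = 0.055)))
  # window boundary is inclusive at 50 ms
  expect_false(is.null(find_impact_peak(two_bump(t_imp = 0.046))))
  raw <- stance_curve(c(0, 800, 500, 900, 0), seq(0, 0.2, by = 0.05))
  expect_error(find_impact_peak(raw), "normalized")
})

test_that("impact-peak detection matches a brute-force scan on random curves", {
  brute <- function(v, t, win) {
    best <- NULL
    for (i in 2:(length(v) - 1)) {
      if (t[i] <= win && v[i] > v[i - 1] && v[i] > v[i + 1] &&
          (is.null(best) || v[i] > v[best])) best <- i
    }
    best
  }
  set.seed(31)
  for (rep in 1:200) {
    t <- seq(0, 0.25, by = 0.001)
    v <- 2 * exp(-0.5 * ((t - 0.1) / 0.04)^2)
    for (j in 1:3)
      v <- v + runif(1, 0, 1) *
        exp(-0.5 * ((t - runif(1, 0, 0.2)) / runif(1, 0.004, 0.03))^2)
    cv <- stance_curve(v, t, normalized = TRUE)
    got <- find_impact_peak(cv)
    want <- brute(v, t, 0.05)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$time_s, t[want])
  }
})

test_that("the deflection scan localizes a single kink and rejects straight lines", {
  kinked <- function(t_kink, stance = 0.3) {
    t <- seq(0, stance, by = 0.001)
    v <- ifelse(t <= t_kink, 20 * t, 20 * t_kink + 5 * (t - t_kink))
    stance_curve(v, t, normalized = TRUE)
  }
  d <- find_deflection_point(kinked(0.040))
  expect_equal(d$time_s, 0.040, tolerance = 1e-9)
  expect_lt(d$angle_rad, 0)
  # locality: moving the kink moves the detection with it (within a step)
  for (tk in c(0.025, 0.055, 0.080)) {
    expect_equal(find_deflection_point(kinked(tk))$time_s, tk,
                 tolerance = 0.0011)
  }
  line <- stance_curve(seq(0, 2, length.out = 301),
                       seq(0, 0.3, by = 0.001), normalized = TRUE)
  expect_warning(res <- find_deflection_point(line), "no downward")
  expect_null(res)
  short <- stance_curve(c(0, 1, 0), c(0, 0.05, 0.1), normalized = TRUE)
  expect_error(find_deflection_point(short), "too short")
})

test_that("the active peak is the global maximum with earliest-time tie-break", {
  t <- seq(0, 0.25, by = 0.001)
  cv <- stance_curve(2.3 * sin(pi * t / 0.25), t, normalized = TRUE)
  ap <- active_peak(cv)
  expect_equal(ap$value_xbw, max(cv$values))
  expect_equal(ap$time_pct, 50, tolerance = 0.5)
  flat <- stance_curve(rep(1.0, 5), seq(0, 0.2, by = 0.05),
                       normalized = TRUE)
  expect_equal(active_peak(flat)$time_s, 0)  # earliest on ties
})

test_that("all three loading rates equal the slope on linear ramps", {
  t <- seq(0, 0.25, by = 0.001)
  ramp <- stance_curve(30 * t, t, normalized = TRUE)
  lr <- loading_rates(ramp, impact = list(time_s = 0.040))
  expect_equal(lr$lr1_xbw_s, 30, tolerance = 1e-9)
  expect_equal(lr$lr2_xbw_s, 30, tolerance = 1e-9)
  expect_equal(lr$lr3_xbw_s, 30, tolerance = 1e-9)
  # affine degeneracy holds for any slope/intercept with crossings present
  for (s in c(12, 55)) {
    aff <- stance_curve(0.05 + s * t, t, normalized = TRUE)
    lr <- loading_rates(aff, impact = list(time_s = 0.045))
    expect_equal(lr$lr1_xbw_s, lr$lr3_xbw_s, tolerance = 1e-9)
    expect_equal(lr$lr2_xbw_s, s, tolerance = 1e-9)
  }
})

test_that("loading rates on a quadratic rise follow the closed forms", {
  t <- seq(0, 0.05, by = 0.0005)
  cv <- stance_curve(100 * t^2, t, normalized = TRUE)
  lr <- loading_rates(cv, impact = list(time_s = 0.05))
  expect_equal(lr$lr1_xbw_s, 100 * 0.05, tolerance = 1e-6)  # F(t)/t = 100 t
  # least-squares slope oracle computed directly from the moments
  y <- 100 * t^2
  want <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(lr$lr3_xbw_s, want, tolerance = 1e-9)
  expect_error(loading_rates(cv, impact = list(time_s = 0)), "positive")
})

test_that("LR-2 is reported missing when the 20/80% crossings do not exist", {
  t <- seq(0, 0.25, by = 0.001)
  # curve starting above 80% of its impact value: no crossings
  cv <- stance_curve(1.4 + 10 * t, t, normalized = TRUE)
  lr <- loading_rates(cv, impact = list(time_s = 0.03))
  expect_true(is.na(lr$lr2_xbw_s))
})

test_that("vertical impulse integrates the curve and is additive", {
  rect <- stance_curve(rep(2, 251), seq(0, 0.25, by = 0.001),
                       normalized = TRUE)
  expect_equal(vertical_impulse(rect)$xbw_s, 0.5, tolerance = 1e-9)
  tri <- stance_curve(c(seq(0, 2, length.out = 126),
                        seq(2, 0, length.out = 126)[-1]),
                      seq(0, 0.25, by = 0.001), normalized = TRUE)
  expect_equal(vertical_impulse(tri)$xbw_s, 0.25, tolerance = 1e-3)
  expect_equal(vertical_impulse(rect)$xbw_pct, 200, tolerance = 1e-9)
  # additivity over concatenated non-overlapping halves
  t <- seq(0, 0.25, by = 0.001)
  v <- 2.3 * sin(pi * t / 0.25)
  whole <- stance_curve(v, t, normalized = TRUE)
  a <- stance_curve(v[1:126], t[1:126], normalized = TRUE)
  b <- stance_curve(v[126:251], t[126:251] - t[126], normalized = TRUE)
  expect_equal(vertical_impulse(whole)$xbw_s,
               vertical_impulse(a)$xbw_s + vertical_impulse(b)$xbw_s,
               tolerance = 1e-12)
})

test_that("running style follows the presence of a prominent impact peak", {
  expect_equal(classify_style_from_vgrf(two_bump(imp = 1.5)), "rearfoot")
  expect_equal(classify_style_from_vgrf(one_bump()), "forefoot_midfoot")
  # a barely-there wiggle below the prominence floor is not an impact peak
  t <- seq(0, 0.25, by = 0.001)
  v <- 2.3 * exp(-0.5 * ((t - 0.105) / 0.04)^2) +
    0.01 * exp(-0.5 * ((t - 0.03) / 0.004)^2)
  wiggle <- stance_curve(v, t, normalized = TRUE)
  expect_equal(classify_style_from_vgrf(wiggle), "forefoot_midfoot")
})

test_that("style accuracy counts exact label agreement", {
  expect_equal(style_accuracy(c("R", "R"), c("R", "R")), 1.0)
  expect_equal(style_accuracy(c("R", "R", "F", "F"),
                              c("R", "F", "F", "F")), 0.75)
  expect_error(style_accuracy(c("R"), c("R", "F")), "equal length")
})

test_that("the combined variable extraction falls back to the deflection point", {
  vars_rf <- extract_biomech_variables(two_bump())
  expect_true(vars_rf$impact_peak_found)
  expect_equal(vars_rf$style_vgrf, "rearfoot")
  vars_ff <- extract_biomech_variables(one_bump())
  expect_false(vars_ff$impact_peak_found)
  expect_equal(vars_ff$style_vgrf, "forefoot_midfoot")
  expect_true(is.finite(vars_ff$t_impact_pct))  # deflection surrogate
  expect_true(is.finite(vars_ff$lr1_xbw_s))
})
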