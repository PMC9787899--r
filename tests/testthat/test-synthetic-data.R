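test_that("cohorts are bit-identical under the same spec and seed", {
  spec <- cohort_spec(n_subjects = 3, cycles_mean = 4, cycles_sd = 0,
                      seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  for (i in seq_along(c1$trials))
    expect_identical(coefficient_vector(c1$trials[[i]]$grf_coeffs),
                     coefficient_vector(c2$trials[[i]]$grf_coeffs))
  c3 <- generate_cohort(cohort_spec(n_subjects = 3, cycles_mean = 4,
                                    cycles_sd = 0, seed = 100))
  expect_false(identical(c1$truth$active_peak_xbw,
                         c3$truth$active_peak_xbw))
})

test_that("cohort counts and defaults track the specification", {
  expect_equal(cohort_spec()$n_subjects, 37)
  expect_equal(cohort_spec()$cycles_mean, 48)
  co <- small_cohort()
  expect_equal(nrow(co$subjects), 6)
  expect_equal(length(co$trials), sum(co$subjects$n_trials))
  expect_equal(nrow(co$truth), length(co$trials))
})

test_that("subject-level draws reproduce the configured population moments", {
  spec <- cohort_spec(n_subjects = 200, cycles_mean = 3, cycles_sd = 0,
                      envelope_noise_sd = 0, seed = 77)
  co <- generate_cohort(spec)
  sub <- co$subjects
  se <- function(s, n) s / sqrt(n)
  expect_lt(abs(mean(sub$mass_kg) - 77), 3 * se(11, 200))
  expect_lt(abs(mean(sub$speed_mps) - 2.75), 3 * se(0.33, 200))
  tr <- co$truth
  expect_lt(abs(mean(tr$active_peak_xbw) - 2.32), 3 * se(0.17, 200))
  rear <- tr[!is.na(tr$impact_peak_xbw), ]
  n_rear <- length(unique(rear$subject_id))
  expect_lt(abs(mean(rear$impact_peak_xbw) - 1.51), 3 * se(0.20, n_rear))
  expect_lt(abs(n_rear / 200 - 0.78), 3 * sqrt(0.78 * 0.22 / 200))
  # FCA values are drawn consistently with the style thresholds
  lab <- classify_fca(vapply(co$trials, `[[`, 0, "fca_deg"))
  style <- tr$style
  expect_true(all(lab[style == "rearfoot"] == "rearfoot"))
  expect_true(all(lab[style != "rearfoot"] != "rearfoot"))
})

test_that("generated curves honor their drawn peaks and the stance envelope", {
  par <- list(impact_peak_xbw = 1.51, t_impact_pct = 13.51,
              active_peak_xbw = 2.32, t_active_pct = 42.33,
              stance_time_s = 0.25)
  g <- seq(0, 1, length.out = 401)
  rf <- generate_vgrf("rearfoot", par, g)
  expect_equal(rf$values[1], 0)
  expect_equal(rf$values[401], 0)
  expect_gt(min(rf$values[2:400]), 0.025)
  # the curve passes through the drawn peak values at the drawn times
  # (tolerance covers linear interpolation on the 0.25%-stance grid)
  expect_equal(approx(100 * g, rf$values, 13.51)$y, 1.51, tolerance = 5e-3)
  expect_equal(approx(100 * g, rf$values, 42.33)$y, 2.32, tolerance = 1e-3)
  ff <- generate_vgrf("forefoot_midfoot", par, g)
  # no local maximum within the first 50 ms (20% of a 250 ms stance)
  early <- ff$values[g <= 0.2]
  expect_true(all(diff(early) > 0))
  expect_error(generate_vgrf("rearfoot",
                             within(par, t_impact_pct <- 60), g))
})

test_that("noise-free detector closure recovers the generated peaks", {
  co <- clean_cohort()
  rear <- co$truth[!is.na(co$truth$impact_peak_xbw), ]
  g <- seq(0, 1, length.out = 401)
  for (k in seq_len(nrow(rear))) {
    cv <- generate_vgrf("rearfoot",
                        list(impact_peak_xbw = rear$impact_peak_xbw[k],
                             t_impact_pct = rear$t_impact_pct[k],
                             active_peak_xbw = rear$active_peak_xbw[k],
                             t_active_pct = rear$t_active_pct[k],
                             stance_time_s = rear$stance_time_s[k]), g)
    ip <- find_impact_peak(cv)
    expect_false(is.null(ip))
    expect_lt(abs(ip$value_xbw - rear$impact_peak_xbw[k]) /
                rear$impact_peak_xbw[k], 0.01)
    expect_lt(abs(ip$time_pct - rear$t_impact_pct[k]), 0.5)
    ap <- active_peak(cv)
    expect_lt(abs(ap$value_xbw - rear$active_peak_xbw[k]) /
                rear$active_peak_xbw[k], 0.01)
    expect_lt(abs(ap$time_pct - rear$t_active_pct[k]), 0.5)
  }
})

test_that("envelope generation is a known deterministic map of the force", {
  par <- list(impact_peak_xbw = 1.5, t_impact_pct = 13,
              active_peak_xbw = 2.3, t_active_pct = 42,
              stance_time_s = 0.25)
  cv <- generate_vgrf("rearfoot", par)
  envs <- generate_envelopes(cv, mic_gains = rep(1, 4), noise_sd = 0)
  expect_equal(envs$Mic1$values, envs$Mic4$values)
  gains <- c(1, 2, 0.5, 3)
  envg <- generate_envelopes(cv, mic_gains = gains, noise_sd = 0)
  expect_equal(envg$Mic2$values, 2 * envg$Mic1$values, tolerance = 1e-12)
  # with w2 = 0 the early envelope is linear in the loading rate:
  # doubling the curve doubles the envelope everywhere
  cpl <- list(w1 = 0.01, w2 = 0, decay_s = 0.010)
  e1 <- generate_envelopes(cv, rep(1, 4), coupling = cpl, noise_sd = 0)
  cv2 <- cv; cv2$values <- 2 * cv$values
  e2 <- generate_envelopes(cv2, rep(1, 4), coupling = cpl, noise_sd = 0)
  expect_equal(e2$Mic1$values, 2 * e1$Mic1$values, tolerance = 1e-10)
  # same seed, same noise
  n1 <- generate_envelopes(cv, rep(1, 4), noise_sd = 0.1, seed = 3)
  n2 <- generate_envelopes(cv, rep(1, 4), noise_sd = 0.1, seed = 3)
  expect_identical(n1$Mic3$values, n2$Mic3$values)
})
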