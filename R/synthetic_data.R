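# Synthetic cohorts of coupled vGRF / sound-envelope trials with known
# ground truth. The generator emulates the study conditions: 37 recreational
# runners, ~48 footsteps each, 78% of subjects rearfoot strikers, two-peak
# stance curves whose impact/active peak magnitudes and timings follow the
# reported group distributions, and four microphone envelopes tied to the
# force by a known noisy mapping.

#' Specification of a synthetic running cohort
#'
#' Population distributions are Normal(mean, sd) with the defaults below;
#' per-trial values are the subject's draw plus Normal(0,
#' `trial_jitter_frac * sd`) jitter, so subjects differ more than their own
#' repeated footsteps.
#'
#' @param n_subjects Number of virtual runners (default 37).
#' @param cycles_mean,cycles_sd Footsteps per runner (defaults 48 and 8).
#' @param rearfoot_fraction Fraction of subjects who are rearfoot strikers
#'   (default 0.78); the rest are forefoot/midfoot.
#' @param mass_kg,speed_mps,stance_time_s Two-element `c(mean, sd)` vectors
#'   (defaults 77/11 kg, 2.75/0.33 m/s, 0.25/0.02 s).
#' @param impact_peak_xbw,t_impact_pct Impact-peak magnitude (xBW) and time
#'   (\% stance) distributions (defaults 1.51/0.20 and 13.51/0.71);
#'   rearfoot subjects only.
#' @param active_peak_xbw,t_active_pct Active-peak magnitude and time
#'   distributions (defaults 2.32/0.17 and 42.33/2.41).
#' @param trial_jitter_frac Trial-to-trial SD as a fraction of the
#'   population SD (default 0.3).
#' @param envelope_noise_sd SD of the per-sample multiplicative log-normal
#'   envelope noise (default 0.10; 0 = noise-free).
#' @param subject_gain_sd SD (log scale) of per-subject microphone gain
#'   multipliers — the subject-level random effect that makes
#'   leave-one-subject-out genuinely harder than trial-level splits
#'   (default 0.15).
#' @param mic_gains Base gains of the four microphones.
#' @param coupling List with `w1` (weight of the smoothed
#'   loading-rate term), `w2` (weight of the direct force term) and
#'   `decay_s` (exponential decay of the impact-to-sound kernel, s).
#' @param grid_n Samples per generated stance curve (default 401).
#' @param K Fourier harmonics fitted to every curve (default 15).
#' @param fca_step_fractions Step-level fractions of rearfoot/midfoot/
#'   forefoot foot-contact angles used when drawing FCA values.
#' @param seed Integer RNG seed; the same spec and seed reproduce the
#'   cohort bit for bit.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 37, cycles_mean = 48, cycles_sd = 8,
                        rearfoot_fraction = 0.78,
                        mass_kg = c(77, 11), speed_mps = c(2.75, 0.33),
                        stance_time_s = c(0.25, 0.02),
                        impact_peak_xbw = c(1.51, 0.20),
                        t_impact_pct = c(13.51, 0.71),
                        active_peak_xbw = c(2.32, 0.17),
                        t_active_pct = c(42.33, 2.41),
                        trial_jitter_frac = 0.3,
                        envelope_noise_sd = 0.10,
                        subject_gain_sd = 0.15,
                        mic_gains = c(Mic1 = 1.00, Mic2 = 0.90,
                                      Mic3 = 1.10, Mic4 = 0.95),
                        coupling = list(w1 = 0.01, w2 = 0.3,
                                        decay_s = 0.010),
                        grid_n = 401, K = 15,
                        fca_step_fractions = c(rearfoot = 0.70,
                                               midfoot = 0.21,
                                               forefoot = 0.09),
                        seed = 1L) {
  stopifnot(n_subjects >= 1, cycles_mean > 0,
            rearfoot_fraction >= 0, rearfoot_fraction <= 1,
            all(c(mass_kg[1], speed_mps[1], stance_time_s[1]) > 0),
            all(mic_gains > 0), grid_n >= 2 * K + 1,
            envelope_noise_sd >= 0, subject_gain_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# Window forcing curves to exactly 0 at 0% and 100% stance while barely
# touching mid-stance values; pct in [0, 100].
edge_window <- function(pct) sin(pi * pct / 100)^0.15

# Broad low-amplitude support keeping the interior above the 20 N
# segmentation threshold (~0.025 xBW) right up to the edges.
support_bump <- function(pct) 0.15 * sin(pi * pct / 100)^0.25

#' Generate one synthetic vGRF stance curve
#'
#' Curves are built from a broad support bump plus windowed Gaussian
#' components: an active bump (width 15\% stance) and, for rearfoot style,
#' a narrow impact bump (width 2\% stance). Component amplitudes are solved
#' so the curve passes exactly through the drawn peak values at the drawn
#' times; the curve is exactly 0 at 0\% and 100\% stance and exceeds
#' ~0.025 xBW over the interior, so 20 N stance segmentation recovers the
#' full window.
#'
#' @param style `"rearfoot"` or `"forefoot_midfoot"`.
#' @param params List with `active_peak_xbw`, `t_active_pct`,
#'   `stance_time_s` and, for rearfoot, `impact_peak_xbw`, `t_impact_pct`.
#' @param grid Normalized time grid in \[0, 1\].
#' @return A normalized `stance_curve` (xBW).
#' @export
generate_vgrf <- function(style = c("rearfoot", "forefoot_midfoot"),
                          params, grid = seq(0, 1, length.out = 401)) {
  style <- match.arg(style)
  pct <- 100 * grid
  ta <- params$t_active_pct; Fa <- params$active_peak_xbw
  stopifnot(ta > 0, ta < 100, Fa > 0, params$stance_time_s > 0)
  w_act <- 15; w_imp <- 2.5   # % stance; impact bump band-limited for K = 15
  phi_a <- function(p) exp(-0.5 * ((p - ta) / w_act)^2) * edge_window(p)
  rearfoot <- style == "rearfoot"
  if (rearfoot) {
    ti <- params$t_impact_pct; Fi <- params$impact_peak_xbw
    stopifnot(ti > 0, ti < ta, Fi > 0)
    phi_i <- function(p) exp(-0.5 * ((p - ti) / w_imp)^2) * edge_window(p)
  }
  # The bumps sit on a sloped background, so a bump centered exactly at a
  # drawn peak time realizes its local maximum slightly downhill of it.
  # Keep the interpolation constraints fixed at the drawn peaks and shift
  # the bump centers until the realized maxima land on the constraints;
  # the curve then attains exactly (Fi at ti) and (Fa at ta).
  ci <- if (rearfoot) ti else NA
  ca <- ta
  for (it in 1:6) {
    bump_i <- if (rearfoot)
      function(p) exp(-0.5 * ((p - ci) / w_imp)^2) * edge_window(p)
    bump_a <- function(p) exp(-0.5 * ((p - ca) / w_act)^2) * edge_window(p)
    if (rearfoot) {
      M <- rbind(c(bump_i(ti), bump_a(ti)), c(bump_i(ta), bump_a(ta)))
      amp <- solve(M, c(Fi - support_bump(ti), Fa - support_bump(ta)))
      curve_at <- function(p) support_bump(p) + amp[1] * bump_i(p) +
        amp[2] * bump_a(p)
    } else {
      amp <- (Fa - support_bump(ta)) / bump_a(ta)
      curve_at <- function(p) support_bump(p) + amp * bump_a(p)
    }
    if (any(amp <= 0))
      stop("inconsistent draws: non-positive bump amplitude", call. = FALSE)
    loc_max <- function(center, half) {
      p <- seq(max(0.5, center - half), min(99.5, center + half),
               by = 0.005)
      p[which.max(curve_at(p))]
    }
    shift_i <- if (rearfoot) loc_max(ti, 3) - ti else 0
    shift_a <- loc_max(ta, 6) - ta
    if (abs(shift_i) < 0.005 && abs(shift_a) < 0.005) break
    if (rearfoot) ci <- ci - shift_i
    ca <- ca - shift_a
  }
  if (abs(shift_i) > 0.05 || abs(shift_a) > 0.05)
    stop("inconsistent draws: impact and active peaks merge", call. = FALSE)
  v <- curve_at(pct)
  v[pct <= 0 | pct >= 100] <- 0
  stance_curve(v, grid * params$stance_time_s, normalized = TRUE)
}

#' Generate the four microphone envelopes for one stance
#'
#' Each envelope is
#' `gain_m * (w1 * smooth(|dF/dt|) + w2 * F) * exp(noise)`, where
#' `smooth()` convolves the absolute loading rate with a causal exponential
#' decay kernel (`decay_s`, default 10 ms) — louder footstep sound for
#' sharper impact loading — and `noise` is per-sample Gaussian on the log
#' scale. With zero noise and equal gains all four envelopes are identical
#' up to gain, and the early envelope peak is linear in the impact loading
#' rate when `w2 = 0`.
#'
#' @param vgrf A normalized `stance_curve`.
#' @param mic_gains Named (or ordered) vector of four positive gains.
#' @param coupling List with `w1`, `w2`, `decay_s`.
#' @param noise_sd Log-scale SD of the multiplicative noise.
#' @param seed Optional seed for standalone reproducibility; when `NULL`
#'   the surrounding RNG stream is used.
#' @return Named list `Mic1..Mic4` of `envelope_curve`s.
#' @export
generate_envelopes <- function(vgrf, mic_gains = c(1, 0.9, 1.1, 0.95),
                               coupling = list(w1 = 0.01, w2 = 0.3,
                                               decay_s = 0.010),
                               noise_sd = 0, seed = NULL) {
  stopifnot(length(mic_gains) == 4, all(mic_gains > 0))
  run <- function() {
    dt <- diff(vgrf$times)
    rate <- abs(c(diff(vgrf$values) / dt, 0))
    m <- max(2L, ceiling(3 * coupling$decay_s / dt[1]))
    kern <- exp(-(0:m) * dt[1] / coupling$decay_s)
    kern <- kern / sum(kern)
    smoothed <- as.numeric(stats::filter(c(numeric(m), rate), kern,
                                         sides = 1))[m + seq_along(rate)]
    base <- coupling$w1 * smoothed + coupling$w2 * vgrf$values
    mics <- c("Mic1", "Mic2", "Mic3", "Mic4")
    out <- lapply(seq_len(4), function(j) {
      noise <- if (noise_sd > 0)
        exp(rnorm(length(base), 0, noise_sd)) else 1
      envelope_curve(mic_gains[[j]] * base * noise, vgrf$times,
                     mic_id = mics[j])
    })
    names(out) <- mics
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Draw a per-trial FCA consistent with the curve style and the step-level
# strike-type fractions.
draw_fca <- function(style, fractions) {
  if (style == "rearfoot") {
    max(8, rnorm(1, 15, 3))
  } else {
    p_mid <- fractions[["midfoot"]] /
      (fractions[["midfoot"]] + fractions[["forefoot"]])
    if (runif(1) < p_mid) min(max(rnorm(1, 3, 1.8), -1.55), 7.95)
    else min(rnorm(1, -5, 2), -1.6)
  }
}

#' Generate a full synthetic cohort
#'
#' Draws subjects (mass, speed, stance time, style, curve-shape means,
#' microphone gain multipliers), then trials per subject (jittered shapes,
#' vGRF curve, four envelopes, Fourier coefficients), fully reproducible
#' from `spec$seed`. Inconsistent trial draws (impact at or after the
#' active peak, non-positive amplitudes) are redrawn.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with `trials` (list of
#'   [trial_record()]), `truth` (per-trial ground-truth data.frame),
#'   `subjects` (per-subject table) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    grid <- seq(0, 1, length.out = spec$grid_n)
    trials <- list(); truth <- list(); subjects <- list()
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%02d", s)
      style <- if (runif(1) < spec$rearfoot_fraction) "rearfoot"
               else "forefoot_midfoot"
      sub <- list(
        mass = max(45, rnorm(1, spec$mass_kg[1], spec$mass_kg[2])),
        speed = max(1.2, rnorm(1, spec$speed_mps[1], spec$speed_mps[2])),
        stance = max(0.15, rnorm(1, spec$stance_time_s[1],
                                 spec$stance_time_s[2])),
        imp = rnorm(1, spec$impact_peak_xbw[1], spec$impact_peak_xbw[2]),
        t_imp = rnorm(1, spec$t_impact_pct[1], spec$t_impact_pct[2]),
        act = rnorm(1, spec$active_peak_xbw[1], spec$active_peak_xbw[2]),
        t_act = rnorm(1, spec$t_active_pct[1], spec$t_active_pct[2]),
        gains = spec$mic_gains * exp(rnorm(4, 0, spec$subject_gain_sd)))
      n_tr <- max(3L, round(rnorm(1, spec$cycles_mean, spec$cycles_sd)))
      subjects[[s]] <- data.frame(
        subject_id = sid, style = style, mass_kg = sub$mass,
        speed_mps = sub$speed, n_trials = n_tr,
        body_weight_n = sub$mass * 9.81)
      jf <- spec$trial_jitter_frac
      for (k in seq_len(n_tr)) {
        repeat {
          par <- list(
            stance_time_s = max(0.15, sub$stance +
              rnorm(1, 0, jf * spec$stance_time_s[2])),
            active_peak_xbw = sub$act +
              rnorm(1, 0, jf * spec$active_peak_xbw[2]),
            t_active_pct = sub$t_act +
              rnorm(1, 0, jf * spec$t_active_pct[2]),
            impact_peak_xbw = sub$imp +
              rnorm(1, 0, jf * spec$impact_peak_xbw[2]),
            t_impact_pct = sub$t_imp +
              rnorm(1, 0, jf * spec$t_impact_pct[2]))
          ok <- par$active_peak_xbw > 0.5 && par$t_active_pct > 20 &&
            par$t_active_pct < 80 &&
            (style != "rearfoot" ||
               (par$impact_peak_xbw > 0.3 &&
                par$t_impact_pct > 5 &&
                par$t_impact_pct + 10 < par$t_active_pct))
          if (!ok) next
          curve <- tryCatch(generate_vgrf(style, par, grid),
                            error = function(e) NULL)
          if (!is.null(curve)) break
        }
        envs <- generate_envelopes(curve, mic_gains = sub$gains,
                                   coupling = spec$coupling,
                                   noise_sd = spec$envelope_noise_sd)
        speed_k <- max(1.0, sub$speed + rnorm(1, 0, 0.05))
        tid <- sprintf("%s_T%03d", sid, k)
        trials[[length(trials) + 1L]] <- trial_record(
          subject_id = sid, mass_kg = sub$mass, speed_mps = speed_k,
          stance_time_s = par$stance_time_s,
          envelope_coeffs = lapply(envs, fit_curve_fourier, K = spec$K),
          grf_coeffs = fit_curve_fourier(curve, K = spec$K),
          fca_deg = draw_fca(style, spec$fca_step_fractions),
          trial_id = tid)
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = sid, trial_id = tid, style = style,
          mass_kg = sub$mass, speed_mps = speed_k,
          stance_time_s = par$stance_time_s,
          impact_peak_xbw = if (style == "rearfoot")
            par$impact_peak_xbw else NA_real_,
          t_impact_pct = if (style == "rearfoot")
            par$t_impact_pct else NA_real_,
          active_peak_xbw = par$active_peak_xbw,
          t_active_pct = par$t_active_pct)
      }
    }
    structure(list(trials = trials, truth = do.call(rbind, truth),
                   subjects = do.call(rbind, subjects), spec = spec),
              class = "synthetic_cohort")
  })
}
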