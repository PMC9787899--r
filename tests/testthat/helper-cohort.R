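# Shared fixtures built in code. Cohorts are cached per test session so
# several test files can reuse them without regenerating.

.fixtures <- new.env(parent = emptyenv())

# Small noisy cohort: 6 subjects, ~8 trials each.
small_cohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generate_cohort(
      cohort_spec(n_subjects = 6, cycles_mean = 8, cycles_sd = 1,
                  seed = 101))
  .fixtures$small
}

# Noise-free cohort (no envelope noise, no subject gain effects) for
# detector-closure checks.
clean_cohort <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- generate_cohort(
      cohort_spec(n_subjects = 10, cycles_mean = 6, cycles_sd = 0,
                  envelope_noise_sd = 0, subject_gain_sd = 0,
                  seed = 202))
  .fixtures$clean
}

# Full-scale study cohort (37 subjects, ~48 cycles) for the acceptance
# checks; generated once.
study_cohort <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- generate_cohort(cohort_spec(seed = 303))
  .fixtures$study
}

# A deterministic single-bump stance curve for metric tests.
toy_curve <- function(stance = 0.25, n = 251, peak = 2.3, t_peak = 0.42) {
  g <- seq(0, 1, length.out = n)
  v <- peak * exp(-0.5 * ((g - t_peak) / 0.16)^2) * sin(pi * g)^0.2
  stance_curve(v, g * stance, normalized = TRUE)
}

# A minimal valid trial record with given coefficient vectors.
toy_trial <- function(subject = "S1", trial = "T1", K = 3,
                      stance = 0.25, env_scale = 1, grf_scale = 1) {
  mk <- function(s) fourier_coefficients(s, rep(s / 2, K), rep(-s / 3, K),
                                         duration_s = stance)
  envs <- list(Mic1 = mk(env_scale), Mic2 = mk(2 * env_scale),
               Mic3 = mk(3 * env_scale), Mic4 = mk(4 * env_scale))
  trial_record(subject, mass_kg = 77, speed_mps = 2.75,
               stance_time_s = stance, envelope_coeffs = envs,
               grf_coeffs = mk(grf_scale), trial_id = trial)
}
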