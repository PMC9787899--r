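# End-to-end orchestration: write a synthetic cohort to disk in the raw
# acquisition layout (force CSV + per-mic WAV), preprocess raw recordings
# into trial records, and run the full leave-one-subject-out experiment
# over the nine microphone combinations.

#' Write a synthetic cohort to disk in the raw acquisition layout
#'
#' For every subject: a force CSV (`force_<id>.csv`, columns `time_s`,
#' `fz_n` at 1000 Hz) and four WAV files (`<id>_Mic<k>.wav`, 44.1 kHz,
#' 32-bit float) holding a 1 kHz carrier amplitude-modulated by the
#' generated sound envelope, so the preprocessing chain recovers the
#' envelope up to a known 2/pi rectification factor. Stances are embedded
#' with `gap_s` of silence between footsteps. Also writes `subjects.csv`,
#' `ground_truth.csv` and a `manifest.json` with the seed and counts.
#'
#' @param spec A [cohort_spec()] (small cohorts recommended: raw audio is
#'   ~176 k samples per subject-second).
#' @param dir Output directory (created if needed).
#' @param force_rate,sound_rate Sampling rates of the written force and
#'   audio files (Hz).
#' @param gap_s Silence between consecutive footsteps (s).
#' @param carrier_hz Carrier frequency of the synthesized audio (Hz).
#' @return The cohort (invisibly), as generated by [generate_cohort()].
#' @export
simulate_to_disk <- function(spec, dir, force_rate = 1000,
                             sound_rate = 44100, gap_s = 0.45,
                             carrier_hz = 1000) {
  cohort <- generate_cohort(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub_ids <- vapply(cohort$trials, `[[`, "", "subject_id")
  for (s in cohort$subjects$subject_id) {
    idx <- which(sub_ids == s)
    bw <- cohort$subjects$body_weight_n[cohort$subjects$subject_id == s]
    durations <- vapply(idx, function(i)
      cohort$trials[[i]]$stance_time_s, 0)
    total_s <- gap_s + sum(durations + gap_s)
    nf <- ceiling(total_s * force_rate)
    ns <- ceiling(total_s * sound_rate)
    fz <- numeric(nf)
    audio <- matrix(0, nrow = ns, ncol = 4)
    cursor <- gap_s
    grid <- seq(0, 1, length.out = spec$grid_n)
    for (i in idx) {
      tr <- cohort$trials[[i]]
      stance_t <- grid * tr$stance_time_s
      vgrf <- eval_fourier(tr$grf_coeffs, grid)
      fi <- which(seq_len(nf) / force_rate >= cursor &
                  seq_len(nf) / force_rate <= cursor + tr$stance_time_s)
      fz[fi] <- pmax(0, interp_curve(stance_t,
                                     vgrf * bw,
                                     seq_len(nf)[fi] / force_rate - cursor))
      si <- which(seq_len(ns) / sound_rate >= cursor &
                  seq_len(ns) / sound_rate <= cursor + tr$stance_time_s)
      ts <- seq_len(ns)[si] / sound_rate - cursor
      for (m in 1:4) {
        env <- eval_fourier(tr$envelope_coeffs[[m]],
                            ts / tr$stance_time_s)
        audio[si, m] <- pmax(env, 0) * sin(2 * pi * carrier_hz * ts)
      }
      cursor <- cursor + tr$stance_time_s + gap_s
    }
    con <- file(file.path(dir, sprintf("force_%s.csv", s)), "wb")
    writeLines("time_s,fz_n", con)
    writeLines(sprintf("%.9g,%.9g", seq_len(nf) / force_rate, fz), con)
    close(con)
    for (m in 1:4)
      write_wav(audio[, m], sound_rate,
                file.path(dir, sprintf("%s_Mic%d.wav", s, m)))
  }
  wtab <- function(d, f) {
    con <- file(file.path(dir, f), "wb")
    write.csv(d, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  wtab(cohort$subjects, "subjects.csv")
  wtab(within(cohort$truth, {
    active_peak_xbw <- sprintf("%.9g", active_peak_xbw)
    t_active_pct <- sprintf("%.9g", t_active_pct)
  }), "ground_truth.csv")
  jsonlite::write_json(
    list(seed = spec$seed, n_subjects = spec$n_subjects,
         n_trials = length(cohort$trials),
         force_rate = force_rate, sound_rate = sound_rate,
         gap_s = gap_s, carrier_hz = carrier_hz),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Preprocess raw recordings into trial records
#'
#' Reads the layout written by [simulate_to_disk()] (or any matching
#' laboratory export): per subject, the force CSV is low-pass filtered and
#' segmented into stances (20 N rule), stance curves are body-weight
#' normalized, the four WAV channels are turned into linear envelopes and
#' cut with the force-derived stance events, and every curve is reduced to
#' its truncated Fourier coefficients.
#'
#' @param dir Directory holding `subjects.csv`, `force_<id>.csv` and
#'   `<id>_Mic1..4.wav`.
#' @param cfg A [processing_config()].
#' @param K Fourier harmonics per curve.
#' @param verbose Log per-subject stance counts.
#' @return List of [trial_record()]s.
#' @export
preprocess_recordings <- function(dir, cfg = processing_config(), K = 15,
                                  verbose = FALSE) {
  subjects <- read.csv(file.path(dir, "subjects.csv"))
  trials <- list()
  for (r in seq_len(nrow(subjects))) {
    s <- subjects$subject_id[r]
    rec <- read_force_csv(file.path(dir, sprintf("force_%s.csv", s)),
                          subject_id = s)
    rec <- filter_force(rec, cfg)
    stances <- segment_stances(rec, cfg)
    envs <- lapply(1:4, function(m) {
      w <- read_wav(file.path(dir, sprintf("%s_Mic%d.wav", s, m)))
      compute_envelope(sound_recording(w$samples[, 1], w$rate,
                                       sprintf("Mic%d", m)), cfg)
    })
    names(envs) <- sprintf("Mic%d", 1:4)
    if (verbose)
      message(s, ": ", nrow(stances), " stances detected")
    for (j in seq_len(nrow(stances))) {
      iv <- stances[j, ]
      curve <- normalize_stance(extract_stance(rec, iv),
                                subjects$body_weight_n[r])
      seg <- lapply(envs, segment_envelope, interval = iv,
                    force_rate = rec$rate)
      trials[[length(trials) + 1L]] <- trial_record(
        subject_id = s, mass_kg = subjects$mass_kg[r],
        speed_mps = subjects$speed_mps[r],
        stance_time_s = stance_duration(curve),
        envelope_coeffs = lapply(seg, fit_curve_fourier, K = K),
        grf_coeffs = fit_curve_fourier(curve, K = K),
        trial_id = sprintf("%s_T%03d", s, j))
    }
  }
  trials
}

#' Run the full leave-one-subject-out experiment
#'
#' For every requested microphone combination: LOSO prediction of all
#' trials, per-trial curve similarity, per-subject averages, and real/
#' predicted foot-strike classification with per-runner accuracy. For the
#' combinations in `biomech_combos` the full biomechanical variable set is
#' extracted from real and predicted curves and compared with paired
#' t-tests and Cohen's d. A repeated-measures ANOVA across combinations is
#' run on the per-subject rRMSE (and on style accuracy) when more than one
#' combination is evaluated.
#'
#' @param trials List of [trial_record()]s.
#' @param combos Character vector of combination names (default all nine).
#' @param grid Normalized evaluation grid (default 101 points, 0–100\%
#'   stance).
#' @param biomech_combos Combinations for which the Table-style variable
#'   comparison is computed (default `"Mic1234"`).
#' @param ... Passed to [fit_conditional_model()].
#' @return A list of class `stepforce_experiment` with elements
#'   `per_trial`, `per_subject`, `style_by_subject`, `style_summary`,
#'   `variable_comparison`, `anova_rrmse`, `anova_style`.
#' @export
run_experiment <- function(trials, combos = names(mic_combinations()),
                           grid = seq(0, 1, length.out = 101),
                           biomech_combos = "Mic1234", ...) {
  per_trial <- list(); per_subject <- list(); style_sub <- list()
  varcomp <- list()
  for (combo in combos) {
    res <- loso_evaluate(trials, combo, grid, ...)
    m <- res$metrics
    m$combo <- combo
    real_lab <- vapply(res$pairs, function(p)
      classify_style_from_vgrf(p$real), "")
    pred_lab <- vapply(res$pairs, function(p)
      classify_style_from_vgrf(p$pred), "")
    m$real_style <- real_lab
    m$pred_style <- pred_lab
    per_trial[[combo]] <- m
    agg <- do.call(rbind, lapply(split(m, m$subject_id), function(d)
      data.frame(combo = combo, subject_id = d$subject_id[1],
                 n_trials = nrow(d),
                 mean_r = mean(d$pearson_r),
                 mean_rmse_xbw = mean(d$rmse_xbw),
                 mean_rrmse_pct = mean(d$rrmse_pct),
                 style_accuracy_pct = 100 *
                   style_accuracy(d$real_style, d$pred_style))))
    per_subject[[combo]] <- agg
    style_sub[[combo]] <- agg[, c("combo", "subject_id",
                                  "style_accuracy_pct")]
    if (combo %in% biomech_combos)
      varcomp[[combo]] <- compare_biomech(res$pairs, combo)
  }
  per_subject <- do.call(rbind, c(per_subject, make.row.names = FALSE))
  style_summary <- do.call(rbind, lapply(split(per_subject,
                                               per_subject$combo),
    function(d) {
      acc <- d$style_accuracy_pct
      ci <- ci_of_mean(mean(acc), sd(acc), length(acc))
      data.frame(combo = d$combo[1], mean_pct = mean(acc),
                 sd_pct = sd(acc), median_pct = stats::median(acc),
                 ci_lower_pct = ci[1], ci_upper_pct = ci[2])
    }))
  anova_rrmse <- NULL; anova_style <- NULL
  if (length(combos) > 1) {
    wide <- function(col) {
      v <- split(per_subject[[col]], per_subject$combo)
      do.call(cbind, v[combos])
    }
    anova_rrmse <- rm_anova(wide("mean_rrmse_pct"))
    anova_style <- rm_anova(wide("style_accuracy_pct"))
  }
  structure(list(per_trial = do.call(rbind,
                                     c(per_trial, make.row.names = FALSE)),
                 per_subject = per_subject,
                 style_by_subject = do.call(rbind,
                                            c(style_sub,
                                              make.row.names = FALSE)),
                 style_summary = style_summary,
                 variable_comparison = if (length(varcomp))
                   do.call(rbind, c(varcomp, make.row.names = FALSE))
                 else NULL,
                 anova_rrmse = anova_rrmse, anova_style = anova_style),
            class = "stepforce_experiment")
}

# Paired real-vs-predicted comparison of the biomechanical variable set,
# averaged per subject before group statistics.
compare_biomech <- function(pairs, combo) {
  rows <- lapply(pairs, function(p) {
    pv <- extract_biomech_variables(p$pred)
    cbind(subject_id = p$subject_id,
          extract_biomech_variables(p$real),
          setNames(pv, paste0("pred_", names(pv))))
  })
  d <- do.call(rbind, rows)
  vars <- c("impact_peak_xbw", "t_impact_pct", "active_peak_xbw",
            "t_active_pct", "lr1_xbw_s", "lr2_xbw_s", "lr3_xbw_s",
            "impulse_xbw_s", "impulse_xbw_pct")
  out <- lapply(vars, function(v) {
    per_sub <- do.call(rbind, lapply(split(d, d$subject_id), function(g) {
      rv <- g[[v]]; pv <- g[[paste0("pred_", v)]]
      ok <- is.finite(rv) & is.finite(pv)
      if (!any(ok)) return(NULL)
      data.frame(real = mean(rv[ok]), pred = mean(pv[ok]))
    }))
    if (is.null(per_sub) || nrow(per_sub) < 3) return(NULL)
    pc <- paired_comparison(per_sub$real, per_sub$pred)
    all_r <- d[[v]]; all_p <- d[[paste0("pred_", v)]]
    ok <- is.finite(all_r) & is.finite(all_p)
    data.frame(combo = combo, variable = v,
               real_mean = mean(per_sub$real), real_sd = sd(per_sub$real),
               pred_mean = mean(per_sub$pred), pred_sd = sd(per_sub$pred),
               p_value = pc$p, cohens_d = pc$cohens_d,
               pearson_r = if (sum(ok) > 2 && sd(all_r[ok]) > 0 &&
                               sd(all_p[ok]) > 0)
                 cor(all_r[ok], all_p[ok]) else NA_real_,
               n_subjects = nrow(per_sub))
  })
  do.call(rbind, out)
}

#' Write experiment summaries as byte-stable CSV files
#'
#' Writes `per_trial.csv`, `per_subject.csv`, `style_summary.csv` and
#' `variable_comparison.csv` with fixed `%.9g` numeric formatting so the
#' same experiment always produces byte-identical files.
#'
#' @param experiment A `stepforce_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) {
    if (is.null(d)) return(invisible(NULL))
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) sprintf("%.9g", x))
    con <- file(file.path(dir, f), "wb")
    write.csv(d, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  wr(experiment$per_trial, "per_trial.csv")
  wr(experiment$per_subject, "per_subject.csv")
  wr(experiment$style_summary, "style_summary.csv")
  wr(experiment$variable_comparison, "variable_comparison.csv")
  invisible(dir)
}
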