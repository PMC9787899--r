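#' The nine microphone combinations
#'
#' Singles Mic1..Mic4, pairs Mic12 (medial), Mic14 (posterior), Mic23
#' (anterior), Mic34 (lateral), and all four (Mic1234).
#'
#' @param name Optional combination name; when given, only that
#'   combination's member vector is returned.
#' @return Named list of member-mic character vectors, or one member vector.
#' @export
#' @examples
#' names(mic_combinations())
#' mic_combinations("Mic14")
mic_combinations <- function(name = NULL) {
  combos <- list(
    Mic1 = "Mic1", Mic2 = "Mic2", Mic3 = "Mic3", Mic4 = "Mic4",
    Mic12 = c("Mic1", "Mic2"),
    Mic14 = c("Mic1", "Mic4"),
    Mic23 = c("Mic2", "Mic3"),
    Mic34 = c("Mic3", "Mic4"),
    Mic1234 = c("Mic1", "Mic2", "Mic3", "Mic4"))
  if (is.null(name)) return(combos)
  if (!name %in% names(combos))
    stop("unknown microphone combination: ", name, call. = FALSE)
  combos[[name]]
}

#' One footstep trial: sound coefficients, scalars and vGRF coefficients
#'
#' @param subject_id Subject label.
#' @param mass_kg Body mass (kg).
#' @param speed_mps Running speed (m/s).
#' @param stance_time_s Stance duration (s).
#' @param envelope_coeffs Named list `Mic1..Mic4` of
#'   [fourier_coefficients()] for the sound envelopes.
#' @param grf_coeffs [fourier_coefficients()] of the body-weight-normalized
#'   vGRF; its `duration_s` must equal `stance_time_s`.
#' @param fca_deg Optional foot contact angle (degrees).
#' @param trial_id Optional trial label.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, mass_kg, speed_mps, stance_time_s,
                         envelope_coeffs, grf_coeffs, fca_deg = NA_real_,
                         trial_id = NA_character_) {
  stopifnot(mass_kg > 0, speed_mps > 0, stance_time_s > 0,
            inherits(grf_coeffs, "fourier_coefficients"))
  mics <- c("Mic1", "Mic2", "Mic3", "Mic4")
  if (!all(mics %in% names(envelope_coeffs)))
    stop("envelope_coeffs must contain all four microphones", call. = FALSE)
  if (abs(grf_coeffs$duration_s - stance_time_s) > 1e-9)
    stop("grf_coeffs duration must equal stance_time_s", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), mass_kg = mass_kg,
                 speed_mps = speed_mps, stance_time_s = stance_time_s,
                 envelope_coeffs = envelope_coeffs[mics],
                 grf_coeffs = grf_coeffs, fca_deg = fca_deg,
                 trial_id = as.character(trial_id)),
            class = "trial_record")
}

#' Assemble the predictor vector for one trial
#'
#' Concatenates the flat envelope coefficient vectors of the combination's
#' microphones (in combination order) followed by the three scalars: body
#' mass (kg), running speed (m/s) and stance time (s). With K = 15 the
#' length is `|mics| * 31 + 3` (e.g. 127 for Mic1234, 34 for a single mic).
#'
#' @param trial A [trial_record()].
#' @param combo Combination name (see [mic_combinations()]).
#' @return Numeric predictor vector.
#' @export
assemble_predictor_vector <- function(trial, combo) {
  members <- mic_combinations(combo)
  missing <- setdiff(members, names(trial$envelope_coeffs))
  if (length(missing))
    stop("trial lacks microphones: ", paste(missing, collapse = ", "),
         call. = FALSE)
  c(unlist(lapply(trial$envelope_coeffs[members], coefficient_vector),
           use.names = FALSE),
    trial$mass_kg, trial$speed_mps, trial$stance_time_s)
}

#' Fit the joint conditional-Gaussian model
#'
#' Predictor and target (vGRF coefficient) vectors are stacked per trial
#' into joint vectors, standardized per dimension (variance floor
#' `1e-12`), mean-centered and decomposed by PCA. Components are retained
#' up to `var_threshold` of the explained variance (always at least one).
#' The implied joint covariance in standardized space is
#' `B diag(lambda) B' + ridge * I` with `B` the retained components —
#' exactly the Gaussian the conditional prediction maximizes.
#'
#' @param trials List of [trial_record()]s (>= 2 trials, >= 2 subjects
#'   recommended; a single repeated trial degenerates to its mean).
#' @param combo Combination name.
#' @param var_threshold Fraction of variance retained by the PCA (default
#'   0.99).
#' @param ridge Tikhonov regularization added to the implied covariance
#'   (default 1e-8) so conditional solves stay well-posed.
#' @param subspace `"retained"` (default) restricts the covariance to the
#'   retained principal subspace; `"full"` keeps all components (the sample
#'   covariance).
#' @return An object of class `conditional_model`.
#' @export
fit_conditional_model <- function(trials, combo, var_threshold = 0.99,
                                  ridge = 1e-8,
                                  subspace = c("retained", "full")) {
  subspace <- match.arg(subspace)
  if (length(trials) < 2)
    stop("need at least 2 trials to estimate variation", call. = FALSE)
  X <- t(vapply(trials, assemble_predictor_vector, combo = combo,
                FUN.VALUE = assemble_predictor_vector(trials[[1]], combo)))
  Y <- t(vapply(trials, function(tr) coefficient_vector(tr$grf_coeffs),
                FUN.VALUE = coefficient_vector(trials[[1]]$grf_coeffs)))
  Z <- cbind(X, Y)
  if (!all(is.finite(Z))) stop("non-finite joint vectors", call. = FALSE)
  center <- colMeans(Z)
  scale_ <- pmax(apply(Z, 2, sd), 1e-6)   # variance floor 1e-12
  Zs <- sweep(sweep(Z, 2, center), 2, scale_, "/")
  pc <- prcomp(Zs, center = FALSE, scale. = FALSE)
  vars <- pc$sdev^2
  if (subspace == "retained") {
    total <- sum(vars)
    m <- if (total <= 0) 1L else
      max(1L, which(cumsum(vars) / total >= var_threshold)[1])
  } else {
    m <- sum(vars > 0)
    m <- max(1L, m)
  }
  structure(list(center = center, scale = scale_,
                 basis = pc$rotation[, seq_len(m), drop = FALSE],
                 variances = vars[seq_len(m)],
                 n_components = m,
                 predictor_len = ncol(X), target_len = ncol(Y),
                 ridge = ridge, subspace = subspace, combo = combo,
                 grf_K = trials[[1]]$grf_coeffs$K,
                 n_trials = nrow(Z)),
            class = "conditional_model")
}

# Implied joint covariance of the model in standardized space.
model_covariance <- function(model) {
  B <- model$basis
  S <- B %*% (model$variances * t(B))
  S + diag(model$ridge, nrow(S))
}

#' Predict vGRF coefficients by conditional maximum likelihood
#'
#' Given a predictor vector x, returns the target vector y maximizing the
#' Gaussian log-likelihood implied by the model's mean, PCA basis and
#' component variances with the predictor coordinates fixed — the solution
#' of the equality-constrained quadratic program
#' \deqn{\min_y \; (z - \mu)^\top \Sigma^{-1} (z - \mu), \quad z = (x, y),}
#' which is the Gaussian conditional mean
#' \eqn{\mu_y + \Sigma_{yx} \Sigma_{xx}^{-1}(x - \mu_x)}.
#'
#' @param object A `conditional_model`.
#' @param predictor_vector Numeric vector of length `predictor_len`.
#' @param ... Unused.
#' @return Predicted flat vGRF coefficient vector (length `target_len`).
#' @export
predict.conditional_model <- function(object, predictor_vector, ...) {
  p <- object$predictor_len
  if (length(predictor_vector) != p)
    stop("predictor vector has length ", length(predictor_vector),
         ", expected ", p, call. = FALSE)
  q <- object$target_len
  xi <- seq_len(p); yi <- p + seq_len(q)
  xs <- (predictor_vector - object$center[xi]) / object$scale[xi]
  S <- model_covariance(object)
  Sxx <- S[xi, xi, drop = FALSE]
  Syx <- S[yi, xi, drop = FALSE]
  ys <- as.numeric(Syx %*% solve(Sxx, xs))
  ys * object$scale[yi] + object$center[yi]
}

#' Predict a full vGRF stance curve for one trial
#'
#' Runs [predict.conditional_model()] on the trial's predictor vector,
#' unflattens the result with the trial's measured stance time, and
#' evaluates the series on a normalized grid (default 101 points,
#' 0–100\% stance).
#'
#' @param model A `conditional_model`.
#' @param trial A [trial_record()].
#' @param grid Normalized times in \[0, 1\].
#' @return A normalized `stance_curve` (xBW) on `grid * stance_time`.
#' @export
predict_curve <- function(model, trial, grid = seq(0, 1, length.out = 101)) {
  yhat <- predict(model, assemble_predictor_vector(trial, model$combo))
  fc <- vector_to_coefficients(yhat, duration_s = trial$stance_time_s)
  stance_curve(eval_fourier(fc, grid), grid * trial$stance_time_s,
               normalized = TRUE)
}

#' Leave-one-subject-out evaluation of the sound-to-force predictor
#'
#' For each subject in turn, a model is fitted on all other subjects'
#' trials only (no target information from the held-out subject enters
#' training) and every held-out trial is predicted. Real curves are the
#' trials' own Fourier reconstructions on the same grid, so real and
#' predicted curves are compared in the same representation.
#'
#' @param trials List of [trial_record()]s covering >= 2 subjects.
#' @param combo Combination name.
#' @param grid Normalized evaluation grid in \[0, 1\].
#' @param ... Passed to [fit_conditional_model()].
#' @return A list with `combo`, `pairs` (per-trial list of `subject_id`,
#'   `trial_id`, `real`, `pred` stance curves) and `metrics` (data.frame of
#'   per-trial Pearson r, RMSE and rRMSE from [curve_similarity()]).
#' @export
loso_evaluate <- function(trials, combo, grid = seq(0, 1, length.out = 101),
                          ...) {
  subjects <- vapply(trials, `[[`, "", "subject_id")
  if (length(unique(subjects)) < 2)
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  pairs <- vector("list", length(trials))
  k <- 1L
  for (s in unique(subjects)) {
    model <- fit_conditional_model(trials[subjects != s], combo, ...)
    for (i in which(subjects == s)) {
      tr <- trials[[i]]
      real <- stance_curve(eval_fourier(tr$grf_coeffs, grid),
                           grid * tr$stance_time_s, normalized = TRUE)
      pairs[[k]] <- list(subject_id = s, trial_id = tr$trial_id,
                         real = real, pred = predict_curve(model, tr, grid))
      k <- k + 1L
    }
  }
  metrics <- do.call(rbind, lapply(pairs, function(p) {
    q <- curve_similarity(p$real, p$pred)
    data.frame(subject_id = p$subject_id, trial_id = p$trial_id,
               pearson_r = q$pearson_r, rmse_xbw = q$rmse_xbw,
               rrmse_pct = q$rrmse_pct)
  }))
  list(combo = combo, pairs = pairs, metrics = metrics)
}
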