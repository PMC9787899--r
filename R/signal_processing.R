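#' Force and sound recording containers
#'
#' Light containers for raw vertical force and microphone recordings.
#' `force_recording()` holds vertical force in Newtons at a fixed sampling
#' rate (nominally 1000 Hz); `sound_recording()` holds a single microphone
#' channel in linear amplitude units (nominally 44.1 kHz).
#'
#' @param samples Numeric vector of samples (force in N, sound in linear
#'   amplitude).
#' @param rate Sampling rate in Hz.
#' @param subject_id Opaque subject label.
#' @param mic_id One of `"Mic1"`, `"Mic2"`, `"Mic3"`, `"Mic4"`.
#' @return An object of class `force_recording` or `sound_recording`.
#' @export
force_recording <- function(samples, rate, subject_id = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) >= 2, rate > 0)
  assert_finite(samples, "force samples")
  structure(list(samples = as.numeric(samples), rate = rate,
                 subject_id = subject_id),
            class = "force_recording")
}

#' @rdname force_recording
#' @export
sound_recording <- function(samples, rate, mic_id) {
  stopifnot(is.numeric(samples), rate > 0)
  mic_id <- match.arg(mic_id, c("Mic1", "Mic2", "Mic3", "Mic4"))
  assert_finite(samples, "sound samples")
  structure(list(samples = as.numeric(samples), rate = rate, mic_id = mic_id),
            class = "sound_recording")
}

#' Stance-phase curve containers
#'
#' `stance_curve()` holds the vertical force over one stance phase on a time
#' base starting at initial contact (t = 0). Values are Newtons until
#' [normalize_stance()] converts them to multiples of body weight (xBW).
#' `envelope_curve()` holds the non-negative sound envelope of one
#' microphone over the same stance window.
#'
#' @param values Numeric vector (force or envelope amplitude).
#' @param times Seconds from initial contact; strictly increasing, first
#'   element 0.
#' @param body_weight Subject body weight in Newtons (optional until
#'   normalization).
#' @param normalized Logical: are `values` already in xBW?
#' @param mic_id Microphone label for envelope curves.
#' @return An object of class `stance_curve` or `envelope_curve`.
#' @export
stance_curve <- function(values, times, body_weight = NA_real_,
                         normalized = FALSE) {
  stopifnot(length(values) == length(times), length(values) >= 2)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 body_weight = body_weight, normalized = isTRUE(normalized)),
            class = "stance_curve")
}

#' @rdname stance_curve
#' @export
envelope_curve <- function(values, times, mic_id) {
  stopifnot(length(values) == length(times), length(values) >= 2)
  mic_id <- match.arg(mic_id, c("Mic1", "Mic2", "Mic3", "Mic4"))
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 mic_id = mic_id),
            class = "envelope_curve")
}

#' Stance duration of a curve, in seconds
#' @param curve A `stance_curve`.
#' @return Duration in seconds (time of the last sample).
#' @export
stance_duration <- function(curve) {
  tail(curve$times, 1)
}

#' Low-pass filter a vertical force recording
#'
#' Applies a 4th-order Butterworth low-pass (default cut-off 60 Hz) to the
#' raw force signal. Filtering is zero-phase (forward-backward) so stance
#' event timing is not lagged.
#'
#' @param rec A [force_recording()].
#' @param cfg A [processing_config()].
#' @return A `force_recording` of the same length, filtered.
#' @export
#' @examples
#' rec <- force_recording(rep(800, 500), rate = 1000)
#' filtered <- filter_force(rec)
#' range(filtered$samples)  # DC passes unchanged
filter_force <- function(rec, cfg = processing_config()) {
  stopifnot(inherits(rec, "force_recording"))
  fc <- cfg$force_lowpass_hz
  if (rec$rate <= 2 * fc)
    stop("sampling rate must exceed twice the low-pass cut-off", call. = FALSE)
  bf <- signal::butter(4, fc / (rec$rate / 2), type = "low")
  rec$samples <- zero_phase_filter(bf$b, bf$a, rec$samples)
  rec
}

#' Segment stance phases from a force recording
#'
#' A stance phase is a maximal contiguous run of samples with vertical force
#' strictly above the threshold (default 20 N). Runs shorter than
#' `cfg$min_stance_s` are discarded as bounces or noise.
#'
#' @param rec A (filtered) [force_recording()].
#' @param cfg A [processing_config()].
#' @return A data.frame with columns `start`, `end` (1-based sample indices,
#'   inclusive), in temporal order; zero rows when no sample exceeds the
#'   threshold.
#' @export
segment_stances <- function(rec, cfg = processing_config()) {
  stopifnot(inherits(rec, "force_recording"), cfg$stance_threshold_n > 0)
  above <- rec$samples > cfg$stance_threshold_n
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  min_n <- ceiling(cfg$min_stance_s * rec$rate)
  out[out$end - out$start + 1L >= min_n, , drop = FALSE]
}

#' Extract one stance curve from a force recording
#'
#' @param rec A (filtered) [force_recording()].
#' @param interval One row of the [segment_stances()] result (or any list
#'   with `start` and `end` sample indices).
#' @param body_weight Subject body weight in Newtons (optional).
#' @return A `stance_curve` in Newtons with times re-based to 0.
#' @export
extract_stance <- function(rec, interval, body_weight = NA_real_) {
  i <- seq.int(interval$start, interval$end)
  stance_curve(rec$samples[i], (i - i[1]) / rec$rate,
               body_weight = body_weight, normalized = FALSE)
}

#' Normalize a stance curve to body weight
#'
#' Divides the force values by the subject's body weight, yielding xBW.
#'
#' @param curve A `stance_curve` in Newtons (not yet normalized).
#' @param body_weight_n Body weight in Newtons; must be positive.
#' @return The normalized `stance_curve`.
#' @export
normalize_stance <- function(curve, body_weight_n) {
  stopifnot(inherits(curve, "stance_curve"))
  if (!is.finite(body_weight_n) || body_weight_n <= 0)
    stop("body weight must be a positive number of Newtons", call. = FALSE)
  if (curve$normalized) stop("curve is already normalized", call. = FALSE)
  curve$values <- curve$values / body_weight_n
  curve$body_weight <- body_weight_n
  curve$normalized <- TRUE
  curve
}

#' Compute the linear envelope of a sound recording
#'
#' Chain: resample to `cfg$sound_resample_hz` (polyphase FIR) -> band-pass
#' with a 1st-order Butterworth over `cfg$band_edges_hz` -> full-wave
#' rectification -> zero-phase low-pass at `cfg$envelope_lowpass_hz`.
#' When the upper band edge is at or above Nyquist of the resampled rate the
#' band-pass degenerates to a pure high-pass at the lower edge (a message is
#' emitted once per call).
#'
#' @param rec A [sound_recording()].
#' @param cfg A [processing_config()].
#' @return A list with `values` (envelope samples), `rate`
#'   (= `cfg$sound_resample_hz`) and `mic_id`.
#' @export
compute_envelope <- function(rec, cfg = processing_config()) {
  stopifnot(inherits(rec, "sound_recording"))
  x <- rec$samples
  if (length(x) == 0L)
    return(list(values = numeric(0), rate = cfg$sound_resample_hz,
                mic_id = rec$mic_id))
  fs <- cfg$sound_resample_hz
  if (fs < 2 * cfg$envelope_lowpass_hz)
    stop("resample rate below twice the envelope low-pass cut-off",
         call. = FALSE)
  if (cfg$decibel_conversion) x <- sign(x) * 20 * log10(1 + abs(x) / 1e-6)
  if (rec$rate != fs) {
    g <- gcd(round(fs), round(rec$rate))
    x <- as.numeric(signal::resample(x, round(fs) / g, round(rec$rate) / g))
  }
  nyq <- fs / 2
  lo <- cfg$band_edges_hz[1]
  hi <- cfg$band_edges_hz[2]
  bh <- signal::butter(1, lo / nyq, type = "high")
  x <- zero_phase_filter(bh$b, bh$a, x)
  if (hi < nyq) {
    bl <- signal::butter(1, hi / nyq, type = "low")
    x <- zero_phase_filter(bl$b, bl$a, x)
  } else {
    message("band-pass upper edge at/above Nyquist (", hi,
            " Hz >= ", nyq, " Hz): applied as high-pass only")
  }
  x <- abs(x)
  be <- signal::butter(cfg$envelope_lowpass_order,
                       cfg$envelope_lowpass_hz / nyq, type = "low")
  x <- zero_phase_filter(be$b, be$a, x)
  list(values = x, rate = fs, mic_id = rec$mic_id)
}

#' Cut a sound envelope to a force-defined stance window
#'
#' The force and sound streams are assumed to share a common start trigger
#' (synchronized acquisition); samples are mapped through the rate ratio.
#'
#' @param env Envelope list as returned by [compute_envelope()].
#' @param interval Stance interval (`start`, `end` force-sample indices).
#' @param force_rate Force sampling rate (Hz).
#' @return An `envelope_curve` with times re-based to 0 at initial contact.
#' @export
segment_envelope <- function(env, interval, force_rate) {
  ratio <- env$rate / force_rate
  s <- round((interval$start - 1L) * ratio) + 1L
  e <- round((interval$end - 1L) * ratio) + 1L
  if (s < 1L || e > length(env$values))
    stop("stance window falls outside the sound recording", call. = FALSE)
  i <- seq.int(s, e)
  envelope_curve(env$values[i], (i - s) / env$rate, mic_id = env$mic_id)
}

#' Classify foot strike from the foot contact angle
#'
#' Rearfoot when FCA >= 8 degrees, forefoot when FCA <= -1.6 degrees,
#' midfoot in between (boundaries per the standard sagittal-plane
#' convention; both thresholds configurable).
#'
#' @param fca_deg Foot contact angle in degrees (finite scalar or vector).
#' @param cfg A [processing_config()].
#' @return Character vector in `{"rearfoot", "midfoot", "forefoot"}`.
#' @export
#' @examples
#' classify_fca(c(10, 0, -3))
classify_fca <- function(fca_deg, cfg = processing_config()) {
  if (!all(is.finite(fca_deg)))
    stop("foot contact angle must be finite", call. = FALSE)
  ifelse(fca_deg >= cfg$fca_rearfoot_deg, "rearfoot",
         ifelse(fca_deg <= cfg$fca_forefoot_deg, "forefoot", "midfoot"))
}
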