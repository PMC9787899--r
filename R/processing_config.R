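#' Processing configuration for force and sound signal chains
#'
#' Bundles every tunable constant of the preprocessing stage. Defaults are
#' the standard laboratory values for overground running with a 1000 Hz
#' force plate and 44.1 kHz microphones.
#'
#' @param force_lowpass_hz Cut-off of the 4th-order Butterworth low-pass
#'   applied to the raw vertical force (Hz).
#' @param stance_threshold_n Vertical force threshold defining stance:
#'   samples strictly above this value (N) belong to a stance phase.
#' @param min_stance_s Minimal duration for an accepted stance interval (s);
#'   shorter supra-threshold runs are treated as bounces/noise and dropped.
#' @param sound_resample_hz Common sampling rate sound is resampled to
#'   before envelope extraction (Hz).
#' @param band_edges_hz Two-element band-pass range (Hz) applied with a
#'   1st-order Butterworth. An upper edge at or above Nyquist of
#'   `sound_resample_hz` degenerates to a pure high-pass.
#' @param envelope_lowpass_hz Cut-off of the envelope low-pass applied after
#'   full-wave rectification (Hz).
#' @param envelope_lowpass_order Order of the envelope low-pass Butterworth.
#' @param fca_rearfoot_deg Foot contact angle at or above which a step is a
#'   rearfoot strike (degrees).
#' @param fca_forefoot_deg Foot contact angle at or below which a step is a
#'   forefoot strike (degrees).
#' @param decibel_conversion If `TRUE`, convert sound amplitude to a dB-like
#'   log scale before envelope extraction. Off by default: envelopes are
#'   computed on linear amplitude.
#'
#' @return A list of class `processing_config`.
#' @export
#' @examples
#' cfg <- processing_config()
#' cfg$force_lowpass_hz
processing_config <- function(force_lowpass_hz = 60,
                              stance_threshold_n = 20,
                              min_stance_s = 0.08,
                              sound_resample_hz = 20000,
                              band_edges_hz = c(5, 20000),
                              envelope_lowpass_hz = 200,
                              envelope_lowpass_order = 4,
                              fca_rearfoot_deg = 8,
                              fca_forefoot_deg = -1.6,
                              decibel_conversion = FALSE) {
  stopifnot(force_lowpass_hz > 0, stance_threshold_n > 0,
            min_stance_s >= 0, sound_resample_hz > 0,
            length(band_edges_hz) == 2, all(band_edges_hz > 0),
            band_edges_hz[1] < band_edges_hz[2],
            envelope_lowpass_hz > 0, envelope_lowpass_order >= 1,
            fca_forefoot_deg < fca_rearfoot_deg)
  structure(list(force_lowpass_hz = force_lowpass_hz,
                 stance_threshold_n = stance_threshold_n,
                 min_stance_s = min_stance_s,
                 sound_resample_hz = sound_resample_hz,
                 band_edges_hz = band_edges_hz,
                 envelope_lowpass_hz = envelope_lowpass_hz,
                 envelope_lowpass_order = envelope_lowpass_order,
                 fca_rearfoot_deg = fca_rearfoot_deg,
                 fca_forefoot_deg = fca_forefoot_deg,
                 decibel_conversion = decibel_conversion),
            class = "processing_config")
}
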