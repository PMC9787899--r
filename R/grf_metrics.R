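# Biomechanical variables extracted from body-weight-normalized vGRF stance
# curves: impact/active peaks, deflection fallback, loading rates, vertical
# impulse and foot-strike classification from curve shape.

check_normalized <- function(curve) {
  stopifnot(inherits(curve, "stance_curve"))
  if (!curve$normalized)
    stop("curve must be body-weight normalized (xBW)", call. = FALSE)
  invisible(curve)
}

# Indices of strict local maxima (greater than both neighbours).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# Topographic prominence of a local maximum: height above the higher of the
# two deepest minima separating it from higher terrain on each side.
peak_prominence <- function(v, i) {
  left <- v[seq_len(i - 1)]
  higher_l <- which(left > v[i])
  base_l <- if (length(higher_l)) min(v[(max(higher_l) + 1):(i - 1)]) else min(left)
  right <- v[(i + 1):length(v)]
  higher_r <- which(right > v[i])
  base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else min(right)
  v[i] - max(base_l, base_r)
}

#' Find the impact peak of a vGRF stance curve
#'
#' The impact peak, when identifiable, is the local maximum of the vGRF
#' within the first 50 ms after initial contact. Returns `NULL` when no
#' (sufficiently prominent) local maximum exists in the window.
#'
#' @param curve A normalized `stance_curve` (xBW).
#' @param window_s Search window after initial contact (default 0.050 s).
#' @param min_prominence Minimal topographic prominence (xBW) for a local
#'   maximum to count; 0 accepts any strict local maximum.
#' @return `NULL`, or a list with `value_xbw`, `time_s` and `time_pct`
#'   (percent of stance).
#' @export
find_impact_peak <- function(curve, window_s = 0.050, min_prominence = 0) {
  check_normalized(curve)
  if (stance_duration(curve) <= window_s)
    stop("stance shorter than the impact-peak window", call. = FALSE)
  cand <- local_maxima(curve$values)
  cand <- cand[curve$times[cand] <= window_s]
  if (min_prominence > 0 && length(cand))
    cand <- cand[vapply(cand, function(i)
      peak_prominence(curve$values, i), 0) >= min_prominence]
  if (!length(cand)) return(NULL)
  i <- cand[which.max(curve$values[cand])]
  list(value_xbw = curve$values[i], time_s = curve$times[i],
       time_pct = 100 * curve$times[i] / stance_duration(curve))
}

#' Locate the onset of curve deflection (impact-peak surrogate)
#'
#' When no impact peak exists, the impact location is estimated from the
#' curve's geometry: for each candidate time t between 10 and 100 ms
#' (1 ms steps), two sequential 15 ms chords are formed in a scaled
#' (time, force) plane — u from (t-15 ms) to t, v from t to (t+15 ms) —
#' and the signed turning angle from u to v is computed. The t with the
#' most negative angle (sharpest downward deflection) is returned.
#'
#' The angle values depend on the plane's aspect ratio; time is scaled by
#' `time_scale` (default 100, i.e. seconds-times-100 against xBW) which
#' makes 15 ms chords and typical force changes commensurate. The argmin is
#' insensitive to this choice for single-kink curves.
#'
#' @param curve A normalized `stance_curve` longer than 115 ms.
#' @param vector_s Chord length (default 0.015 s).
#' @param from_s,to_s Candidate window (defaults 0.010 and 0.100 s).
#' @param step_s Candidate spacing (default 0.001 s).
#' @param time_scale Multiplier applied to time (s) before angle
#'   computation.
#' @return A list with `time_s`, `time_pct`, `value_xbw` and `angle_rad`,
#'   or `NULL` (with a warning) when no negative deflection exists.
#' @export
find_deflection_point <- function(curve, vector_s = 0.015, from_s = 0.010,
                                  to_s = 0.100, step_s = 0.001,
                                  time_scale = 100) {
  check_normalized(curve)
  if (stance_duration(curve) <= to_s + vector_s)
    stop("stance too short for the deflection scan", call. = FALSE)
  # both chords must lie inside the record: candidates below the chord
  # length would need samples before initial contact
  cand <- seq(max(from_s, vector_s), to_s, by = step_s)
  f0 <- interp_curve(curve$times, curve$values, cand - vector_s)
  f1 <- interp_curve(curve$times, curve$values, cand)
  f2 <- interp_curve(curve$times, curve$values, cand + vector_s)
  ux <- time_scale * vector_s; uy <- f1 - f0; vy <- f2 - f1
  ang <- atan2(ux * vy - uy * ux, ux * ux + uy * vy)   # signed turn u -> v
  if (all(ang >= -1e-12)) {
    warning("no downward deflection found; curve has no impact-like event")
    return(NULL)
  }
  i <- which.min(ang)
  list(time_s = cand[i],
       time_pct = 100 * cand[i] / stance_duration(curve),
       value_xbw = f1[i], angle_rad = ang[i])
}

#' Active peak of a vGRF stance curve
#'
#' Global maximum of the curve; ties resolve to the earliest time.
#'
#' @param curve A normalized `stance_curve`.
#' @return A list with `value_xbw`, `time_s` and `time_pct`.
#' @export
active_peak <- function(curve) {
  check_normalized(curve)
  i <- which.max(curve$values)   # first index on ties
  list(value_xbw = curve$values[i], time_s = curve$times[i],
       time_pct = 100 * curve$times[i] / stance_duration(curve))
}

#' Vertical loading rates LR-1, LR-2, LR-3
#'
#' Three conventions for the slope of the rising vGRF, all in xBW/s:
#' \itemize{
#'   \item LR-1: average slope from initial contact to the impact peak
#'     (secant slope over \[0, t_ip\]).
#'   \item LR-2: slope of the line between the first crossings of 20\% and
#'     80\% of the impact-peak force (crossing times linearly
#'     interpolated); `NA` when either crossing does not exist before
#'     t_ip.
#'   \item LR-3: slope of the force over the first 50 ms (least-squares by
#'     default, endpoint secant via `lr3_method = "secant"`).
#' }
#' When the curve has no true impact peak, the deflection-point time from
#' [find_deflection_point()] is used as t_ip.
#'
#' @param curve A normalized `stance_curve`.
#' @param impact Result of [find_impact_peak()] or
#'   [find_deflection_point()] (any list with `time_s`); found
#'   automatically when `NULL`.
#' @param lr3_window_s Window for LR-3 (default 0.050 s).
#' @param lr3_method `"least_squares"` (default) or `"secant"`.
#' @return A list with `lr1_xbw_s`, `lr2_xbw_s`, `lr3_xbw_s`.
#' @export
loading_rates <- function(curve, impact = NULL, lr3_window_s = 0.050,
                          lr3_method = c("least_squares", "secant")) {
  check_normalized(curve)
  lr3_method <- match.arg(lr3_method)
  if (is.null(impact)) {
    impact <- find_impact_peak(curve)
    if (is.null(impact)) impact <- find_deflection_point(curve)
    if (is.null(impact)) stop("no impact location available", call. = FALSE)
  }
  t_ip <- impact$time_s
  if (!is.finite(t_ip) || t_ip <= 0)
    stop("impact time must be positive", call. = FALSE)
  f_ip <- interp_curve(curve$times, curve$values, t_ip)
  f0 <- curve$values[1]
  lr1 <- (f_ip - f0) / t_ip

  rising_t <- c(curve$times[curve$times < t_ip], t_ip)
  rising_f <- c(curve$values[curve$times < t_ip], f_ip)
  first_crossing <- function(level) {
    above <- which(rising_f >= level)
    if (!length(above)) return(NA_real_)
    i <- above[1]
    if (i == 1L) return(rising_t[1])
    t0 <- rising_t[i - 1]; t1 <- rising_t[i]
    y0 <- rising_f[i - 1]; y1 <- rising_f[i]
    t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  t20 <- first_crossing(0.2 * f_ip)
  t80 <- first_crossing(0.8 * f_ip)
  lr2 <- if (is.na(t20) || is.na(t80) || t80 <= t20) NA_real_ else
    (0.8 - 0.2) * f_ip / (t80 - t20)

  w <- curve$times <= lr3_window_s
  lr3 <- if (lr3_method == "least_squares") {
    if (sum(w) < 2) NA_real_ else
      unname(coef(lm(curve$values[w] ~ curve$times[w]))[2])
  } else {
    fe <- interp_curve(curve$times, curve$values, lr3_window_s)
    (fe - f0) / lr3_window_s
  }
  list(lr1_xbw_s = lr1, lr2_xbw_s = lr2, lr3_xbw_s = lr3)
}

#' Vertical impulse (area under the vGRF curve)
#'
#' Trapezoidal integral of the normalized force over stance. Two unit
#' conventions are reported: `xbw_s` integrates over seconds (xBW·s) and
#' `xbw_pct` integrates over percent-of-stance units
#' (`= xbw_s * 100 / stance_time`).
#'
#' @param curve A normalized `stance_curve`.
#' @return A list with `xbw_s` and `xbw_pct`.
#' @export
vertical_impulse <- function(curve) {
  check_normalized(curve)
  dt <- diff(curve$times)
  area <- sum(dt * (head(curve$values, -1) + tail(curve$values, -1)) / 2)
  list(xbw_s = area, xbw_pct = area * 100 / stance_duration(curve))
}

#' Classify running style from the vGRF curve
#'
#' Curves with a prominent impact peak are rearfoot strikes; curves without
#' one are forefoot/midfoot strikes (the two are merged: curve shape cannot
#' separate them).
#'
#' @param curve A normalized `stance_curve`.
#' @param min_prominence Prominence (xBW) a local maximum needs to count as
#'   a "prominent" impact peak (default 0.05).
#' @return `"rearfoot"` or `"forefoot_midfoot"`.
#' @export
classify_style_from_vgrf <- function(curve, min_prominence = 0.05) {
  ip <- find_impact_peak(curve, min_prominence = min_prominence)
  if (is.null(ip)) "forefoot_midfoot" else "rearfoot"
}

#' Fraction of correctly predicted style labels
#'
#' @param real_labels,pred_labels Equal-length character vectors.
#' @return Fraction in \[0, 1\] of positions where the labels agree.
#' @export
style_accuracy <- function(real_labels, pred_labels) {
  if (length(real_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (!length(real_labels)) return(NA_real_)
  mean(real_labels == pred_labels)
}

#' Extract the full set of biomechanical variables from one stance curve
#'
#' Combines peak detection (with deflection fallback), loading rates,
#' vertical impulse and style classification into one row of results.
#'
#' @param curve A normalized `stance_curve`.
#' @param min_prominence Prominence rule for the style decision.
#' @return A one-row data.frame with columns `impact_peak_xbw`,
#'   `t_impact_pct`, `impact_peak_found`, `active_peak_xbw`,
#'   `t_active_pct`, `lr1_xbw_s`, `lr2_xbw_s`, `lr3_xbw_s`,
#'   `impulse_xbw_s`, `impulse_xbw_pct`, `style_vgrf`.
#' @export
extract_biomech_variables <- function(curve, min_prominence = 0.05) {
  ip <- find_impact_peak(curve)
  found <- !is.null(ip)
  loc <- ip
  if (!found)
    loc <- suppressWarnings(find_deflection_point(curve))
  lr <- if (is.null(loc)) list(lr1_xbw_s = NA_real_, lr2_xbw_s = NA_real_,
                               lr3_xbw_s = NA_real_)
        else loading_rates(curve, impact = loc)
  ap <- active_peak(curve)
  imp <- vertical_impulse(curve)
  data.frame(
    impact_peak_xbw = if (is.null(loc)) NA_real_ else loc$value_xbw,
    t_impact_pct = if (is.null(loc)) NA_real_ else loc$time_pct,
    impact_peak_found = found,
    active_peak_xbw = ap$value_xbw, t_active_pct = ap$time_pct,
    lr1_xbw_s = lr$lr1_xbw_s, lr2_xbw_s = lr$lr2_xbw_s,
    lr3_xbw_s = lr$lr3_xbw_s,
    impulse_xbw_s = imp$xbw_s, impulse_xbw_pct = imp$xbw_pct,
    style_vgrf = classify_style_from_vgrf(curve, min_prominence))
}
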