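# Curve-similarity metrics and the group statistics used to compare real
# and predicted vGRF outputs across microphone combinations.

#' Similarity between a real and a predicted curve
#'
#' Pearson correlation, absolute RMSE (xBW) and relative RMSE. rRMSE is
#' normalized by the range (max - min) of the \emph{real} curve by default
#' (`normalizer = "range"`), or by its peak (`"peak"`), and expressed in
#' percent.
#'
#' @param real,pred `stance_curve`s (or plain numeric vectors) on the same
#'   grid, at least 3 points.
#' @param normalizer `"range"` (default) or `"peak"`.
#' @return A list with `pearson_r`, `rmse_xbw`, `rrmse_pct`. `pearson_r` is
#'   `NA` when either series has zero variance.
#' @export
#' @examples
#' a <- sin(seq(0, pi, length.out = 50))
#' curve_similarity(a, a + 0.1)  # r = 1, rmse = 0.1
curve_similarity <- function(real, pred, normalizer = c("range", "peak")) {
  normalizer <- match.arg(normalizer)
  x <- if (inherits(real, "stance_curve")) real$values else as.numeric(real)
  y <- if (inherits(pred, "stance_curve")) pred$values else as.numeric(pred)
  if (length(x) != length(y) || length(x) < 3)
    stop("curves must share a grid of at least 3 points", call. = FALSE)
  r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  rmse <- sqrt(mean((x - y)^2))
  denom <- if (normalizer == "range") diff(range(x)) else max(x)
  rrmse <- if (denom <= 0) NA_real_ else 100 * rmse / denom
  list(pearson_r = r, rmse_xbw = rmse, rrmse_pct = rrmse)
}

#' Paired comparison of real vs. predicted variables
#'
#' Paired Student t-test (two-sided, n-1 df) plus Cohen's d. The default d
#' uses the pooled SD of the two conditions,
#' `mean(x - y) / sqrt((var(x) + var(y)) / 2)`; set
#' `d_method = "difference"` for the difference-SD variant
#' `mean(x - y) / sd(x - y)`.
#'
#' @param real_vals,pred_vals Equal-length numeric vectors, n >= 2.
#' @param d_method `"pooled"` (default) or `"difference"`.
#' @return A list with `t`, `p`, `cohens_d`, `df` and `degenerate` (TRUE
#'   when the differences have zero variance; then `t = 0`, `p = 1`).
#' @export
paired_comparison <- function(real_vals, pred_vals,
                              d_method = c("pooled", "difference")) {
  d_method <- match.arg(d_method)
  stopifnot(length(real_vals) == length(pred_vals), length(real_vals) >= 2)
  diffs <- real_vals - pred_vals
  if (sd(diffs) == 0) {
    return(list(t = 0, p = 1, cohens_d = 0,
                df = length(diffs) - 1L, degenerate = TRUE))
  }
  tt <- t.test(real_vals, pred_vals, paired = TRUE)
  denom <- if (d_method == "pooled")
    sqrt((var(real_vals) + var(pred_vals)) / 2) else sd(diffs)
  list(t = unname(tt$statistic), p = tt$p.value,
       cohens_d = mean(diffs) / denom,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Tests for a condition effect (e.g. microphone combination) with subjects
#' as the repeated factor, via `stats::aov` with an `Error(subject)`
#' stratum. No sphericity correction is applied.
#'
#' @param values Numeric matrix, subjects in rows, conditions in columns;
#'   complete (no missing cells), >= 2 subjects and >= 2 conditions.
#' @return A list with `F`, `p`, `df1` (k-1) and `df2` ((k-1)(n-1)).
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop(">= 2 subjects and conditions required",
                           call. = FALSE)
  if (anyNA(values)) stop("missing cells are not supported", call. = FALSE)
  d <- data.frame(value = as.numeric(values),
                  subject = factor(rep(seq_len(n), times = k)),
                  condition = factor(rep(seq_len(k), each = n)))
  fit <- aov(value ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  pv <- tab["condition", "Pr(>F)"]
  # a condition sum of squares at floating-point noise level is no effect
  ss_cond <- tab["condition", "Sum Sq"]
  ss_tot <- sum((d$value - mean(d$value))^2)
  if (!is.finite(Fv) || ss_cond <= 1e-12 * max(ss_tot, .Machine$double.xmin)) {
    Fv <- 0; pv <- 1
  }
  list(F = unname(Fv), p = unname(if (is.finite(pv)) pv else 1),
       df1 = k - 1L, df2 = (k - 1L) * (n - 1L))
}

#' Classify the strength of a Pearson correlation
#'
#' Low for 0.1 < r <= 0.3, moderate for 0.4 < r <= 0.7, strong for r > 0.7.
#' Values in the gaps of this taxonomy (r <= 0.1, 0.3 < r <= 0.4) return
#' `"unclassified"` rather than a guess.
#'
#' @param r Finite correlation value(s).
#' @return Character vector in
#'   `{"low", "moderate", "strong", "unclassified"}`.
#' @export
classify_correlation <- function(r) {
  if (!all(is.finite(r))) stop("r must be finite", call. = FALSE)
  ifelse(r > 0.7, "strong",
         ifelse(r > 0.4, "moderate",
                ifelse(r > 0.3, "unclassified",
                       ifelse(r > 0.1, "low", "unclassified"))))
}

#' Normal-approximation confidence interval of a mean
#'
#' `mean +/- z * sd / sqrt(n)` with the standard normal quantile.
#'
#' @param mean,sd Sample mean and SD (`sd >= 0`).
#' @param n Sample size, >= 2.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
#' @examples
#' round(ci_of_mean(77, 27, 37), 1)  # c(68.3, 85.7)
ci_of_mean <- function(mean, sd, n, level = 0.95) {
  stopifnot(sd >= 0, level > 0, level < 1)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  c(mean - z * sd / sqrt(n), mean + z * sd / sqrt(n))
}
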