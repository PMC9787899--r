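---
title: "From footstep sounds to ground reaction forces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From footstep sounds to ground reaction forces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepforce)
```

## The problem

During running, the vertical ground reaction force (vGRF) over one stance
phase is a two-feature curve: an optional early *impact peak* (within
~50 ms of initial contact, typical of rearfoot strikers) and a mid-stance
*active peak* near 42% of stance. Measuring it requires a force plate.
Footstep sounds are a cheap, wearable proxy: the louder and sharper the
footstep, the higher the instantaneous impact loading. `stepforce`
reconstructs the vGRF curve from the linear envelopes of footstep sounds
recorded by up to four microphones around the point of contact, and then
extracts the standard kinetic variables from the reconstruction.

This vignette explains the model, its assumptions, the tunable parameters,
the synthetic data the package validates itself on, and the design choices
made where the method leaves details open.

## Signal conditioning

Force signals (Newtons, nominally 1000 Hz) are low-pass filtered with a
4th-order Butterworth at 60 Hz. Stance phases are maximal runs of samples
with force *strictly above* 20 N; runs shorter than 80 ms are discarded as
bounces (the method defines stance by the 20 N rule but is silent on a
minimum duration — 80 ms is far below any physiological stance and only
removes noise). Curves are then normalized to body weight (xBW).

Sound channels (linear amplitude, nominally 44.1 kHz) are resampled to
20 kHz with polyphase FIR anti-aliasing, band-pass filtered with a
1st-order Butterworth over 5 Hz – 20 kHz, full-wave rectified and low-pass
filtered at 200 Hz to form the linear envelope. Two details are worth
flagging:

* With a 20 kHz sampling rate the nominal 20 kHz upper band edge sits at
  Nyquist, so the band-pass degenerates to a pure 5 Hz high-pass. The
  implementation applies exactly that and says so in a message.
* The envelope low-pass order is not prescribed anywhere; a 4th-order
  Butterworth is used (common biomechanical practice) and is configurable
  (`envelope_lowpass_order`).

All filtering is zero-phase (forward–backward with odd-reflection padding),
so filter lag never shifts stance events or peak timings. Envelopes are
computed on linear amplitude; a decibel-style conversion is available as a
config switch (`decibel_conversion`) but off by default, since the envelope
chain is defined on amplitude and the predictor is insensitive to
monotone per-channel rescaling after standardization.

Envelopes are cut into stances using the force-derived events, assuming
both streams share a start trigger (synchronized acquisition).

## Curve representation

Each stance-aligned curve is reduced to a truncated Fourier series with
`K = 15` harmonics plus a constant (31 real coefficients), fitted by least
squares on the curve's own time grid and carried together with the stance
duration `T`; the coefficients describe shape on normalized time, and `T`
re-enters as a scalar predictor. Fifteen harmonics resolve features down to
about 1/15 of stance (~17 ms of a 250 ms stance), enough for impact peaks;
six harmonics — adequate for smooth kinematic curves — are not. "15 terms"
could alternatively be read as 15 total coefficients (7 harmonics); that
reading is available by passing `K = 7`, but 15 harmonics is the default
because capturing the impact peak is the stated reason for the larger
basis. Least squares (rather than FFT bin extraction) keeps the fit valid
on non-uniform or cropped grids; the two coincide on uniform grids.

The flat coefficient layout is `(a0, a1..aK, b1..bK)` — an arbitrary but
fixed convention asserted by round-trip tests.

## Conditional prediction

For a trial and a microphone combination, the predictor vector stacks the
member microphones' 31 envelope coefficients each, plus body mass (kg),
running speed (m/s) and stance time (s); the target is the 31 vGRF
coefficients. Over the training trials the joint vector is standardized
per dimension (variance floor 1e-12, so constant dimensions are inert) and
decomposed by PCA; components are kept up to 99% explained variance. The
implied joint Gaussian has covariance `B Λ Bᵀ + λI` with ridge
`λ = 1e-8`.

Prediction maximizes the likelihood of the target coefficients with the
predictor coordinates fixed — an equality-constrained quadratic program.
For a Gaussian this QP has the closed-form solution
`ŷ = μ_y + Σ_yx Σ_xx⁻¹ (x − μ_x)`, and the implementation uses the
closed form; the test suite separately minimizes the Mahalanobis quadratic
form numerically and checks agreement to 1e-6, so the QP formulation and
the conditional mean are verified to be the same thing rather than assumed.

Two open design points and how they are resolved:

* *Subspace behaviour.* Whether prediction should be confined to the
  retained principal subspace or use the full sample covariance is
  ambiguous. Both are implemented (`subspace = "retained"` / `"full"`);
  the default is the retained subspace with component-variance weighting,
  which is the better-conditioned choice when trials are fewer than
  dimensions.
* *Within-subject correlation.* Trials are treated as independent; no
  subject-level random effect enters the model. The leave-one-subject-out
  protocol (below) is what protects the evaluation from this
  simplification.

Validation is leave-one-subject-out: for each subject, the model is fitted
on all other subjects' trials and every held-out trial is predicted. A
dedicated invariance test perturbs a held-out subject's vGRF coefficients
and asserts bit-identical predictions — the strongest possible statement
that no target information leaks. Predicted curves are evaluated on a
101-point grid (0–100% stance, the conventional normalization) using the
trial's measured stance time; estimating stance time from sound alone is
out of scope.

## Biomechanical variables

All detectors operate on body-weight-normalized curves:

* **Impact peak** — largest strict local maximum within 50 ms of initial
  contact; absent if the curve only rises there.
* **Deflection point** — when no impact peak exists, the impact location
  is estimated geometrically: for candidate times at 1 ms steps, two
  sequential 15 ms chords are formed in a scaled (time, force) plane and
  the candidate with the most negative turning angle (sharpest downward
  deflection) is selected. The scan window is nominally 10–100 ms, but a
  15 ms chord reaching before initial contact is undefined, so candidates
  start at 15 ms. The angle's magnitude depends on the plane's aspect
  ratio (time is scaled ×100 against xBW by default, making the two axes
  commensurate); the argmin location does not, for single-kink curves —
  which is what the locality tests assert.
* **Active peak** — global maximum, earliest sample on ties.
* **Loading rates** (xBW/s): LR-1 is the secant slope from initial contact
  to the impact location; LR-2 the slope between the first crossings of
  20% and 80% of the impact-peak force (crossings linearly interpolated;
  reported missing when they do not exist); LR-3 the least-squares slope
  over the first 50 ms (an endpoint-secant variant is available — least
  squares is the default because it is robust to ripple in reconstructed
  curves). On any affine curve all three coincide exactly, a degeneracy
  the tests exploit.
* **Vertical impulse** — trapezoidal area under the curve. Reported in
  both xBW·s and percent-stance units (`xbw_s × 100 / T`), because the
  field is inconsistent about the convention: a group mean of ~0.25 xBW·s
  corresponds to ~100 in percent-stance units, and published tables
  labelled "xBW/s" with magnitudes near 100 are only consistent with the
  latter. Neither is presented as the single truth.
* **Foot strike from curve shape** — rearfoot iff a *prominent* impact
  peak exists. Prominence is never quantified in the literature this
  follows; the package requires topographic prominence ≥ 0.05 xBW
  (configurable), large enough to ignore Fourier ripple in reconstructed
  curves and small enough to keep genuine impact peaks.

Foot contact angle (FCA), when available from motion capture, classifies
strike style independently: rearfoot at ≥ 8°, forefoot at ≤ −1.6°, midfoot
between — closed boundaries exactly as printed in the convention this
follows.

## Statistics

Curve agreement is summarized by Pearson r, RMSE (xBW), and relative RMSE.
rRMSE is not a standardized quantity; here it is RMSE divided by the
*range of the real curve*, in percent (peak-normalization is available via
`normalizer = "peak"`). Real-vs-predicted variables are compared with
paired t-tests and Cohen's d; the default d divides by the pooled SD of
the two conditions rather than the SD of differences — the variant
consistent with published effect sizes for this design — with the
difference-SD variant available. Combination effects use one-way
repeated-measures ANOVA (no sphericity correction; none is conventional
here), and `F = t²` for two conditions is verified by test. Confidence
intervals of means use the normal quantile (`mean ± 1.96·sd/√n`), which is
what published 95% CIs for this design reproduce. Correlation strengths
are bucketed as low (0.1 < r ≤ 0.3), moderate (0.4 < r ≤ 0.7), strong
(r > 0.7); values in the taxonomy's gaps return `"unclassified"` rather
than a guess.

## The synthetic cohort

No suitable public dataset pairs footstep audio with force-plate curves,
so the package validates itself on synthetic cohorts with known ground
truth. The generator's defaults emulate the study conditions this method
targets: 37 runners, 48 ± 8 footsteps each, 78% of subjects rearfoot
strikers, body mass 77 ± 11 kg, speed 2.75 ± 0.33 m/s, stance time
250 ± 20 ms, impact peak 1.51 ± 0.20 xBW at 13.51 ± 0.71% of stance,
active peak 2.32 ± 0.17 xBW at 42.33 ± 2.41%. Step-level foot-contact
angles are drawn to match 70/21/9% rearfoot/midfoot/forefoot fractions and
respect the FCA thresholds.

Curves are sums of a broad support bump and Gaussian components (impact
width 2.5% stance — narrow enough to be a distinct peak, wide enough to
survive the 15-harmonic representation; active width 15%), tapered to
exactly zero at 0 and 100% stance and held above ~0.025 xBW (20 N for a
typical runner) over the interior so threshold segmentation recovers the
full window. Because a bump on a sloped background attains its maximum
slightly off-center, the generator shifts the bump centers iteratively
until the realized local maxima land exactly on the drawn peak values and
times; draws whose impact and active peaks would merge are rejected and
redrawn. This is what makes *detector closure* a meaningful test: on
noise-free curves the impact-peak detector must recover the drawn
magnitude within 1% and timing within 0.5% of stance.

Envelopes follow a known generative link: each microphone's envelope is
`gain × (w1 · smooth(|dF/dt|) + w2 · F)` with a causal 10 ms exponential
decay kernel — louder sound for sharper loading — times per-sample
log-normal noise (SD 0.10). Subjects carry log-normal gain multipliers
(SD 0.15) on every microphone, a subject-level random effect that makes
leave-one-subject-out genuinely harder than trial-level splits. The
weights (w1 = 0.01 s, w2 = 0.3) put the derivative and direct-force terms
at comparable magnitudes for typical curves.

What the generator does *not* emulate: room acoustics, surface and shoe
material, stick-slip transients, asymmetric or multi-modal envelope
shapes, and any nonlinearity between loading and loudness. Passing the
LOSO acceptance check (median per-curve r ≥ 0.95, median rRMSE ≤ 15% for
Mic1234 at the defaults) therefore demonstrates that the pipeline is
*correct and leak-free*, not that real footstep sounds carry this much
information; on laboratory data the same pipeline is expected to score
lower, and synthetic results should be read as upper bounds.

Raw-data emulation: `simulate_to_disk()` writes force CSVs (1000 Hz) and
44.1 kHz WAV files whose content is a 1 kHz carrier amplitude-modulated by
the generated envelope. Full-wave rectification of a modulated sine
recovers the envelope times 2/π — a known scale factor that the
standardization in the predictor absorbs, and which the end-to-end tests
rely on.

## Numerical choices

* Fourier fits solve a QR-decomposed least-squares system; at least
  `2K + 1` samples are required, and rank deficiency is an error rather
  than a silent pseudo-inverse.
* Standardization floors per-dimension variance at 1e-12 so constant
  dimensions (e.g. a cohort at one fixed speed) cannot produce division
  blow-ups.
* The conditional solve adds ridge 1e-8 to the implied covariance; with
  the retained-subspace default this also makes the predictor-block solve
  well-posed when components are few.
* Problem sizes in the shipped tests: unit tests run on 6–10 subject
  cohorts; the LOSO acceptance check uses the full 37-subject, ~1800-trial
  cohort; detector closure uses 500 draws; the end-to-end byte-determinism
  check uses a 4-subject raw-audio round trip.
* Deterministic output formatting (`%.9g`) makes repeated experiments
  byte-identical, which the determinism tests assert literally.

## Known limitations

* The predictor is linear-Gaussian; systematically nonlinear
  sound-to-force relationships would be attenuated toward the mean (the
  worked example in the README shows the characteristic peak smoothing).
* Stance time is taken from the force-derived segmentation; a sound-only
  deployment would need a stance-time estimator, which is out of scope.
* The deflection-point surrogate on curves without any impact-like event
  returns the strongest downward turn in its window, which for a smooth
  single-bump curve sits near the rise to the active peak — a property of
  the method, inherited deliberately.
* Midfoot and forefoot strikes are indistinguishable from curve shape and
  are merged into one class; only FCA separates them.
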