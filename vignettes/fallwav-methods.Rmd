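---
title: "Wavelet-matched fall detection: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-matched fall detection: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwav)
```

## The detection problem

A body-worn tri-axial accelerometer at the lower back records, during a
fall, a stereotyped sequence in the acceleration sum vector
$SV(t) = \sqrt{a_x^2 + a_y^2 + a_z^2}$ (units of g): rest near 1 g, a dip
toward free fall (the *lower peak value*, LPV), a sharp impact peak (the
*upper peak value*, UPV), damped ringing, and rest again. Classic
detectors threshold UPV or LPV directly; they are cheap but blind to the
*shape* of the event, so any energetic daily activity (sitting down hard,
a stumble, a knock against a table) with a comparable peak fires them too.

`fallwav` instead treats the averaged fall morphology as a template. The
fitting function `fall_wavelet()` averages the 2-second, peak-centered SV
windows of the training falls into a prototype pattern and converts it
into an admissible mother wavelet $\Psi_{\mathrm{fall}}$ on $[0,1]$. A new
recording is scored by the maximum continuous-wavelet-transform similarity
of any candidate impact window to this prototype; the score responds to
the dip–spike–ring *sequence*, not just to peak height.

Assumptions worth making explicit:

* uniform sampling at a known rate (100 Hz by default) and accelerations
  already in g — the package performs no resampling and no unit
  conversion;
* one event of interest per recording suffices for evaluation (recordings
  are scored by their single best window, which matches the one-minute,
  impact-centered recording protocol the evaluation emulates);
* falls in the training and test sets share an impact morphology; the
  method is explicitly a template matcher and inherits the template's
  population specificity;
* no pre-filtering of SV is applied anywhere: the averaged prototype is
  used as recorded, and candidate windows are compared raw.

## Fitting the prototype

For each training fall the global SV maximum (first occurrence on ties —
a deterministic tie-break) centers a window of $2$ s, i.e. $2 F_s$
samples, indexed half-open so the peak sits exactly at offset $F_s$.
Falls whose peak lies within one second of a recording edge are excluded
with a warning rather than padded: padding would fabricate data, and
peak-centered recordings never trigger the case. The per-sample mean of
the windows is the fall pattern; the per-sample standard deviation is kept
for plotting.

The conversion to a mother wavelet enforces, in this order:

1. mean subtraction (any constant offset of the pattern is irrelevant);
2. an endpoint taper to zero over 2% of the grid on each side (a cosine
   ramp), so the wavelet is continuous when extended by zero outside
   $[0,1]$;
3. exact zero discrete integral, restored after the taper by subtracting a
   multiple of the taper profile (which keeps the endpoints at zero);
4. unit discrete L2 norm.

The grid has one point per pattern sample (200 at 100 Hz, $\Delta x =
1/199$): resampling would only add interpolation artifacts. A constant
pattern has no admissible wavelet and is rejected as degenerate.

**Conversion method.** Two conversions are provided. The default,
`method = "direct"`, uses the mean-subtracted pattern itself. The
alternative, `method = "polynomial"`, projects it onto polynomials of
degree `poly_degree` (default 6) by constrained least squares with the
zero-integral condition imposed exactly via the KKT system, on an
orthogonal-polynomial basis for numerical stability. The direct form is
the default because the prototype's discriminative content lives in its
narrow impact spike: a polynomial of degree $d$ cannot resolve features
narrower than roughly $1/d$ of the window, so with impacts of 0.05–0.15 s
inside a 2-s window a faithful polynomial would need degree of order
20–40, while a low-degree fit broadens the spike into a generic bump that
correlates as well with smooth everyday transients as with falls —
destroying precisely the shape sensitivity the method exists for.
Averaging across training falls already suppresses noise, so the direct
form gives up little smoothness in exchange for keeping the spike. The
polynomial option remains useful when an analytic, very smooth wavelet is
wanted and impacts are broad.

## The restricted CWT and its discretization

For a candidate window $w$ and the prototype $\Psi_{\mathrm{fall}}$
defined on $[0,1]$, the coefficient at integer scale $a$ (samples) and
translation $b$ is the discrete analogue of

$$C(a,b) \;=\; \frac{1}{\sqrt{a}} \int w(t)\,
\Psi_{\mathrm{fall}}\!\Big(\frac{t-b}{a}\Big)\, dt .$$

Since the prototype spans 2 s, a self-similar input matches at
$a = 2F_s$; the search is restricted to $a \in [1.5F_s,\, 2.5F_s]$.
Both the prototype and the candidate window are peak-centered, so the
match is expected near the window center: $b$ (the *center* of the
dilated wavelet's support $[b - a/2,\, b + a/2]$ within the window) is
restricted to $[0.5F_s,\, 1.5F_s]$, which also keeps the bulk of the
wavelet away from the window borders. Centering the translation on the
wavelet's support is what makes $b = F_s$ the aligned value for a
centered event; an alternative "support starts at $b$" convention would
put the aligned translation at 0, outside the search box, and make the
restriction meaningless.

Numerical choices, all deliberate and tested:

* **Riemann sum, $\Delta t = 1$ sample.** Feature values are only
  meaningful relative to one fixed convention; thresholds are in these
  units.
* **Linear interpolation** of the wavelet samples at $(t-b)/a + 1/2$,
  zero outside $[0,1]$; signal samples beyond the window count as zero.
* **Exact discrete admissibility per row.** Each sampled, truncated
  wavelet is re-centered to zero mean over the window. Without this, at
  scales whose support is cut by the window edge, the resting 1 g
  baseline leaks into the coefficients (the continuous zero-integral
  property does not survive truncation); with it, adding any constant to
  a window changes no coefficient at all.
* **Exact per-row energy normalization.** The default
  `cwt_norm = "inverse_sqrt_scale"` divides by the computed L2 norm of
  the sampled row — the discrete realization of $1/\sqrt{a}$, since
  $\|\Psi((\cdot-b)/a)\|_2 = \sqrt{a}$ for the unit-norm prototype. With
  unit energy at every scale, the Cauchy–Schwarz inequality pins the
  coefficient maximum of a self-similar input to the generating scale and
  translation; the tests verify recovery within ±2 samples. The
  alternative `"inverse_scale"` weights by $1/a$; it is retained as a
  convention option but systematically tilts the scale profile toward
  small scales (the profile goes as $\sqrt{a_0/a}$ times the shape
  correlation), so it is not the default.
* **Ties** in the maximum take the first grid point, scanning scales in
  increasing order and translations within each scale.

The grid is dense (101 scales × 101 translations at 100 Hz, steps of one
sample, configurable via `scale_step`/`translation_step`); scoring is a
single matrix product of the precomputed filter bank with the batch of
candidate windows, so no FFT machinery is needed at these sizes.

## From coefficients to a feature

`wavelet_feature()` scans SV in sample order (stride 1 by default — every
supra-threshold sample seeds a candidate; a larger `scan_stride` trades
fidelity for speed). A sample triggers when SV exceeds
`trigger_threshold_g` (default 1.5 g: low enough that no fall can be
missed, high enough to skip quiet signal). Candidate windows overrunning
the recording are skipped (`edge_policy = "reflect"` pads instead, for
callers who want edge events scored). The feature is the overall maximum
coefficient across candidates, clipped below at zero — an anti-correlated
best match carries no evidence *for* a fall — and exactly zero when
nothing triggers, which classifies quiet recordings as non-falls at any
positive threshold.

The baselines are `upv_feature()` (the SV maximum, in g) and
`lpv_feature()` (the SV minimum within 1 s before the global peak,
in g). One second covers the falling phase preceding an impact at normal
fall kinematics; the span is configurable (`lpv_search_s`). For ROC
purposes lower LPV is more fall-like, so LPV scores are ranked negated.

## Evaluation design

Because the prototype is learned from falls, all reported discrimination
is cross-validated: `evaluate_features()` makes a stratified k-fold split
(default 10 folds, both classes split proportionally, seeded and
reproducible), refits the wavelet on each training set's falls only, and
scores only held-out recordings. Fold ROCs (detection rule: score
strictly greater than threshold) are combined by vertical averaging:
sensitivities are sampled at fixed specificities from 0 to 1 in steps of
0.001 — along the threshold-ordered vertex path, linearly interpolated,
taking the achievable maximum where a specificity hosts a vertical run —
and averaged across folds per grid point. The averaged AUC uses the
trapezoid rule on this grid; per-fold AUCs are computed exactly from the
fold vertices and equal the Mann–Whitney statistic (with half-credit for
ties), which the tests assert.

The operating point maximizes the Youden index over the grid; ties prefer
the higher specificity (fewer false alarms at equal YI). Its threshold is
reported as the median across folds of the smallest per-fold threshold
reaching the chosen specificity. False alarms convert as
$(1-\mathrm{specificity}) \times n_{\mathrm{ADL}}$, divided by the
monitoring hours the ADLs represent.

Per-fold AUC and YI pairs are compared by an exact paired Wilcoxon
signed-rank test: zero differences dropped, mid-ranks for ties, and the
full null distribution of the rank sum computed over all $2^m$ sign
assignments (via the shift algorithm on doubled ranks, identical to
enumeration) for up to 25 nonzero differences, with a tie-corrected
normal approximation above. Two comparisons per metric (wavelet vs UPV,
wavelet vs LPV) are Bonferroni-corrected with $m = 2$, boundary
inclusive. Confidence intervals on AUC and max YI are
$\bar{x} \pm 1.96\, s/\sqrt{k}$ over the $k$ fold values — a documented
choice, not the only possible one; with 10 folds they are wide.

## What the simulator does and does not emulate

`simulate_dataset()` generates the study conditions the package is
evaluated under: one-minute recordings at 100 Hz; falls whose designed SV
rests at 1 g, dips to an LPV drawn from [0.2, 0.8] g over 0.2–0.4 s,
spikes to a UPV from [2, 6] g over 0.05–0.15 s near the recording
midpoint (±5 s jitter), rings down (3–8 Hz, 0.2–0.5 s damping constant)
and returns to rest; ADLs built from a gait-band sinusoid (1.5–2.5 Hz,
0.2–0.6 g) with occasional smooth Gaussian transients (Poisson rate
2/min, up to 2 g above baseline, 0.15–0.5 s wide) and accepted only if
they satisfy the active-period criterion, SV range > 1.01 g. Additive
Gaussian noise (SD 0.02 g) is applied to the designed SV, which is then
decomposed into three axes along a slowly drifting unit direction so the
root sum of squares reproduces the design exactly; an optional `clip_g`
saturates the axes, emulating a ±2 g sensor. These values are the
package's fixed reference conditions: peak magnitudes and phase durations
sit in the ranges reported for real-world falls of older adults, and ADL
transients are deliberately wider and smoother than impacts while
overlapping them in magnitude, so that peak-height features genuinely
confuse the two classes.

What the simulator does **not** capture: real sensor drift and
orientation changes, subject-specific gait spectra, fall types with weak
or double impacts, pre-impact activity, and the heavy-tailed variety of
real ADL transients (vehicle rides, stair descents). A passing test suite
therefore demonstrates internal correctness and the method's behavior
under its stated morphology assumptions — not clinical performance. The
difficulty of the synthetic task is controlled by the ADL transient
parameters; making spikes sharper and taller than the defaults will
erode the wavelet feature's margin over UPV, as it should.

Problem sizes were chosen so the full suite and the acceptance script run
comfortably on one CPU: the reference dataset is 29 falls and 200 ADLs
(29 matches the size of the real-world fall corpus this line of work
builds on; 200 ADLs keep specificity estimates stable at 20 per held-out
fold), and replicate counts (10 seeds) bound sampling variability without
hour-long runs.

## Known limitations

* The wavelet score is reported in implementation-defined units; absolute
  thresholds do not transfer across normalization conventions or
  discretizations, only across datasets scored by the same pipeline.
* Scale localization of spike-dominated prototypes is intrinsically weak
  (the coefficient ridge along the scale axis is nearly flat), which is
  why the energy normalization and exact row admissibility matter; with
  the `inverse_scale` option the argmax drifts to the small-scale edge of
  the search box.
* One prototype per training set: heterogeneous fall types are averaged
  into a single template. A multi-prototype dictionary is out of scope.
* Only the impact phase is modeled. Resting/recovery-phase evidence,
  which real deployments use to suppress false alarms, is deliberately
  not implemented.
* With 10 folds and few falls per fold, fold-level sensitivities are
  coarse (steps of 1/3 at 3 falls per fold), so averaged curves are
  step-like and CIs wide; this mirrors the small-sample reality of
  real-world fall corpora rather than a fixable defect.
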