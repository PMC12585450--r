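---
title: "Methods: modified vector coding, circular variability, and the mixed ANOVA layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modified vector coding, circular variability, and the mixed ANOVA layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordgait)
```

This vignette documents the models, conventions and numerical choices behind
`coordgait`, in the spirit of a methods section: what is computed, under
which assumptions, which decisions were genuinely open, and what the
synthetic-data generator does and does not emulate.

## The coordination model

Modified vector coding quantifies the instantaneous coordination of a joint
pair from the *first differences* of their angle trajectories over the
normalized gait cycle. With the distal joint (ankle) on the X axis of an
angle–angle plot and the proximal joint (hip or knee) on the Y axis, the
coupling angle at step $t$ of a 101-point cycle is

$$\theta_{coord}(t) = \operatorname{atan2}\!\big(\Delta\theta_{prox}(t),\,
\Delta\theta_{dist}(t)\big) \bmod 360^\circ .$$

The method is often printed as a one-argument arctangent of the increment
ratio followed by a modulo; that form cannot reach all four quadrants, so
this package uses the two-argument arctangent, which is the
quadrant-preserving realization the technique requires and what the
vector-coding literature computes in practice. Steps at which *neither*
joint moves have no direction; they are returned as missing and excluded
from circular statistics, because any imputed direction would be arbitrary.

Coupling angles live on a circle, so summaries use circular statistics. For
angles $\theta_i$ (radians), the mean resultant length is
$R = \lvert n^{-1} \sum_i e^{j\theta_i}\rvert$, the circular mean is the
argument of that complex mean, and the circular standard deviation is
$\sqrt{-2\ln R}\cdot 180/\pi$ degrees. $R = 1$ indicates perfect
concentration; $R \to 0$ indicates dispersion (or antipodal cancellation, in
which case the mean is undefined: the package flags `mean_deg = NA`,
`sd_deg = Inf` when $R < 10^{-12}$ rather than returning an arbitrary
direction).

Pattern classification follows the standard polar plot: left-closed,
right-open 45° bins, with 0–45°/180–225° in-phase proximal dominancy,
45–90°/225–270° in-phase distal, 90–135°/270–315° anti-phase distal, and
135–180°/315–360° anti-phase proximal. Boundary membership is measure-zero
in practice; the left-closed choice (45.0° is in-phase distal) is arbitrary
but fixed and tested. One geometric caveat is worth stating: with the
distal joint on X, an angle near 0° is a step almost entirely along the
distal axis, yet the conventional labels call 0–45° *proximal* dominancy.
The package follows the conventional published mapping verbatim — it is the
standard against which results in this literature are narrated — and the
`45–135/225–315 equals |Δprox| ≥ |Δdist|` geometry is separately covered by
a regression test so the tension stays visible rather than silently
"fixed".

### Two pathways: mean coordination versus variability

Subphase *coordination angles* are computed from the coupling series of the
**ensemble-mean** joint trajectories (pointwise arithmetic mean of the
angle channels across strides, legitimate because joint excursions are far
below 360°). Stride-to-stride *variability* is computed from **per-stride**
coupling series. These are distinct estimands and the package keeps them as
separate, separately-tested operations (`subphase_coordination()` on the
mean-trajectory coupling; `coordination_variability()` on per-stride
couplings).

"Variability per subphase" is ambiguous in the literature. The default
convention here (`method = "pointwise"`) computes, at each cycle step, the
across-stride circular SD (via $R$ over strides) and averages those SDs
within the window — the dominant convention in coupling-variability work.
The alternative (`method = "stride_mean"`) takes each stride's circular
mean over the window first and then the circular SD of those means; it is
smaller in general (within-window direction changes cancel) and is provided
behind an explicit switch rather than silently.

Pre/post changes of angular outcomes use the minimal signed circular
difference in $(-180°, 180°]$; for all realistic group means this
coincides with plain subtraction, and the wrap-around case is covered by a
brute-force test.

## Preprocessing conventions

* **Filtering.** Third-order low-pass Butterworth, applied forward and
  backward (zero phase), 10 Hz for kinematics and 50 Hz for the GRF. The
  zero-phase choice is the biomechanics norm — a one-way pass would shift
  gait events in time — at the cost of squaring the magnitude response
  (documented, and tested against the analytic response). Coefficients come
  from `signal::butter()`; the forward–backward pass itself is implemented
  with odd-reflection padding whose length is derived from the filter's
  pole radii so that start-up transients decay below $10^{-13}$: constants
  and linear trends pass through to within $10^{-9}$ over the *entire*
  output, which matters because subphase windows reach the record edges.
* **Gap filling** precedes filtering (the IIR filter cannot cross `NA`s).
  Gaps are filled by a local quintic: the unique degree-5 polynomial
  through the three nearest valid samples on each side, which reproduces
  degree-5 trajectories exactly. Gaps longer than 10 samples are refused —
  short occlusions are recoverable, long ones are not, and silently
  inventing data would be worse than failing. Leading/trailing gaps cannot
  be interpolated and are errors.
* **Event detection.** Initial contact is the first sample of a maximal
  run of GRF above 20 N lasting at least 50 ms; toe-off is the first sample
  after the run. The 50 ms debounce is not part of the classical threshold
  rule — clean laboratory force data do not need it — but synthetic or
  noisy data do, and 50 ms is far below any plausible sprint stance, so it
  cannot swallow a real phase. Runs already in progress at the first
  sample, and runs whose end coincides with the end of the record, have no
  observable contact/toe-off and are dropped.
* **Segmentation.** A cycle is contact-to-ipsilateral-contact (stride),
  since the subphase windows span both stance and swing of one limb. Event
  times on the 1000 Hz GRF grid are snapped to the nearest 120 Hz kinematic
  sample before interpolation: sub-frame alignment is below kinematic
  resolution, and snapping keeps the normalized grid reproducible. Channels
  are resampled to 101 points by natural cubic splines. Strides whose
  toe-off falls outside 40 ± 5% of the cycle are *flagged, not warped or
  dropped*: the 0–40% stance convention is treated as a fixed analysis
  window, and re-anchoring each stride would silently change the estimand.
* **Minimum strides.** Variability estimates require at least 8 strides;
  `require_min_strides()` enforces this as a hard gate.

## The inferential layer

Each outcome × pair × subphase enters a 2×2 mixed ANOVA (between: group;
within: time) via the classical split-plot decomposition — group tested
against subjects-within-groups, time and interaction against
time × subjects-within-groups. With a two-level within factor sphericity
holds trivially; no correction is applied. Subjects missing either time
point are excluded listwise and recorded; each exclusion drops the
within-stratum error df by one. The implementation is an explicit
sums-of-squares computation, tested to $10^{-8}$ against a brute-force
mean-decomposition oracle and cross-checked against
`stats::aov(y ~ group*time + Error(subject))`.

Partial eta-squared is $SS_{effect}/(SS_{effect}+SS_{error})$, labelled by
the 0.01/0.06/0.14 (small/medium/large) thresholds. Its 95% CI inverts the
noncentral-F CDF in the noncentrality parameter $\lambda$ (clamped at 0,
which is why null-true intervals hit exactly 0 about 97.5% of the time).
Two conversions from $\lambda$ to the $\eta_p^2$ scale circulate:
$\lambda/(\lambda+df_2)$ — the bound plugged into the sample statistic's
form $F\,df_1/(F\,df_1+df_2)$, which is what SPSS's noncentral-F plug-in
computes and therefore what most sports-science reports contain — and
Smithson's $\lambda/(\lambda+df_1+df_2+1)$. They differ in the second
decimal at small samples. The default is `conversion = "sample"` so that
package output is directly comparable with SPSS-derived reports;
`"smithson"` is available.

Angular outcomes enter the ANOVA as linear values, exactly as this
literature does. That is only safe away from the 0°/360° wrap, so the
pipeline warns whenever a cell mean lies within 20° of the wrap; the
warning is informational (the analysis still runs, faithfully to field
practice).

Demographic comparisons use pooled-variance independent t-tests
(`stats::t.test`), with the zero-variance/equal-means degenerate case
defined as $t = 0, p = 1$ rather than an error.

## The synthetic-gait generator

The generator emulates the *structure* of an instrumented-treadmill
running trial, not any particular athlete:

* Strides of nominal duration 0.62 s (≈ 1.6 Hz stride rate at fast running
  speeds, giving ≥ 8 strides in a five-second capture) with multiplicative
  Gaussian timing noise (CV 2%, truncated at ±3 SD) — enough to make event
  detection non-trivial without pathological strides.
* Stance occupying 40% of each stride. Real near-sprint stance fractions
  are shorter; 40% is chosen to align with the 0–40% stance convention of
  the subphase analysis, which matters more for testing the pipeline than
  locomotor realism.
* A vertical GRF that is a smooth half-sine bump per stance, scaled to a
  2000 N peak, equal to the 20 N threshold *exactly* at the stance
  boundaries and above it strictly inside — so the threshold crossings are
  at the constructed boundaries by design and event recovery can be tested
  to one sample. The bump's shape is otherwise irrelevant to the pipeline
  (only the crossings matter), so no attempt is made to reproduce the
  impact/active double peak of real running GRF.
* Joint waveforms: truncated two-harmonic Fourier series per joint (smooth,
  periodic, differentiable, parameterizable), with stylised defaults; any
  joint can instead be given an explicit 101-point cycle template, which is
  how prescribed coupling profiles are injected.
* Stride-level coordination noise: per step, the (hip, ankle) increment
  pair is rotated by a von Mises deviate with concentration $\kappa$
  (default 8, stride-level circular SD ≈ 21°, comparable to reported
  coordination variability once combined with within-window direction
  changes); the knee increment receives its own rotation against the base
  ankle increment. With a shared ankle, both pairs cannot follow an exact
  von Mises law simultaneously; the exact law is guaranteed in
  `generate_coupled_pair()`, which is where parameter-recovery properties
  are tested. Endpoint drift introduced by the noise is removed by a linear
  correction across the 100 steps so consecutive strides join continuously.

`generate_coupled_pair()` is the ground-truth construction: per-step
increment directions drawn from von Mises around a prescribed 100-entry
profile (exact at $\kappa = \infty$), unit step magnitude, cumulated from
zero. Coupling angles computed from its output reproduce the profile to
$10^{-9}$ degrees in the noise-free case, and across-stride circular SDs
match the analytic von Mises circular SD
$\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}\cdot 180/\pi$.

`simulate_cohort()` composes these into a two-group pre/post study in
which only the treatment group's hip–ankle coupling shifts, in one
subphase. Three of its choices deserve explanation:

* **Loop closure.** A coupling profile fixes step *directions*; step
  magnitudes are then minimally reweighted (bounded below at 0.3, since
  near-zero steps have ill-conditioned directions) so each joint template
  returns to its start. Joint angles are periodic over a stride; without
  closure every contact would carry a discontinuity that zero-phase
  filtering smears into the adjacent subphases — an artefact of the
  construction, not of the pipeline.
* **Between- and within-subject noise.** Subject-specific direction
  offsets (SD 8°, centred within each group so group-level means stay on
  the prescription) provide between-subject variance; a per-recording
  offset (SD 3°, common to all subphases of that recording) emulates
  day-to-day marker-placement and calibration shifts, the dominant source
  of test–retest variance in gait kinematics. Without the latter, the
  within-subject error would be implausibly small and any nanoscopic
  systematic difference would masquerade as a huge effect.
* **Ground truth.** The generator returns, per subject × time, the circular
  mean of the realized step directions in each window — computed from the
  construction, independent of the analysis pipeline — so end-to-end tests
  compare against a genuine oracle.

What the generator does **not** emulate: 3D marker kinematics and inverse
kinematics, frontal/transverse-plane angles, realistic GRF waveform shape,
speed ramps or belt-speed dynamics, fatigue drift, or the empirical shapes
of real athletes' angle–angle loops. Passing tests therefore demonstrate
that the *pipeline* recovers what was constructed, under realistic sampling
rates, timing jitter and directional noise — not that it would be robust to
every artefact of real motion-capture data (soft-tissue artefact, marker
swaps, non-stationary noise).

## Numerical choices and problem sizes

* Butterworth padding length: $\lceil \ln 10^{-13} / \ln r \rceil$ samples
  ($r$ = largest pole modulus), floored at $3(\text{order}+1)$ and capped at
  the signal length.
* Noncentrality inversion: `uniroot` on a bracket grown geometrically until
  it straddles the target CDF value, tolerance $10^{-10}$; bounds clamp at
  $\lambda = 0$.
* Circular degeneracy: $R < 10^{-12}$ is treated as exact cancellation.
* Zero-motion steps are detected by exact zero increments (the only case in
  which direction is genuinely undefined; floating noise keeps real data
  away from it).
* Test and demonstration sizes — 10–20 strides per trial, 12 subjects per
  group, 2000 null simulations for the type-I check, 1000 random sets for
  the circular-statistics oracle — were chosen to give stable Monte-Carlo
  margins (binomial SE ≈ 0.5% at 2000 simulations) while keeping the whole
  suite fast enough to run habitually.

## Known limitations

* The linear treatment of angles in the ANOVA is faithful to field practice
  but statistically improper near the wrap; the package warns rather than
  substitutes a circular ANOVA, which would change the estimand.
* The pointwise variability convention and the stride-mean alternative can
  disagree substantially when coupling direction changes within a window;
  conclusions about "variability" should state the convention.
* The generator's trial-level noise gives both joint pairs approximately —
  not exactly — von Mises coupling noise (shared ankle); exact-law
  properties are only claimed for `generate_coupled_pair()`.
* Unbalanced designs use the sequential (aov-matching) decomposition; with
  listwise exclusion and unequal group sizes, the time main effect differs
  from SPSS's Type III value (the interaction, with two-level factors, does
  not).
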