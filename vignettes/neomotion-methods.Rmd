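---
title: "Quantifying neonatal movement from pose landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neonatal movement from pose landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomotion)
```

## The problem

Preterm infants in a NICU are routinely assessed by weight, size and
vital signs; the *amount* they move is an additional, traditionally
subjective indicator of development. Contactless pose tracking makes it
objective: a camera-side model emits, per video frame, 33 body
landmarks as normalized image coordinates $(x, y) \in [0,1]^2$ plus a
signed relative depth $z$, and no images need to be stored. neomotion
turns such landmark time series into movement quantities that can be
compared across sessions (e.g. near admission versus near discharge),
across body regions, and across quantification methods.

A recording is held in a `PoseSequence`, a `SummarizedExperiment` whose
assays `x`, `y`, `z` are landmarks-by-frames matrices and whose column
data are the frame timestamps in Unix milliseconds. Regions and time
windows are row and column subsets of this one container.

## The movement model

All quantifiers estimate the cumulative motion
$\Delta I_{\mathrm{total}} = \sum_{i} \Delta I(t_i, t_{i+1})$, the sum
over frame transitions of a per-transition movement measure, itself
summed over the landmarks of the analysed region. Nine methods are
implemented.

**Distance metrics** on the per-landmark displacement
$d = P_{i+1} - P_i$:

* Euclidean $\sqrt{d_x^2+d_y^2+d_z^2}$, Manhattan $|d_x|+|d_y|+|d_z|$,
  Chebyshev $\max(|d_x|,|d_y|,|d_z|)$;
* Minkowski $(|d_x|^p+|d_y|^p+|d_z|^p)^{1/p}$ with $p \ge 1$. The
  default is $p = 3$: reported Minkowski results in this literature are
  distinct from Manhattan ($p=1$) and Euclidean ($p=2$) and sit between
  the Euclidean and Chebyshev scales, consistent with $p > 2$; the
  exact order is a free parameter (`minkowskiP`).
* Mahalanobis $\sqrt{d^\top S^{-1} d}$, with $S$ the $3\times3$
  covariance of all pooled $(x,y,z)$ samples of the analysis window.
  Fitting per window keeps every window self-contained (usable in a
  streaming setting) and makes the metric adapt to the local spread of
  the data. If the condition number of $S$ exceeds $10^8$ a ridge of
  $10^{-9}\,\mathrm{tr}(S)/3$ is added; a fully degenerate window
  (frozen pose) falls back to the identity, flagged.

**Kinematic stencils** over three consecutive frames:

* *Differential acceleration*: velocities
  $V_{i-1,i} = (P_i - P_{i-1})\cdot\mathrm{fps}$ and
  $V_{i,i+1} = (P_{i+1} - P_i)\cdot\mathrm{fps}$; the total sums
  $|V_{i,i+1} - V_{i-1,i}|$ over dimensions, landmarks and interior
  frames. Uniform linear motion contributes exactly zero.
* *Angular displacement*: the turning angle between successive
  displacement vectors $a = P_i - P_{i-1}$ and $b = P_{i+1} - P_i$,
  $\theta = \arccos\!\big(a\cdot b / (|a||b|)\big)$ with the cosine
  clamped to $[-1,1]$; zero-length steps contribute zero. Successive
  displacements (rather than position vectors from the image origin)
  make $\theta$ a translation-invariant turning angle that does not
  depend on camera framing.

**Optical-flow approaches**:

* *Lucas–Kanade on landmarks*: central-difference spatial gradients
  $g = (P_{i+1} - P_{i-1})/2$ and temporal difference
  $b = P_{i+1} - P_i$ form a least-squares system $Av = b$. For a
  single tracked point the design matrix is not canonically defined;
  the documented assembly stacks the gradient row once per coordinate
  equation, and the pseudoinverse solution has the closed form
  $v = g\,\Sigma b / (3|g|^2)$. Stencils with $|g|^2$ below $10^{-12}$
  contribute zero and are flagged ill-conditioned; the quantifier never
  fails for data reasons.
* *Farnebäck on rasterized frames*: each frame is drawn as a grayscale
  image (landmarks as filled circles), dense polynomial-expansion
  optical flow is estimated between consecutive images, and the total
  adds $\sum_{x,y} |F(x,y)|$ over pixels and transitions. The flow is
  implemented in compiled code inside the package: quadratic
  polynomial expansion per pixel (separable Gaussian applicability),
  coarse-to-fine pyramid at scale 0.5, iterative displacement updates
  with box-filter neighbourhood averaging. Depth is not encoded in the
  raster; this is a documented limitation of the image route.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `minkowskiP` | 3 | Minkowski order (dimensionless) |
| `gapFactor` | 3 | transitions with $\Delta t >$ `gapFactor` × median gap are excluded |
| `condThreshold`, `ridgeScale` | 1e8, 1e-9 | Mahalanobis regularization |
| `lkGradEps` | 1e-12 | Lucas–Kanade ill-conditioning threshold |
| `render$width/height` | 64 | raster size in pixels (min 32) |
| `render$radius`, `intensity` | 3 px, 255 | landmark blob size/brightness |
| `flow$levels/winsize/iterations` | 2 / 9 / 2 | pyramid depth, averaging window, refinement steps |
| `flow$polyN/polySigma` | 5 / 1.1 | expansion neighbourhood and applicability width |

The raster and flow defaults were chosen for blob images of tens of
landmarks: a 64-pixel raster resolves the normalized coordinate grid
at ~0.016 per pixel, and displacement recovery is linear for shifts up
to about 4 px at that scale (larger per-frame jumps saturate, as for
any pyramidal flow). All values are exposed through `params` and the
CLI config. Frame gaps: recordings have occasional dropouts; a
transition spanning more than `gapFactor` times the median inter-frame
gap would register the dropout itself as motion and is therefore
excluded (counted in the result's flags).

## Windowing and summaries

Sequences are segmented by timestamp into half-open windows
$[t_0 + k\,w,\; t_0 + (k+1)\,w)$ of exactly $w \in \{30, 60, 120,
180\}$ seconds (any positive $w$ is accepted). The trailing partial
window is discarded — padding would bias totals downward and distort
interval-proportionality comparisons. Windows are independent:
transitions that straddle a boundary count in neither window. Each
(subject, interval, region, method) summary stores the per-window
totals with min, max, mean, median and the *population* standard
deviation ($\sigma$ with divisor $n$): the summary describes the
realized windows themselves, not an inference about hypothetical ones;
"standard deviation of the mean" phrasing in this literature is
ambiguous between SD and SEM, and the population SD is the choice
consistent with the coefficient of variation below.

Cohort-level operations:

* **Percent change** $100\,( \bar m_{\mathrm{late}} -
  \bar m_{\mathrm{early}}) / \bar m_{\mathrm{early}}$ on per-window
  mean levels of the same subject/region/method/interval; which
  sessions are "near admission/discharge" is an explicit input.
  Changes are computed per subject and then averaged (not pooled).
* **Coefficient of variation** $100\,\sigma/\mu$ with population
  $\sigma$. The default cohort-table CV is computed across the
  per-subject whole-body percent changes of each method; other bases
  (across regions, none) are selectable, because the population used
  in published tables of this kind is typically not recoverable from
  the printed rows alone.
* **Interval proportionality**: per-window means normalized to a
  30 s baseline; for stationary movement these ratios approach 2, 4
  and 6 at 60, 120 and 180 s.
* **Region similarity**: $100\,|v_{\mathrm{region}} -
  v_{\mathrm{whole}}| / v_{\mathrm{whole}}$ on cohort-mean values,
  with a strict 10 % acceptability margin; computed at cohort level
  because the corresponding published analyses are cohort heatmaps.

## Body regions

Landmark indices follow the standard 33-point pose convention: head
0–10, arms 11–22 (odd left, even right), hips 23–24, legs 25–32.
`upper_body` (0–22) and `lower_body` (23–32) partition the body at the
waist. The trunk is defined as shoulders plus hips {11, 12, 23, 24} —
anatomically the torso spans the waist, so the trunk is deliberately
*not* a subset of the upper half. The table is overridable from JSON
for reduced or non-standard landmark schemes.

## The synthetic-motion generator

Real recordings are not required anywhere: `generateSequence()` emits
statistically controlled sequences with exact ground truth. Each
landmark follows *base pose + amplitude × (sinusoid + random-walk
jitter)*, where:

* the random walk (per-frame Gaussian steps, SD `jitterSD`) makes the
  expected path length grow linearly with observation time — the
  stationarity that underlies the interval-proportionality analysis;
  i.i.d. noise around the base pose would not have this property;
* the small sinusoid adds a smooth correlated component;
* amplitudes are set per body part (head, arms, trunk, legs), so
  region-resolved recovery can be tested;
* coordinates are clipped to $[0,1]$ with a clip counter; default
  amplitudes keep clipping below 0.1 % of samples.

Defaults emulate the target recording setting: 5 frames/s landmark
logging, 185 s sessions, jitter SD 0.003 normalized units/frame,
amplitude 0.5. The frame rate represents bedside landmark-logging
platforms (which typically log well below video rate); the jitter
scale yields per-window whole-body Euclidean totals of order 10 per
30 s, comfortably inside the unit coordinate box. The generator
records the exact Euclidean path length (after clipping), which the
Euclidean quantifier must reproduce to machine precision.

`generateCohort()` builds paired admission/discharge sessions with a
per-subject lognormal amplitude effect applied to *both* sessions, so
between-subject variability does not bias within-subject percent
change: with late/early amplitude ratio $r$, the expected recovered
mean percent change is $100(r-1)$. Subjects receive independent jitter
realizations (derived per-subject seeds); with the random effect set
to zero, subjects share identical expected levels but remain
independent realizations. `occludeRegion()` marks a region's
landmarks invalid in a chosen fraction of frames, emulating blankets
or interventions; quantifiers drop affected frames in views containing
those landmarks and fail with an insufficient-data error when a region
is fully occluded, while other regions are untouched.

### What the generator does and does not emulate

It reproduces the data *format* (33 landmarks, normalized coordinates,
millisecond timestamps), stationary stochastic motion with known
amplitude structure, recording dropouts and partial occlusion. It does
not model biomechanics: no joint constraints, no alternation between
quiet sleep and active movement, no tracking noise correlated with
pose. Passing tests therefore demonstrate the correctness and
statistical calibration of the pipeline, not clinical validity on real
infants.

## Numerical choices

* Frame rate is derived as $1000/\mathrm{median}(\Delta t)$ — robust
  to dropped frames, unlike the mean.
* The angular cosine is clamped to $[-1,1]$ before `acos`; zero-length
  displacement vectors contribute zero angle by convention.
* Row validation on input rejects (rather than clamps) out-of-range
  coordinates by default: clamping fabricates motion at the image
  border. Clamping remains available per config.
* Windows with fewer than 2 frames are dropped with a log entry;
  quantifiers require ≥ 2 frames (≥ 3 for three-frame stencils) after
  removing invalid frames.
* The identity `v = g Σb / (3|g|²)` is used instead of a generic
  pseudoinverse routine in the Lucas–Kanade path; it is exact for the
  rank-one design matrix and is cross-checked against an explicit
  `ginv` oracle in the tests.
* Farnebäck flow on identical frames short-circuits to exactly zero
  (the solver would return the same, up to representation).

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on generated
data at desk scale: the full combinatorial study uses 10 subjects ×
4 intervals × 9 regions × 9 methods (3240 summary files) at the
default 5 fps / 185 s profile; interval proportionality uses one
9200 s stationary sequence (≥ 50 windows at 180 s); percent-change
recovery uses 4-subject cohorts at amplitude ratios 1.5 and 2.0.
Per-transition Farnebäck contributions are cached per subject and
region and reused across interval lengths — exact, because transition
values do not depend on the windowing.

## Known limitations

* The raster route ignores depth ($z$) entirely; flow totals respond
  only to in-plane motion.
* Pyramidal flow saturates for per-frame displacements beyond a few
  pixels at the chosen raster size; at realistic frame rates neonatal
  movement is far below that bound, but sub-sampled inputs may not be.
* The Mahalanobis metric depends on the window's own covariance, so
  totals are not comparable across windows with very different spread;
  this mirrors its definition rather than a defect.
* MediaPipe-style visibility/presence scores are not modelled; rows
  are either valid or rejected.
* Timing profiles are reported, never asserted: wall times are
  machine-dependent.
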