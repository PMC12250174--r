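# neomotion

Contactless quantification of neonatal movement from pose landmarks.

## The problem

How much a preterm infant moves is an emerging, objective complement to
weight, size and vital signs when tracking development in the NICU.
Camera-side pose tracking makes the measurement contactless and
privacy-preserving: instead of video, only 33 anonymized body landmarks
per frame are stored — normalized image coordinates `(x, y) ∈ [0, 1]²`
plus a signed relative depth `z`, with a Unix-millisecond timestamp.
`neomotion` is for researchers and engineers working with such landmark
streams who need reproducible movement quantities per session, body
region and time window.

## What it computes

The core quantity is the cumulative motion over a landmark sequence,

```
ΔI_total = Σ_i ΔI(t_i, t_{i+1}),
```

the sum over frame transitions (and over the landmarks of the analysed
region) of a per-transition movement measure. Nine quantifiers are
implemented: Euclidean, Manhattan, Chebyshev, Minkowski (order `p`,
default 3) and Mahalanobis (`√(dᵀS⁻¹d)`, windowed covariance `S` with
ridge regularization) distances; differential acceleration
(`Σ|ΔV|·fps` over three-frame stencils); angular displacement (summed
turning angles `arccos(a·b/|a||b|)` in radians); Lucas–Kanade
gradient-based landmark flow; and Farnebäck dense optical flow on
frames rasterized to grayscale images (the polynomial-expansion flow is
implemented in compiled code inside the package).

Around the quantifiers sit:

- **pose I/O** — CSV reader/writer with validation policies, nine body
  regions (head, arms, trunk, legs, body halves, whole body) as row
  subsets of a `PoseSequence` (a `SummarizedExperiment` of `x`/`y`/`z`
  assays);
- **windowing** — timestamp-based segmentation into 30/60/120/180 s
  windows and per-(subject, interval, region, method) JSON summaries
  (values, min, max, mean, population SD, median);
- **cohort analysis** — admission→discharge percent change, coefficient
  of variation `100·σ/μ`, interval-proportionality ratios, and
  region-versus-whole-body similarity with a strict 10 % proxy margin;
- **synthetic motion** — a generator with exact ground-truth path
  lengths (random-walk jitter plus sinusoid, per-region amplitudes),
  paired admission/discharge cohorts and occlusion, so the whole
  pipeline is testable without clinical data.

## Worked example

```r
library(neomotion)

## a synthetic 185 s recording at 5 fps with known kinematics
g <- generateSequence(motionProfile(durationS = 185, seed = 42),
                      subjectID = "demo01")
g$seq
#> PoseSequence: demo01
#>   landmarks: 33 (region: whole_body)
#>   frames: 925 (184.8 s @ 5.00 fps)

## whole-body Chebyshev movement per 30 s window
summarizeMovement(g$seq, 30, "whole_body", "chebyshev")
#> MovementSummary: demo01 / 30s / whole_body / chebyshev
#>   6 window(s): avg 12.1602, std 0.0885926, median 12.1664 [12.043, 12.2861]

## one region, one total
motionTotal(projectRegion(g$seq, "lower_body"), "minkowski")
#> MotionTotal: minkowski on lower_body = 24.9358 (924 steps, 0 excluded)
```

The summary says the infant-surrogate accrued ≈ 12.16 Chebyshev units
of whole-body movement per 30 s window, with small between-window
variability (population SD 0.089) — the stationary regime in which
60/120/180 s windows scale to ≈ 2×/4×/6× the 30 s total. The
`MotionTotal` is the same kind of quantity for a single region over the
whole session; `0 excluded` reports that no transition was dropped by
the recording-gap rule.

A command-line interface wrapping the same functions ships as
`inst/scripts/neomotion.R` (subcommands `synth`, `quantify`, `cohort`,
`timing`), e.g.:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/neomotion.R", package="neomotion"))')" \
  synth --outdir cohort_csvs --seed 7 --n-subjects 10
```

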