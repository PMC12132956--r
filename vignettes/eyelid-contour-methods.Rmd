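---
title: "Measuring the upper eyelid contour with cubic Bezier landmarks"
author: "bezlid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the upper eyelid contour with cubic Bezier landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bezlid)
```

## The measurement model

Oculoplastic assessment of the upper eyelid rests on distances measured
from the pupil centre to the lid margin. The classical scalar is MRD1
(margin reflex distance 1), the vertical distance from the pupil centre to
the margin; a richer description is the radial mid-pupil lid distance
(MPLD) profile, the distance to the margin along rays every 15 degrees
from the nasal horizontal (0) through vertical (90) to the temporal
horizontal (180). `bezlid` computes these, plus the horizontal eye width,
the contour peak (the highest point of the margin, usually sitting
temporal to the pupil), the palpebral fissure obliquity (the up-slant of
the canthal line, prominent in Asian eyelids where the medial contour
endpoint is taken at the medial palpebral commissure rather than the
lacrimal punctum), and six temporal-to-nasal MPLD ratios.

The margin itself is represented by a cubic Bezier curve
$$B(t) = (1-t)^3 p_0 + 3(1-t)^2 t\, p_1 + 3(1-t)t^2 p_2 + t^3 p_3,
\qquad t \in [0,1],$$
digitized on a photograph as two on-curve canthal endpoints and two
interior control points. Two interior control points are enough to follow
the gentle arch of a lid margin, and the four-point representation can be
stored, exchanged and re-rendered exactly. All metrics are then exact
functions of the four control points:

* **Contour peak.** $y'(t)$ is quadratic, so the global maximum of the
  curve's height over $[0,1]$ is found from the (at most two) real roots
  of a quadratic plus the endpoints. Ties on a flat maximum are broken
  toward smaller $t$, so output is deterministic.
* **MPLD at angle $\theta$.** A margin point on the ray satisfies
  $\sin\theta\, x(t) - \cos\theta\, y(t) = 0$, a cubic in $t$ solved by
  the companion-matrix method (`polyroot`) with two Newton polishing
  steps; roots with imaginary part below $10^{-9}$ are treated as real.
  Admissible hits need $t \in [0,1]$ and non-negative radius
  $r = x\cos\theta + y\sin\theta$; the smallest admissible $r$ is
  returned, i.e. the first crossing of the margin seen from the pupil.
  A ray that misses the curve yields `NA`, not an error: the horizontal
  rays legitimately miss a lid arch that stays above the pupil line.
  MRD1 is defined as the MPLD at 90 degrees, and `measure_all()` copies
  it from the profile so the identity holds bit-for-bit.

## Calibration and frames

Raw landmark files store image pixels exactly as digitized (origin
top-left, y down). Every convention is applied in one function,
`normalize_eye()`:

* **Scale.** The white-to-white corneal diameter is assumed to be a fixed
  anatomical length — 12.0 mm by default, following its common use as a
  photogrammetric reference — and divides the pixel distance between the
  two limbus landmarks. The constant is an argument (and a CLI flag)
  because it is an assumption, not a measurement; all millimetre outputs
  are exactly proportional to it, which the tests verify.
* **Origin and axes.** The pupil centre becomes the origin and the
  vertical axis is flipped to anatomical y-up.
* **Laterality.** So that one angle grid serves both eyes, the horizontal
  axis is mirrored per laterality to put nasal at +x and temporal at −x.
  The default `"viewer"` policy assumes a standard non-mirrored
  photograph (for a right eye the nose is to the viewer's right, so OD
  needs no flip and OS is flipped). Because photograph orientation is a
  property of the capture pipeline that the geometry alone cannot reveal
  — a wrongly mirrored eye is still a perfectly valid mirrored eye — the
  policy is configurable (`"mirrored"`, `"none"`) rather than assumed.

`denormalize_eye()` inverts the whole transformation exactly; the test
suite round-trips every frame operation to $10^{-9}$ pixels.

## Curve fitting

`fit_bezier()` fits a cubic to an ordered polyline by chord-length
parameterization and a linear least-squares solve for the two interior
control points (endpoints fixed). Chord-length parameterization is the
standard deterministic choice, but it is an approximation: samples of an
exact cubic are reproduced exactly only when each sample's parameter
equals its chord-length fraction, and a curve of non-constant speed
admits no such dense sample set (in the limit it would force
$|B'(t)|$ constant). On a strongly curved arch the resulting bias is
about 0.2 mm rms. When generating parameters are known — digitizers that
report them, or validation settings — they can be passed via `params`,
and recovery is then exact to machine precision. No iterative
reparameterization is performed, keeping the fit reproducible.

## The synthetic eye generator

Because per-subject clinical coordinates are not redistributable, every
pipeline stage is validated against synthetic eyes with analytic ground
truth. `generate_eye()` *solves* for the curve rather than sampling one:
given the target width, obliquity, peak height and peak temporal offset,
the endpoints are placed from width and obliquity, and the peak is pinned
at $t = 1/2$, which turns the three peak conditions ($x$, $y$, $y' = 0$)
into linear equations for the interior control points. The x-split of the
interior points is chosen to keep $x(t)$ monotone, and the construction is
verified against the analytic peak before the eye is emitted, so the
returned ground truth is exact, not estimated. The curve is then converted
to raw pixel landmarks (scale, pupil position, laterality mirroring,
digitization order lateral-first) with optional Gaussian jitter.

The pupil sits `pupil_offset_mm` from the canthi: by default 0.35 mm
temporal of the intercanthal x-midpoint and 0.4 mm above the lateral
canthal endpoint. Anchoring the vertical offset at the *lateral* canthus
keeps both canthi below the pupil horizontal for any up-slanted fissure
(the medial canthus drops by the obliquity rise), so the 0/180-degree
horizontal radii always exist, as they do in reported adult cohorts. The
default offset was chosen once so that the default eye's horizontal radii
fall near the anatomically reported ~9 mm (nasal) and ~12 mm (temporal);
a single cubic arch renders them 3–6% shorter, a known limitation of
emulating the entire margin with one cubic segment.

`generate_cohort()` draws per-subject parameters from truncated normal
population distributions (truncation at ±4 SD and at physical bounds such
as positive width and feasible peak offsets). The default moments emulate
a young adult Asian cohort: eye width 24.82 ± 1.82 mm (women) and
25.25 ± 2.00 mm (men); contour peak height 4.74 ± 0.68 and 3.84 ± 0.93 mm;
peak temporal offset 1.67 ± 1.02 and 1.49 ± 1.33 mm; fissure obliquity
9.98 ± 3.07 and 7.52 ± 2.89 degrees. What the generator does *not*
emulate: head tilt, perspective, eyelash and reflection artifacts,
digitization ambiguity near the epicanthal fold, and any correlation
structure between the four parameters (they are drawn independently).
Passing tests therefore demonstrates the correctness of the geometry and
statistics, not robustness to photographic confounders.

`simulate_raters()` models two independent digitizations: each rater's
control points receive Gaussian placement error (default 0.15 mm, about
3 px at the default 0.05 mm/px scale — realistic click precision), and
rater 2 can carry a systematic vertical bias. With between-subject peak
height SD near 0.9 mm, a 0.15 mm placement error puts the expected
inter-rater ICC in the high 0.9s, the range reported for this kind of
landmark digitization.

## Reliability statistics

`icc_2_1()` computes the two-way random-effects, absolute-agreement,
single-measure intraclass correlation
$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$
from the closed-form balanced two-way mean squares, with the McGraw–Wong
F-based confidence interval. Reliability reports in the literature mix the
single-measure and average-measure forms (sometimes within one paper), so
the average-measure ICC(A,$k$) is always reported alongside, its interval
obtained through the Spearman–Brown transform of the single-measure
limits. The estimator is checked in the tests against an independent
`aov` decomposition and against a simulation with known variance
components. `bland_altman()` uses the conventional bias ± 1.96 SD limits;
`welch_t()` defaults to the unequal-variance form (with a pooled-variance
toggle) because the equal-variance assumption is rarely defensible for
anatomical measurements.

Two definitions of the summary "ratio total" of the six temporal-to-nasal
MPLD ratios circulate without a stated formula; `tn_ratios()` defaults to
the arithmetic mean of the six pair ratios and offers the
ratio-of-summed-distances alternative, labelling the output with the
definition used. Neither is asserted to be the published convention.

## Numerical choices and problem sizes

* Cubic roots: companion matrix + two Newton steps; imaginary parts below
  $10^{-9}$ treated as real; parameters within $10^{-9}$ outside $[0,1]$
  clamped.
* Peak ties: smaller $t$ wins, at a relative tolerance of $10^{-10}$.
* Degenerate rays (the whole curve lying on the ray's line) return the
  minimum admissible radius over the segment.
* Validation suites use 1,000 random lid-like curves against
  dense-sampling oracles: a $5 \times 10^4$-point shared evaluation grid,
  sign-change scanning with 60 bisection refinements per bracket for ray
  hits (oracle error ~$10^{-12}$, asserted agreement $10^{-4}$ mm), and
  grid maxima for the peak (interpolation error ~$10^{-8}$, asserted
  $10^{-6}$ mm). Round-trip identity runs on 500 noise-free synthetic
  eyes; ICC recovery on 500 replicates of a 200-subject two-rater design;
  Bland–Altman coverage on $10^4$ simulated differences. These sizes are
  the package's validation conditions and are chosen to keep the full
  suite's runtime around a minute on one CPU.

## Example

```{r example, eval = FALSE}
cohort <- generate_cohort(n_female = 40, n_male = 40, seed = 1)
raters <- simulate_raters(cohort, rater_sd_mm = 0.15)
metrics <- metrics_table(measure_landmarks(raters$rater1))
summarize_cohort(metrics, cohort$sex)

icc_2_1(cbind(metrics$peak_height_mm,
              metrics_table(measure_landmarks(raters$rater2))$peak_height_mm))
```

## Known limitations

* A single cubic segment slightly under-reaches the horizontal MPLD radii
  of real margins (see above); applications needing the far nasal/temporal
  margin may require two segments, which is out of scope here.
* The obliquity baseline is the image horizontal; no head-pose correction
  is attempted.
* Landmarks are inputs: the package does not detect the pupil, limbus or
  margin from pixels.
* Calibration assumes a 12.0 mm corneal diameter for every subject, so
  all lengths are ratios in disguise; between-subject comparisons inherit
  the (small) biological variance of the true corneal diameter.
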