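---
title: "Measuring femoral offset from rotation-swept radiographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral offset from rotation-swept radiographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femoffset)
library(dplyr)
```

## The measurement problem

Femoral offset — the perpendicular distance from the centre of rotation of
the femoral head to the long axis of the proximal femoral shaft — drives
abductor moment arm, soft-tissue tension and implant choice in total hip
arthroplasty, and is routinely measured on plain radiographs during
preoperative templating. A radiograph, however, only shows the *projection*
of the offset. If the plane containing the head centre and the shaft axis
(the offset plane) makes angle $\theta - \theta_0$ with the image plane, an
orthographic projection shows

$$\mathrm{offset}(\theta) \;=\; R\,\lvert\cos(\theta - \theta_0)\rvert,$$

where $R$ is the true three-dimensional offset, $\theta$ the femoral
rotation about the shaft axis (internal rotation positive, external
negative), and $\theta_0$ the rotation at which the offset plane is parallel
to the image plane. Any rotation away from $\theta_0$ *underestimates* the
offset; the projection can never overestimate it.

Two radiographic lines produced by the anterior and posterior cortex of the
medial greater trochanter give the rater a rotational landmark: the rotation
at which the lines superimpose (the *aligned neutral*, rotation 0 in this
package's convention) closely approximates the rotation of maximum offset.
This package implements the computational side of validating that idea:

1. **geometry** — measure the offset on one annotated radiograph;
2. **simulator** — generate synthetic radiograph annotations with known
   ground truth;
3. **sweep** — per-specimen offset-vs-rotation analysis and cohort
   statistics;
4. **reliability** — intrarater repeatability via ICC(2,1) with bootstrap
   intervals.

## Per-image measurement model

The rater annotates four kinds of landmarks on each image: 5 points on the
medial and 5 on the lateral cortical border of the proximal shaft, 6 points
around the projected femoral head, and points on the outline of a 1-inch
(25.4 mm, exactly) calibration sphere placed in the plane of the femur.

* **Cortical lines** are fitted by *total* (orthogonal) least squares — the
  first principal axis through the centroid. Cortical borders are
  near-vertical in these images, where ordinary y-on-x regression is
  ill-conditioned; orthogonal regression is also invariant under image
  rotation, which a measurement of a physical distance must be.
* **The shaft axis** is the bisector of the two cortical lines: the
  direction is the normalised sum of the two unit directions (after flipping
  one if they point oppositely, so the *acute* angle is bisected), anchored
  at their intersection. Nearly parallel lines
  ($\lvert\sin\angle\rvert < 10^{-6}$) anchor instead at the midpoint of the
  two canonical anchors, which is exact for the textbook case of parallel
  cortices. Only the axis direction and any point on it enter the distance,
  so the anchor convention is internal.
* **Circles** (head and sphere) are fitted by the Kåsa algebraic
  least-squares fit, refined by Gauss–Newton minimisation of the geometric
  objective $\sum_i (\lVert p_i - c\rVert - r)^2$. With only six points on a
  partial arc the algebraic fit is measurably biased; the geometric
  refinement converges in a handful of iterations (normal-equation steps,
  terminated at a relative step below $10^{-12}$ or 50 iterations).
  Collinear or coincident point sets raise degenerate-geometry errors.
* **The offset** is the perpendicular distance from the fitted head centre
  to the shaft axis, times `mm_per_px = 25.4 / (2 * sphere_radius_px)`. It
  is reported unsigned.

These choices make the whole chain invariant to rigid motion of the image
and equivariant under pixel rescaling (the sphere rescales with everything
else), properties the test suite checks directly.

## The synthetic cohort

No annotated radiographs ship with the package; the simulator generates
them. A specimen is a parametric proximal femur: shaft cylinder (radius
14 mm), head sphere (radius 22 mm) at perpendicular distance $R$ from the
shaft axis, and two trochanteric source points given in cylindrical
coordinates about the shaft axis. Projection is orthographic (parallel
beam): this is precisely the idealisation under which a single in-plane
calibration sphere corrects magnification everywhere, and matches the
non-goal of modelling cone-beam geometry. A feature at cylindrical position
$(d, \varphi)$ projects to horizontal coordinate
$d\cos(\theta-\varphi)/\texttt{mm\_per\_px}$ relative to the projected shaft
axis, so the head centre follows the cosine law by construction and the
shaft silhouette half-width is constant in $\theta$.

The angular discrepancy between the line-aligned neutral and the
offset-plane rotation is modelled as a single per-specimen parameter
$\theta_0$, not derived from trochanteric micro-anatomy: the study the
package emulates measured that discrepancy but did not model its anatomical
cause. The two trochanteric points are placed so their projections coincide
horizontally at rotation 0 (the defining property of the aligned neutral);
their depths and azimuths (posterior: 28 mm at −35°; anterior azimuth +50°,
depth derived from the superimposition constraint) are free parameters
documented as such — any placement satisfying the constraint gives the same
measurements, since the trochanteric points are not annotated landmarks.

Cohort defaults reproduce the emulated study design:

| parameter | default | meaning |
|---|---|---|
| `n_specimens` | 11 | cohort size |
| `offset_mean_mm`, `offset_sd_mm` | 38.2, 4.9 | true offset $R \sim N$, truncated $> 0$ by resampling |
| `theta0_mean_deg`, `theta0_sd_deg` | −3.6, 5.6 | $\theta_0 \sim N$ (ER negative) |
| `angle_grid_deg` | −30, −10 … +10 by 2, +30 | 13 radiographs per specimen |
| `landmark_noise_sd_px` | 0.5 | isotropic Gaussian annotation noise |
| `mm_per_px_true` | 0.25 | true image scale |
| `n_rater_rounds` | 3 | independent re-annotations per image |

The noise model is a single isotropic Gaussian sd shared by all roles; no
annotation-noise model was published, and 0.5 px (≈ 0.125 mm) was chosen
once so that the within-specimen spread of measured offsets over ±10° is
comparable to the ~2.7 mm range the emulated study reports (which is
dominated by the cosine effect, not noise). Each rater round re-noises the
same noiseless geometry independently — re-measurement of one radiograph,
not re-acquisition. Per-specimen seeds are derived from the cohort seed by a
counter scheme, so specimen *i* is reproducible regardless of cohort size.

What the simulator does *not* emulate: real cortical borders are curved and
partly occluded, fluoroscopes add pincushion distortion, raters click
correlated (not isotropic i.i.d.) errors, and the sphere may sit slightly
out of plane. Passing parameter-recovery tests therefore demonstrates the
*computational* chain is unbiased and well-calibrated under the stated
model, not that a clinical measurement inherits those properties.

## Sweep analysis

`analyze_sweeps()` reduces each specimen's measurements to the quantities of
interest. *True offset* is operationally the maximum measured offset over
the rotation grid (no interpolation between grid angles — the discrete
maximum is the estimand the emulated protocol defines); *aligned offset* is
the measurement at rotation 0, which must be present; *underestimation* is
their difference, also expressed as a percentage of the true offset. Rounds
are averaged before maximisation by default (`mean_of_rounds`), since the
rounds model re-measurement of the same image; `per_round` analyses each
round separately. Ties at the maximum are broken towards the smallest
rotation magnitude, then towards internal rotation, and flagged — a rule
chosen to be deterministic and biased towards neutral.

`summarize_cohort()` reports mean, sample sd, median, min and max per
metric. Because the maximum includes rotation 0, aligned ≤ true for every
specimen, and the cohort mean underestimation equals the difference of the
cohort means exactly. The extra `underestimation_pct_pooled` row is
$100(\overline{\mathrm{true}} - \overline{\mathrm{aligned}})/\overline{\mathrm{true}}$
— the ratio in which "x mm, or y %" cohort statements are quoted, which
differs from the mean of per-specimen percentages.

## Reliability

Intrarater repeatability uses the two-way random-effects,
absolute-agreement, *single-measures* intraclass correlation,

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with mean squares from the subjects × rounds ANOVA (computed via
`stats::aov`). Subjects are whatever rows the user supplies; the simulator's
natural table is one row per specimen-image (11 × 13 = 143 subjects, k = 3
rounds). Design choices where the convention was open:

* **Bootstrap**: nonparametric, resampling *subjects* with replacement so a
  subject's rounds stay paired; percentile 95% interval (not BCa); 2000
  replicates by default; an explicit seed is required.
* **Degenerate tables** (all cells equal) are defined as ICC = 1 with a
  `degenerate` flag; bootstrap replicates that collapse this way are handled
  the same.
* **Negative estimates** are reported as computed, never truncated at 0.
* **Bands**: < 0.40 poor, 0.40–0.75 fair-to-good, > 0.75 excellent. The
  conventional strict inequalities leave the boundaries ambiguous; both
  0.40 and 0.75 are assigned to fair-to-good here.

## Numerical and interface conventions

* Pixel coordinates use the image convention (origin top-left, y downward);
  all geometry uses distances only, so this is documentation, not
  computation.
* `rotation_deg` stores the nominal actuator angle relative to the aligned
  neutral; external rotation is negative, internal positive.
* CSV landmark files round-trip at full double precision: the writer emits
  shortest round-trip representations and the reader parses via base
  `strtod`. The schema's 6 canonical columns are extended by an optional
  `round` column (defaulting to 1) so that rater rounds survive the file
  format.
* The rotation grid defaults to the 13 enumerated angles; the schema accepts
  any grid containing 0.

## Problem sizes used in validation

The test suite and the acceptance script validate at these sizes, chosen as
the package's own study conditions: the cosine law is checked noiselessly
over $R \in \{30,\dots,46\}$ mm and $\theta_0 \in \{-10,\dots,10\}°$ at all
13 grid angles (tolerance $10^{-6}$ mm); fit oracles (grid search for lines,
Nelder–Mead for circles, from-definition ANOVA for ICC) are compared on 100
random instances each; parameter recovery simulates cohorts at the default
configuration with a single rater round — one measurement per radiograph,
as the rotation-sweep results need no re-measurement — 500 cohorts in the
test suite and 200 in the acceptance script; reliability is estimated on
one default three-round cohort with 2000 bootstrap replicates.

## Known limitations

* The cosine projection law is exact only under parallel-beam geometry; a
  cone beam adds a magnification gradient that the in-plane sphere corrects
  only at its own depth.
* The operational "true offset" (discrete maximum over the grid) is biased
  slightly *upward* under annotation noise (a maximum over noisy values)
  and *downward* when $\theta_0$ falls outside the fine ±10° grid; both
  effects are visible in, and quantified by, the recovery tests.
* ICC(2,1) treats per-image measurements as exchangeable subjects; images
  of the same specimen share a specimen effect the two-way model folds into
  the subject term. Other ICC forms (consistency, average-measures) are out
  of scope.
* The simulator's trochanteric anatomy is a stand-in satisfying the
  superimposition constraint, not a measured shape model.
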