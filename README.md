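# femoffset

Measurement of **femoral offset** — the perpendicular distance from the
centre of rotation of the femoral head to the long axis of the proximal
femoral shaft — from landmark-annotated radiographs, and analysis of how
that measurement changes as the femur rotates about its shaft axis.

Radiographs only show the *projection* of the offset: if the plane through
the head centre and shaft axis makes angle θ − θ₀ with the image plane, the
measured offset is R·|cos(θ − θ₀)|, never more than the true offset R.
Aligning two radiographic lines created by the anterior and posterior
cortex of the greater trochanter gives a reproducible rotational landmark
close to the rotation of maximum (true) offset — the idea this package's
pipeline quantifies. It is aimed at researchers validating radiographic
measurement protocols for hip arthroplasty templating, and at anyone who
needs a clean, tested implementation of the component steps.

The package provides:

* **Per-image measurement** (`measure_offset()`, `measure_offsets()`):
  total-least-squares lines through 5 medial + 5 lateral cortical points,
  their acute-angle bisector as the shaft axis, a Kåsa + Gauss–Newton
  least-squares circle through 6 head points, pixel-to-mm calibration from
  a 1-inch (25.4 mm) sphere, perpendicular point-to-line distance.
* **A synthetic cohort simulator** (`femur_model()`, `project_femur()`,
  `simulate_cohort()`): orthographic projection of a parametric proximal
  femur with ground truth, controlled annotation noise and per-specimen
  reproducible seeds.
* **Rotation-sweep analysis** (`analyze_sweeps()`, `summarize_cohort()`,
  `plot_offset_curves()`): true offset (max over the grid), aligned offset
  (at the line-aligned neutral, rotation 0), underestimation in mm and %,
  rotation at maximum, cohort statistics.
* **Intrarater reliability** (`icc21()`, `icc_bootstrap()`): ICC(2,1) —
  two-way random effects, absolute agreement, single measures — with
  percentile bootstrap CIs resampling subjects; `tidy()`/`glance()`
  methods.
* **An end-to-end driver** (`run_pipeline()`): simulate → measure → sweep →
  ICC, writing all artifacts plus a config snapshot, byte-deterministic
  under a seed.

Landmark tables are plain tibbles (one row per annotated point) that
round-trip through CSV/JSON via `read_landmarks()`/`write_landmarks()`;
every user-facing function takes a data frame first and returns a tibble.

## Worked example

```r
library(femoffset)

sim    <- simulate_cohort(cohort_config(seed = 1))   # 11 specimens, 13 angles, 3 rounds
meas   <- measure_offsets(sim$landmarks)             # 429 per-image offsets
sweeps <- analyze_sweeps(meas)                       # rounds averaged, one row per specimen
summarize_cohort(sweeps)
#> # A tibble: 7 × 7
#>   metric                       mean     sd median     min   max     n
#>   <chr>                       <dbl>  <dbl>  <dbl>   <dbl> <dbl> <int>
#> 1 true_offset_mm             38.0    5.05  38.7    30.0   44.4     11
#> 2 aligned_offset_mm          37.6    5.00  37.6    30.0   44.2     11
#> 3 underestimation_mm          0.368  0.402  0.223   0      1.22    11
#> 4 underestimation_pct         0.960  1.06   0.675   0      3.14    11
#> 5 rotation_at_max_deg        -0.727  5.75   0     -10      6       11
#> 6 range_pm10_mm               1.45   0.901  0.939   0.655  3.34    11
#> 7 underestimation_pct_pooled  0.969 NA     NA      NA     NA       11

icc_bootstrap(ratings_matrix(meas), n_boot = 2000, seed = 1)
#> ICC(2,1) = 0.9986 (excellent agreement)
#>   bootstrap 95% CI [0.9983, 0.9989]  (2000 replicates, seed 1)
#>   143 subjects x 3 rounds; MS rows 79.11, cols 0.08409, error 0.03609
```

Reading the summary: this simulated cohort's mean true offset (38.0 mm)
sits near the generating mean of 38.2 mm; measuring only at the aligned
neutral would underestimate it by ~0.4 mm (~1 %) on average; specimens
peaked between −10° and +6° of rotation; and with 0.5 px annotation noise
the three rater rounds agree almost perfectly (ICC ≈ 0.999, "excellent").

`plot_offset_curves(meas)` draws the offset-vs-rotation curve per specimen
with a dot at each maximum.

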