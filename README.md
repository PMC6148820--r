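# rvseg

Semi-automatic right-ventricle (RV) segmentation for short-axis cine
cardiac MR, with the full evaluation apparatus used to validate such a
method: Simpson's-rule volumetry and ejection fraction, Dice and Hausdorff
contour validity metrics, and Bland–Altman / Wilcoxon observer-agreement
statistics. A built-in synthetic cine phantom with analytic ground truth
makes the whole pipeline testable end-to-end without patient data.

It is written for imaging scientists who need a reproducible, scriptable
RV pipeline: one rough endocardial seed contour per cardiac phase in, all
slice contours between the annotated basal and apical slices out.

## Method

Segmentation on the seeded slice is a seeded cellular automaton (GrowCut
family). Pixels carry a label, a strength θ ∈ [0, 1] and a normalized
intensity; a labelled pixel *q* attacks its neighbour *p* with strength

    a = λ · g(|I_p − I_q|) · θ_q,   g(d) = 1 − d

and conquers it iff the attack exceeds θ_p. Foreground seeds come from the
eroded user contour; background seeds from the image border plus static
tissue identified by the temporal-SD motion map of the cine. The refined
contour then propagates toward base and apex — each step corrects
inter-slice misalignment by windowed normalized cross-correlation and
shrinks the transferred seed apex-ward (area factor 0.85/slice) — and each
slice result is attached to the LV epicardium so both contours share the
septum. Volumes follow the clinical Simpson rule,

    Volume = Σ_i Area_i · Thickness_i,    EF = (EDV − ESV) / EDV × 100%,

with Thickness the slice thickness plus interslice gap. Validity metrics:
Dice 2|A∩B|/(|A|+|B|) on rasterized areas, Hausdorff max–min distance on
boundary points in mm. See the methods vignette
(`vignettes/rvseg-methods.Rmd`) for the full account, including every
design decision and the phantom geometry.

## Worked example

```r
library(rvseg)

# a synthetic subject: SSFP-like stack + analytic ground truth
ds <- generate_phantom(phantom_spec())
ds$truth_volumes
#> <volume_set> EDV 166.2 mL, ESV 74.5 mL, EF 55.2%

# segment ED and ES from 2 mm-perturbed mid-slice seeds,
# attached to the phantom's LV epicardial contours
seg <- segment_phantom(ds, seed_magnitude_mm = 2, rng_seed = 42)

measure_volumes(seg, ds$annotations)
#> <volume_set> EDV 164.8 mL, ESV 73.8 mL, EF 55.2%

library(dplyr)
contour_metrics(seg, ds$truth, c(ds$stack$n_rows, ds$stack$n_cols)) |>
  mutate(phase_tag = ifelse(phase == ds$annotations$ed_phase, "ed", "es")) |>
  group_by(phase_tag) |>
  summarise(median_dice = median(dice), median_hd_mm = median(hausdorff_mm))
#> # A tibble: 2 × 3
#>   phase_tag median_dice median_hd_mm
#>   <chr>           <dbl>        <dbl>
#> 1 ed              0.998         1.81
#> 2 es              0.999         1.88
```

The segmented volumes land within about 1% of the analytic truth and the
per-slice contours overlap it at Dice ≈ 0.998 with worst-case boundary
deviations under 2 mm on this noise-and-misalignment phantom.

For observer studies, `run_protocol()` takes the six measurement tables
(M1, M2a, M2b, A1, A2a, A2b) and emits the five standard comparisons
(manual and semi-automatic inter-/intra-observer variability plus
validity) for ED volume, ES volume and EF; `autoplot()` on any
`agreement_report` draws the Bland–Altman plot.

A command-line wrapper ships at `inst/cli/rvseg`
(`rvseg phantom | segment | volumes | metrics | agree | e2e`).

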