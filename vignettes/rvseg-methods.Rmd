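---
title: "Methods: cellular-automata right-ventricle segmentation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellular-automata right-ventricle segmentation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvseg)
```

## The problem

Right-ventricular (RV) volumes and ejection fraction are standard outcome
measures in cardiac MR, but the RV is tedious to contour by hand: its
crescent-shaped blood pool wraps around the left ventricle (LV), its free
wall is thin, and a short-axis cine study contains two phases (end-diastole,
ED; end-systole, ES) times up to ten slices to delineate. `rvseg` implements
a semi-automatic pipeline that asks the user for exactly one rough
endocardial contour per phase and produces all slice contours between the
annotated basal and apical slices, together with Simpson's-rule volumes,
the ejection fraction, contour validity metrics (Dice, Hausdorff) and the
observer-agreement statistics used to validate such a method.

Because patient data cannot ship with a package, every stage is testable
against a synthetic short-axis cine phantom with analytic ground truth; the
phantom is first-class, seeded, and deterministic.

## Single-slice segmentation: the label automaton

Segmentation on the seeded slice is a seeded cellular automaton of the
GrowCut family. Each pixel carries a label (unlabeled, foreground,
background), a strength $\theta \in [0,1]$, and a feature value: the slice
intensity min–max normalized to $[0,1]$ (SSFP intensity units are
arbitrary, so only contrast matters; after normalization no neighbour
difference can exceed 1). In one synchronous iteration every labelled pixel
$q$ attacks each neighbour $p$ (8-connected by default) with strength

$$ a_{q \to p} \;=\; \lambda \, g(|I_p - I_q|)\, \theta_q,
   \qquad g(d) = 1 - d, $$

and $p$ is conquered — taking $q$'s label and the attack value as its new
strength — iff the strongest attack exceeds $\theta_p$. Seeds start at
$\theta = 1$, everything else at $0$. Strengths therefore never decrease,
are bounded by 1, and the iteration reaches a true fixpoint: running
`evolve()` on a converged field changes nothing. Updates are Jacobi-style
(computed against the previous iteration's state), which makes the result
independent of memory layout; among simultaneous equal attackers the fixed
scan order N, NE, E, SE, S, SW, W, NW decides, so uniform regions have a
deterministic, platform-independent partition. The per-step factor
$\lambda \in (0,1]$ (default 1) attenuates transmitted strength with every
step and is the one knob encoding distance-to-seed; at $\lambda = 1$
competition is driven purely by intensity similarity along paths.

The published description of the method names the automaton framework but
not the update rule; the attack function $g$, the neighbourhood, and
$\lambda$ above are this package's own formalization, chosen to match the
standard conquest rule of that family while keeping a single interpretable
parameter.

### Seeding

Foreground seeds are the pixels inside the user polygon after a 2 px
erosion (a careless contour that slightly overshoots the border must not
plant foreground seeds in myocardium). Background seeding is automatic, from
the image itself and the cardiac motion: the one-pixel image border, plus
every pixel outside the 10 px-dilated seed polygon whose temporal intensity
standard deviation across the cine phases lies at or below the 50th
percentile of that motion map — static tissue away from the moving heart.
The moving LV pool is deliberately *not* background-seeded; if the
foreground front crosses the septum the epicardial attachment step removes
the spill (below). An eroded-empty seed is an error instructing the user to
draw a larger contour.

### Contour extraction

The converged foreground is reduced to its largest 8-connected component,
interior holes are filled, and the boundary is traced at the 0.5 level of
the component indicator (marching squares, sub-pixel), resampled to 120
points and smoothed with one pass of a 3-point moving average. A refined
contour whose area grows beyond 3x the rough seed area (or collapses below
a third of it) carries a quality flag — the signature of a seed dropped
into homogeneous tissue.

## Propagation across slices

The refined contour marches from the seeded slice toward the basal and the
apical annotation bounds. For each next slice the previous contour is

1. translated by the integer-pixel shift maximizing normalized
   cross-correlation of a window around the contour (search radius 10 mm;
   ties resolve to the smallest shift) — breath-hold misalignment between
   slices is typically a few millimetres;
2. shrunk by an area factor of 0.85 when moving apex-ward (the only
   geometry prior: the transferred *seed* narrows the way a ventricle
   does; the automaton then finds the actual border, so the prior never
   constrains the final contour);
3. used as the rough seed for the automaton on that slice.

Results below a minimum area (10 px) are omitted with a warning and stop
the march in that direction. Sub-pixel alignment is not attempted: the seed
is rough by construction, and the automaton absorbs residual misalignment.

### Attachment to the LV epicardium

Displaying RV endocardial and LV epicardial contours that overlap or leave
a gap at the septum is a known error source. When LV contours are
available (the usual clinical workflow segments the LV first), each slice
result is clipped against the LV epicardium: the overlap region is removed
and the freed boundary stretch is replaced by the epicardial arc between
the two junction points, so both contours share the septum exactly.
Disjoint contours are returned unchanged (flagged), as is the degenerate
case of an RV contour entirely inside the epicardium; more than one
overlap region yields the polygon difference with a multi-junction flag.
Attachment is idempotent. The polygon boolean operations use integer-robust
clipping (polyclip).

## Volumetry and metrics

Clinical Simpson's rule: volume is the sum over segmented slices of
contour area (shoelace, in mm^2 via the pixel spacings) times the
effective slice thickness — slice thickness *plus* interslice gap, stored
separately and summed only here. Slices omitted by propagation contribute
zero area and are counted. EF is $(EDV - ESV)/EDV \times 100$.

The Dice metric is computed on areas — contours rasterized on the image
grid with a strict pixel-centre, even–odd rule (centres on an edge
excluded) — while the Hausdorff distance is computed on boundary points:
contours resampled in physical mm at a step of at most 0.25 mm, then the
symmetric max–min Euclidean distance. The two definitions intentionally
differ (area overlap vs boundary deviation). Two empty masks have Dice 1,
empty vs non-empty 0; the convention matters only for degenerate inputs.
Per-slice metric pairs are pooled across slices and subjects before taking
medians, mirroring how such results are usually reported; the pooling unit
is a function argument, not a hidden constant.

## Agreement statistics

The validation protocol compares six measurement sets — manual M1, M2a,
M2b and semi-automatic A1, A2a, A2b — in five comparisons (manual
inter-/intra-observer, semi-automatic inter-/intra-observer, validity A1 vs
M1) for ED volume, ES volume and EF. For each paired comparison the package
reports median and IQR (linear interpolation between closest ranks, R type
7 — IQRs depend on the percentile convention, so it is fixed and
documented), mean ± sample SD, 95% limits of agreement (mean ± 1.96 SD,
exactly), the same four on the percentage scale, a two-tailed Wilcoxon
signed-rank p, and an OLS regression with $R^2$.

Two deliberate choices:

* **Percentage denominator.** The percentage difference divides by the
  pair mean by default. For observer-vs-observer comparisons both members
  are equivalent measurements and the pair mean is the only symmetric
  choice; for validity against a manual reference a
  `pct_denominator = "y"` mode divides by the reference value instead.
* **Wilcoxon p.** Zero differences are dropped and ties mid-ranked. With
  12 or fewer non-zero differences the two-sided p is exact by sign
  enumeration ($2^n$ assignments); beyond that, a normal approximation
  with tie and continuity corrections. `stats::wilcox.test` abandons the
  exact path under ties, which is why the exact branch is implemented
  here (and cross-checked against `wilcox.test` in tie-free cases and an
  independent counting oracle otherwise). Normality pre-tests are not
  performed: the nonparametric path is always used.

## The synthetic phantom

The phantom emulates a 2D SSFP short-axis cine acquisition: bright blood
(1.0), darker myocardium (0.35), dim background (0.1), Gaussian noise
(default SD 0.05, i.e. 5% of the blood level), 8 mm slices + 2 mm gap,
1.25 mm pixels, 24 phases, 10 slices with slices 1–8 annotated
basal-to-apical. Geometry per slice:

* the LV is a disc (endocardium) inside an annulus whose wall area is
  conserved through the cycle (incompressible myocardium, so the
  epicardium barely moves while the endocardium contracts);
* the RV blood pool is the *lune* between the LV epicardial circle and a
  larger off-centre circle, clipped by nothing else — its inner border
  *is* the epicardial circle, giving the attached-septum topology the
  segmentation assumes, and its area has a closed form (circle–circle
  lens formula). A thin free wall (4 mm) of myocardium wraps the outer
  arc. The crescent's angular extent follows from the circle geometry
  rather than an explicit sector parameter;
* all in-plane geometry scales per slice by a linear taper (1 at the
  basal slice to 0.45 at the apical slice) about the RV long axis (the ED
  crescent centroid) — scaling about the LV centre instead would drag the
  RV sideways slice-to-slice and masquerade as misalignment;
* phases follow a cosine time course ED -> ES -> ED (ES at phase 9 of 24,
  a physiologic systolic fraction; zero slope at both extremes so areas
  change smoothly).

Because every cross-section is a scaled copy of the mid-cavity lune, the
ground-truth volume is closed-form. The generator *calibrates itself*: the
global in-plane scale is solved so the analytic EDV equals the target
(default 166.2 mL, a healthy adult RV), and the ES in-plane contraction
factor is solved by `uniroot` so the analytic ESV equals
$(1 - \text{contraction fraction}) \cdot EDV$ (default ESV 74.5 mL, EF
about 55%). Per-slice integer-pixel shifts (default magnitude 2 mm) model
breath-hold misalignment and are applied to image *and* truth; noise is
applied to the image only. Trabeculation is not simulated: the protocol
being emulated counts trabeculae with the blood pool, so a clean pool is
the correct truth. One integer seed drives all randomness;
identical seeds give bit-identical datasets.

Rough user seeds are emulated by `perturb_seed()`: a low-order (orders
1–4) random Fourier modulation of the contour radius about its centroid
with peak amplitude equal to the requested magnitude (default 2 mm),
redrawn if a draw self-intersects.

What the phantom does *not* contain — trabeculation, papillary muscles,
coil shading, banding, through-plane motion, valve-plane ambiguity at the
base, pathology shapes — bounds what a passing benchmark shows: the
pipeline recovers clean SSFP-like geometry under noise, misalignment and
careless seeding; it says nothing about basal-slice disambiguation or
diseased ventricles.

## Numerical choices and degenerate inputs

* Coordinates are 0-based; contour points are continuous pixel
  coordinates with $(x, y) = (\text{col}, \text{row})$; mm are obtained
  via the per-axis pixel spacing. One convention, asserted in round-trip
  tests.
* Slice order is never assumed: annotations carry basal and apical
  indices explicitly and propagation iterates basal -> apical whatever
  their numeric order.
* NIfTI z-spacing conflates thickness and gap, so a sidecar JSON carries
  them separately; absent a sidecar, z-spacing is read as thickness with
  zero gap.
* The automaton's iteration cap is rows x cols (it converges far sooner
  in practice: every conquest strictly raises a bounded strength).
* Rasterization uses strict interior (edge pixels excluded) so that
  Dice is exactly reproducible across platforms.
* Contours are stored implicitly closed; a repeated final vertex is
  dropped on read.

## Problem sizes in the test suite

The package's own benchmarks run a 10-subject phantom cohort at the
default study conditions (default noise, shifts on, 2 mm seed
perturbation), segmented twice per subject with independent seed draws;
validity is the pooled per-slice median Dice/Hausdorff per phase, and
reproducibility the largest per-parameter median absolute percentage
difference between the two runs. The phantom grid is 160 x 160 at 1.25 mm —
a deliberate desk-scale choice relative to a 256 x 256 scanner matrix that
leaves the structure sizes, spacings and contrasts unchanged. Unit tests
use a smaller 5-slice, 6-phase phantom with a gentler per-step taper
(0.75 at the apex over 4 steps), since four annotated slices would
otherwise shrink cross-sections per step far faster than the acquisitions
the defaults emulate.

```{r example, eval = FALSE}
ds <- generate_phantom(phantom_spec())
seg <- segment_phantom(ds, seed_magnitude_mm = 2, rng_seed = 7)
contour_metrics(seg, ds$truth, c(ds$stack$n_rows, ds$stack$n_cols)) |>
  dplyr::group_by(phase) |>
  dplyr::summarise(dice = median(dice), hd = median(hausdorff_mm))
measure_volumes(seg, ds$annotations)
```

## Known limitations

* The automaton is 2D per slice; the third dimension is handled only by
  explicit propagation (by design — no volumetric automaton).
* Alignment is integer-pixel.
* The method segments ED and ES only, not the full cycle.
* The exact update rule of the originally described software is not
  public; this implementation fixes one member of the family and
  validates it against its own oracle, not against that software.
* Basal-slice selection, four-chamber/tricuspid-view inference and LV
  segmentation are inputs, not outputs.
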