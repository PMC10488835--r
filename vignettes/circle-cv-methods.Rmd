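---
title: "Circle-based conduction velocity and voltage analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circle-based conduction velocity and voltage analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamap)
```

This vignette is the package's account of its science: the estimator, the
geometric construction behind it, the statistical model, the synthetic data
used to validate everything, and the numerical and design choices that were
genuinely open.

## The measurement problem

An electroanatomical map is a triangulated reconstruction of a heart
chamber's inner surface on which every vertex carries a local activation
time (ms) and a unipolar voltage amplitude (mV). Two derived quantities
matter clinically: the conduction velocity (CV) of the activation
wavefront, whose slow zones sustain re-entrant arrhythmias, and the
voltage amplitude (VA), whose low zones mark scar. The difficulty with CV
is that the wavefront direction is unknown and varies across the surface;
any estimator built on a fixed direction is biased wherever the front
turns.

The circle method sidesteps direction. A circular region of radius $r$ is
cut from the surface; if a front crosses it at speed $v$, the first and
last activations inside the circle sit (for a planar front) at opposite
ends of the diameter along the propagation direction, so

$$\mathrm{CV} \;=\; \frac{2\sqrt{A/\pi}}{\Delta t},
\qquad \Delta t = t_\mathrm{last} - t_\mathrm{first},$$

where $A$ is the *measured* area of the clipped patch. Working throughout
in mm, ms and mV makes CV come out in mm/ms, which equals m/s with no
conversion factor — one entire class of unit bugs is structurally
impossible. Using the measured rather than nominal area matters at map
borders and next to cutouts, where the patch is a truncated disk and the
effective diameter is genuinely smaller.

## Sphere-clipped patches on a triangle mesh

`clip_ball()` intersects the mesh with a Euclidean ball, the mesh analogue
of an implicit-function (spherical) clip. The distance-to-center field is
evaluated at the vertices and iso-clipped at level $r$ assuming linear
variation along edges: triangles fully inside are kept whole, boundary
triangles are split exactly where the interpolated distance equals $r$,
and activation and voltage are linearly interpolated at the split points —
consistent with linear finite elements on the mesh. Euclidean (chordal)
balls, not geodesic disks, are used deliberately: on patches whose
curvature radius is large against $r$ the difference is second order, and
the chordal construction is what an implicit-function clip in standard
visualisation tools computes.

Numerical behaviour, measured by the test suite on flat sheets where the
answer is analytic:

* clipped area converges to $\pi r^2$ as the edge length $h \to 0$; at
  $h = 0.25$ mm and $r = 5$ mm the error is about 0.04%, and the error
  decreases monotonically through $h \in \{1, 0.5, 0.25\}$ (first order in
  $h$, set by the perimeter cells);
* a vertex exactly on the clip level is treated as inside; a split at
  parameter 0 produces a zero-area fragment and is harmless;
* the patch's $\Delta t$ includes the interpolated boundary points, so a
  front entering only the rim of the circle is still seen;
* `n_points` counts original vertices strictly inside the ball — the
  mesh-resolution analogue of "measurement points per circle".

Cutouts (vessel and valve transitions, annotated per vertex) are excluded
conservatively: a triangle touching any cutout vertex never contributes,
and a circle centered on a cutout vertex is rejected outright. Empty
intersections return an empty-patch marker rather than an error, because
downstream code drops them as a matter of course.

**Circle placement.** The study design this package models reports only
the *outcome* of circle placement (about 131 overlapping circles per map),
not the rule. We chose greedy farthest-point sampling on the non-cutout
vertices with a stopping distance equal to the `spacing` parameter:
deterministic given a seed (which picks the start vertex and breaks exact
distance ties), near-uniform, and guaranteed to leave no vertex farther
than `spacing` from a center. Defaults are radius 5 mm and spacing 5 mm,
which produce overlapping circles at the reported order of density on
chamber-scale surfaces; both are configuration knobs, and center placement
on vertices (rather than arbitrary surface points) is acceptable because
mapped surfaces are dense (order 1.4 points/mm²).

**Voltage aggregation.** The per-circle VA is the area-weighted integral
of the interpolated voltage over the clipped patch divided by the patch
area — the mean over the covered *surface*, not over the point list. A
`vertex_mean` option exists for comparison; the two agree exactly on
constant fields and differ on gradients where vertex density varies.

## Exclusion rules

Two rules remove circles before any statistics:

* $\Delta t = 0$ (constant activation over the patch) makes the estimator
  undefined; such circles are flagged `zero_dt`, never reported as
  infinite.
* CV > 6 m/s is non-physiological for working myocardium and indicates
  near-simultaneous activation across the circle. The comparison is a
  strict inequality — exactly 6 m/s is kept — and the threshold is
  configurable.

A property worth recording: two *equal-speed* colliding planar fronts
inflate the estimate near the collision line by at most a factor of two
(the spread over a straddling circle is at least half the full crossing
time), which at physiological speeds stays below 6 m/s. The >6 m/s rule
therefore catches the stronger pathology — locally flat activation, as at
breakthrough sites — while collision-line inflation of up to 2× passes the
filter and remains a documented bias of all spread-based estimators. The
small circle radius keeps the affected strip narrow.

## The statistical model

Per-circle measurements from a multi-animal study are nested: circles
within maps within animals, with each animal contributing several chambers
and repeat maps at different heart rates. The model is

$$\log \mathrm{CV}_{ij} \;=\; \beta_{\mathrm{loc}(ij)}
  + \beta_{HR}\,\mathrm{HR}_{ij} + b_i + \varepsilon_{ij},
  \qquad b_i \sim N(0, \sigma_b^2),\;
  \varepsilon_{ij} \sim N(0, \sigma^2),$$

with an animal-level random intercept $b_i$ and no location×heart-rate
interaction; VA uses the same structure on the mV scale. Velocity is
log-transformed because per-circle velocities are right-skewed and
because chamber comparisons are naturally multiplicative (reported as
ratios). The natural log is used; contrast ratios are then
$\exp(\Delta\log)$, and estimated marginal means are back-transformed with
delta-method standard errors.

Choices the underlying literature leaves open, decided here:

* **REML** estimation, the default for variance-component inference.
* **Satterthwaite** denominator degrees of freedom (`lmerTest`), with a
  documented `df_method = "normal"` fallback for settings where the
  Satterthwaite computation is unavailable or unstable.
* **Reference heart rate 90 bpm** for all reported EMMs; requesting a
  rate outside the observed range warns about extrapolation rather than
  failing.
* **Tukey's HSD** (studentized-range) for all-pairs contrast sets;
  **Sidak**, $1-(1-p)^m$, for targeted subsets, applied by closed form to
  the selected contrasts. Asking for Tukey on a hand-picked subset is
  refused, since the studentized-range criterion presumes the full pair
  set.
* A fit with zero estimated random-intercept variance is *flagged*
  singular, not rejected — with four animals this is a live possibility —
  while fewer than two animals, single-sex data for the sex test, and
  rank-deficient fixed designs are hard errors.

Pearson correlations between CV and VA follow the reporting convention
r(df) with df = n − 2, an interpretation rule that |r| < 0.2 is "no
linear correlation" regardless of significance (with thousands of circles,
tiny r is easily significant), and an optional slow-conduction restriction
CV < 1.5 m/s, the range where scar physiology predicts the association.

## What the synthetic data emulates — and what it does not

Closed-form activation fields keep ground truth exact: planar
($t = (x \cdot n)/v$), focal (straight-line distance over speed, exact on
flat geometry and an approximation on curved surfaces), and colliding
(pointwise minimum of two fields). Geometries are flat sheets (for
analytic checks) and subdivided-icosahedron ellipsoids standing in for
chambers, with wall labels planted as azimuthal sectors plus a superior
polar cap for atria, cutout disks at chosen sites, wall-wise voltage
means with vertex-level Gaussian noise (clamped at zero to respect the
unipolar-amplitude invariant), and optional activation jitter and
flat-spot regions that plant genuine >6 m/s outliers.

The hierarchical study simulator exists in two forms. `generate_study()`
builds full surface maps, one per design row, with animal intercepts
applied multiplicatively to wave speed (log scale) and additively to
voltage. `simulate_measurements()` draws per-circle values directly from
the mixed model above — the right tool for parameter-recovery and
CI-coverage studies, because it makes every generative parameter exactly
known and is fast enough for hundreds of replications. Its defaults are
the study conditions this package models: 4 animals (two female), the
21-map design with per-map heart rates from the reference inventory
(`reference_map_design()`), 131 circles per map, chamber CV means
0.50/0.79/0.54/0.59 m/s (RA/LA/RV/LV) and VA means 3.35/4.81/7.83/10.98
mV at 90 bpm. Values nothing states were chosen once as field-plausible
and documented here: residual sd 0.30 on log CV (circle-level spread) and
1.5 mV on VA; animal-intercept sd 0.10 (log CV) and 0.5 mV; heart-rate
slopes −0.002 per bpm (log CV) and −0.01 mV per bpm, small negative
effects of rate on both quantities.

What passing tests on this data shows: the geometry layer is exact where
exact answers exist, the estimator recovers planted speeds within 2% on
dense flat sheets, the exclusion rules remove exactly the planted
pathologies, and the inference layer is calibrated (≥93% empirical CI
coverage over 500 replications) under the model it assumes. What it does
not show: behaviour under fractionated electrograms, annotation error,
spatially autocorrelated voltage (the generator's voltage noise is i.i.d.
by default), genuinely curved wavefronts interacting with trabeculated
anatomy, or mapping-system-specific artefacts. Real-data conclusions
inherit those caveats.

## Problem sizes and replication counts

The validation studies use sizes chosen to make their target quantity
well-estimated: patch-area and convergence checks on sheets of 15–40 mm
with edges 0.25–1 mm; speed recovery on a 40 × 40 mm sheet at 0.5 mm
edges (about 50 circles per run, 4 speeds); CI coverage over 500
replications of the 21-map design at 30 circles per map (the fixed-effect
coverage probability is a property of the design, not of the circle
count, and 30 circles per map already puts the Monte Carlo error of a
95% coverage estimate near 1%); chamber-ordering recovery over 40
replications at the full 131 circles per map. The acceptance script
re-runs the same computations from scratch with a user-supplied seed.

## Known limitations

* The estimator assumes one front crossing per circle; re-entry around a
  circle or multiple activations per beat violate it upstream.
* Euclidean clipping slightly overestimates geodesic patch extent on
  strongly curved regions (second-order in curvature × radius).
* Focal activation on curved geometry uses chordal, not geodesic,
  distance; speeds recovered from focal scenarios on ellipsoids are
  approximations by construction.
* The enclosed-volume of a non-watertight map is best-effort and flagged;
  exported chamber surfaces are not guaranteed closed.
* With four animals, between-animal quantities (random-intercept
  variance, the sex contrast) carry few degrees of freedom; the package
  reports them honestly rather than pretending precision.
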