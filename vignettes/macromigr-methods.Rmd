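---
title: "Methods: models, estimators and design choices in macromigr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in macromigr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macromigr)
```

# The measurement problem

Macrophages migrating on two-dimensional extracellular-matrix coatings show
two contrasting phenotypes. On fibronectin they spread, elongate and move
slowly but persistently (mesenchymal-like); on laminin they stay compact,
move several-fold faster, change direction often, and intermittently
"slingshot": the cell elongates, releases its rear, and the body snaps
forward within a single frame, producing an abrupt drop in circularity.
`macromigr` implements the quantitative layer needed to resolve this
contrast from overnight time-lapse movies (one frame every 10 minutes for at
least 16 hours, so a typical movie has 97 frames): cell detection and track
linking, velocity and persistence, circularity morphodynamics and slingshot
counting, confocal ventral-fraction measurement, adhesion ratios, and the
superplot statistics used to compare conditions.

Because the raw movies belong to the originating laboratory, the package
ships a synthetic-data generator whose ground truth is known exactly. Every
estimator in the package is validated against that generator; what this does
and does not establish about real data is discussed at the end.

# The synthetic-data generator

## Persistent random walk with slingshot recoils

Each simulated cell follows a persistent random walk. The heading evolves by
independent Gaussian increments with standard deviation `angular_sd`
(radians/frame) and the cell advances a fixed step of
`mean_step_speed * minutes_per_frame` microns per frame. Positions reflect
at the field boundary (real cells simply leave the field, but reflection
keeps the ground truth complete, which is what the validation needs).
Circularity is `circ_baseline` plus Gaussian noise (`circ_noise_sd`),
clipped to (0, 1]; elongation is derived as 1/C, so a recoiling cell
stretches.

Slingshot events are a per-frame Bernoulli process with probability
`slingshot_rate * minutes_per_frame / 60`. At an event frame the
circularity drops by exactly `slingshot_delta_c` relative to the previous
frame and the step leaving that frame has length `slingshot_step`. The
circularity then ramps back to baseline linearly over `recovery_frames`
(default 4) frames. The ramp is a deliberate choice: a one-frame dip would
produce *two* supra-threshold frame-to-frame changes (the drop and the
rebound), so a single physical recoil would be counted twice downstream.
With the ramp, each event contributes exactly one change of magnitude
`slingshot_delta_c` followed by sub-threshold recovery steps
(`slingshot_delta_c / (recovery_frames + 1)` each, about 0.11 with the
defaults — comfortably below the 0.4 event threshold). New events are
suppressed while a previous one recovers, so the realised event rate is the
renewal rate `p / (1 + p * recovery_frames)` per frame; the tests use this
expression as the expectation.

## The two presets

`fn_mode()` (0.35 µm/min, `angular_sd` 0.35, baseline circularity 0.45, no
slingshots) and `lam_mode()` (1.05 µm/min — 3× faster, `angular_sd` 1.4,
baseline circularity 0.80, 0.6 slingshots/h with a 0.55 circularity drop and
a 20 µm recoil) are artifact defaults chosen to reproduce the *orderings*
of the two phenotypes — faster, less persistent, larger shape change, more
events per cell on laminin — not to match measured magnitudes, which the
source study reports only graphically. The circularity baselines follow the
biology (spread, irregular cells on fibronectin score low; compact round
cells on laminin score high); the slingshot drop of 0.55 sits well above the
0.4 detection threshold so that detection validation is a test of the
pipeline, not of luck with noise.

## Rendering, z-stacks, adhesion fields

`render_movie()` draws each visible cell as an elliptical Gaussian spot of
constant integrated intensity (default 25 intensity-units on the [0, 1]
16-bit scale, sigma 3 px) whose axis ratio encodes the frame's elongation
and whose major axis follows the heading, over a constant background
(default 0.05) with additive Gaussian noise (default sd 0.01). Gaussian
additive noise is the simplest model sufficient for validating
Laplacian-of-Gaussian detection; no photorealistic texture, cell contact,
division or merging is simulated. Cells are omitted per frame with
probability `detection_dropout_prob` to exercise gap closing.

`simulate_zstack()` places `ventral_fraction * total_intensity` in the
bottom slice and splits the remainder evenly among the others, spread over a
disk footprint with per-pixel Gaussian noise. `simulate_adhesion_field()`
removes each pre-wash cell independently with probability `detach_prob`.

All generators take an integer seed and are bit-reproducible; rendering
draws from a stream derived from the same seed so track and movie
reproducibility are independent contracts.

# Detection and linking

## Spot detection

Frames are optionally flattened by subtracting a large-scale Gaussian blur
(`background_sigma`) — the same intent as the bandpass pre-filter commonly
applied before tracking, in a simpler, directly testable form. Detection is
scale-normalised Laplacian-of-Gaussian filtering at sigma =
`spot_diameter` / (2√2), so a blob of the nominal diameter gives the peak
response; 8-neighbour local maxima above `quality_threshold` are kept, and
the centroid is refined to subpixel precision by a separable quadratic fit.
On rendered movies the localization error is ≈ 0.1 px (worst case < 0.35 px
across 50 cells × 97 frames), against a 1 px validation bound.

## LAP linking and gap closing

Linking follows the two-pass linear-assignment formulation. Pass 1 matches
detections in consecutive frames, cost = squared distance, with links longer
than `max_link_distance` forbidden. Pass 2 matches ends of the pass-1
segments to later segment starts (again cost = squared distance, distance ≤
`max_link_distance`, and at most `max_gap_frames` missing frames), then
splices the matched chains. Both passes price the non-link alternative at
b = `max_link_distance`². Minimising total cost is equivalent to a
maximum-weight bipartite matching with edge weights (2b − d²), all strictly
positive for admissible links; this is solved exactly with the Kuhn–Munkres
algorithm (igraph), and the tests verify optimality against brute-force
enumeration on small instances. Edges are supplied in lexicographic
(source, target) order so equal-cost optima resolve deterministically.

Distance thresholds are compared in calibrated units; with the default
calibration of 1 µm/px they coincide numerically with the plugin settings
(70.0 for linking and gap closing, 10-frame maximum gap). One-point
fragments are dropped by default (`keep_singletons = TRUE` retains them as
stubs, used when split behaviour itself is under test).

## Track filters

`filter_tracks()` retains tracks with duration ≥ `min_duration_frames`
(frames spanned, gaps included, default 20), mean speed ≥ `min_mean_speed`
(path length over elapsed frame intervals, gap steps measured end-to-end,
default 2.00) and net displacement ≥ `min_displacement` (default 8.00), all
inclusive ("at least"), matching the settings used to remove dead cells and
debris. The source analysis does not state whether its thresholds were in
px/frame or µm/interval; making the units follow the calibration sidesteps
the ambiguity while keeping the defaults literal.

# Motility metrics

Velocity is the accumulated path length divided by elapsed time between the
first and last frame (µm/min). Persistence is read as *directness*: net
displacement divided by path length, a dimensionless number in [0, 1]. The
"d/T" label could also be read as displacement over time; directness is
adopted because the persistence panels are dimensionless and sit alongside a
separate velocity panel, and the chemotaxis tool that produced them reports
directness. The displacement/time variant remains available via
`track_persistence(t, "displacement_rate")`. A track that never moved has
undefined persistence and is reported `NA`, not 0.

# Shape analysis

## Circularity

Circularity is 4πA/P², clipped at 1. The closed form is exposed as
`circ_index(area, perimeter)` for analytic geometry; for raster masks,
area is the pixel count and the perimeter is measured on a subpixel contour:
the mask is lightly Gaussian-smoothed (sigma 1.2) and the 0.5 iso-level is
traced by marching squares with linear interpolation (saddle cells are
disambiguated by the centre value). Naive pixel-edge perimeters overestimate
by up to 4/π and would bias circularity low — a rasterized disk of radius
30 px would score ≈ 0.6; with the subpixel contour it scores ≥ 0.995. For
very small or very round shapes the estimator can slightly undershoot the
true perimeter, pushing 4πA/P² marginally above 1; the clip at 1.0 keeps
the statistic in its defined range.

## Elongation

Elongation is the square-rooted ratio of the eigenvalues of the region's
second-moment matrix (the equivalent-ellipse axis ratio), ≥ 1, with 1/12
added to each diagonal moment so a single pixel carries its unit-square
footprint rather than collapsing to a point. The acquisition software used
in the original workflow does not document its "elongation" formula, so
values here are on the standard moment-ellipse scale and not comparable to
that software's arbitrary units.

## Shape change and slingshots

`shape_change()` computes sₙ = |Cₙ − Cₙ₊₁| over the analysis window and
their mean. The default window is the first 31 frames (5 h at 10 min/frame),
with a configurable offset, since only "the same timeframes within an
experiment" is specified by the source workflow. `detect_slingshots()`
counts sₙ ≥ threshold with the threshold at 0.4 by default and the
comparison inclusive — a change of exactly 0.4 is an event. Absolute changes
are used (the direction of the jump is not interrogated), consistent with
the |Cₙ − Cₙ₊₁| definition. `events_per_cell()` sums events across a
population and divides by the number of cells, the per-run statistic used
for condition comparisons.

`trace_masks()` provides the semi-automated stand-in for hand-outlining:
per-frame thresholding plus the connected component containing the tracked
centroid. Touching cells that merge into one basin are a documented
limitation, as they are for any wand-style selection.

# Intensity quantifications

The ventral fraction is the integrated in-mask intensity of the lowest
(coverslip-proximal) slice over the total across slices; per-slice fractions
sum to 1 and the statistic is invariant to global intensity scaling. The
ventral slice is *defined* as the first slice in stack order — acquisition
order must be declared, no metadata convention is assumed. Background is
handled by subtracting the per-slice median of a cell-free border strip
(default 4 px) with negative pixels clipped to zero; the source workflow
does not describe background handling, and masked (not whole-frame)
integration is adopted since cells were hand-outlined per slice. Under the
generator's noise conditions the recovered fraction is within ±0.005 of
truth, against a ±0.05 validation bound.

Band densitometry reads "integrated density" as the sum over the box
(area × mean), requires identically sized target and control boxes, and
reports target/control. The adhesion ratio is post-wash count over pre-wash
count, not clipped at 1 — counting noise can legitimately exceed 1 and is
flagged rather than hidden. Saturation ("only unsaturated exposures") is an
acquisition rule, surfaced as a warning when the maximum pixel sits at the
dtype ceiling.

# Statistics

`summarize_superplot()` reports per-(condition, run) mean, SEM (sd/√n, NA
when a run has a single cell) and n, and per-condition grand means computed
as the mean of run means — not the pooled per-cell mean; the two differ
whenever runs are unbalanced, and the tests assert the distinction on a
fixture where they differ.

`compare_groups()` dispatches to the study's four tests: Kruskal–Wallis
with Dunn's post-hoc, Mann–Whitney, Welch t, and one-way ANOVA. Test
selection is an explicit argument: the package does not choose tests from
normality screens. The omnibus tests delegate to base R (`kruskal.test`,
`wilcox.test`, `t.test`, `aov`). Dunn's pairwise z-tests are implemented
in-package (no installed package provides them) with the standard tie
correction, and validated against an independent rank-based recomputation.
The p-adjustment across the pairwise family is not named in the source
methods; Holm is the default, configurable, and recorded in the pipeline
manifest. Following the source reporting convention, tests pool per-cell
values across runs (n = cells); per-run summaries are reported alongside,
and the pseudo-replication caveat of pooled per-cell testing applies here as
it does to the original analysis.

Under null simulations (all four options, n = 50/group, 1,000 replicates)
each option's type-I error at α = 0.05 falls within [0.03, 0.07].

# Numerical and interface conventions

- Coordinates are 0-based pixel centres, x = column, y = row, origin
  top-left; frames are 0-based. CSV schemas: tracks
  `track_id, frame, x, y` (extra columns ignored on read, e.g.
  TrackMate-dialect exports); ground truth adds `circularity, elongation,
  is_slingshot`.
- Movies and stacks are multi-page 16-bit TIFF, page order time (movies) or
  z ascending from ventral (stacks), calibration in a YAML sidecar.
- All thresholds are inclusive where the source says "at least"; the
  slingshot threshold is inclusive at 0.4.
- Every stochastic function takes an explicit integer seed and restores the
  caller's RNG state.
- Degenerate inputs are errors or NA by contract: single-point tracks,
  zero-path persistence, empty or disconnected masks, zero-total stacks,
  zero pre-wash counts.

# Validation scope and problem sizes

The test suite validates each stage against independent oracles:
brute-force assignment enumeration for the LAP solver, an independent
brute-force filter on 1,000 random tracks, closed-form metric values,
moment-oracle elongation, injected-event slingshot counts, binomial
intervals for dropout and adhesion, and recovery of generator parameters by
Monte Carlo (≥ 10⁴ steps at 1% for speed; 3σ bands elsewhere). The
flagship round trip — 50 cells over 97 rendered frames, detection plus
linking against ground truth — recovers 100% of tracks within 1 px. These
sizes were chosen to give the Monte-Carlo assertions comfortable power while
keeping the default suite fast on a laptop.

Passing these tests shows the estimators are correct on data matching the
generator's assumptions: well-separated point-like cells, Gaussian noise,
fixed per-condition migration mode. It does not establish performance on
crowded fields, touching or dividing cells, uneven illumination beyond
smooth backgrounds, or cells that switch modes mid-movie — none of which the
generator emulates, and the last of which nothing in the source study
constrains. Magnitudes produced by the presets (speeds, event rates) are
artifact choices; only their orderings carry meaning.
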