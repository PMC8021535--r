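---
title: "Tissue image cytometry with imic: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue image cytometry with imic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`imic` quantifies cell lineages and their marker coexpression in
multiplexed immunofluorescence images of tissue sections. One acquisition
is a four-channel stack: a DAPI nuclear counterstain (the *master channel*)
plus three cytoplasmic marker channels — AF488 (pancytokeratin, epithelial
cells), eFluor 570 (vimentin, connective-tissue cells) and AF594
(CD45/CD18, leukocytes). The pipeline segments nuclei, grows per-channel
cell masks, gates each cell positive or negative per marker against the
slide's own background, and tabulates the eight marker-combination
populations separately for the epithelial layer and the lamina propria.

This vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic phantom used for validation, and the design
choices made where the procedure left genuine freedom.

## Nuclear segmentation and the 40–100 µm² gate

Nuclei are detected in the DAPI channel by Gaussian smoothing
(`smoothing_sigma_um`, default 0.5 µm), a global threshold (Otsu's method
by default, or a fixed camera-unit value), connected-component labelling,
and a distance-transform watershed that splits touching nuclei.
`min_split_distance_um` (default 2 µm) controls the watershed merge
tolerance: basins whose distance-map depth difference is below half this
value are merged, so structures closer than this are not split; setting it
to 0 disables splitting. On large rasters the watershed runs per connected
component on cropped windows — this is exactly equivalent to a global
watershed because basins can never cross background, and it makes the cost
linear in foreground area.

Sections cut nuclei at marginal sphere segments and project overlapping
nuclei into conglomerates. The *remove labels* gate deletes segmented
events with area outside [`area_min_um2`, `area_max_um2`] = [40, 100] µm²,
keeping biologically plausible nuclei. The interval is closed: the
procedure excludes events *smaller than* 40 and *larger than* 100 µm², so
areas exactly at either bound are retained. The gate necessarily trades
off against sampling bias — cut nuclei of genuinely large cells are
excluded, and merged pairs of small nuclei can survive if their union is
under 100 µm²; the phantom's truth tables make both effects measurable.

## Cell-mask growing

Cytoplasmic immunostaining surrounds and overlaps the nucleus in a 5 µm
section, so per-channel cell masks grow from the nuclear margin both
outward and inward in rings ("growing steps") of `step_width_um`
(default 0.5 µm). Growth stops at a *sudden step* in staining intensity,
at the nucleus centre (inward), at a neighbouring cell, or at the
per-channel `max_growing_steps` limit (outward). Defaults are 2.0 steps
for AF488 and AF594 and 4.0 for eFluor 570: connective-tissue cells are
elongated and vimentin is often sparse immediately at the nuclear
membrane, so the vimentin channel is allowed to search deeper.

The source procedure does not define "sudden step" quantitatively; here it
is a relative drop of `step_drop_fraction` (default 0.5) between
consecutive ring *medians*, the median being robust to single-pixel
outliers. Fractional step counts (the printed "4.0") are interpreted as
fractional physical reach — `max_growing_steps * step_width_um`, with the
final ring truncated by distance — rather than truncated to an integer.
Contested pixels between neighbouring cells go to the nucleus with the
smaller geodesic distance, which keeps each channel's masks pairwise
disjoint; the nearest-nucleus partition is computed with a seeded
geodesic propagation, tiled with a reach-sized margin so the result is
exact at any raster size. The physical width of one growing step in the
original software is unknown; `step_width_um` is exposed and documented as
a free parameter.

## Background and the positivity gate

No background subtraction is applied. Instead, re-running segmentation
with nuclear parameters at zero turns the nucleus-free area of the
analyzed regions into many small *events* (individual pixels by default;
small tiles optionally), whose per-channel median intensity `b` is the
background reference. Note that cytoplasm is part of this area — the
background is the slide's ambient intensity distribution, not a
signal-free ideal.

Each cell's per-channel statistic is the cell/background ratio of its mask
mean `m` to `b`. Two definitions are implemented: the quotient `m/b`
(default) and the relative difference `(m − b)/m`. They are linked by the
strictly increasing map `d = 1 − 1/r`, so any quantile-based threshold
classifies identically under either; the quotient is the default because
realized thresholds are conventionally quoted on that scale (values above
1). The threshold τ per channel is the upper bound of the 95% confidence
interval of the *median* ratio, computed on a 30% simple random sample of
all cells (floor convention, seeded, pooled across the analyzed material);
a cell is positive iff its ratio is *strictly* greater than τ. The CI
defaults to the distribution-free order-statistic interval
`(X(k), X(n−k+1))` with `k` the largest integer such that
`P(Binom(n, 1/2) ≤ k − 1) ≤ 0.025` — no distributional assumption, exact
conservative coverage — with a percentile bootstrap offered for
comparison. Whether the original 95% CI was taken over cells, patients or
bootstrap replicates is not documented; all implemented modes are
labelled, and none is claimed as the original.

This gate has a structural property worth understanding: with thousands of
cells the CI is narrow, so τ sits near the pooled sample's ~52nd
percentile. Classification therefore hinges on where that rank falls
relative to the channel's true positive fraction. When about half the
cells express a marker, the rank lands in the gap between the negative and
positive intensity clusters and recovery is excellent; compositions far
from 50% shift τ into one of the clusters and misclassify the cells
nearest the boundary, in proportion to the rank offset. The acceptance
checks make this visible quantitatively.

Domain-violating cells (non-positive denominators) and cells with an empty
mask are flagged, excluded from threshold estimation, and classified
negative. Multiplying a channel (cells and background) by any positive
constant changes nothing — the quotient gate is scale-invariant — which is
why the optional per-channel normalization hook is a documented no-op by
default.

## Populations and comparisons

The positivity triple maps bijectively onto eight populations
(cytokeratin-single … triple negative). Percentages use all cells of the
same (group, region) stratum as denominator — the epithelium/lamina
propria columns of the standard table only make sense per stratum — and
cells falling outside every tissue polygon (or inside an exclusion) are
reported separately, never silently dropped. Region membership of a cell
straddling a boundary is decided by its nucleus centroid alone. Paired
epithelium-versus-lamina-propria contrasts use the two-sided Wilcoxon
signed-rank test (exact for n ≤ 25 without ties, normal approximation
beyond). Per-population group contrasts use pairwise pooled-variance
two-proportion z-tests, Bonferroni-corrected over the pairs within the
row, flagging the larger-proportion group of each significant pair.
Quartile summaries interpolate linearly (quantile type 7); the original
software's quantile rule is unknown, so the rule is fixed and documented.

## The synthetic phantom

Because no images are deposited with the study this pipeline reproduces,
validation runs on synthetic tissue with full ground truth. The phantom
emulates a pseudostratified respiratory epithelial band (default 15% of
image height) over a lamina-propria block: non-overlapping elliptical
nuclei (axis ratio uniform in [1, 2.5]; near-vertical orientation in the
epithelium, isotropic in the lamina propria) placed by rejection sampling
at 3486 cells/mm², nucleus areas lognormal with median 64 µm² and log-SD
0.09 (matching the reported quartiles 59–67 µm²), pixel size 0.25378 µm,
14-bit intensities. Each cell draws one of the eight lineages from
per-region fractions; the defaults are the normalized per-region group
means of the published population table. Cytokeratin-expressing cells in
the lamina propria cluster around gland centres (12 mm⁻², Gaussian
scatter SD 80 µm), mimicking seromucous glands and deliberately creating
the neighbour-overlap artifacts the growing stage must cope with.
Expressing cells paint lognormal amplitudes (mean 2400 camera units,
CV 0.35 — calibration knobs, not claims about the original tissue) on
cytoplasmic halos 2 µm wide; fibroblast-like lineages (vimentin-positive,
cytokeratin-negative) get halos elongated 4 µm along the major axis to
exercise the deeper eFluor 570 growing limit. Marker channels mix through
a 3×3 spillover matrix (default off-diagonals 0.005), then add diffuse
background (300 camera units in marker channels, 100 in DAPI) and
additive Gaussian noise (SD 50).

What the phantom does *not* emulate: optical point-spread functions, shot
noise (noise is additive Gaussian on Poisson-free means — adequate for
gating logic), 3-D sectioning artifacts, stitching seams, and realistic
autofluorescence spectra. Passing tests therefore demonstrate the
correctness and calibration behaviour of the *analysis*, not robustness to
every acquisition pathology of real slides.

Isotype-control phantoms share the identical nuclear/DAPI content (same
seed, same draws) with markers at background only; single-stain phantoms
carry specific signal in one channel, with the others receiving only
spillover. The spillover check classifies single-stain runs with the
multiplexed run's thresholds (the original's choice between multiplexed
and single-stain thresholds is undocumented; multiplexed is used and
labelled).

## Numerical choices and degenerate inputs

* Coordinates are 0-based with pixel centres at integer positions;
  polygons live in pixel units with closed boundaries (a point on an edge
  is inside). Polygon areas are rasterized pixel counts so mask and
  polygon areas agree exactly and disjoint areas add.
* Blank DAPI rasters segment to an empty label map, not an error; an
  all-nuclear image makes the background unestimable and errors.
* Degenerate ratio samples (all equal) give a zero-width CI; threshold
  samples below 20 cells error rather than produce an unreliable CI.
* Ties in ratios are handled by stable sorting; all sampling is seeded and
  every run is bit-reproducible for a fixed configuration and seed.
* Intensities clip to [0, 16383] with the clipped-pixel count recorded.

## Problem sizes

The shipped test-suite works at desk scale, chosen so each statistical
check has the power it needs and nothing more: constructive fixtures at
tens of micrometres; 0.3–0.8 mm phantoms for determinism, segmentation
fidelity and spillover monotonicity; a 1 × 1 mm balanced-composition
phantom (~3500 cells) for QC; a 1.6 × 1.6 mm phantom (~8900 cells) for
sensitivity/specificity recovery, sized so the threshold's
order-statistic rank noise (≈1/√n of the sample) stays well inside the
5% misclassification budget; and one 2 × 2 mm phantom (~14 000 cells)
for end-to-end population recovery at the study's cell density. The acceptance script reruns the 1 × 1 mm default-composition
pipeline plus the negative-control and spillover checks.

## Known limitations

* The segmentation is the stated method family (smooth → threshold →
  watershed), not a reproduction of the original proprietary
  implementation; its parameters are exposed with logged defaults.
* The median-CI gate is honest but knife-edged for compositions far from
  50% per channel (see above); users analyzing such tissue should inspect
  the threshold's position relative to their intensity histogram.
* Spillover is measured, not corrected: no compensation is applied to
  pixel data.
* Per-lineage intensity distributions in real tissue are unknown; phantom
  signal levels are calibration knobs and recovery rates on phantoms
  should not be read as accuracy claims for any particular stain.
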