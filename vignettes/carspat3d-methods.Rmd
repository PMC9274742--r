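---
title: "Methods: multimodal spatial quantification of T-cell distribution"
author: "carspat3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal spatial quantification of T-cell distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, conventions and
numerical choices — the things a maintainer or reviewer needs to judge what
a passing test suite does and does not establish.

## Coordinate and distance conventions

All volumes are 3D arrays in (z, y, x) order with a physical voxel spacing
per axis. The center of voxel `i` (1-based) lies at `(i − 0.5) · spacing`,
and every distance in the package is Euclidean in physical units, so
anisotropic light-sheet stacks (coarse z, fine xy) are handled without
resampling.

Distance maps use an exact separable Euclidean distance transform
(lower-envelope-of-parabolas algorithm, implemented in C++ with per-axis
spacing). Because a binary mask has no sub-voxel surface, a convention is
needed for where "distance 0" sits. We define: the distance of an interior
voxel is its center-to-center distance to the nearest outside voxel,
*minus half the smallest voxel spacing, floored at zero*. This puts zero
approximately on the mask surface rather than half a voxel inside it, is
symmetric between surface and structure maps, and — crucially — is exactly
reproducible by brute-force enumeration, which is how the test suite
verifies the fast transform on every random mask it tries. Exterior voxels
of a surface map are undefined (`NA`); when a map is *sampled* at point
locations (trilinear interpolation), undefined voxels are treated as 0,
the natural continuation of a distance field across its own zero level
set. Without this, spots within half a voxel of the surface would be
dropped or biased upward.

Mask dilation ("dilated by a factor of 10 voxels") is a Euclidean ball of
radius *n* in index space — the set of voxels whose center-to-center voxel
distance to the region is at most *n*. We read the phrase as radius 10
rather than 10 iterated unit dilations; for a ball element the two differ
only in far-corner voxels (an iterated cross would differ much more). A
physical-distance dilation can be emulated by scaling *n* when spacing is
isotropic; for anisotropic grids the index-space definition is what the
voxel-counting phrasing implies.

When dilated organ regions overlap, each organ keeps its full dilated
region for signal sums (voxels may be double-counted); the number of
multiply-claimed voxels is reported so users can judge the effect. The
alternative — partitioning contested voxels — would make per-organ sums
depend on the set of other organs being quantified.

## The body phantom and organ quantification

The body phantom stands in for a reconstructed bioluminescence volume with
a co-registered anatomical mask. It is deliberately simple: disjoint organ
ellipsoids inside a body ellipsoid; each luminescent source deposits a
known total uniformly over its organ's voxels; the deep-tissue effect is
modeled as a fixed centroid translation (default 3 mm, the scale of a
mouse abdomen) followed by an isotropic Gaussian blur (default σ = 1 mm).
No photon-transport or tomographic modeling is attempted — the workflow
consumes reconstructed volumes, so the phantom only needs to produce the
*failure mode* that dilation compensates: signal displaced out of its
anatomical mask.

Defaults: 0.5 mm voxels on an 80×48×48 grid (a 40×24×24 mm animal),
sources tumor 2·10⁶ / spleen 10⁶ (shifted) / lung 5·10⁵ a.u. At this
spacing the 10-voxel dilation is 5 mm, leaving ~2 mm of margin over the
3 mm shift; the Gaussian tail beyond that margin loses under 2% of the
signal, which is why the ≥95% recovery property is attainable and honest.
The flank tumor bulges out of the body ellipsoid (subcutaneous), so a few
percent of its blurred signal leaves the whole-body region — visible in
the worked example, and a realistic feature, not a bug. The "whole mouse"
region is the body ellipsoid united with the organs; for real data, where
no such truth exists, `organ_signal()` falls back to Otsu thresholding of
the volume, since the vendor's body-segmentation rule is unpublished.

Daily normalization divides each region by the same-day whole-mouse total;
baseline normalization divides each (animal, region) series by its day-0
value. Missing days stay missing — no interpolation. Caliper volumes use
V = ½·L·W² with a swap-and-warn guard when width exceeds length.

## The tumor phantom and LSFM spatial statistics

The tumor phantom emulates a cleared-tumor light-sheet acquisition at
5 µm isotropic voxels (between the 4 µm step size and ~10 µm lateral
sampling of low-zoom acquisitions): an ellipsoidal tumor (default
semi-axes 250/230/210 µm; a 120³ grid), a vessel tree grown as a seeded
branching random walk rasterized as 10 µm tubes, and T cells rendered as
Gaussian blobs with FWHM equal to the cell diameter (default 10 µm) at
peak amplitude 100 over additive Gaussian noise σ = 5 (SNR 20), clipped at
zero. Cell centers are drawn from a voxel-weighted mixture: with weight
`1 − w` from `exp(−d_surface/λ)` (default λ = 50 µm) and with weight `w`
("vessel attraction") from `exp(−d_vessel/λ_v)` (λ_v = 30 µm), then
jittered uniformly within the voxel. An optional hard-core minimum
separation supports detection benchmarks with well-separated cells.

What the phantom does *not* emulate: depth-dependent attenuation,
antibody-penetration gradients, clearing artifacts, stripe shadows, or
anisotropic PSFs. Passing tests therefore show that the *quantification*
is correct on images whose difficulty comes from noise, crowding and
geometry — not that detection would meet the same recall on degraded real
acquisitions.

Spot detection is multiscale Laplacian-of-Gaussian: scales map to
diameters via σ = d/(2√3), probed from the 8 µm minimum up to twice that
by default, plus a *guard scale* at 0.7× the minimum. Candidates are
26-neighborhood maxima of the across-scale maximum response; a candidate
whose best scale is the guard is discarded, which is what enforces "no
cells below 8 µm" — a plain scale cutoff would still respond, weakly, to
smaller objects. Two thresholds apply: a relative one (default 0.1 of the
in-mask response maximum) and a robust per-scale noise floor of 12 MADs of
that scale's response. The MAD estimates the noise background even with
spots present (blobs are sparse); 12 is sized for the extreme-value tail
of a field with millions of correlated voxels — measured noise extremes
reach 11–12 MADs in such volumes, and true 10 µm blobs at SNR 20 sit near
40 MADs, so the floor rejects noise without touching signal down to about
SNR 5. The response (not raw intensity) carries the thresholds because the
zero-clipped noise floor shifts intensity baselines but has zero Laplacian.
Greedy non-maximum suppression within the larger of two candidate radii
removes cross-scale duplicates. Localization is the voxel center of the
response maximum; on the separated-cell phantom the mean error is about
half a voxel.

Vessel segmentation is Otsu thresholding of the in-tumor lectin channel
with removal of 6-connected components under 10 voxels; an explicit
threshold can replace Otsu. This is a deliberate re-implementation of a
"surface detection" feature whose internals are proprietary; equivalence
with the commercial tool is not claimed, only the measurable contract (a
binary vessel mask suitable for distance queries).

Shell histograms bin spot distances into fixed-width shells (default
100 µm, matching the 100 µm bands in which infiltration frequencies are
usually discussed; 25 µm for decay fits). The decay length λ is estimated
by a count-weighted linear fit of `log(count/shell volume)` versus shell
center, with shell volumes measured from the distance map itself — this
removes the geometric bias an uncorrected histogram would have on a
bounded ellipsoid.

The periphery/core split supports two boundary definitions, because the
source description ("equal amounts … assigned to each region" alongside a
periphery-vs-core percentage) is self-contradictory: the default
*equal-volume* mode cuts at the median in-mask surface distance, so the
peripheral shell and the core have the same volume and a uniform cell
population lands 50/50 — making the reported percentage interpretable as
enrichment; a *fixed-depth* mode is provided. Neither is asserted to be
the original tool's rule.

The middle-third profile restricts the channel to the central third of the
tumor's bounding box along the stack axis (slices ⌊n/3⌋+1 … ⌈2n/3⌉),
maximum-projects along that axis, and reads the projection along the line
through the tumor centroid parallel to the longer in-plane axis. A second
*maximum* projection would be wrong here, flattening exactly the
rim-enhanced patterns the profile exists to show — every lateral position
crosses the bright rim — so the center-line read is used instead.

Density classes count neighbors within 100 µm (the order of the
inter-vessel distance at this scale) and bin the counts by sample
quantiles into 5 ordered classes; ties share a class, so a constant count
collapses to one class (e.g. infinite radius).

## The cyclic-IF phantom and single-cell phenotyping

Segmentation uses the published tool settings as its defaults: nucleus
diameter 18–60 px, cytoplasm donut width 11 px, cytoplasm sensitivity
100%, nucleus detection 90%, nucleus separation 70%. The two percentage
knobs have no public definition, so they are mapped onto this package's
own mechanisms and calibrated on the phantom: detection scales the global
Otsu threshold (`thr = otsu · (2 − detection)`, so 100% keeps the plain
Otsu cut and lower values demand brighter nuclei), and separation sets the
distance-map watershed merge tolerance (`tol = (1 − separation) ·
max_diameter/2`: 0 merges touching nuclei, values near 1 split
aggressively). These are calibrated analogues, not vendor equivalents.

The "constrained donut" is approximated geometrically: nucleus labels are
propagated through the dilated footprint (EBImage's `propagate` with a
large regularization, i.e. a Voronoi growth), and each cell's donut is its
propagated region minus its nucleus — rings clipped against neighbors.
The commercial marker-weighted refinement is not reproducible and is
reduced to recording mean marker signal on the constrained ring.

Marker quantification takes the per-cell mean over the donut (membrane
default; nucleus available per marker), transforms to `log2(x+1)`, and
shifts each channel so its background mode is zero — the mode being the
midpoint of the fullest bin of a 64-bin histogram of the per-cell log2
values, since the original mode estimator is unspecified. Outlier
exclusion is a single pass: mean ± 3 SD per channel on QC-passing cells,
flagged if any channel exceeds its interval; zero-spread channels exclude
nothing. The 5.7% excluded in the original tissue data is a property of
that data, not a target; on a Gaussian null the rule excludes the analytic
0.27%. CD3 gating thresholds the mode-centered log2 CD3 with Otsu per
treatment group (mirroring a per-group heuristic choice) or an explicit
value; CD4/CD8 are sub-gated within CD3⁺ by the same rule. The UMAP
embedding (uwot, single-threaded) is deterministic under a fixed seed.

The phantom renders each cell's markers uniformly over its footprint at
`2^ℓ − 1`, so ideal quantification returns exactly ℓ; background
(default 0.5) and noise perturb this by ≲0.1 log2 at the default
population means (lowest mean 3 → `log2(8.5) ≈ 3.09`). Overlapping
footprints are owned by the nearest nucleus *boundary*, matching the
Voronoi clip on the measurement side; population composition is exact
(largest-remainder counts, shuffled), so the default 60/25/15 split makes
"40% CD3⁺" a sharp truth rather than a binomial draw. Real tissue —
out-of-focus light, lint, touching nuclei in 3D section, autofluorescence
— is harder in ways this phantom does not probe; QC regions are accepted
as an input mask, not auto-detected.

## Group statistics and the significance matrix

Two groups are compared by an unpaired two-sided t-test; three or more by
one-way ANOVA. The post-hoc behind the matrix entries is unspecified in
the source description, so the default is pairwise Welch t-tests with no
multiplicity correction — the literal reading of a flat "p < 0.05"
criterion — with Holm and Tukey HSD modes available; Welch is the default
over pooled variance because it is safer for small, possibly unequal
groups (n = 7 per group is typical here). The PSM stores one p-value per
unordered pair, looked up symmetrically; significance is strictly
p < α, so p = 0.05 renders red. Under a simulated null (4 groups of 7,
1000 repeats) the per-pair green rate matches α within Monte-Carlo error
in the uncorrected mode, and is at most α with correction. Pair ordering
in renderings is lexicographic by default (the original comparison order
lives in an unavailable supplement) and configurable.

## Problem sizes and numerical edge cases

Sizes used by the test suite and the acceptance script, chosen to make
Monte-Carlo error small relative to each tolerance: distance/dilation
oracles on 50 and 20 random masks up to 20³; detection benchmarks with 200
hard-core-separated 10 µm cells; decay-length recovery on a 160³ grid
with 340/310/280 µm semi-axes and 2000 cells (the larger tumor roughly
halves the crowding-induced spot-merging bias relative to the 120³
default); attraction contrast at n = 500 per arm; 10⁵ draws for the
outlier null; 300 cells on a 1000² field for the end-to-end cyc-IF check;
1000 null repeats for PSM calibration.

Edge-case policies, all tested: empty spot sets give empty histograms
(n = 0, no normalization) and refuse a periphery/core split; a mask
covering the whole grid has no surface and errors; all-equal intensity
distributions make Otsu undefined — vessel segmentation warns and returns
an empty mask, CD3 auto-gating errors and asks for an explicit threshold;
sd = 0 channels exclude no outliers; degenerate color ramps map to the
midpoint; unplaceable cell counts error with the achieved count; fewer
spots than density classes collapse to one class with a warning.

## Known limitations

* Phantoms validate quantification, not acquisition robustness (no PSFs,
  attenuation, stripes, or clearing artifacts).
* The dilation overlap policy can double-count signal between adjacent
  dilated organs; inspect `overlap_voxels` when organs are close.
* Spot detection reports the LoG scale as the radius estimate; for
  Gaussian-profile cells this underestimates the rendered FWHM radius and
  should be read as a scale, not a measured size.
* The vendor mappings (nucleus detection/separation percentages,
  constrained donut, "surface detection") are calibrated analogues;
  numerical equivalence with the commercial tools is not claimed.
* Decay-length estimation assumes a monotone exponential bias from the
  surface; mixtures with strong vessel attraction need the two-component
  story, not a single λ.
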