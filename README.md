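# carspat3d

Multimodal spatial quantification of (CAR) T-cell distribution for
preclinical imaging studies. The package re-implements, as tested and
reusable R functions, the quantification layer of a typical CAR T cell
monitoring workflow across three modalities:

1. **3D bioluminescence tomography (BLT)** — per-organ quantification of
   reconstructed luminescence volumes against µCT-derived organ masks, with
   spherical fallback segmentation (e.g. a 10 mm spleen sphere), Euclidean
   mask dilation to compensate the apparent displacement of light emerging
   from deep tissue ("dilated by 10 voxels"), daily whole-mouse
   normalization, day-0 fold changes, and caliper
   (V = ½·L·W²) and µCT tumor volumes.
2. **Light-sheet fluorescence microscopy (LSFM)** — single-cell spatial
   analysis of cleared tumors: tumor masking, Otsu vessel segmentation,
   multiscale Laplacian-of-Gaussian spot detection with a minimum cellular
   diameter of 8 µm, anisotropy-aware Euclidean distance transforms,
   distance-to-surface and distance-to-vessel shell histograms,
   periphery/core partition, local-density classes, and middle-third
   maximum-projection gray-value profiles.
3. **2D cyclic immunofluorescence** — nucleus segmentation (18–60 px
   diameter), Voronoi-constrained cytoplasm donuts (11 px), per-marker
   `log2(x+1)` intensities with the background mode shifted to 0, 3×SD
   outlier exclusion, CD3/CD4/CD8 gating, per-population marker
   distributions, and a UMAP embedding.
4. **Group statistics** — unpaired t-tests / one-way ANOVA with all-pairs
   post hocs rendered as a **pairwise significance matrix** (PSM): one box
   per pair, green where p < 0.05, red otherwise.

Every stage is driven by a **synthetic phantom generator** with exact
ground truth (a mouse-body phantom with known per-organ signal, an
ellipsoidal tumor with a branching vessel tree and a distance-biased
T-cell point process, and a 2D multi-population cell image), so the whole
pipeline runs and validates itself with no external data.

## The quantities at the core

* Organ signal: `S(o) = Σ_{v ∈ dilated(o)} I(v)`, normalized per day to
  the whole-mouse total, `f(o) = S(o) / S(body)`; dilation is a Euclidean
  ball of radius *n* voxels in index space.
* Infiltration depth: the anisotropic Euclidean distance transform
  `d(v) = max(0, min_{b ∉ T} ‖c(v) − c(b)‖ − s_min/2)` (voxel centers,
  physical units), read at detected spot positions and binned into shells;
  an exponential decay `ρ(d) ∝ exp(−d/λ)` fitted with shell-volume
  correction recovers the decay length λ.
* Spot detection: scale-normalized LoG response `−σ²∇²(G_σ ∗ I)` maximized
  over scales `σ = d/(2√3)` for diameters from 8 µm up, 26-neighborhood
  maxima, a robust per-scale noise floor, and greedy non-maximum
  suppression.

## Worked example

Generate the default body phantom (three luminescent sources with known
totals: tumor 2·10⁶, spleen 10⁶ with a 3 mm ventral shift, lung 5·10⁵),
quantify with the organ masks, and normalize:

```r
library(carspat3d)
ph  <- make_body_phantom(body_phantom_spec())
sig <- organ_signal(ph$volume, ph$mask,
                    dilation = c(spleen = 10, lung = 10), body = ph$body)
sig
#>        region label dilation_voxels n_voxels raw_signal
#> 1       tumor     1               0     1072    1268253
#> 2      spleen     2              10    18504     998231
#> 3       liver     3               0     1224       1080
#> 4        lung     4              10    24912     851351
#> 5 whole_mouse    NA              NA    87381    2986120

tab <- data.frame(animal = "phantom", day = 0,
                  region = sig$region, raw_signal = sig$raw_signal)
normalize_daily(tab)[, c("region", "normalized_signal")]
#>        region normalized_signal
#> 1       tumor          0.424716
#> 2      spleen          0.334290
#> 3       liver          0.000362
#> 4        lung          0.285103
#> 5 whole_mouse          1.000000
```

Reading the numbers: the spleen source was shifted 3 mm and blurred by the
1 mm optical kernel, so the undilated spleen mask captures only ~28% of
its true 10⁶ signal — the 10-voxel (5 mm) dilation recovers 99.8%
(`998231`). The tumor sits at the body surface, so part of its blurred
signal leaves the undilated mask and the whole-body region; the dilated
lung region overlaps the adjacent flank tumor and illustrates the
double-counting policy for overlapping dilated organs (reported via the
`overlap_voxels` attribute).

The LSFM and cyclic-IF stages follow the same pattern; see
`?make_tumor_phantom`, `?detect_spots`, `?spot_distance_histogram`,
`?segment_cells` and the methods vignette
(`vignettes/carspat3d-methods.Rmd`).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/carspat3d.R simulate tumor --out sim --seed 1
Rscript inst/cli/carspat3d.R lsfm --cd3 sim/cd3.tif --lectin sim/lectin.tif \
        --tumor-mask sim/tumor_mask.tif --out out
```

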