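#' Dilate one organ region of a label mask
#'
#' Expands the named organ to all voxels within Euclidean index-space
#' distance `n_voxels` of its original region (a spherical structuring
#' element of radius `n_voxels`, counted center-to-center in voxels, i.e.
#' independent of physical spacing). This implements the dilation used to
#' compensate the apparent displacement of bioluminescent signal emerging
#' from deep tissue. Other labels are left untouched; where the dilated
#' region would run into another organ's voxels, those voxels keep their
#' original label in the returned mask, and the full (overlapping) dilated
#' region is recorded in the `"regions"` attribute so that signal sums can
#' count it — overlapping voxels may then be counted for both organs, which
#' is flagged in [organ_signal()] output.
#'
#' @param mask a [label_mask()].
#' @param organ organ name (or label value) to dilate.
#' @param n_voxels non-negative dilation radius in voxels.
#' @return a [label_mask()]; attribute `"regions"` holds the dilated
#'   logical region.
#' @export
dilate_mask <- function(mask, organ, n_voxels) {
  stopifnot(inherits(mask, "label_mask"))
  if (n_voxels < 0) stop("n_voxels must be >= 0")
  reg <- region_mask(mask, organ)  # errors for unknown organ
  dil <- dilate_region(reg, n_voxels)
  lab <- if (is.character(organ)) mask$labels[[organ]] else as.integer(organ)
  out <- mask$data
  out[dil & out == 0L] <- lab
  res <- label_mask(out, mask$spacing, labels = mask$labels,
                    unit = mask$unit)
  attr(res, "regions") <- setNames(list(dil),
                                   if (is.character(organ)) organ
                                   else names(mask$labels)[match(lab, mask$labels)])
  res
}

# Euclidean ball dilation in index space: voxels within center-to-center
# voxel distance <= n of the region.
dilate_region <- function(region, n_voxels) {
  if (n_voxels == 0 || !any(region)) return(region)
  d2 <- sq_edt(!region, c(1, 1, 1))
  d2 <= n_voxels^2 + 1e-9
}

#' Spherical segmentation in physical coordinates
#'
#' Marks all voxels whose physical centers lie within `radius_mm` of a seed
#' point — the fallback used for organs without soft-tissue contrast (the
#' workflow segments spleens as a 10 mm sphere).
#'
#' @param center_mm physical (z, y, x) center in the grid's units.
#' @param radius_mm sphere radius (> 0).
#' @param grid a [volume_image()] or [label_mask()] supplying grid and
#'   spacing.
#' @param name region name for the resulting mask.
#' @return a single-label [label_mask()] with provenance metadata.
#' @export
sphere_segment <- function(center_mm, radius_mm, grid, name = "sphere") {
  if (radius_mm <= 0) stop("radius must be > 0")
  gs <- dim(grid$data)
  sp <- grid$spacing
  extent <- gs * sp
  if (any(center_mm < 0) || any(center_mm > extent))
    stop("sphere center lies outside the grid")
  ax <- lapply(1:3, function(a) ((seq_len(gs[a]) - 0.5) * sp[a] -
                                   center_mm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  m <- label_mask(array(as.integer(d2 <= radius_mm^2), gs), sp,
                  labels = setNames(1L, name), unit = grid$unit %||% "mm")
  attr(m, "provenance") <- list(type = "sphere", center = center_mm,
                                radius = radius_mm)
  m
}

#' Per-organ integrated signal with dilation compensation
#'
#' Sums voxel intensities over each organ region (each dilated independently
#' by its entry in `dilation`, so regions may overlap after dilation and
#' double-count shared voxels — reported in the `overlap_voxels` attribute),
#' plus a `whole_mouse` row summed over the body region.
#'
#' @param volume a [volume_image()].
#' @param seg a [label_mask()] of organs on the same grid.
#' @param dilation named integer vector of per-organ dilation radii in
#'   voxels (missing organs get 0).
#' @param body body region for the whole-mouse sum: a logical array on the
#'   same grid, or `NULL` to threshold `volume` with Otsu's method (the
#'   vendor rule for "the segmented mouse" is unspecified; thresholding is
#'   this package's default).
#' @return data.frame with columns `region`, `label`, `dilation_voxels`,
#'   `n_voxels`, `raw_signal`; attribute `overlap_voxels` counts voxels
#'   claimed by more than one (dilated) organ.
#' @export
organ_signal <- function(volume, seg, dilation = NULL, body = NULL) {
  stopifnot(inherits(volume, "volume_image"), inherits(seg, "label_mask"))
  stop_if_grid_mismatch(volume, seg)
  dilation <- dilation %||% integer()
  regions <- lapply(names(seg$labels), function(nm) {
    n <- if (nm %in% names(dilation)) as.integer(dilation[[nm]]) else 0L
    dilate_region(region_mask(seg, nm), n)
  })
  names(regions) <- names(seg$labels)

  if (is.null(body)) {
    thr <- otsu_threshold(as.numeric(volume$data))
    body <- if (is.na(thr)) array(TRUE, dim(volume$data))
            else volume$data > thr
  }
  if (!is.logical(body) || !identical(dim(body), dim(volume$data)))
    stop("`body` must be a logical array on the volume grid")

  sums <- vapply(regions, function(r) sum(volume$data[r]), 0)
  nvox <- vapply(regions, sum, 0L)
  dil <- vapply(names(regions), function(nm)
    if (nm %in% names(dilation)) as.integer(dilation[[nm]]) else 0L, 0L)

  out <- data.frame(
    region = c(names(regions), "whole_mouse"),
    label = c(as.integer(seg$labels), NA_integer_),
    dilation_voxels = c(dil, NA_integer_),
    n_voxels = c(nvox, sum(body)),
    raw_signal = c(sums, sum(volume$data[body])),
    row.names = NULL)
  cover <- Reduce(`+`, lapply(regions, as.integer))
  attr(out, "overlap_voxels") <- sum(cover > 1L)
  out
}

#' Normalize organ signal to the whole-mouse total of the same day
#'
#' For every (animal, day), divides each region's raw signal by the
#' `whole_mouse` raw signal measured that day, so organ values become
#' fractions of total body signal and the whole-mouse value becomes 1.
#'
#' @param table data.frame with columns `animal`, `day`, `region`,
#'   `raw_signal` (and optionally `group`); must contain a `whole_mouse`
#'   region per (animal, day).
#' @param whole_region region name holding the total (default
#'   `"whole_mouse"`).
#' @return the table with a `normalized_signal` column appended.
#' @export
normalize_daily <- function(table, whole_region = "whole_mouse") {
  need <- c("animal", "day", "region", "raw_signal")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(table$day < 0)) stop("days must be non-negative")
  key <- interaction(table$animal, table$day, drop = TRUE)
  out <- table
  out$normalized_signal <- NA_real_
  for (k in levels(key)) {
    rows <- which(key == k)
    wm <- rows[table$region[rows] == whole_region]
    if (length(wm) != 1 || !is.finite(table$raw_signal[wm]) ||
        table$raw_signal[wm] <= 0)
      stop("missing or non-positive '", whole_region, "' record for animal ",
           table$animal[rows[1]], ", day ", table$day[rows[1]])
    out$normalized_signal[rows] <- table$raw_signal[rows] /
      table$raw_signal[wm]
  }
  out
}

#' Normalize a longitudinal series to its baseline day
#'
#' Fold change of each (animal, region) series relative to its own value on
#' `baseline_day`; the baseline value becomes 1.
#'
#' @param table data.frame with columns `animal`, `day`, `region`,
#'   `raw_signal`.
#' @param baseline_day day used as reference (default 0).
#' @return the table with a `normalized_signal` column appended.
#' @export
normalize_to_baseline <- function(table, baseline_day = 0) {
  need <- c("animal", "day", "region", "raw_signal")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(table$animal, table$region, drop = TRUE)
  out <- table
  out$normalized_signal <- NA_real_
  for (k in levels(key)) {
    rows <- which(key == k)
    b <- rows[table$day[rows] == baseline_day]
    if (length(b) != 1 || !is.finite(table$raw_signal[b]) ||
        table$raw_signal[b] <= 0)
      stop("missing or non-positive baseline (day ", baseline_day,
           ") for animal ", table$animal[rows[1]], ", region ",
           table$region[rows[1]])
    out$normalized_signal[rows] <- table$raw_signal[rows] /
      table$raw_signal[b]
  }
  out
}

#' Caliper tumor volume
#'
#' The standard ellipsoid approximation from two caliper measurements:
#' `V = 1/2 * length * width^2`. If `width > length` the two are swapped
#' with a warning (the formula assumes length is the larger axis).
#'
#' @param length_mm,width_mm caliper measurements in mm (vectorized).
#' @return tumor volume(s) in mm^3.
#' @examples
#' caliper_volume(6, 5)  # 75
#' @export
caliper_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0))
    stop("caliper measurements must be positive")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); swapping")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Tumor volume from a CT label mask
#'
#' Voxel count of the tumor label times the physical voxel volume.
#'
#' @param mask a [label_mask()].
#' @param label tumor region name or label value (default `"tumor"`).
#' @return volume in cubic grid units (mm^3 for mm-spaced grids); 0 with a
#'   warning if the label is absent from the mask.
#' @export
ct_tumor_volume <- function(mask, label = "tumor") {
  stopifnot(inherits(mask, "label_mask"))
  lab <- if (is.character(label)) {
    if (!label %in% names(mask$labels)) {
      warning("label '", label, "' absent from mask; returning 0")
      return(0)
    }
    mask$labels[[label]]
  } else as.integer(label)
  n <- sum(mask$data == lab)
  if (n == 0) warning("tumor label has no voxels; returning 0")
  n * prod(mask$spacing)
}
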