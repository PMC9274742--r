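#' 3D intensity volume with physical voxel spacing
#'
#' The basic container for reconstructed bioluminescence volumes and
#' light-sheet channels: a 3D numeric array plus the physical size of a voxel
#' along each axis. Axis order is (z, y, x) and the physical coordinate of
#' the center of voxel `i` (1-based) along an axis is `(i - 0.5) * spacing`.
#' All distances computed by the package are Euclidean in these physical
#' units and respect anisotropic spacing.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param spacing voxel size per axis (z, y, x) in physical units; a scalar
#'   is recycled. Must be positive.
#' @param unit name of the physical unit, e.g. `"mm"` or `"um"`; carried as
#'   metadata only.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, unit = "um") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  structure(list(data = data, spacing = spacing, unit = unit),
            class = "volume_image")
}

#' Integer label volume on a voxel grid
#'
#' Names organs, tumor or vessels on the same grid as a [volume_image()].
#' Label 0 is background; positive labels map to region names.
#'
#' @param data 3D integer array (z, y, x); 2D input is promoted to a
#'   single-slice 3D array.
#' @param spacing voxel size per axis, as in [volume_image()].
#' @param labels named integer vector mapping region names to label values;
#'   defaults to `region_<k>` for each positive label present.
#' @param unit physical unit name.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(data, spacing, labels = NULL, unit = "um") {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 2D or 3D integer array")
  storage.mode(data) <- "integer"
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  present <- sort(unique(data[data > 0L]))
  if (is.null(labels)) {
    labels <- if (length(present) == 0) setNames(integer(0), character(0))
              else setNames(as.integer(present), paste0("region_", present))
  } else {
    labels <- setNames(as.integer(labels), names(labels))
    if (anyDuplicated(labels) || any(labels <= 0L))
      stop("labels must be unique positive integers")
    if (!all(present %in% labels))
      stop("mask contains label values not described in `labels`")
  }
  structure(list(data = data, spacing = spacing, labels = labels,
                 unit = unit), class = "label_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (z,y,x) = ",
      paste(signif(x$spacing, 4), collapse = ", "), " ", x$unit,
      "\n  intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (z,y,x) = ",
      paste(signif(x$spacing, 4), collapse = ", "), " ", x$unit, "\n", sep = "")
  for (nm in names(x$labels)) {
    cat("  ", nm, " (label ", x$labels[[nm]], "): ",
        sum(x$data == x$labels[[nm]]), " voxels\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' @export
dim.label_mask <- function(x) dim(x$data)

# Logical mask for one region (by name or label value).
region_mask <- function(mask, region) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.character(region)) {
    if (!region %in% names(mask$labels))
      stop("unknown region '", region, "'")
    lab <- mask$labels[[region]]
  } else {
    lab <- as.integer(region)
  }
  mask$data == lab
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("volume and mask are not on the same grid ",
         "(dimensions or voxel spacing differ)")
  invisible(TRUE)
}

# Physical center coordinates (z,y,x) of the voxels selected by a logical
# array or index vector; returns an n x 3 matrix.
voxel_centers <- function(which_vox, grid_shape, spacing) {
  idx <- if (is.logical(which_vox)) which(which_vox) else as.integer(which_vox)
  ai <- arrayInd(idx, .dim = grid_shape)
  sweep(ai - 0.5, 2, spacing, `*`)
}

# Trilinear interpolation of a 3D array at physical points (n x 3, (z,y,x)).
# Points outside the grid's physical extent give NA.
trilinear_sample <- function(arr, spacing, pts) {
  d <- dim(arr)
  g <- sweep(pts, 2, spacing, `/`) + 0.5  # continuous 1-based voxel index
  out <- rep(NA_real_, nrow(pts))
  ext_lo <- sweep(pts, 2, rep(0, 3), `<`)
  ext_hi <- sweep(pts, 2, d * spacing, `>`)
  inside <- !apply(ext_lo | ext_hi, 1, any)
  if (!any(inside)) return(out)
  g <- g[inside, , drop = FALSE]
  i0 <- pmax(1L, pmin(d[col(g)] - 1L, floor(g)))
  dim(i0) <- dim(g)
  fr <- g - i0
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  acc <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cz) fr[, 1] else 1 - fr[, 1]) *
         (if (cy) fr[, 2] else 1 - fr[, 2]) *
         (if (cx) fr[, 3] else 1 - fr[, 3])
    v <- arr[cbind(i0[, 1] + cz, i0[, 2] + cy, i0[, 3] + cx)]
    acc <- acc + w * v
  }
  out[inside] <- acc
  out
}

#' Read / write volumes and label masks
#'
#' NIfTI files (`.nii`, `.nii.gz`) carry voxel spacing in their `pixdim`
#' header. Multi-page TIFF files cannot hold arbitrary metadata through
#' [tiff::writeTIFF()], so spacing (and the intensity scale used to map data
#' into the TIFF's unit range) is written to a JSON sidecar
#' `<file>.meta.json` and read back transparently.
#'
#' @param x a [volume_image()] or [label_mask()].
#' @param path output file; format chosen by extension.
#' @return `read_volume` returns a `volume_image` (or `label_mask` when the
#'   sidecar marks the file as a label image); `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(x, path) {
  is_label <- inherits(x, "label_mask")
  arr <- x$data
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, x$spacing)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    mx <- max(arr)
    scale <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(spacing = x$spacing, unit = x$unit, scale = scale,
                 kind = if (is_label) "label" else "intensity")
    if (is_label) meta$labels <- as.list(x$labels)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param spacing fallback voxel spacing when the file carries none.
#' @param unit fallback unit name.
#' @export
read_volume <- function(path, spacing = NULL, unit = "um") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img), dim = dim(img))
    return(volume_image(arr, spacing %||% sp, unit = unit))
  }
  if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1]]))
    arr <- array(0, dim = d)
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    side <- paste0(path, ".meta.json")
    meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                       simplifyVector = TRUE)
            else list()
    arr <- arr * (meta$scale %||% 1)
    sp <- spacing %||% meta$spacing %||% c(1, 1, 1)
    if (identical(meta$kind, "label")) {
      labs <- unlist(meta$labels)
      return(label_mask(array(as.integer(round(arr)), dim = d), sp,
                        labels = labs, unit = meta$unit %||% unit))
    }
    return(volume_image(arr, sp, unit = meta$unit %||% unit))
  }
  stop("unsupported volume format: ", path)
}
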