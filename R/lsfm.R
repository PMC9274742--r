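#' Zero all voxels outside the tumor mask
#'
#' @param volume a [volume_image()].
#' @param tumor_mask a [label_mask()] on the same grid.
#' @return a [volume_image()] with out-of-mask voxels set to exactly 0.
#' @export
apply_tumor_mask <- function(volume, tumor_mask) {
  stopifnot(inherits(volume, "volume_image"),
            inherits(tumor_mask, "label_mask"))
  stop_if_grid_mismatch(volume, tumor_mask)
  out <- volume$data
  out[tumor_mask$data == 0L] <- 0
  volume_image(out, volume$spacing, unit = volume$unit)
}

#' Segment vasculature from the lectin channel
#'
#' Binary vessel mask inside the tumor: thresholding of in-mask voxels
#' (Otsu by default, or an explicit value) followed by removal of connected
#' components (6-connectivity) smaller than `min_component_voxels`.
#'
#' @param lectin_channel a [volume_image()] (vessel stain).
#' @param tumor_mask a [label_mask()] on the same grid.
#' @param threshold explicit intensity threshold (voxels `>= threshold` are
#'   vessel), or `NULL` for Otsu on in-mask voxels.
#' @param min_component_voxels minimum component size kept (default 10).
#' @return a [label_mask()] with a single `vessel` label (possibly empty,
#'   with a warning).
#' @export
segment_vessels <- function(lectin_channel, tumor_mask, threshold = NULL,
                            min_component_voxels = 10L) {
  masked <- apply_tumor_mask(lectin_channel, tumor_mask)
  inmask <- tumor_mask$data > 0L
  if (!any(inmask)) stop("tumor mask is empty")
  if (is.null(threshold)) {
    threshold <- otsu_threshold(masked$data[inmask])
    if (is.na(threshold)) {
      warning("degenerate intensity distribution; returning empty vessel mask")
      return(label_mask(array(0L, dim(masked$data)), masked$spacing,
                        labels = c(vessel = 1L)))
    }
  }
  bin <- masked$data >= threshold & inmask
  if (!any(bin)) {
    warning("no voxel above the vessel threshold; returning empty mask")
    return(label_mask(array(0L, dim(masked$data)), masked$spacing,
                      labels = c(vessel = 1L)))
  }
  bin <- filter_small_components(bin, min_component_voxels)
  m <- label_mask(array(as.integer(bin), dim(bin)), masked$spacing,
                  labels = c(vessel = 1L), unit = masked$unit)
  attr(m, "threshold") <- threshold
  m
}

# Drop 6-connected components smaller than min_size. Frontier-growing BFS
# with vectorized shifts; adequate for sparse structures like vessel trees.
filter_small_components <- function(bin, min_size) {
  if (min_size <= 1L || !any(bin)) return(bin)
  d <- dim(bin)
  lab <- array(0L, d)
  cur <- 0L
  todo <- which(bin & lab == 0L)
  while (length(todo) > 0) {
    cur <- cur + 1L
    frontier <- array(FALSE, d)
    frontier[todo[1]] <- TRUE
    comp <- frontier
    repeat {
      grown <- grow6(frontier) & bin & !comp
      if (!any(grown)) break
      comp <- comp | grown
      frontier <- grown
    }
    lab[comp] <- cur
    todo <- which(bin & lab == 0L)
  }
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  keep <- which(sizes >= min_size)
  array(lab %in% keep & bin, d)
}

grow6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Detect cell-sized spots in a 3D channel
#'
#' Multiscale Laplacian-of-Gaussian blob detection restricted to scales at
#' or above the minimum cellular diameter (default 8 µm), with 26-neighbor
#' local-maximum selection and greedy non-maximum suppression. A guard
#' scale below the minimum diameter absorbs sub-minimum blobs: candidates
#' whose response peaks at the guard scale are discarded, so objects smaller
#' than `min_diameter_um` yield no spots. Spots outside the tumor mask are
#' dropped; coordinates are physical voxel centers.
#'
#' @param cd3_channel a [volume_image()] (T-cell stain).
#' @param tumor_mask a [label_mask()] on the same grid.
#' @param min_diameter_um smallest detectable cell diameter (default 8).
#' @param max_diameter_um largest scale probed (default `2 * min`).
#' @param n_scales number of scales from min to max diameter.
#' @param intensity_rel_threshold candidates must reach at least this
#'   fraction of the in-mask maximum of the scale-normalized blob response
#'   (default 0.1). The response is used rather than raw intensity because
#'   it is zero-mean under flat backgrounds, making the relative cut robust
#'   to baseline offsets (e.g. autofluorescence or clipped noise floors).
#'   A robust per-scale noise floor of `noise_nsigma` MADs of that scale's
#'   in-mask response is applied in addition, so noise extremes are not
#'   detected even when no brighter structure dominates the maximum.
#' @param noise_nsigma noise-floor multiplier (default 12, sized for the
#'   extreme-value tail of millions of correlated response voxels).
#' @return a [spot_set()] with provenance `"detected"`.
#' @export
detect_spots <- function(cd3_channel, tumor_mask, min_diameter_um = 8,
                         max_diameter_um = 2 * min_diameter_um,
                         n_scales = 4L, intensity_rel_threshold = 0.1,
                         noise_nsigma = 12) {
  stopifnot(inherits(cd3_channel, "volume_image"))
  if (min_diameter_um <= 0) stop("min_diameter_um must be > 0")
  sp <- cd3_channel$spacing
  if (any(sp > min_diameter_um))
    stop("voxel spacing (", paste(signif(sp, 3), collapse = ", "),
         ") is coarser than min_diameter_um along at least one axis; ",
         "such cells are undetectable")
  masked <- apply_tumor_mask(cd3_channel, tumor_mask)
  inmask <- tumor_mask$data > 0L
  d <- dim(masked$data)

  diams <- c(0.7 * min_diameter_um,
             seq(min_diameter_um, max_diameter_um, length.out = n_scales))
  sigmas <- diams / (2 * sqrt(3))

  best_resp <- array(-Inf, d)
  best_scale <- array(0L, d)
  best_sm <- array(0, d)
  scale_mad <- numeric(length(sigmas))
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    sm <- gaussian_blur3(masked$data, s / sp)
    resp <- -s^2 * laplacian3(sm, sp)
    scale_mad[k] <- mad(resp[inmask])
    upd <- resp > best_resp
    best_resp[upd] <- resp[upd]
    best_scale[upd] <- k
    best_sm[upd] <- sm[upd]
  }

  is_max <- array(cpp_local_max3(as.numeric(best_resp), d), d)
  # per-scale robust noise floor: blobs are sparse, so the MAD of each
  # scale's response estimates its noise background even with spots present
  floor_k <- noise_nsigma * scale_mad
  resp_thr <- pmax(intensity_rel_threshold * max(best_resp[inmask]),
                   floor_k[pmax(best_scale, 1L)])
  dim(resp_thr) <- d
  cand <- which(is_max & inmask & best_resp > 0 & best_scale > 1L &
                  best_resp >= resp_thr)
  if (length(cand) == 0)
    return(spot_set(matrix(numeric(), ncol = 3), provenance = "detected"))

  resp <- best_resp[cand]
  ord <- order(resp, decreasing = TRUE)
  cand <- cand[ord]
  coords <- voxel_centers(cand, d, sp)
  radius <- sigmas[best_scale[cand]] * sqrt(3)

  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    if (!keep[i]) next
    if (i < length(cand)) {
      j <- (i + 1):length(cand)
      d2 <- colSums((t(coords[j, , drop = FALSE]) - coords[i, ])^2)
      lim <- pmax(radius[i], radius[j])
      keep[j[d2 <= lim^2]] <- FALSE
    }
  }
  spot_set(coords[keep, , drop = FALSE], radius_um = radius[keep],
           intensity = best_sm[cand][keep], provenance = "detected")
}

# Finite-difference Laplacian with physical spacing (replicated boundary).
laplacian3 <- function(a, spacing) {
  d <- dim(a)
  out <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    if (ax == 1) dd <- a[ip, , ] + a[im, , ] - 2 * a
    else if (ax == 2) dd <- a[, ip, ] + a[, im, ] - 2 * a
    else dd <- a[, , ip] + a[, , im] - 2 * a
    out <- out + dd / spacing[ax]^2
  }
  out
}

#' Shell histogram of spot distances
#'
#' Samples a distance map at the spot centers (trilinear interpolation),
#' bins the distances into fixed-width shells starting at 0, and normalizes
#' to relative frequency — the representation used for infiltration-depth
#' and vessel-proximity profiles.
#'
#' @param spots a [spot_set()].
#' @param dmap a `distance_map` (see [distance_to_surface()]).
#' @param bin_width_um shell width in µm (default 100).
#' @return a `shell_histogram`: list with `bin_edges`, `counts`,
#'   `relative_frequency`, `n_total`, `distances`, `reference`. Empty spot
#'   sets give `n_total = 0` and no bins.
#' @export
spot_distance_histogram <- function(spots, dmap, bin_width_um = 100) {
  stopifnot(inherits(spots, "spot_set"), inherits(dmap, "distance_map"))
  if (nrow(spots) == 0) {
    return(structure(list(bin_edges = numeric(0), counts = integer(0),
                          relative_frequency = numeric(0), n_total = 0L,
                          distances = numeric(0), reference = dmap$reference),
                     class = "shell_histogram"))
  }
  dist <- sample_distance_map(dmap, spot_coords(spots))
  if (anyNA(dist)) {
    warning(sum(is.na(dist)), " spot(s) outside the mapped region dropped")
    dist <- dist[!is.na(dist)]
  }
  edges <- seq(0, max(bin_width_um, ceiling(max(dist) / bin_width_um) *
                        bin_width_um), by = bin_width_um)
  counts <- tabulate(findInterval(dist, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 relative_frequency = counts / sum(counts),
                 n_total = length(dist), distances = dist,
                 reference = dmap$reference),
            class = "shell_histogram")
}

#' @export
print.shell_histogram <- function(x, ...) {
  cat("<shell_histogram> reference:", x$reference, "| n =", x$n_total, "\n")
  if (x$n_total > 0) {
    df <- data.frame(from = x$bin_edges[-length(x$bin_edges)],
                     to = x$bin_edges[-1], count = x$counts,
                     rel_freq = round(x$relative_frequency, 4))
    print(head(df, 10))
  }
  invisible(x)
}

#' Distances of spots to the vessel surface
#'
#' Computes the vessel-surface distance map and bins spot distances with
#' the same contract as [spot_distance_histogram()].
#'
#' @param spots a [spot_set()].
#' @param vessel_mask a [label_mask()]; must be non-empty.
#' @param bin_width_um shell width in µm.
#' @export
spot_vessel_distances <- function(spots, vessel_mask, bin_width_um = 100) {
  stopifnot(inherits(vessel_mask, "label_mask"))
  if (!any(vessel_mask$data > 0L)) stop("vessel mask is empty")
  dmap <- distance_to_structure(vessel_mask)
  spot_distance_histogram(spots, dmap, bin_width_um)
}

#' Partition spots into tumor periphery and core
#'
#' Classifies each spot by its distance to the tumor surface. Two boundary
#' definitions are supported: `"equal_volume"` (default) places the cut at
#' the median in-mask surface distance, so the peripheral shell and the
#' core have equal volume; `"fixed"` uses an explicit depth in µm.
#'
#' @param tumor_mask a [label_mask()].
#' @param spots a [spot_set()]; must be non-empty.
#' @param boundary_distance_um depth of the peripheral shell (required for
#'   `mode = "fixed"`).
#' @param mode `"equal_volume"` or `"fixed"`.
#' @param dmap optional precomputed surface [distance_to_surface()] map.
#' @return list with `mode`, `threshold_um`, `periphery_pct`, `core_pct`,
#'   `n`, and the per-spot `region` factor.
#' @export
periphery_core_split <- function(tumor_mask, spots,
                                 boundary_distance_um = NULL,
                                 mode = c("equal_volume", "fixed"),
                                 dmap = NULL) {
  mode <- match.arg(mode)
  if (nrow(spots) == 0) stop("empty spot set: nothing to partition")
  dmap <- dmap %||% distance_to_surface(tumor_mask)
  thr <- switch(mode,
    equal_volume = median(dmap$values[is.finite(dmap$values)]),
    fixed = {
      if (is.null(boundary_distance_um) || boundary_distance_um <= 0)
        stop("mode 'fixed' requires boundary_distance_um > 0")
      boundary_distance_um
    })
  dist <- sample_distance_map(dmap, spot_coords(spots))
  if (anyNA(dist)) {
    warning(sum(is.na(dist)), " spot(s) outside the tumor dropped")
    dist <- dist[!is.na(dist)]
  }
  region <- factor(ifelse(dist <= thr, "periphery", "core"),
                   levels = c("periphery", "core"))
  n <- length(dist)
  list(mode = mode, threshold_um = thr,
       periphery_pct = 100 * sum(region == "periphery") / n,
       core_pct = 100 * sum(region == "core") / n,
       n = n, region = region)
}

#' Local-density classes of spots
#'
#' Counts, for every spot, the neighbors within `radius_um`, then bins the
#' counts into `n_classes` ordered classes by sample quantiles (class 1 =
#' sparsest). Ties share a class, so a constant neighbor count collapses to
#' a single class.
#'
#' @param spots a [spot_set()].
#' @param radius_um neighborhood radius in µm (default 100).
#' @param n_classes number of ordered density classes (default 5).
#' @return integer vector of per-spot classes (attribute
#'   `"neighbor_counts"` carries the raw counts).
#' @export
density_clusters <- function(spots, radius_um = 100, n_classes = 5L) {
  if (radius_um <= 0) stop("radius_um must be > 0")
  n <- nrow(spots)
  if (n == 0) return(integer(0))
  if (n < n_classes) {
    warning("fewer spots than classes; assigning all spots to one class")
    return(structure(rep(1L, n), neighbor_counts = rep(n - 1L, n)))
  }
  xyz <- spot_coords(spots)
  counts <- integer(n)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rowSums(xyz[s:e, , drop = FALSE]^2), rowSums(xyz^2), `+`) -
      2 * xyz[s:e, , drop = FALSE] %*% t(xyz)
    counts[s:e] <- rowSums(d2 <= radius_um^2) - 1L
  }
  br <- unique(quantile(counts, seq(0, 1, length.out = n_classes + 1)))
  cls <- if (length(br) < 2) rep(1L, n)
         else as.integer(cut(counts, br, include.lowest = TRUE,
                             labels = FALSE))
  structure(cls, neighbor_counts = counts)
}

#' Maximum-projection gray-value profile of the tumor's middle third
#'
#' Restricts the masked channel to the middle third of the tumor's bounding
#' box along `axis`, maximum-projects along that axis, and reads the
#' projection's gray values along the line through the tumor centroid
#' parallel to the principal (longer) in-plane axis — the trace used to
#' compare infiltration at the tumor margin versus center. (A second
#' maximum projection would flatten any rim-enhanced pattern, since every
#' lateral position crosses the rim; the center-line read preserves
#' margin-versus-core contrast.)
#'
#' @param channel a [volume_image()].
#' @param tumor_mask a [label_mask()] on the same grid.
#' @param axis projection axis: 1 = z (stack axis, default), 2 = y, 3 = x.
#' @return data.frame with `position_um` (voxel centers along the principal
#'   in-plane axis) and `gray_value`.
#' @export
middle_third_profile <- function(channel, tumor_mask, axis = 1L) {
  masked <- apply_tumor_mask(channel, tumor_mask)
  fg <- tumor_mask$data > 0L
  if (!any(fg)) stop("tumor mask is empty")
  d <- dim(fg)
  present <- apply(fg, axis, any)
  bb <- range(which(present))
  n <- bb[2] - bb[1] + 1L
  if (n < 3L) stop("tumor extent along the projection axis is below 3 slices")
  lo <- floor(n / 3)
  hi <- ceiling(2 * n / 3)
  slices <- (bb[1] + lo):(bb[1] + hi - 1L)

  sub <- switch(axis,
                masked$data[slices, , , drop = FALSE],
                masked$data[, slices, , drop = FALSE],
                masked$data[, , slices, drop = FALSE])
  mip <- apply(sub, setdiff(1:3, axis), max)

  inplane <- setdiff(1:3, axis)
  fg_sub <- switch(axis,
                   fg[slices, , , drop = FALSE],
                   fg[, slices, , drop = FALSE],
                   fg[, , slices, drop = FALSE])
  fg_mip <- apply(fg_sub, setdiff(1:3, axis), any)
  ext <- vapply(1:2, function(k) diff(range(which(apply(fg_mip, k, any)))),
                0)
  principal <- inplane[which.max(ext)]
  pk <- which.max(ext)   # principal axis within the 2D projection
  ok <- 3L - pk          # the other in-plane axis
  ctr <- round(mean(which(apply(fg_mip, ok, any))))
  prof <- if (pk == 1) mip[, ctr] else mip[ctr, ]
  keep <- if (pk == 1) fg_mip[, ctr] else fg_mip[ctr, ]
  pos_idx <- seq_len(d[principal])
  data.frame(position_um = (pos_idx[keep] - 0.5) *
               masked$spacing[principal],
             gray_value = prof[keep])
}

#' Export spots as a color-coded point cloud
#'
#' Writes a CSV (and optionally an ASCII PLY) of the spots with a per-spot
#' attribute mapped onto an 8-bit red-to-blue ramp: red = smallest value
#' (e.g. closest to the tumor surface), blue = largest. A degenerate range
#' maps every spot to the ramp midpoint.
#'
#' @param spots a [spot_set()].
#' @param values numeric attribute per spot (e.g. surface distance or
#'   density class).
#' @param csv_path output CSV path.
#' @param ply_path optional output PLY path.
#' @param attribute name of the attribute column.
#' @return the exported data.frame, invisibly.
#' @export
colorcode_export <- function(spots, values, csv_path, ply_path = NULL,
                             attribute = "value") {
  stopifnot(nrow(spots) == length(values))
  rng <- range(values)
  t <- if (diff(rng) == 0) rep(0.5, length(values))
       else (values - rng[1]) / diff(rng)
  df <- as.data.frame(spots)
  df[[attribute]] <- values
  df$r <- as.integer(round(255 * (1 - t)))
  df$g <- 0L
  df$b <- as.integer(round(255 * t))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(ply_path)) {
    con <- file(ply_path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(df)),
                 "property float x", "property float y", "property float z",
                 "property uchar red", "property uchar green",
                 "property uchar blue", "end_header"), con)
    writeLines(paste(df$x_um, df$y_um, df$z_um, df$r, df$g, df$b), con)
  }
  invisible(df)
}

#' Estimate the surface-decay length of an infiltration profile
#'
#' Fits an exponential decay to spot surface distances, correcting each
#' shell's count by the shell volume measured from the distance map (so the
#' estimate is unbiased by tumor geometry): a weighted linear fit of
#' `log(count / shell_volume)` against shell-center distance returns the
#' decay length as `-1 / slope`.
#'
#' @param spots a [spot_set()].
#' @param dmap the tumor-surface `distance_map`.
#' @param bin_width_um shell width used for the fit (default 25 µm).
#' @param min_count shells with fewer spots are excluded (default 5).
#' @return estimated decay length in µm.
#' @export
estimate_decay_length <- function(spots, dmap, bin_width_um = 25,
                                  min_count = 5L) {
  h <- spot_distance_histogram(spots, dmap, bin_width_um)
  if (h$n_total == 0) stop("no spots to fit")
  vox <- dmap$values[is.finite(dmap$values)]
  edges <- h$bin_edges
  shell_vox <- tabulate(findInterval(vox, edges, rightmost.closed = TRUE,
                                     all.inside = TRUE),
                        nbins = length(edges) - 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- h$counts >= min_count & shell_vox > 0
  if (sum(ok) < 2) stop("too few populated shells to fit a decay length")
  y <- log(h$counts[ok] / shell_vox[ok])
  fit <- stats::lm(y ~ mids[ok], weights = h$counts[ok])
  -1 / unname(coef(fit)[2])
}
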