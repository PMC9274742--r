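#' Specification of a cleared-tumor light-sheet phantom
#'
#' Describes a synthetic three-channel light-sheet volume: an ellipsoidal
#' tumor, a branching vessel tree grown as a seeded random walk and
#' rasterized as tubes (lectin channel), and a T-cell point process rendered
#' as Gaussian blobs (CD3 channel) whose spatial density decays
#' exponentially with distance from the tumor surface and is mixed, with
#' weight `vessel_attraction_weight`, with a component that decays with
#' distance from the vessel surface. The exact cell centers are returned as
#' ground truth, so spot detection and every downstream distance statistic
#' can be validated end to end.
#'
#' Defaults describe a 600 µm cube at 5 µm isotropic voxels with a
#' surface-decay length of 50 µm and 10 µm cells at signal-to-noise 20;
#' these are package choices for a cleared-tissue scale, not a measured
#' dataset.
#'
#' @param grid_shape voxels per axis (z, y, x).
#' @param voxel_spacing_um voxel size in µm per axis.
#' @param tumor_radii_um ellipsoid semi-axes in µm (tumor centered in grid).
#' @param vessel_params list: `n_trunks`, `branch_prob` (per step),
#'   `radius_um`, `step_um`, `max_steps`, `max_segments`.
#' @param cell_params list: `n_cells`, `surface_decay_length_um`,
#'   `vessel_attraction_weight` in `[0,1]`, `vessel_decay_length_um`,
#'   `min_cell_diameter_um` (must be at least the largest voxel spacing),
#'   `min_separation_um` (0 = none; positive values thin the process to a
#'   hard-core minimum spacing, used for well-separated detection tests).
#' @param intensities list of channel amplitudes: `cd3_amplitude`,
#'   `lectin_amplitude`, `background_amplitude`.
#' @param noise_sd additive Gaussian noise scale (clipped at 0).
#' @param seed integer RNG seed.
#' @return a `tumor_phantom_spec` list.
#' @export
tumor_phantom_spec <- function(
    grid_shape = c(120L, 120L, 120L),
    voxel_spacing_um = c(5, 5, 5),
    tumor_radii_um = c(250, 230, 210),
    vessel_params = list(n_trunks = 3L, branch_prob = 0.05, radius_um = 10,
                         step_um = 10, max_steps = 200L, max_segments = 40L),
    cell_params = list(n_cells = 2000L, surface_decay_length_um = 50,
                       vessel_attraction_weight = 0.3,
                       vessel_decay_length_um = 30,
                       min_cell_diameter_um = 10,
                       min_separation_um = 0),
    intensities = list(cd3_amplitude = 100, lectin_amplitude = 100,
                       background_amplitude = 10),
    noise_sd = 5,
    seed = 1L) {
  spec <- list(grid_shape = as.integer(rep_len(grid_shape, 3L)),
               voxel_spacing_um = rep_len(as.numeric(voxel_spacing_um), 3L),
               tumor_radii_um = rep_len(as.numeric(tumor_radii_um), 3L),
               vessel_params = vessel_params, cell_params = cell_params,
               intensities = intensities, noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "tumor_phantom_spec"
  validate_tumor_phantom_spec(spec)
  spec
}

validate_tumor_phantom_spec <- function(spec) {
  cp <- spec$cell_params
  if (cp$n_cells < 0) stop("n_cells must be >= 0")
  w <- cp$vessel_attraction_weight
  if (w < 0 || w > 1) stop("vessel_attraction_weight must be in [0, 1]")
  if (cp$min_cell_diameter_um < max(spec$voxel_spacing_um))
    stop("min_cell_diameter_um must be at least the voxel size")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(spec)
}

#' Generate a cleared-tumor light-sheet phantom
#'
#' @param spec a [tumor_phantom_spec()].
#' @return list with `channels` (named list of [volume_image()]:
#'   `background`, `lectin`, `cd3`), `tumor_mask`, `vessel_mask`
#'   ([label_mask()]), `true_cells` ([spot_set()] with exact centers), the
#'   surface/vessel distance maps used for sampling (`d_surface`,
#'   `d_vessel`), and `spec`.
#' @export
make_tumor_phantom <- function(spec) {
  stopifnot(inherits(spec, "tumor_phantom_spec"))
  validate_tumor_phantom_spec(spec)
  set.seed(spec$seed)
  gs <- spec$grid_shape
  sp <- spec$voxel_spacing_um
  center <- gs * sp / 2

  tumor <- ellipsoid_mask(gs, sp, center, spec$tumor_radii_um)
  n_tumor <- sum(tumor)
  if (spec$cell_params$n_cells > 0 && n_tumor == 0)
    stop("tumor volume is zero but n_cells > 0")
  tumor_mask <- label_mask(array(as.integer(tumor), gs), sp,
                           labels = c(tumor = 1L))

  vessel <- grow_vessel_tree(spec, center, tumor)
  vessel_mask <- label_mask(array(as.integer(vessel), gs), sp,
                            labels = c(vessel = 1L))

  d_surf <- distance_to_surface(tumor_mask)
  d_ves <- if (any(vessel)) distance_to_structure(vessel_mask) else NULL

  cells <- sample_tumor_cells(spec, tumor, d_surf, d_ves)

  cd3 <- render_blobs(gs, sp, cells,
                      diameter_um = spec$cell_params$min_cell_diameter_um,
                      amplitude = spec$intensities$cd3_amplitude)
  lectin <- array(0, gs)
  lectin[vessel] <- spec$intensities$lectin_amplitude
  if (any(vessel)) lectin <- gaussian_blur3(lectin, 2.5 / sp)
  background <- array(0, gs)
  background[tumor] <- spec$intensities$background_amplitude

  channels <- lapply(list(background = background, lectin = lectin,
                          cd3 = cd3), function(ch) {
    if (spec$noise_sd > 0)
      ch <- pmax(0, ch + array(rnorm(length(ch), 0, spec$noise_sd), dim(ch)))
    volume_image(array(ch, gs), sp, unit = "um")
  })

  true_cells <- spot_set(cells,
                         radius_um = spec$cell_params$min_cell_diameter_um / 2,
                         intensity = spec$intensities$cd3_amplitude,
                         provenance = "ground_truth")

  list(channels = channels, tumor_mask = tumor_mask,
       vessel_mask = vessel_mask, true_cells = true_cells,
       d_surface = d_surf, d_vessel = d_ves, spec = spec)
}

# Seeded random-walk branching tree rasterized as tubes, clipped to the
# tumor. Trunks enter at random surface points heading inward; branches
# fork off with probability branch_prob per step.
grow_vessel_tree <- function(spec, center, tumor) {
  vp <- spec$vessel_params
  gs <- spec$grid_shape
  sp <- spec$voxel_spacing_um
  vessel <- array(FALSE, gs)
  if ((vp$n_trunks %||% 0L) < 1L) return(vessel)
  radii <- spec$tumor_radii_um
  max_seg <- vp$max_segments %||% 40L

  inside_tumor <- function(p) sum(((p - center) / radii)^2) <= 1
  queue <- list()
  for (i in seq_len(vp$n_trunks)) {
    u <- runif_sphere(1)[1, ]
    start <- center + u * radii  # point on the ellipsoid surface
    dir <- -u / sqrt(sum(u^2))
    queue[[length(queue) + 1]] <- list(pos = start, dir = dir)
  }
  pts <- list()
  n_seg <- length(queue)
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue[[1]] <- NULL
    pos <- seg$pos; dir <- seg$dir
    for (step in seq_len(vp$max_steps %||% 200L)) {
      pos <- pos + dir * vp$step_um
      if (!inside_tumor(pos)) break
      pts[[length(pts) + 1]] <- pos
      dir <- dir + rnorm(3, sd = 0.35)
      dir <- dir / sqrt(sum(dir^2))
      if (n_seg < max_seg && runif(1) < vp$branch_prob) {
        bdir <- dir + rnorm(3, sd = 0.8)
        bdir <- bdir / sqrt(sum(bdir^2))
        queue[[length(queue) + 1]] <- list(pos = pos, dir = bdir)
        n_seg <- n_seg + 1
      }
    }
  }
  if (length(pts) == 0) return(vessel)
  pts <- do.call(rbind, pts)
  stamp_balls(vessel, pts, vp$radius_um, sp) & tumor
}

# Set to TRUE all voxels whose centers lie within `radius` of any point.
stamp_balls <- function(mask, pts, radius, spacing) {
  d <- dim(mask)
  rv <- ceiling(radius / spacing)
  offs <- expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3])
  keep <- (offs$dz * spacing[1])^2 + (offs$dy * spacing[2])^2 +
    (offs$dx * spacing[3])^2 <= radius^2
  offs <- as.matrix(offs[keep, ])
  ctr <- round(sweep(pts, 2, spacing, `/`) + 0.5)
  for (i in seq_len(nrow(ctr))) {
    vox <- sweep(offs, 2, ctr[i, ], `+`)
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
      vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
    mask[vox[ok, , drop = FALSE]] <- TRUE
  }
  mask
}

# Sample cell centers inside the tumor: voxel weights are a mixture of a
# surface-decay density and a vessel-proximity density, then a uniform
# jitter within the chosen voxel. Hard-core thinning if min_separation > 0.
sample_tumor_cells <- function(spec, tumor, d_surf, d_ves) {
  cp <- spec$cell_params
  n <- cp$n_cells
  if (n == 0) return(matrix(numeric(), ncol = 3))
  sp <- spec$voxel_spacing_um
  idx <- which(tumor)
  ds <- d_surf$values[idx]
  p_surf <- exp(-ds / cp$surface_decay_length_um)
  p_surf <- p_surf / sum(p_surf)
  w <- cp$vessel_attraction_weight
  if (w > 0 && !is.null(d_ves)) {
    dv <- d_ves$values[idx]
    p_ves <- exp(-dv / cp$vessel_decay_length_um)
    p_ves <- p_ves / sum(p_ves)
    prob <- (1 - w) * p_surf + w * p_ves
  } else {
    prob <- p_surf
  }
  draw <- function(k) {
    vox <- sample(length(idx), k, replace = TRUE, prob = prob)
    ctr <- voxel_centers(idx[vox], spec$grid_shape, sp)
    jit <- matrix(runif(3 * k, -0.5, 0.5), ncol = 3)
    ctr + sweep(jit, 2, sp, `*`)
  }
  if ((cp$min_separation_um %||% 0) <= 0) return(draw(n))

  # greedy hard-core acceptance with a bounded retry budget
  sep2 <- cp$min_separation_um^2
  acc <- matrix(numeric(), ncol = 3)
  tries <- 0L
  while (nrow(acc) < n && tries < 200L * n) {
    cand <- draw(min(n, 4L * (n - nrow(acc))))
    for (i in seq_len(nrow(cand))) {
      tries <- tries + 1L
      if (nrow(acc) == 0 ||
          min(colSums((t(acc) - cand[i, ])^2)) > sep2) {
        acc <- rbind(acc, cand[i, , drop = FALSE])
        if (nrow(acc) == n) break
      }
    }
  }
  if (nrow(acc) < n)
    warning("hard-core thinning placed only ", nrow(acc), " of ", n,
            " cells")
  acc
}

# Render cells as Gaussian blobs (FWHM = diameter) of the given peak
# amplitude, added into a zero volume.
render_blobs <- function(grid_shape, spacing, centers, diameter_um,
                         amplitude) {
  vol <- array(0, grid_shape)
  if (is.null(centers) || nrow(centers) == 0) return(vol)
  sigma <- diameter_um / (2 * sqrt(2 * log(2)))
  rv <- ceiling(3 * sigma / spacing)
  d <- grid_shape
  for (i in seq_len(nrow(centers))) {
    c_i <- centers[i, ]
    ci <- c_i / spacing + 0.5
    lo <- pmax(1, floor(ci - rv))
    hi <- pmin(d, ceiling(ci + rv))
    zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
    gz <- exp(-((zz - 0.5) * spacing[1] - c_i[1])^2 / (2 * sigma^2))
    gy <- exp(-((yy - 0.5) * spacing[2] - c_i[2])^2 / (2 * sigma^2))
    gx <- exp(-((xx - 0.5) * spacing[3] - c_i[3])^2 / (2 * sigma^2))
    blob <- amplitude * outer(outer(gz, gy), gx)
    vol[zz, yy, xx] <- vol[zz, yy, xx] + blob
  }
  vol
}
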