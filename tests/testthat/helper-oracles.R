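# Independent brute-force oracles and small phantom configurations shared
# across test files. The oracles deliberately avoid the package's separable
# EDT: they enumerate voxel pairs directly.

# Squared distance from every voxel to the nearest background voxel center,
# by exhaustive enumeration (physical spacing).
brute_sq_edt <- function(fg, spacing) {
  d <- dim(fg)
  out <- array(0, d)
  bg <- which(!fg)
  if (length(bg) == 0) { out[] <- Inf; return(out) }
  B <- carspat3d:::voxel_centers(bg, d, spacing)
  fgi <- which(fg)
  if (length(fgi) > 0) {
    F <- carspat3d:::voxel_centers(fgi, d, spacing)
    d2 <- outer(rowSums(F^2), rowSums(B^2), `+`) - 2 * F %*% t(B)
    out[fgi] <- pmax(0, apply(d2, 1, min))
  }
  out
}

# All voxels within index-space Euclidean distance <= n of the region.
brute_dilate <- function(region, n) {
  d <- dim(region)
  idx <- which(region)
  out <- array(FALSE, d)
  if (length(idx) == 0) return(out)
  R <- arrayInd(idx, d)
  all_i <- arrayInd(seq_len(prod(d)), d)
  d2 <- outer(rowSums(all_i^2), rowSums(R^2), `+`) - 2 * all_i %*% t(R)
  out[apply(d2, 1, min) <= n^2 + 1e-9] <- TRUE
  out
}

random_mask <- function(dims, p = 0.5) {
  array(runif(prod(dims)) < p, dims)
}

# Greedy one-to-one matching of detected spots to ground truth within a
# radius; returns recall, precision and mean localization error.
match_spots <- function(truth_xyz, det_xyz, radius) {
  if (nrow(det_xyz) == 0)
    return(list(recall = 0, precision = NA_real_, mean_err = NA_real_))
  used <- rep(FALSE, nrow(det_xyz))
  tp <- 0; errs <- numeric(0)
  for (i in seq_len(nrow(truth_xyz))) {
    d2 <- colSums((t(det_xyz) - truth_xyz[i, ])^2)
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) {
      used[j] <- TRUE
      tp <- tp + 1
      errs <- c(errs, sqrt(d2[j]))
    }
  }
  list(recall = tp / nrow(truth_xyz), precision = tp / nrow(det_xyz),
       mean_err = mean(errs))
}

# Small/fast phantom specs used by several files.
small_tumor_spec <- function(n_cells, seed, attraction = 0,
                             decay = 50, separation = 0,
                             vessels = TRUE, noise_sd = 5,
                             diameter = 10) {
  tumor_phantom_spec(
    grid_shape = c(80L, 80L, 80L),
    tumor_radii_um = c(170, 160, 150),
    vessel_params = if (vessels)
      list(n_trunks = 3L, branch_prob = 0.05, radius_um = 10, step_um = 10,
           max_steps = 200L, max_segments = 40L)
    else list(n_trunks = 0L, branch_prob = 0, radius_um = 10, step_um = 10),
    cell_params = list(n_cells = as.integer(n_cells),
                       surface_decay_length_um = decay,
                       vessel_attraction_weight = attraction,
                       vessel_decay_length_um = 30,
                       min_cell_diameter_um = diameter,
                       min_separation_um = separation),
    noise_sd = noise_sd,
    seed = seed)
}

small_cycif_spec <- function(n_cells = 120L, seed = 1L, ...) {
  cycif_phantom_spec(image_shape = c(620L, 620L), n_cells = n_cells,
                     seed = seed, ...)
}
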