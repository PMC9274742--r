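test_that("tumor masking zeroes exactly the outside voxels", {
  v <- volume_image(array(1, c(4, 4, 4)), 1)
  half <- array(0L, c(4, 4, 4)); half[1:2, , ] <- 1L
  lm <- label_mask(half, 1)
  expect_equal(sum(apply_tumor_mask(v, lm)$data), 32)
  full <- label_mask(array(1L, c(4, 4, 4)), 1)
  expect_identical(apply_tumor_mask(v, full)$data, v$data)
  none <- label_mask(array(0L, c(4, 4, 4)), 1)
  expect_true(all(apply_tumor_mask(v, none)$data == 0))
})

test_that("vessel segmentation recovers the phantom tree", {
  ph <- make_tumor_phantom(small_tumor_spec(n_cells = 0, seed = 31,
                                            noise_sd = 0))
  vs <- segment_vessels(ph$channels$lectin, ph$tumor_mask)
  truth <- ph$vessel_mask$data > 0L
  got <- vs$data > 0L
  dice <- 2 * sum(got & truth) / (sum(got) + sum(truth))
  expect_gte(dice, 0.95)

  # explicit threshold: mask = {v >= t} after the size filter
  vs2 <- segment_vessels(ph$channels$lectin, ph$tumor_mask, threshold = 50,
                         min_component_voxels = 1)
  manual <- ph$channels$lectin$data >= 50 & ph$tumor_mask$data > 0L
  expect_identical(vs2$data > 0L, manual)

  zero <- volume_image(array(0, dim(ph$channels$lectin$data)),
                       ph$channels$lectin$spacing)
  expect_warning(empty <- segment_vessels(zero, ph$tumor_mask))
  expect_equal(sum(empty$data), 0)
})

test_that("spot detection recovers well-separated cells and rejects small ones", {
  spec <- small_tumor_spec(n_cells = 120, seed = 7, vessels = FALSE,
                           decay = 1e6, separation = 25)
  ph <- make_tumor_phantom(spec)
  spots <- detect_spots(ph$channels$cd3, ph$tumor_mask)
  st <- match_spots(carspat3d:::spot_coords(ph$true_cells),
                    carspat3d:::spot_coords(spots), radius = 10)
  expect_gte(st$recall, 0.95)
  expect_gte(st$precision, 0.95)
  expect_lte(st$mean_err, max(ph$channels$cd3$spacing))

  # all spots inside the tumor and radii at or above half the minimum
  expect_true(all(spots$radius_um >= 4))

  # empty channel: no spots
  zero <- volume_image(array(0, dim(ph$channels$cd3$data)),
                       ph$channels$cd3$spacing)
  expect_equal(nrow(detect_spots(zero, ph$tumor_mask)), 0)

  # blobs below the 8 um minimum are rejected by the scale cutoff
  spec4 <- tumor_phantom_spec(grid_shape = c(80L, 80L, 80L),
    voxel_spacing_um = c(3, 3, 3), tumor_radii_um = c(110, 100, 95),
    vessel_params = list(n_trunks = 0L, branch_prob = 0, radius_um = 10,
                         step_um = 10),
    cell_params = list(n_cells = 40L, surface_decay_length_um = 1e6,
                       vessel_attraction_weight = 0,
                       vessel_decay_length_um = 30,
                       min_cell_diameter_um = 4, min_separation_um = 30),
    seed = 8)
  ph4 <- make_tumor_phantom(spec4)
  expect_equal(nrow(detect_spots(ph4$channels$cd3, ph4$tumor_mask,
                                 min_diameter_um = 8)), 0)

  # spacing coarser than the minimum diameter is an error
  coarse <- volume_image(array(0, c(4, 4, 4)), c(10, 10, 10))
  cm <- label_mask(array(1L, c(4, 4, 4)), c(10, 10, 10))
  expect_error(detect_spots(coarse, cm, min_diameter_um = 8),
               "undetectable")
})

test_that("shell histograms normalize, respect ordering and geometry", {
  ph <- make_tumor_phantom(small_tumor_spec(n_cells = 3000, seed = 41,
                                            vessels = FALSE, decay = 1e9))
  h <- spot_distance_histogram(ph$true_cells, ph$d_surface,
                               bin_width_um = 25)
  expect_equal(sum(h$relative_frequency), 1)
  expect_equal(h$n_total, 3000)

  # uniform spots: per-shell frequency proportional to shell volume
  vox <- ph$d_surface$values[ph$tumor_mask$data > 0]
  shell_vox <- tabulate(findInterval(vox, h$bin_edges,
                                     rightmost.closed = TRUE,
                                     all.inside = TRUE),
                        nbins = length(h$bin_edges) - 1)
  expected <- shell_vox / sum(shell_vox)
  expect_lt(max(abs(h$relative_frequency - expected)), 0.03)

  # invariant to spot ordering
  shuf <- ph$true_cells[sample(nrow(ph$true_cells)), ]
  class(shuf) <- class(ph$true_cells)
  h2 <- spot_distance_histogram(shuf, ph$d_surface, bin_width_um = 25)
  expect_equal(h2$relative_frequency, h$relative_frequency)

  # empty spot set: empty histogram, no normalization
  h0 <- spot_distance_histogram(
    spot_set(matrix(numeric(), ncol = 3), provenance = "ground_truth"),
    ph$d_surface)
  expect_equal(h0$n_total, 0)
  expect_length(h0$relative_frequency, 0)
})

test_that("decay length is recovered from biased point processes", {
  ph <- make_tumor_phantom(small_tumor_spec(n_cells = 2000, seed = 13,
                                            vessels = FALSE, decay = 50))
  lam <- estimate_decay_length(ph$true_cells, ph$d_surface)
  expect_lt(abs(lam - 50) / 50, 0.2)
})

test_that("vessel distance contract: zeros on vessels, geometry offsets", {
  # straight tube along z, spots at known lateral offsets
  m <- array(0L, c(40, 40, 40))
  m[5:35, 20, 20] <- 1L
  vm <- label_mask(m, c(2, 2, 2), labels = c(vessel = 1L))
  # voxel (20, 20, 20) center: (39, 39, 39); offsets along y
  offs <- c(0, 4, 8, 16)
  pts <- cbind(39, 39 + offs, 39)
  spots <- spot_set(pts, radius_um = 4, intensity = 1,
                    provenance = "ground_truth")
  h <- spot_vessel_distances(spots, vm, bin_width_um = 2)
  expect_equal(h$distances, pmax(0, offs - 1), tolerance = 1e-9)

  on_vessel <- spot_set(cbind(c(9, 39), 39, 39), 4, 1, "ground_truth")
  hv <- spot_vessel_distances(on_vessel, vm, bin_width_um = 10)
  expect_equal(hv$relative_frequency[1], 1)

  empty <- label_mask(array(0L, c(4, 4, 4)), 1, labels = c(vessel = 1L))
  expect_error(spot_vessel_distances(spots, empty), "empty")
})

test_that("attraction phantoms give stochastically smaller vessel distances", {
  ph1 <- make_tumor_phantom(small_tumor_spec(n_cells = 500, seed = 21,
                                             attraction = 1))
  ph0 <- make_tumor_phantom(small_tumor_spec(n_cells = 500, seed = 21,
                                             attraction = 0))
  h1 <- spot_vessel_distances(ph1$true_cells, ph1$vessel_mask)
  h0 <- spot_vessel_distances(ph0$true_cells, ph0$vessel_mask)
  expect_lt(median(h1$distances), median(h0$distances))
  p <- stats::wilcox.test(h1$distances, h0$distances,
                          alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("periphery/core split behaves in both modes", {
  ph <- make_tumor_phantom(small_tumor_spec(n_cells = 2000, seed = 41,
                                            vessels = FALSE, decay = 1e9))
  spl <- periphery_core_split(ph$tumor_mask, ph$true_cells, dmap = ph$d_surface)
  expect_equal(spl$periphery_pct, 50, tolerance = 5)
  expect_equal(spl$periphery_pct + spl$core_pct, 100)

  biased <- make_tumor_phantom(small_tumor_spec(n_cells = 1000, seed = 42,
                                                vessels = FALSE, decay = 40))
  spb <- periphery_core_split(biased$tumor_mask, biased$true_cells,
                              dmap = biased$d_surface)
  expect_gt(spb$periphery_pct, spb$core_pct)

  # fixed threshold beyond the maximum depth: everything is periphery
  deep <- periphery_core_split(ph$tumor_mask, ph$true_cells,
                               boundary_distance_um = 1e5, mode = "fixed",
                               dmap = ph$d_surface)
  expect_equal(deep$periphery_pct, 100)

  empty <- spot_set(matrix(numeric(), ncol = 3), provenance = "detected")
  expect_error(periphery_core_split(ph$tumor_mask, empty), "empty")
})

test_that("density classes order clustered above isolated spots", {
  set.seed(3)
  clustered <- matrix(rnorm(3 * 60, sd = 15), ncol = 3) + 500
  isolated <- cbind(runif(12, 0, 200), runif(12, 0, 200), runif(12, 0, 200))
  spots <- spot_set(rbind(clustered, isolated), 5, 1, "ground_truth")
  cls <- density_clusters(spots, radius_um = 100, n_classes = 5)
  expect_true(all(cls[1:60] == max(cls)))
  expect_true(all(cls[61:72] == 1))

  # infinite radius: everyone sees everyone, a single class
  cls_inf <- density_clusters(spots, radius_um = 1e9, n_classes = 5)
  expect_true(all(cls_inf == 1))

  # uniform spots: near-equal class occupancy
  ph <- make_tumor_phantom(small_tumor_spec(n_cells = 1000, seed = 44,
                                            vessels = FALSE, decay = 1e9))
  clu <- density_clusters(ph$true_cells, radius_um = 50, n_classes = 4)
  occ <- table(clu) / length(clu)
  expect_lt(max(abs(occ - 1 / 4)), 0.12)

  few <- spot_set(matrix(runif(6), ncol = 3), 5, 1, "ground_truth")
  expect_warning(c2 <- density_clusters(few, 10, n_classes = 5), "fewer")
  expect_true(all(c2 == 1))
})

test_that("middle-third profile slices and projections are correct", {
  # constant tumor: flat profile at that constant
  m <- array(0L, c(30, 30, 30)); m[6:25, 6:25, 6:25] <- 1L
  lm <- label_mask(m, 2)
  v <- volume_image(array(0, c(30, 30, 30)), 2)
  v$data[m == 1L] <- 7
  prof <- middle_third_profile(v, lm)
  expect_true(all(prof$gray_value == 7))

  # bright shell: profile peaks at the margins
  shell <- v
  inner <- array(0L, c(30, 30, 30)); inner[10:21, 10:21, 10:21] <- 1L
  shell$data[m == 1L] <- 10
  shell$data[inner == 1L] <- 2
  ps <- middle_third_profile(shell, lm)
  mid <- ceiling(nrow(ps) / 2)
  expect_gt(ps$gray_value[1], ps$gray_value[mid])
  expect_gt(ps$gray_value[nrow(ps)], ps$gray_value[mid])

  # 9 slices along the axis: slices 4..6 (1-based) are used
  m9 <- array(0L, c(20, 10, 10)); m9[6:14, 3:8, 3:8] <- 1L
  lm9 <- label_mask(m9, 1)
  v9 <- volume_image(array(0, c(20, 10, 10)), 1)
  v9$data[9, 3:8, 3:8] <- 5   # inside the middle third (slices 9:11)
  v9$data[6, 3:8, 3:8] <- 50  # outside it
  p9 <- middle_third_profile(v9, lm9)
  expect_equal(max(p9$gray_value), 5)

  thin <- array(0L, c(20, 10, 10)); thin[6:7, 3:8, 3:8] <- 1L
  expect_error(middle_third_profile(v9, label_mask(thin, 1)), "3 slices")
})

test_that("color-coded export writes ramp endpoints and round-trips", {
  spots <- spot_set(rbind(c(0, 0, 0), c(10, 10, 10), c(5, 5, 5)),
                    radius_um = 4, intensity = 1, provenance = "detected")
  csv <- tempfile(fileext = ".csv")
  ply <- tempfile(fileext = ".ply")
  df <- colorcode_export(spots, c(0, 100, 50), csv, ply)
  expect_equal(df$r, c(255L, 0L, 128L))
  expect_equal(df$b, c(0L, 255L, 128L))
  back <- read.csv(csv)
  expect_equal(back$value, c(0, 100, 50))
  expect_equal(readLines(ply)[3], "element vertex 3")

  # degenerate range: midpoint color
  one <- colorcode_export(spots[1, ], 5, tempfile(fileext = ".csv"))
  expect_equal(one$r, 128L)
})
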