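test_that("body phantom conserves signal exactly without blur", {
  spec <- body_phantom_spec(
    blur_sigma_mm = 0,
    sources = list(list(organ = "spleen", total_signal = 1000,
                        centroid_shift_mm = c(0, 0, 0))))
  ph <- make_body_phantom(spec)
  spleen <- region_signal <- sum(ph$volume$data[ph$mask$data ==
                                                  ph$mask$labels[["spleen"]]])
  expect_equal(spleen, 1000)
  expect_equal(sum(ph$volume$data), 1000)
  expect_equal(nrow(ph$truth), 4)  # all organs tabulated, sources or not
})

test_that("shifted+blurred source leaks out of its mask and dilation recovers it", {
  spec <- body_phantom_spec(
    sources = list(list(organ = "spleen", total_signal = 1000,
                        centroid_shift_mm = c(0, -3, 0))))
  ph <- make_body_phantom(spec)
  inmask <- sum(ph$volume$data[ph$mask$data == ph$mask$labels[["spleen"]]])
  expect_lt(inmask, 1000)
  dil <- dilate_mask(ph$mask, "spleen", 10)
  reg <- attr(dil, "regions")$spleen
  expect_gt(sum(ph$volume$data[reg]), inmask)
  # blur conserves total signal up to boundary loss < 1%
  expect_gt(sum(ph$volume$data), 0.99 * 1000)
})

test_that("body phantom rejects overlapping organs and oversized organs", {
  expect_error(make_body_phantom(body_phantom_spec(organs = list(
    list(name = "a", center_mm = c(20, 12, 12), radii_mm = c(4, 4, 4)),
    list(name = "b", center_mm = c(22, 12, 12), radii_mm = c(4, 4, 4))),
    sources = list())), "overlap.*a.*b")
  expect_error(body_phantom_spec(organs = list(
    list(name = "big", center_mm = c(20, 12, 12), radii_mm = c(30, 4, 4))),
    sources = list()), "grid too small")
})

test_that("phantom generators are bit-identical under a fixed seed", {
  s <- small_tumor_spec(n_cells = 100, seed = 9)
  a <- make_tumor_phantom(s)
  b <- make_tumor_phantom(s)
  expect_identical(a$channels$cd3$data, b$channels$cd3$data)
  expect_identical(as.data.frame(a$true_cells), as.data.frame(b$true_cells))

  cs <- small_cycif_spec(n_cells = 60L, seed = 2L)
  c1 <- make_cycif_phantom(cs)
  c2 <- make_cycif_phantom(cs)
  expect_identical(c1$true_cells, c2$true_cells)
  expect_identical(c1$channels$CD3, c2$channels$CD3)
})

test_that("tumor cell process matches a rejection-sampling oracle", {
  # pure surface decay: compare median distance-to-surface of generated
  # cells with an independent rejection sampler on the same distance map
  spec <- small_tumor_spec(n_cells = 1500, seed = 5, vessels = FALSE,
                           decay = 50)
  ph <- make_tumor_phantom(spec)
  d_cells <- carspat3d:::sample_distance_map(
    ph$d_surface, carspat3d:::spot_coords(ph$true_cells))

  set.seed(1234)  # oracle: rejection sampling over in-tumor voxels
  vox_d <- ph$d_surface$values[ph$tumor_mask$data > 0]
  meds <- replicate(40, {
    keep <- runif(length(vox_d)) < exp(-vox_d / 50)
    median(vox_d[keep])
  })
  expect_lt(abs(median(d_cells) - mean(meds)), 3 * sd(meds) + 1)
})

test_that("vessel attraction pulls cells toward vessels at matched seeds", {
  ph1 <- make_tumor_phantom(small_tumor_spec(n_cells = 500, seed = 21,
                                             attraction = 1))
  ph0 <- make_tumor_phantom(small_tumor_spec(n_cells = 500, seed = 21,
                                             attraction = 0))
  d1 <- carspat3d:::sample_distance_map(
    distance_to_structure(ph1$vessel_mask),
    carspat3d:::spot_coords(ph1$true_cells))
  d0 <- carspat3d:::sample_distance_map(
    distance_to_structure(ph0$vessel_mask),
    carspat3d:::spot_coords(ph0$true_cells))
  expect_lt(median(d1), median(d0))
})

test_that("edge cases: zero cells, zero-size tumor, empty spot set", {
  spec <- small_tumor_spec(n_cells = 0, seed = 2, vessels = FALSE)
  ph <- make_tumor_phantom(spec)
  expect_equal(nrow(ph$true_cells), 0)
  # CD3 channel is pure noise: nothing above a few noise SDs
  expect_lt(max(ph$channels$cd3$data), 6 * spec$noise_sd)
  expect_error(
    tumor_phantom_spec(cell_params = list(
      n_cells = -1L, surface_decay_length_um = 50,
      vessel_attraction_weight = 0, vessel_decay_length_um = 30,
      min_cell_diameter_um = 10, min_separation_um = 0)),
    "n_cells")
})

test_that("cycif phantom respects fractions, background and placement bounds", {
  ph <- make_cycif_phantom(small_cycif_spec(n_cells = 120L, seed = 3L))
  tt <- ph$true_cells
  expect_equal(nrow(tt), 120)
  frac <- table(tt$population) / nrow(tt)
  expect_equal(unname(frac[["CD3neg"]]), 0.6, tolerance = 0.01)
  # CD3 log2 truth is bimodal: big gap between the populations
  expect_gt(min(tt$CD3_log2[tt$population != "CD3neg"]),
            max(tt$CD3_log2[tt$population == "CD3neg"]))

  # background 0 and no noise: pixels outside all cells are exactly 0
  ph0 <- make_cycif_phantom(small_cycif_spec(n_cells = 30L, seed = 4L,
                                             background_level = 0,
                                             noise_sd = 0))
  covered <- matrix(FALSE, 620, 620)
  for (i in seq_len(nrow(ph0$true_cells))) {
    r <- ph0$true_cells$radius_px[i] + ph0$spec$donut_width_px + 1
    yy <- pmax(1, floor(ph0$true_cells$y[i] - r)):
      pmin(620, ceiling(ph0$true_cells$y[i] + r))
    xx <- pmax(1, floor(ph0$true_cells$x[i] - r)):
      pmin(620, ceiling(ph0$true_cells$x[i] + r))
    covered[yy, xx] <- TRUE
  }
  expect_true(all(ph0$channels$CD3[!covered] == 0))

  # unplaceable request errors and reports the achieved count
  expect_error(make_cycif_phantom(cycif_phantom_spec(
    image_shape = c(200L, 200L), n_cells = 500L)), "achieved")
})
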