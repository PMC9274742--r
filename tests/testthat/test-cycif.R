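test_that("segmentation parameters enforce their invariants", {
  p <- segmentation_params()
  expect_equal(p$nucleus_diameter_px, c(18, 60))
  expect_equal(p$cytoplasm_donut_width_px, 11)
  expect_error(segmentation_params(nucleus_diameter_px = c(60, 18)),
               "min < max")
  expect_error(segmentation_params(cytoplasm_donut_width_px = 0), ">= 1")
  expect_error(segmentation_params(nucleus_detection = 1.2), "\\[0, 1\\]")
})

test_that("internal Otsu agrees with EBImage's on bimodal samples", {
  set.seed(19)
  v <- pmin(pmax(c(rnorm(600, 0.25, 0.05), rnorm(400, 0.75, 0.05)), 0), 1)
  ours <- otsu_threshold(v)
  ref <- EBImage::otsu(EBImage::Image(matrix(v, 40, 25)))
  # the between-class variance is flat across the empty valley, so the
  # threshold value is non-unique; the induced classification is what must
  # agree, and both cuts must sit between the two modes
  expect_gt(mean((v > ours) == (v > ref)), 0.995)
  expect_gt(ours, 0.35); expect_lt(ours, 0.65)
})

test_that("nuclei are detected, sized and localized on the phantom", {
  ph <- make_cycif_phantom(small_cycif_spec(n_cells = 100L, seed = 6L))
  cells <- segment_cells(ph$channels$DAPI)
  expect_gte(nrow(cells), 95)
  tt <- ph$true_cells
  derr <- vapply(seq_len(nrow(cells)), function(i)
    sqrt(min((tt$y - cells$y[i])^2 + (tt$x - cells$x[i])^2)), 0)
  expect_gte(mean(derr <= 2), 0.95)
  expect_true(all(cells$diameter_px >= 18 & cells$diameter_px <= 60))
})

test_that("out-of-range nuclei and degenerate images are handled", {
  # nuclei below the 18 px minimum are not detected
  ph <- make_cycif_phantom(cycif_phantom_spec(
    image_shape = c(300L, 300L), n_cells = 15L,
    nucleus_diameter_px_range = c(8, 10), seed = 7L))
  expect_warning(cells <- segment_cells(ph$channels$DAPI), "no nuclei")
  expect_equal(nrow(cells), 0)

  expect_warning(empty <- segment_cells(matrix(0, 50, 50)), "no nuclei")
  expect_equal(nrow(empty), 0)
})

test_that("nucleus separation controls splitting of touching nuclei", {
  # two touching discs rendered directly
  img <- matrix(0, 120, 120)
  for (c0 in list(c(60, 45), c(60, 77))) {
    d2 <- outer((seq_len(120) - c0[1])^2, (seq_len(120) - c0[2])^2, `+`)
    img[d2 <= 17^2] <- 200
  }
  img <- as.matrix(EBImage::gblur(EBImage::Image(img), 1))
  split_high <- segment_cells(img, segmentation_params(nucleus_separation = 0.9))
  merged <- suppressWarnings(
    segment_cells(img, segmentation_params(nucleus_separation = 0,
                                           nucleus_diameter_px = c(18, 80))))
  expect_equal(nrow(split_high), 2)
  expect_equal(nrow(merged), 1)
})

test_that("marker quantification recovers raw means and centers the mode", {
  ph <- make_cycif_phantom(small_cycif_spec(n_cells = 80L, seed = 9L,
                                            noise_sd = 0,
                                            background_level = 0))
  cells <- segment_cells(ph$channels$DAPI)
  # uniform channel: per-cell raw mean equals the constant
  const <- matrix(7, nrow(ph$channels$DAPI), ncol(ph$channels$DAPI))
  q <- quantify_markers(cells, list(M = const))
  expect_true(all(abs(q$M_raw - 7) < 1e-9))
  # after mode centering, the modal cell value sits at 0
  expect_lt(abs(carspat3d:::hist_mode(q$M)), 0.1)

  # population log2 means recovered within 0.2
  cells2 <- quantify_markers(segment_cells(ph$channels$DAPI),
                             ph$channels[names(ph$channels) != "DAPI"])
  tt <- ph$true_cells
  idx <- vapply(seq_len(nrow(cells2)), function(i)
    which.min((tt$y - cells2$y[i])^2 + (tt$x - cells2$x[i])^2), 0L)
  for (p in unique(tt$population)) {
    sel <- tt$population[idx] == p
    for (m in c("CD3", "CD8", "CD38")) {
      est <- mean(cells2[[paste0(m, "_log2")]][sel], na.rm = TRUE)
      tru <- mean(tt[[paste0(m, "_log2")]][tt$population == p])
      expect_lt(abs(est - tru), 0.2)
    }
  }
})

test_that("outlier rule matches the Gaussian 3-sigma tail and edge cases", {
  make_table <- function(v) {
    df <- data.frame(cell = seq_along(v), y = 0, x = 0, area_px = 1,
                     diameter_px = 20, qc_excluded = FALSE,
                     flag_outlier = FALSE, M = v)
    class(df) <- c("cell_table", "data.frame")
    attr(df, "markers") <- "M"
    df
  }
  set.seed(31)
  n <- 1e5
  tab <- exclude_outliers(make_table(rnorm(n)))
  p0 <- 2 * pnorm(-3)
  ci <- p0 + c(-1, 1) * qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  frac <- attr(tab, "excluded_fraction")
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])

  # constant values: sd 0 policy excludes nothing
  expect_equal(attr(exclude_outliers(make_table(rep(2, 50))),
                    "excluded_fraction"), 0)

  # one injected 10-sigma cell is exactly the flagged one (background
  # clipped inside 2.5 sigma so no natural tail cell competes)
  v <- pmin(pmax(rnorm(500), -2.5), 2.5)
  v[123] <- 10 * sd(v)
  tab2 <- exclude_outliers(make_table(v))
  expect_equal(which(tab2$flag_outlier), 123)
})

test_that("CD3 gating hits the generator fraction and is monotone", {
  ph <- make_cycif_phantom(small_cycif_spec(n_cells = 150L, seed = 12L))
  cells <- gate_cd3(exclude_outliers(quantify_markers(
    segment_cells(ph$channels$DAPI),
    ph$channels[names(ph$channels) != "DAPI"])))
  expect_equal(mean(cells$cd3_pos, na.rm = TRUE), 0.40, tolerance = 0.05)

  # explicit extreme thresholds
  hi <- gate_cd3(cells, threshold = 1e6)
  expect_equal(sum(hi$cd3_pos, na.rm = TRUE), 0)
  lo <- gate_cd3(cells, threshold = -1e6)
  expect_true(all(lo$cd3_pos[!lo$qc_excluded & !lo$flag_outlier]))

  # monotone: raising the threshold never gains positives
  thr <- sort(runif(10, -2, 6))
  counts <- vapply(thr, function(t)
    sum(gate_cd3(cells, threshold = t)$cd3_pos, na.rm = TRUE), 0L)
  expect_true(all(diff(counts) <= 0))

  # degenerate distribution in auto mode is an error asking for a threshold
  flat <- cells; flat$CD3 <- 0
  expect_error(gate_cd3(flat), "explicit")
})

test_that("marker distribution summaries are tidy and correct", {
  ph <- make_cycif_phantom(small_cycif_spec(n_cells = 120L, seed = 14L))
  cells <- gate_cd3(exclude_outliers(quantify_markers(
    segment_cells(ph$channels$DAPI),
    ph$channels[names(ph$channels) != "DAPI"])))
  d <- marker_distributions(cells, c("CD3", "TIM3"))
  expect_setequal(unique(d$population), c("CD3+", "CD3-"))
  expect_equal(nrow(d), 4)
  cd3p <- d[d$marker == "CD3" & d$population == "CD3+", ]
  cd3n <- d[d$marker == "CD3" & d$population == "CD3-", ]
  expect_gt(cd3p$median, cd3n$median)
  expect_equal(cd3p$n + cd3n$n,
               sum(!cells$qc_excluded & !cells$flag_outlier))

  # single-cell population: median equals its value
  one <- cells[1, , drop = FALSE]
  class(one) <- class(cells)
  one$cd3_pos <- TRUE
  d1 <- marker_distributions(one, "CD3")
  expect_equal(d1$median[d1$population == "CD3+"], one$CD3)
})

test_that("embedding is deterministic and separates the populations", {
  ph <- make_cycif_phantom(small_cycif_spec(n_cells = 120L, seed = 5L))
  cells <- exclude_outliers(quantify_markers(
    segment_cells(ph$channels$DAPI),
    ph$channels[names(ph$channels) != "DAPI"]))
  mk <- c("CD3", "CD4", "CD8", "CD279", "TIM3", "CD38")
  e1 <- embed_cells(cells, mk, seed = 3)
  e2 <- embed_cells(cells, mk, seed = 3)
  expect_identical(e1$umap1, e2$umap1)

  tt <- ph$true_cells
  idx <- vapply(seq_len(nrow(e1)), function(i)
    which.min((tt$y - e1$y[i])^2 + (tt$x - e1$x[i])^2), 0L)
  lab <- ifelse(tt$population[idx] == "CD3neg", 1L, 2L)
  keep <- !is.na(e1$umap1)
  sil <- cluster::silhouette(lab[keep],
                             dist(cbind(e1$umap1, e1$umap2)[keep, ]))
  expect_gt(mean(sil[, 3]), 0.5)

  # minimal input runs and returns coordinates for every cell
  mini <- cells[1:10, ]
  class(mini) <- class(cells)
  e3 <- embed_cells(mini, mk, seed = 1)
  expect_equal(sum(!is.na(e3$umap1)), 10)

  const <- cells
  for (m in mk) const[[m]] <- 1
  expect_error(embed_cells(const, mk), "constant")
})
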