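#' Segmentation parameters for cyclic-IF cell quantification
#'
#' Defaults follow the acquisition software settings used for tissue
#' analysis: nucleus diameter 18–60 px, constrained cytoplasm donut of
#' width 11 px, cytoplasm sensitivity 100%, nucleus detection 90%, nucleus
#' separation 70%. `nucleus_detection` maps to the global intensity
#' threshold (1.0 keeps the plain Otsu cut; lower values raise it) and
#' `nucleus_separation` maps to the watershed merge tolerance (1.0 splits
#' aggressively, 0 merges touching nuclei); both are package calibrations
#' of dimensionless vendor percentages, not vendor equivalents.
#'
#' @param nucleus_diameter_px min/max accepted nucleus diameter in px.
#' @param cytoplasm_donut_width_px ring width in px (>= 1).
#' @param cytoplasm_sensitivity,nucleus_detection,nucleus_separation
#'   fractions in `[0, 1]`.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(nucleus_diameter_px = c(18, 60),
                                cytoplasm_donut_width_px = 11,
                                cytoplasm_sensitivity = 1.00,
                                nucleus_detection = 0.90,
                                nucleus_separation = 0.70) {
  p <- list(nucleus_diameter_px = as.numeric(nucleus_diameter_px),
            cytoplasm_donut_width_px = cytoplasm_donut_width_px,
            cytoplasm_sensitivity = cytoplasm_sensitivity,
            nucleus_detection = nucleus_detection,
            nucleus_separation = nucleus_separation)
  d <- p$nucleus_diameter_px
  if (length(d) != 2 || d[1] <= 0 || d[2] <= d[1])
    stop("nucleus_diameter_px must be (min, max) with 0 < min < max")
  if (p$cytoplasm_donut_width_px < 1) stop("donut width must be >= 1 px")
  for (f in c("cytoplasm_sensitivity", "nucleus_detection",
              "nucleus_separation"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  class(p) <- "segmentation_params"
  p
}

#' Segment nuclei and constrained cytoplasm donuts
#'
#' Nuclei are detected on the (smoothed) DAPI channel by global
#' thresholding scaled by `nucleus_detection`, split by a distance-map
#' watershed whose merge tolerance derives from `nucleus_separation`, and
#' size-filtered to the accepted diameter range. The cytoplasm is measured
#' on a ring of `cytoplasm_donut_width_px` around each nucleus, clipped
#' against neighboring cells by a Voronoi constraint (geodesic propagation
#' of the nucleus labels into the dilated footprint), approximating the
#' vendor's marker-weighted constrained donut with a reproducible geometric
#' rule.
#'
#' @param dapi 2D numeric matrix (nuclear stain).
#' @param params a [segmentation_params()].
#' @param qc_mask optional logical matrix of regions to drop (lint,
#'   out-of-focus); cells overlapping it are flagged `qc_excluded`.
#' @return a `cell_table` data.frame with columns `cell`, `y`, `x`,
#'   `area_px`, `diameter_px`, `qc_excluded`, `flag_outlier`; the nucleus
#'   and donut label images ride in the `"masks"` attribute for
#'   [quantify_markers()]. Empty (no nuclei) tables are returned with a
#'   warning.
#' @export
segment_cells <- function(dapi, params = segmentation_params(),
                          qc_mask = NULL) {
  stopifnot(is.matrix(dapi))
  img <- EBImage::Image(dapi)
  sm <- EBImage::gblur(img, sigma = 2)
  base_thr <- otsu_threshold(as.numeric(sm))
  empty <- function() {
    warning("no nuclei detected")
    res <- data.frame(cell = integer(0), y = numeric(0), x = numeric(0),
                      area_px = numeric(0), diameter_px = numeric(0),
                      qc_excluded = logical(0), flag_outlier = logical(0))
    class(res) <- c("cell_table", "data.frame")
    res
  }
  if (is.na(base_thr)) return(empty())
  thr <- base_thr * (2 - params$nucleus_detection)
  bin <- EBImage::fillHull(sm > thr)
  if (sum(bin) == 0) return(empty())

  dmap <- EBImage::distmap(bin)
  tol <- (1 - params$nucleus_separation) * params$nucleus_diameter_px[2] / 2
  ws <- EBImage::watershed(dmap, tolerance = max(tol, 0.1), ext = 1)
  lab <- array(as.integer(EBImage::imageData(ws)), dim = dim(dapi))

  nlab <- max(lab)
  if (nlab == 0) return(empty())
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  diam <- 2 * sqrt(areas / pi)
  keep <- which(diam >= params$nucleus_diameter_px[1] &
                  diam <= params$nucleus_diameter_px[2])
  if (length(keep) == 0) return(empty())

  relab <- array(0L, dim(lab))
  for (i in seq_along(keep)) relab[lab == keep[i]] <- i
  idx <- which(relab > 0L)
  ai <- arrayInd(idx, dim(relab))
  cy <- tapply(ai[, 1], relab[idx], mean)
  cx <- tapply(ai[, 2], relab[idx], mean)

  w <- params$cytoplasm_donut_width_px
  foot <- EBImage::dilate(relab > 0L,
                          EBImage::makeBrush(2 * floor(w) + 1, "disc"))
  vor <- EBImage::propagate(EBImage::Image(array(0, dim(dapi))),
                            seeds = EBImage::Image(relab),
                            mask = foot, lambda = 1e8)
  vor <- array(as.integer(EBImage::imageData(vor)), dim = dim(dapi))
  donut <- vor
  donut[relab > 0L] <- 0L  # ring only: Voronoi cell minus own nucleus

  res <- data.frame(cell = seq_along(keep), y = as.numeric(cy),
                    x = as.numeric(cx), area_px = areas[keep],
                    diameter_px = diam[keep])
  res$qc_excluded <- FALSE
  if (!is.null(qc_mask)) {
    stopifnot(identical(dim(qc_mask), dim(dapi)))
    bad <- unique(relab[qc_mask & relab > 0L])
    res$qc_excluded <- res$cell %in% bad
  }
  res$flag_outlier <- FALSE
  class(res) <- c("cell_table", "data.frame")
  attr(res, "masks") <- list(nucleus = relab, donut = donut)
  attr(res, "params") <- params
  res
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x), " cells",
      if (any(x$qc_excluded)) paste0(", ", sum(x$qc_excluded), " QC-excluded"),
      if (any(x$flag_outlier)) paste0(", ", sum(x$flag_outlier), " outliers"),
      "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Quantify marker intensities per cell
#'
#' For each channel, computes the mean raw intensity over the cell's
#' measurement compartment (cytoplasm donut by default — appropriate for
#' membrane markers — or nucleus), applies `log2(x + 1)`, and shifts each
#' channel so its background mode sits at 0: the mode of the per-cell log2
#' values, estimated as the fullest bin of a 64-bin histogram, is
#' subtracted. Columns `<marker>_raw`, `<marker>_log2` (pre-shift) and
#' `<marker>` (mode-centered) are appended.
#'
#' @param cells a `cell_table` from [segment_cells()].
#' @param channels named list of 2D matrices, same grid as the DAPI image.
#' @param compartment `"donut"` (default) or `"nucleus"`, or a named
#'   character vector per marker.
#' @param clip_at_zero clip mode-centered values at 0 (default `FALSE`).
#' @return the `cell_table` with intensity columns appended; the `"markers"`
#'   attribute lists the quantified channel names.
#' @export
quantify_markers <- function(cells, channels,
                             compartment = "donut",
                             clip_at_zero = FALSE) {
  stopifnot(inherits(cells, "cell_table"))
  masks <- attr(cells, "masks")
  if (is.null(masks)) stop("cell table carries no segmentation masks")
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list")
  n <- nrow(cells)
  comp_for <- function(m) {
    cp <- if (length(compartment) > 1 || !is.null(names(compartment)))
      (compartment[[m]] %||% "donut") else compartment
    match.arg(cp, c("donut", "nucleus"))
  }
  for (m in names(channels)) {
    ch <- channels[[m]]
    if (!identical(dim(ch), dim(masks$nucleus)))
      stop("channel '", m, "' is not on the segmentation grid")
    labimg <- masks[[comp_for(m)]]
    sums <- tapply(ch[labimg > 0L], labimg[labimg > 0L], mean)
    raw <- rep(NA_real_, n)
    raw[as.integer(names(sums))] <- as.numeric(sums)
    lg <- log2(raw + 1)
    shift <- hist_mode(lg, n_bins = 64)
    nrm <- lg - shift
    if (clip_at_zero) nrm <- pmax(nrm, 0)
    cells[[paste0(m, "_raw")]] <- raw
    cells[[paste0(m, "_log2")]] <- lg
    cells[[m]] <- nrm
  }
  attr(cells, "markers") <- names(channels)
  cells
}

#' Flag marker-intensity outliers
#'
#' Single-pass rule: a cell is an outlier if any of its marker intensities
#' falls outside mean ± `k_sd` standard deviations of that channel
#' (statistics computed once on QC-passing cells). Channels with zero
#' spread exclude nothing. The excluded fraction is reported in the
#' `"excluded_fraction"` attribute.
#'
#' @param cells a quantified `cell_table`.
#' @param k_sd number of standard deviations (default 3).
#' @param markers channels to screen (default: all quantified markers).
#' @return the `cell_table` with `flag_outlier` set.
#' @export
exclude_outliers <- function(cells, k_sd = 3, markers = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  markers <- markers %||% attr(cells, "markers")
  if (is.null(markers)) stop("no quantified markers found")
  if (nrow(cells) < 10) stop("outlier screening needs at least 10 cells")
  base <- !cells$qc_excluded
  out <- rep(FALSE, nrow(cells))
  for (m in markers) {
    v <- cells[[m]]
    mu <- mean(v[base], na.rm = TRUE)
    s <- sd(v[base], na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    out <- out | (!is.na(v) & abs(v - mu) > k_sd * s)
  }
  cells$flag_outlier <- out & base
  attr(cells, "excluded_fraction") <- sum(cells$flag_outlier) / sum(base)
  cells
}

#' Gate CD3-positive cells (and CD4/CD8 subsets)
#'
#' Thresholds the CD3 intensity of QC-passing, non-outlier cells. In
#' `"auto"` mode the threshold is Otsu's cut on the CD3 distribution,
#' computed per treatment group when a `group` column is present
#' (mirroring a per-group heuristic choice); an explicit numeric threshold
#' overrides it. Cells above threshold are CD3-positive; CD4/CD8 sublabels
#' are assigned within the CD3-positive compartment by the same rule on
#' their channels. Flagged cells get `NA` gates.
#'
#' @param cells a quantified `cell_table`.
#' @param cd3,cd4,cd8 channel names (set `cd4`/`cd8` to `NULL` to skip
#'   subsetting).
#' @param threshold explicit CD3 threshold, or `NULL` for auto (Otsu).
#' @return the `cell_table` with logical columns `cd3_pos`, and `cd4_pos`,
#'   `cd8_pos` within CD3+; thresholds used are stored in the
#'   `"gate_thresholds"` attribute.
#' @export
gate_cd3 <- function(cells, cd3 = "CD3", cd4 = "CD4", cd8 = "CD8",
                     threshold = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  if (!cd3 %in% names(cells)) stop("CD3 channel '", cd3, "' not quantified")
  usable <- !cells$qc_excluded & !cells$flag_outlier
  grp <- if ("group" %in% names(cells)) as.character(cells$group)
         else rep("all", nrow(cells))
  thr_used <- list()
  cells$cd3_pos <- NA
  for (g in unique(grp)) {
    sel <- usable & grp == g
    thr <- threshold %||% otsu_threshold(cells[[cd3]][sel])
    if (is.na(thr))
      stop("CD3 distribution in group '", g, "' is degenerate; ",
           "supply an explicit threshold")
    cells$cd3_pos[sel] <- cells[[cd3]][sel] > thr
    thr_used[[g]] <- thr
  }
  for (sub in c(cd4, cd8)) {
    if (is.null(sub) || !sub %in% names(cells)) next
    col <- paste0(tolower(sub), "_pos")
    cells[[col]] <- NA
    pos <- usable & !is.na(cells$cd3_pos) & cells$cd3_pos
    if (sum(pos) >= 2) {
      thr <- otsu_threshold(cells[[sub]][pos])
      if (!is.na(thr)) cells[[col]][pos] <- cells[[sub]][pos] > thr
    }
  }
  attr(cells, "gate_thresholds") <- thr_used
  cells
}

#' Per-population marker distribution summaries
#'
#' Tidy summary of marker intensity by population (CD3+/CD3− by default)
#' and group: n, median, quartiles, mean, and — when a threshold is given —
#' the positive fraction.
#'
#' @param cells a gated `cell_table`.
#' @param markers channels to summarize.
#' @param thresholds optional named numeric vector of per-marker positivity
#'   thresholds.
#' @param population_col column defining populations (default `"cd3_pos"`,
#'   rendered as `CD3+` / `CD3-`).
#' @return data.frame with one row per (marker, population, group).
#' @export
marker_distributions <- function(cells, markers, thresholds = NULL,
                                 population_col = "cd3_pos") {
  stopifnot(inherits(cells, "cell_table"))
  usable <- !cells$qc_excluded & !cells$flag_outlier
  pop <- cells[[population_col]]
  pop_lab <- if (is.logical(pop)) ifelse(pop, "CD3+", "CD3-")
             else as.character(pop)
  grp <- if ("group" %in% names(cells)) as.character(cells$group)
         else rep("all", nrow(cells))
  rows <- list()
  for (m in markers) {
    for (g in unique(grp)) for (p in unique(pop_lab[!is.na(pop_lab)])) {
      sel <- usable & grp == g & !is.na(pop_lab) & pop_lab == p
      v <- cells[[m]][sel]
      v <- v[is.finite(v)]
      q <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75))
           else rep(NA_real_, 3)
      rows[[length(rows) + 1]] <- data.frame(
        marker = m, population = p, group = g, n = length(v),
        median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3]),
        iqr = unname(q[3] - q[1]), mean = if (length(v)) mean(v) else NA_real_,
        positive_fraction = if (!is.null(thresholds) && m %in% names(thresholds))
          mean(v > thresholds[[m]]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Embed cells into 2D by their marker profile
#'
#' Standardizes the marker matrix of usable cells and projects it to two
#' dimensions with UMAP (via \pkg{uwot}, single-threaded so a fixed seed
#' gives identical coordinates). Coordinates are attached as `umap1`,
#' `umap2` (`NA` for flagged cells).
#'
#' @param cells a quantified `cell_table` (>= 10 usable cells).
#' @param markers channels to embed on (>= 2).
#' @param n_neighbors UMAP neighborhood size (capped at n − 1).
#' @param seed RNG seed for the embedding.
#' @return the `cell_table` with `umap1`/`umap2` columns.
#' @export
embed_cells <- function(cells, markers, n_neighbors = 15L, seed = 1L) {
  stopifnot(inherits(cells, "cell_table"))
  if (length(markers) < 2) stop("need at least 2 markers to embed")
  usable <- !cells$qc_excluded & !cells$flag_outlier
  X0 <- as.matrix(as.data.frame(cells)[usable, markers, drop = FALSE])
  cc <- complete.cases(X0)
  X <- X0[cc, , drop = FALSE]
  if (nrow(X) < 10) stop("need at least 10 usable cells to embed")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) stop("constant marker matrix cannot be embedded")
  Xs <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  set.seed(seed)
  emb <- uwot::umap(Xs, n_neighbors = min(n_neighbors, nrow(Xs) - 1L),
                    n_threads = 1, n_sgd_threads = 0)
  cells$umap1 <- NA_real_
  cells$umap2 <- NA_real_
  rows <- which(usable)[cc]
  cells$umap1[rows] <- emb[, 1]
  cells$umap2[rows] <- emb[, 2]
  cells
}
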