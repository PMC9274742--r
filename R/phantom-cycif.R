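#' Specification of a 2D cyclic-immunofluorescence phantom
#'
#' Describes a synthetic multiplexed-IF field of view: non-overlapping
#' circular nuclei (DAPI channel) with a cytoplasm ring, where each cell
#' belongs to one of several populations and draws its per-marker
#' log2 intensity from that population's normal model. Markers are rendered
#' uniformly over the cell footprint (nucleus + ring) at a raw value of
#' `2^log2 - 1`, so a perfect quantification recovers the drawn log2 value
#' through the package's `log2(x + 1)` transform.
#'
#' The default populations emulate a tumor infiltrate: a CD3-negative
#' compartment (60%) and CD3-positive CD4 and CD8 T cells (25% + 15%,
#' i.e. 40% CD3-positive overall), over a 6-marker panel
#' (CD3, CD4, CD8, CD279, TIM3, CD38).
#'
#' @param image_shape pixels (rows, cols).
#' @param n_cells number of cells to place.
#' @param nucleus_diameter_px_range min/max nucleus diameter in px.
#' @param donut_width_px cytoplasm ring width in px (>= 1).
#' @param populations list of `list(name, fraction, markers)` where
#'   `markers` is a named list of `c(mean, sd)` log2-intensity parameters;
#'   fractions must sum to 1 and all populations must share one marker panel.
#' @param background_level additive background in every marker channel (a.u.).
#' @param dapi_intensity range of per-cell DAPI brightness.
#' @param noise_sd additive Gaussian pixel noise (clipped at 0).
#' @param seed integer RNG seed.
#' @return a `cycif_phantom_spec` list.
#' @export
cycif_phantom_spec <- function(
    image_shape = c(800L, 800L),
    n_cells = 200L,
    nucleus_diameter_px_range = c(20, 40),
    donut_width_px = 11,
    populations = cycif_default_populations(),
    background_level = 0.5,
    dapi_intensity = c(150, 250),
    noise_sd = 0.2,
    seed = 1L) {
  spec <- list(image_shape = as.integer(rep_len(image_shape, 2L)),
               n_cells = as.integer(n_cells),
               nucleus_diameter_px_range = as.numeric(nucleus_diameter_px_range),
               donut_width_px = donut_width_px,
               populations = populations,
               background_level = background_level,
               dapi_intensity = dapi_intensity,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "cycif_phantom_spec"
  validate_cycif_phantom_spec(spec)
  spec
}

#' @rdname cycif_phantom_spec
#' @export
cycif_default_populations <- function() {
  pan <- c("CD3", "CD4", "CD8", "CD279", "TIM3", "CD38")
  mk <- function(means, sd = 0.4)
    setNames(lapply(means, function(mu) c(mu, sd)), pan)
  list(
    list(name = "CD3neg", fraction = 0.60,
         markers = mk(c(3, 3, 3, 3.5, 3, 4))),
    list(name = "CD4_T", fraction = 0.25,
         markers = mk(c(7, 7, 3, 5, 4.5, 5))),
    list(name = "CD8_T", fraction = 0.15,
         markers = mk(c(7, 3, 7, 5.5, 5, 5.5)))
  )
}

validate_cycif_phantom_spec <- function(spec) {
  fr <- vapply(spec$populations, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("population fractions must sum to 1")
  if (spec$donut_width_px < 1) stop("donut_width_px must be >= 1")
  r <- spec$nucleus_diameter_px_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1])
    stop("invalid nucleus_diameter_px_range")
  panels <- lapply(spec$populations, function(p) sort(names(p$markers)))
  if (length(unique(panels)) != 1)
    stop("all populations must share one marker panel")
  invisible(spec)
}

#' Generate a 2D cyclic-immunofluorescence phantom
#'
#' Places non-overlapping nuclei uniformly (bounded rejection sampling;
#' errors if the requested count cannot be placed), assigns populations by
#' their fractions, draws marker log2 intensities, and renders the DAPI and
#' marker channels.
#'
#' @param spec a [cycif_phantom_spec()].
#' @return list with `channels` (named list of matrices: `DAPI` + one per
#'   marker), `true_cells` (data.frame: cell, y, x, radius_px, population,
#'   and one `<marker>_log2` column per marker), and `spec`.
#' @export
make_cycif_phantom <- function(spec) {
  stopifnot(inherits(spec, "cycif_phantom_spec"))
  validate_cycif_phantom_spec(spec)
  set.seed(spec$seed)
  dim2 <- spec$image_shape
  n <- spec$n_cells
  rr <- spec$nucleus_diameter_px_range / 2

  radius <- runif(n, rr[1], rr[2])
  margin <- radius + spec$donut_width_px + 2
  ys <- numeric(0); xs <- numeric(0); rs <- numeric(0)
  tries <- 0L
  budget <- 200L * n
  for (i in seq_len(n)) {
    placed <- FALSE
    while (!placed && tries < budget) {
      tries <- tries + 1L
      y <- runif(1, margin[i], dim2[1] - margin[i])
      x <- runif(1, margin[i], dim2[2] - margin[i])
      if (length(ys) == 0 ||
          all((ys - y)^2 + (xs - x)^2 > (rs + radius[i] + 2)^2)) {
        ys <- c(ys, y); xs <- c(xs, x); rs <- c(rs, radius[i])
        placed <- TRUE
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping cells; achieved ",
           length(ys), " after ", tries, " attempts")
  }

  # deterministic composition: exact population counts (largest-remainder
  # rounding), randomly shuffled — the stated fractions are ground truth,
  # not a sampling probability, so recovery tests see no multinomial noise
  fr <- vapply(spec$populations, `[[`, 0, "fraction")
  pop_names <- vapply(spec$populations, `[[`, "", "name")
  counts <- diff(c(0, round(cumsum(fr) * n)))
  pop <- sample(rep(pop_names, counts))
  markers <- names(spec$populations[[1]]$markers)

  log2_vals <- matrix(0, n, length(markers),
                      dimnames = list(NULL, markers))
  for (p in spec$populations) {
    sel <- pop == p$name
    if (!any(sel)) next
    for (m in markers) {
      pars <- p$markers[[m]]
      log2_vals[sel, m] <- rnorm(sum(sel), pars[1], pars[2])
    }
  }

  dapi <- matrix(0, dim2[1], dim2[2])
  chans <- setNames(replicate(length(markers),
                              matrix(0, dim2[1], dim2[2]),
                              simplify = FALSE), markers)
  dapi_amp <- runif(n, spec$dapi_intensity[1], spec$dapi_intensity[2])
  # overlapping cytoplasm footprints are resolved by smallest distance to
  # the owning nucleus boundary, mirroring the Voronoi constraint used at
  # quantification
  owner_bd <- matrix(Inf, dim2[1], dim2[2])
  for (i in seq_len(n)) {
    foot_r <- rs[i] + spec$donut_width_px
    yy <- max(1, floor(ys[i] - foot_r)):min(dim2[1], ceiling(ys[i] + foot_r))
    xx <- max(1, floor(xs[i] - foot_r)):min(dim2[2], ceiling(xs[i] + foot_r))
    d2 <- outer((yy - ys[i])^2, (xx - xs[i])^2, `+`)
    nuc <- d2 <= rs[i]^2
    bd <- sqrt(d2) - rs[i]
    claim <- d2 <= foot_r^2 & bd < owner_bd[yy, xx]
    dapi[yy, xx][nuc] <- dapi_amp[i]
    od <- owner_bd[yy, xx]; od[claim] <- bd[claim]; owner_bd[yy, xx] <- od
    for (m in markers) {
      val <- 2^log2_vals[i, m] - 1
      sub <- chans[[m]][yy, xx]
      sub[claim] <- val
      chans[[m]][yy, xx] <- sub
    }
  }
  # soften nuclear edges slightly so watershed sees smooth peaks
  dapi <- as.matrix(EBImage::gblur(EBImage::Image(dapi), sigma = 1))
  noisify <- function(ch, bg) {
    ch <- ch + bg
    if (spec$noise_sd > 0)
      ch <- ch + matrix(rnorm(length(ch), 0, spec$noise_sd),
                        nrow(ch), ncol(ch))
    pmax(ch, 0)
  }
  dapi <- noisify(dapi, 0)
  chans <- lapply(chans, noisify, bg = spec$background_level)

  truth <- data.frame(cell = seq_len(n), y = ys, x = xs, radius_px = rs,
                      population = pop)
  for (m in markers) truth[[paste0(m, "_log2")]] <- log2_vals[, m]

  list(channels = c(list(DAPI = dapi), chans), true_cells = truth,
       spec = spec)
}
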