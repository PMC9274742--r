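#' Point-like detected cells in a 3D volume
#'
#' A data frame subclass holding one row per spot: physical center
#' coordinates `z_um`, `y_um`, `x_um`, the spot radius `radius_um`, and a
#' representative `intensity`. The `provenance` attribute records whether
#' the spots were `"detected"` or come from generator `"ground_truth"`.
#'
#' @param coords n x 3 matrix of physical (z, y, x) coordinates.
#' @param radius_um per-spot radius (recycled).
#' @param intensity per-spot intensity (recycled).
#' @param provenance `"detected"` or `"ground_truth"`.
#' @return a `spot_set` data frame.
#' @export
spot_set <- function(coords, radius_um = numeric(), intensity = numeric(),
                     provenance = c("detected", "ground_truth")) {
  provenance <- match.arg(provenance)
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  df <- data.frame(z_um = coords[, 1], y_um = coords[, 2], x_um = coords[, 3],
                   radius_um = rep_len(as.numeric(radius_um), n),
                   intensity = rep_len(as.numeric(intensity), n))
  if (n == 0) df <- df[0, ]
  structure(df, class = c("spot_set", "data.frame"), provenance = provenance)
}

#' @export
print.spot_set <- function(x, ...) {
  cat("<spot_set> ", nrow(x), " spots (", attr(x, "provenance"), ")\n",
      sep = "")
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... and", nrow(x) - 5, "more\n")
  invisible(x)
}

spot_coords <- function(spots) {
  as.matrix(as.data.frame(spots)[, c("z_um", "y_um", "x_um")])
}
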