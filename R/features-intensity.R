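#' Intensity features of a masked image region
#'
#' The 12 canonical intensity measurements over the in-mask pixels:
#' integrated (sum), mean, median, population standard deviation, unscaled
#' median absolute deviation, min, max, lower and upper quartile (linear
#' interpolation), integrated and mean intensity over the boundary ("edge")
#' pixels, and mass displacement — the Euclidean distance (px) between the
#' binary centroid and the intensity-weighted centroid.
#'
#' @param mask Logical matrix, non-empty.
#' @param image Numeric matrix of the same dimension.
#' @return Named numeric vector of length 12.
#' @export
intensity_features <- function(mask, image) {
  if (!any(mask)) abort("intensity_features: empty mask")
  stopifnot(all(dim(mask) == dim(image)))
  v <- image[mask]
  edge <- mask_boundary(mask)
  ve <- image[edge]
  nr <- nrow(mask)
  idx <- which(mask)
  r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
  tot <- sum(v)
  md <- if (tot > 0) {
    sqrt((sum(r * v) / tot - mean(r))^2 + (sum(c * v) / tot - mean(c))^2)
  } else 0
  q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  c(integrated = tot, mean = mean(v), median = median(v), std = sd_pop(v),
    mad = median(abs(v - median(v))), min = min(v), max = max(v),
    lower_quartile = q[1], upper_quartile = q[2],
    edge_integrated = sum(ve), edge_mean = mean(ve),
    mass_displacement = md)
}

#' Peripheral actin metric: edge intensity normalised to area
#'
#' Integrated boundary intensity divided by the mask area — the per-cell
#' summary used to contrast peripheral actin organisation across phenotypes.
#' For a constant image of value v it equals v * (boundary px / area).
#'
#' @inheritParams intensity_features
#' @return A single number.
#' @export
edge_intensity_per_area <- function(mask, image) {
  f <- intensity_features(mask, image)
  unname(f["edge_integrated"]) / sum(mask)
}
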