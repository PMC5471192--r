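#' Radial intensity distribution over four concentric bins
#'
#' The mask is partitioned into 4 bins of equal width in normalized
#' distance-from-edge (distance transform scaled to (0, 1] toward the in-mask
#' point farthest from the edge; bin 1 is the outermost shell, bin 4 the
#' innermost core). Per bin: `frac_at_d` — the fraction of total integrated
#' intensity falling in the bin; `mean_frac` — `frac_at_d` divided by the
#' bin's area fraction (1 everywhere for a uniform image); `radial_cv` — the
#' coefficient of variation (population sd / mean) of mean intensity across 8
#' angular wedges around the farthest-from-edge reference point. Degenerate
#' values (empty bin, zero mean) are imputed as 0.
#'
#' @param mask Logical matrix, non-empty.
#' @param image Numeric matrix of the same dimension.
#' @return Named numeric vector of length 12
#'   (frac_at_d_1..4, mean_frac_1..4, radial_cv_1..4).
#' @export
radial_distribution <- function(mask, image) {
  if (!any(mask)) abort("radial_distribution: empty mask")
  stopifnot(all(dim(mask) == dim(image)))
  dm <- mask_distmap(mask)
  dmax <- max(dm)
  d <- dm[mask] / dmax                    # in (0, 1]
  bin <- pmax(1L, ceiling(4 * d))         # 1 = outermost shell
  v <- image[mask]
  tot <- sum(v)
  A <- sum(mask)

  nr <- nrow(mask)
  ref <- which.max(dm)                    # farthest-from-edge reference point
  r0 <- (ref - 1) %% nr + 1; c0 <- (ref - 1) %/% nr + 1
  idx <- which(mask)
  r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
  ang <- atan2(r - r0, c - c0)            # (-pi, pi]
  wedge <- pmin(8L, 1L + floor((ang + pi) / (2 * pi) * 8))

  frac <- mean_frac <- rcv <- numeric(4)
  for (b in 1:4) {
    in_b <- bin == b
    if (!any(in_b)) next                  # imputed 0 for empty bins
    frac[b] <- if (tot > 0) sum(v[in_b]) / tot else 0
    mean_frac[b] <- frac[b] / (sum(in_b) / A)
    wm <- tapply(v[in_b], wedge[in_b], mean)
    mu <- mean(wm)
    rcv[b] <- if (length(wm) > 1 && mu != 0) sd_pop(wm) / mu else 0
  }
  setNames(c(frac, mean_frac, rcv), radial_feature_names())
}
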