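# Cell/nucleus contour model and rasterization.
#
# A cell outline is the polar curve r(theta) = R * (1 + sum_{k=2..6} a_k
# cos(k*theta + phi_k)) mapped through an anisotropic (elongation) scaling and
# a rotation. Low-order harmonics give lamellar/irregular outlines without
# self-intersection, and the area-preserving elongation mapping
# (x, y) = (u*sqrt(e), v/sqrt(e)) keeps the expected area at pi*R^2
# independent of elongation.

# Evaluate the perturbed radius at polar angle t (vectorised).
blob_radius <- function(t, R, amps, phis) {
  r <- rep(1, length(t))
  for (k in seq_along(amps)) {
    r <- r + amps[k] * cos((k + 1) * t + phis[k])
  }
  R * r
}

# Rasterize the blob on a pixel grid. Pixel (i, j) has centre (i, j) in
# (row, col) coordinates; the blob centre sits at (cy, cx). Returns a logical
# matrix of dimension nr x nc.
rasterize_blob <- function(nr, nc, cy, cx, R, elong = 1, theta = 0,
                           amps = numeric(0), phis = numeric(0)) {
  rr <- matrix(seq_len(nr) - cy, nr, nc)
  cc <- matrix(rep(seq_len(nc) - cx, each = nr), nr, nc)
  # rotate into the blob frame, then undo the elongation scaling
  x <-  cos(theta) * cc + sin(theta) * rr
  y <- -sin(theta) * cc + cos(theta) * rr
  sqe <- sqrt(elong)
  u <- x / sqe
  v <- y * sqe
  t <- atan2(v, u)
  rad <- blob_radius(t, R, amps, phis)
  matrix(u * u + v * v <= rad * rad, nr, nc)
}

#' Draw one cell + nucleus geometry from a phenotype archetype
#'
#' Samples radius, elongation, orientation and boundary harmonics from the
#' archetype's distributions (truncated at physical bounds) and rasterizes a
#' placement-free cell mask with a nucleus mask fully inside it. Uses the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param archetype One row of [phenotype_archetypes()] (or a compatible list).
#' @return A list with logical matrices `cell_mask` and `nucleus_mask` (same
#'   dimensions, nucleus a subset of the cell), the crop centre `centre`
#'   (row, col), and the sampled `params`.
#' @export
#' @examples
#' set.seed(1)
#' g <- sample_cell_geometry(phenotype_archetypes()[5, ])
#' sum(g$cell_mask)  # cell area in px^2
sample_cell_geometry <- function(archetype) {
  validate_archetype(archetype)
  a <- as.list(archetype)

  R     <- rtnorm1(1, a$cell_radius_mean, a$cell_radius_sd, lower = 5)
  elong <- rtnorm1(1, a$elongation_mean, a$elongation_sd, lower = 1)
  theta <- runif(1, 0, pi)
  ks    <- 2:6
  amps  <- runif(5, -a$boundary_irregularity / ks, a$boundary_irregularity / ks)
  phis  <- runif(5, 0, 2 * pi)

  # crop sized to hold the worst-case extent
  ext  <- R * (1 + sum(abs(amps))) * sqrt(elong) + 2
  half <- ceiling(ext)
  side <- 2L * half + 1L
  cy <- cx <- half + 1L
  cell <- rasterize_blob(side, side, cy, cx, R, elong, theta, amps, phis)

  # nucleus: mildly elliptical, clamped to fit the cell's minor semi-axis
  minor_semi <- R * (1 - sum(abs(amps))) / sqrt(elong)
  nuc_r <- rtnorm1(1, a$nucleus_radius_mean, a$nucleus_radius_sd, lower = 4.5)
  nuc_r <- min(nuc_r, 0.8 * minor_semi)
  nuc_e <- 1 + (elong - 1) * 0.3
  off   <- a$nucleus_offset_frac * R
  ang   <- runif(1, 0, 2 * pi)
  ncy <- cy + off * sin(ang)
  ncx <- cx + off * cos(ang)
  nucleus <- rasterize_blob(side, side, ncy, ncx, nuc_r, nuc_e, theta)
  # pull the nucleus back toward the centre until it sits inside the cell
  k <- 0L
  while (any(nucleus & !cell) && k < 8L) {
    off <- off * 0.6
    ncy <- cy + off * sin(ang)
    ncx <- cx + off * cos(ang)
    nucleus <- rasterize_blob(side, side, ncy, ncx, nuc_r, nuc_e, theta)
    k <- k + 1L
  }
  nucleus <- nucleus & cell

  list(
    cell_mask = cell,
    nucleus_mask = nucleus,
    centre = c(cy, cx),
    params = list(R = R, elongation = elong, theta = theta, amps = amps,
                  phis = phis, nucleus_radius = nuc_r,
                  nucleus_centre = c(ncy, ncx))
  )
}
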