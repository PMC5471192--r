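#' Default phenotype archetypes for the synthetic-scene generator
#'
#' Each row parameterises the morphology distributions the generator draws
#' cells of one phenotype (sub)population from. The defaults encode the qualitative orderings seen in
#' polarised human monocyte-derived macrophage cultures: day-0 monocytes are
#' small, round and uniform; day-6 monocytes are larger rounded cells with the
#' largest nuclei; naive macrophages are larger and irregular with a cell-area
#' distribution nearly identical to day-6 monocytes; M1 macrophages are
#' smaller, elongated/irregular cells with a dotted, tightly packed actin
#' texture; M2 macrophages are the largest, flattened cells with smooth actin
#' and a pronounced peripheral actin rim.
#'
#' Units: radii in pixels; `elongation` is the major/minor axis ratio (>= 1);
#' `boundary_irregularity` is the amplitude of the radial Fourier perturbation
#' of the contour as a fraction of the radius; `nucleus_offset_frac` displaces
#' the nucleus centroid as a fraction of the cell radius; `actin_spot_density`
#' is punctae per 100 px^2; `actin_smoothness` is the Gaussian sigma (px)
#' applied to the actin texture field; `edge_rim_gain` multiplies intensity
#' within 2 px of the cell boundary; `dna_intensity_scale` is the mean
#' nuclear-channel intensity per nuclear pixel in arbitrary units.
#'
#' Phenotype classes are allowed more than one archetype row: rows sharing a
#' `name` are morphological subpopulations sampled by `weight` (see
#' [draw_class_geometry()]), which supports modelling heterogeneous
#' populations; the default table uses a single row per phenotype.
#'
#' @return A tibble with one row per phenotype in [phenotype_levels()] order.
#' @export
#' @examples
#' phenotype_archetypes()
phenotype_archetypes <- function() {
  tibble(
    name                  = phenotype_levels(),
    weight                = 1,
    cell_radius_mean      = c(12,   27,   17,    8.5, 16.3),
    cell_radius_sd        = c(1.5,  2.5,  2.5,  0.7,  2.4),
    elongation_mean       = c(1.80, 1.20, 1.15, 1.05, 1.15),
    elongation_sd         = c(0.25, 0.08, 0.08, 0.03, 0.08),
    boundary_irregularity = c(0.25, 0.30, 0.15, 0.03, 0.15),
    nucleus_radius_mean   = c(7,    8.5,  7.5,  6,   10.6),
    nucleus_radius_sd     = c(0.7,  0.9,  0.7,  0.4,  0.9),
    nucleus_offset_frac   = c(0.30, 0.20, 0.20, 0.10, 0.20),
    actin_spot_density    = c(8.0,  0.6,  0.8,  0.8,  0.8),
    actin_smoothness      = c(0.7,  3.0,  2.0,  1.5,  2.0),
    edge_rim_gain         = c(1.4,  1.8,  1.3,  1.2,  1.3),
    dna_intensity_scale   = c(80,   80,   80,   80,   80)
  )
}

#' Validate a phenotype archetype
#'
#' Checks field presence, physical bounds and the cell/nucleus size ordering.
#'
#' @param archetype A one-row data frame (or list) with the fields of
#'   [phenotype_archetypes()].
#' @return The archetype, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_archetype <- function(archetype) {
  a <- as.list(archetype)
  need <- setdiff(names(phenotype_archetypes()), c("name", "weight"))
  missing <- setdiff(need, names(a))
  if (length(missing)) {
    abort(paste0("archetype is missing field(s): ", paste(missing, collapse = ", ")))
  }
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) abort(paste0("invalid archetype field '", field, "': ", why))
  }
  chk(a$cell_radius_mean > 0, "cell_radius_mean", "must be > 0")
  chk(a$cell_radius_sd >= 0, "cell_radius_sd", "must be >= 0")
  chk(a$elongation_mean >= 1, "elongation_mean", "major/minor ratio must be >= 1")
  chk(a$elongation_sd >= 0, "elongation_sd", "must be >= 0")
  chk(a$boundary_irregularity >= 0 && a$boundary_irregularity <= 0.5,
      "boundary_irregularity", "must be in [0, 0.5]")
  chk(a$nucleus_radius_mean > 0, "nucleus_radius_mean", "must be > 0")
  chk(a$nucleus_radius_sd >= 0, "nucleus_radius_sd", "must be >= 0")
  chk(a$nucleus_radius_mean < a$cell_radius_mean, "nucleus_radius_mean",
      "nucleus must be smaller than the cell")
  chk(a$nucleus_offset_frac >= 0 && a$nucleus_offset_frac < 1,
      "nucleus_offset_frac", "must be in [0, 1)")
  chk(a$actin_spot_density >= 0, "actin_spot_density", "must be >= 0")
  chk(a$actin_smoothness >= 0, "actin_smoothness", "must be >= 0")
  chk(a$edge_rim_gain >= 1, "edge_rim_gain", "must be >= 1")
  chk(a$dna_intensity_scale > 0, "dna_intensity_scale", "must be > 0")
  invisible(archetype)
}
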