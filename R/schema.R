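# The fixed 228-measurement cytoprofile schema.
#
# Composition: 14 shape features x 2 objects = 28; 12 intensity features x
# 2 objects x 2 channels = 48; 12 radial-distribution features x 2 x 2 = 48;
# 13 Haralick texture features x 2 objects x 2 channels x 2 scales = 104.
# 28 + 48 + 48 + 104 = 228. Feature order is part of the public contract.

shape_feature_names <- function() {
  c("area", "perimeter", "form_factor", "eccentricity", "solidity", "extent",
    "compactness", "equivalent_diameter", "major_axis_length",
    "minor_axis_length", "orientation", "max_radius", "mean_radius",
    "median_radius")
}

intensity_feature_names <- function() {
  c("integrated", "mean", "median", "std", "mad", "min", "max",
    "lower_quartile", "upper_quartile", "edge_integrated", "edge_mean",
    "mass_displacement")
}

radial_feature_names <- function() {
  c(paste0("frac_at_d_", 1:4), paste0("mean_frac_", 1:4),
    paste0("radial_cv_", 1:4))
}

haralick_feature_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "difference_variance",
    "difference_entropy", "imc1", "imc2")
}

#' The canonical 228-feature cytoprofile schema
#'
#' @param scales Haralick co-occurrence offsets in px (two scales by
#'   construction; the 228-slot arithmetic requires exactly two).
#' @return Tibble with columns name, object, channel, family, scale; exactly
#'   228 rows in the canonical order: shape (nucleus, cell), intensity
#'   (object x channel), radial (object x channel), Haralick (object x
#'   channel x scale).
#' @export
feature_schema <- function(scales = c(3, 8)) {
  stopifnot(length(scales) == 2)
  objects <- c("nucleus", "cell")
  channels <- c("dapi", "actin")
  rows <- list()
  for (ob in objects) {
    rows[[length(rows) + 1]] <- tibble(
      name = paste(ob, "shape", shape_feature_names(), sep = "_"),
      object = ob, channel = "none", family = "shape", scale = NA_real_)
  }
  for (ob in objects) for (ch in channels) {
    rows[[length(rows) + 1]] <- tibble(
      name = paste(ob, ch, "intensity", intensity_feature_names(), sep = "_"),
      object = ob, channel = ch, family = "intensity", scale = NA_real_)
  }
  for (ob in objects) for (ch in channels) {
    rows[[length(rows) + 1]] <- tibble(
      name = paste(ob, ch, "radial", radial_feature_names(), sep = "_"),
      object = ob, channel = ch, family = "radial", scale = NA_real_)
  }
  for (ob in objects) for (ch in channels) for (s in scales) {
    rows[[length(rows) + 1]] <- tibble(
      name = paste(ob, ch, "texture", haralick_feature_names(),
                   paste0("s", s), sep = "_"),
      object = ob, channel = ch, family = "texture", scale = s)
  }
  schema <- bind_rows(rows)
  stopifnot(nrow(schema) == 228, !anyDuplicated(schema$name))
  schema
}

#' Stable hash of the feature schema (order-sensitive)
#' @param schema A [feature_schema()] tibble.
#' @return Character hash.
#' @export
schema_hash <- function(schema = feature_schema()) {
  rlang::hash(schema$name)
}
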