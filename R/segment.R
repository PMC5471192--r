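# Primary (nucleus) and secondary (cell body) object detection.

#' Segmentation parameters
#'
#' @param nucleus_diameter_range Accepted nucleus equivalent-diameter range
#'   (min, max) in px.
#' @param declump_smoothing_sigma Gaussian sigma (px) applied to the distance
#'   transform before watershed declumping.
#' @param actin_threshold_offset Multiplicative factor on the global Otsu
#'   threshold of the actin channel.
#' @param border_policy `"discard"` (drop cells touching the image border) or
#'   `"keep"`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(nucleus_diameter_range = c(8, 60),
                                declump_smoothing_sigma = 2,
                                actin_threshold_offset = 0.9,
                                border_policy = c("discard", "keep")) {
  border_policy <- match.arg(border_policy)
  if (nucleus_diameter_range[1] >= nucleus_diameter_range[2]) {
    abort("nucleus_diameter_range must satisfy min < max")
  }
  if (declump_smoothing_sigma < 0) abort("declump_smoothing_sigma must be >= 0")
  structure(list(nucleus_diameter_range = nucleus_diameter_range,
                 declump_smoothing_sigma = declump_smoothing_sigma,
                 actin_threshold_offset = actin_threshold_offset,
                 border_policy = border_policy),
            class = "segmentation_params")
}

# Per-object boundary refinement. A single global threshold places the
# boundary of a blurred object at a position that depends on its staining
# brightness (bright halos inflate masks, dim cells shrink). Re-thresholding
# each object locally at background + frac * (object median - background)
# puts the boundary at the half-maximum crossing, which is brightness
# invariant. Shrink-only within the object's existing territory.
refine_object_boundaries <- function(lab, img, sigma, frac) {
  ids <- seq_len(max(lab))
  if (!length(ids)) return(lab)
  sm <- EBImage::gblur(img, sigma)
  bg <- median(sm)
  out <- matrix(0L, nrow(lab), ncol(lab))
  H <- nrow(lab)
  for (id in ids) {
    idx <- which(lab == id)
    if (!length(idx)) next
    med <- median(sm[idx])
    if (med <= bg) { out[idx] <- id; next }
    thr <- bg + frac * (med - bg)
    keep <- idx[sm[idx] > thr]
    if (!length(keep)) keep <- idx
    # retain the largest connected component, holes filled
    rr <- ((keep - 1L) %% H) + 1L; cc <- ((keep - 1L) %/% H) + 1L
    r0 <- min(rr) - 1L; c0 <- min(cc) - 1L
    m <- matrix(0, max(rr) - r0, max(cc) - c0)
    m[cbind(rr - r0, cc - c0)] <- 1
    ml <- EBImage::bwlabel(m)
    big <- which.max(tabulate(ml[ml > 0]))
    m <- EBImage::fillHull(matrix(as.numeric(ml == big), nrow(m), ncol(m))) > 0.5
    sel <- which(m)
    srr <- ((sel - 1L) %% nrow(m)) + 1L + r0
    scc <- ((sel - 1L) %/% nrow(m)) + 1L + c0
    out[cbind(srr, scc)] <- id
  }
  out
}

relabel_contiguous <- function(lab) {
  ids <- sort(setdiff(unique(as.vector(lab)), 0))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(match(as.vector(lab), ids, nomatch = 0L), nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  out
}

#' Detect nuclei in the DAPI channel (primary objects)
#'
#' Global Otsu threshold, hole filling, watershed declumping of touching
#' components on the smoothed in-mask distance transform, and removal of
#' components whose equivalent diameter falls outside the accepted range.
#'
#' @param dapi Numeric matrix of nuclear-stain intensities (finite, >= 0).
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background, ids 1..N contiguous).
#' @export
detect_nuclei <- function(dapi, params = segmentation_params()) {
  stopifnot_finite_nonneg(dapi, "dapi")
  rng <- range(dapi)
  if (diff(rng) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  # threshold the log-transformed, noise-suppressed image: Otsu on raw pixels
  # is unreliable when nuclei cover ~1% of the field, and the log transform
  # keeps dimly stained nuclei above a threshold dominated by bright ones
  x <- threshold_image(dapi, 1)
  th <- global_threshold(x)
  mask <- EBImage::fillHull(matrix(as.numeric(x > th), nrow(x), ncol(x))) > 0.5
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  dm <- mask_distmap(mask)
  if (params$declump_smoothing_sigma > 0) {
    dm <- EBImage::gblur(dm, params$declump_smoothing_sigma)
    dm[!mask] <- 0
  }
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  # size filter on equivalent diameter
  drng <- params$nucleus_diameter_range
  a_min <- pi * (drng[1] / 2)^2
  a_max <- pi * (drng[2] / 2)^2
  areas <- tabulate(lab[lab > 0])
  drop_ids <- which(areas < a_min | areas > a_max)
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  lab <- relabel_contiguous(lab)
  refine_object_boundaries(lab, dapi, sigma = 0.5, frac = 0.5)
}

#' Detect cell bodies in the actin channel (secondary objects)
#'
#' Grows cells from nucleus seeds by propagation on the smoothed actin
#' intensity, restricted to the actin foreground mask (global Otsu threshold
#' scaled by `actin_threshold_offset`, always including the seed pixels).
#' Every returned cell label equals its seed nucleus label.
#'
#' @param actin Numeric matrix of actin-stain intensities.
#' @param nuclei Label matrix from [detect_nuclei()] on the same scene.
#' @param params A [segmentation_params()].
#' @return Integer cell label matrix aligned with `nuclei`.
#' @export
detect_cells <- function(actin, nuclei, params = segmentation_params()) {
  stopifnot_finite_nonneg(actin, "actin")
  stopifnot(all(dim(actin) == dim(nuclei)))
  if (!any(nuclei > 0)) return(matrix(0L, nrow(actin), ncol(actin)))
  rng <- range(actin)
  # lighter smoothing than the nuclear channel: the cell boundary is the
  # quantity of interest and over-smoothing rounds off protrusions; log
  # transform as in detect_nuclei so dim cells stay above threshold
  sm <- if (diff(rng) > 0) threshold_image(actin, 0.5) else actin * 0
  th <- if (diff(rng) > 0) global_threshold(sm) * params$actin_threshold_offset else Inf
  fg <- (sm > th) | (nuclei > 0)
  # fill enclosed holes (dim inter-punctae regions) before propagation
  fg <- EBImage::fillHull(matrix(as.numeric(fg), nrow(fg), ncol(fg))) > 0.5
  lab <- EBImage::propagate(sm, seeds = nuclei, mask = fg)
  out <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  out <- refine_object_boundaries(out, actin, sigma = 0.5, frac = 0.45)
  # guarantee nucleus %in% cell even at degenerate thresholds
  out[nuclei > 0] <- nuclei[nuclei > 0]
  out
}

crop_mask <- function(lab_logical, r0, c0, nr, nc) {
  lab_logical[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc), drop = FALSE]
}

#' Pair and quality-filter segmented cells and nuclei
#'
#' Drops cells touching the image border (when `border_policy = "discard"`),
#' cells without a nucleus and nuclei without a cell, relabels contiguously,
#' and returns one record per surviving cell with mask crops.
#'
#' @param cells,nuclei Aligned label matrices sharing seed ids.
#' @param params A [segmentation_params()].
#' @param image_id Provenance string stored on every record.
#' @return Tibble with columns object_id, seed_id, row0/col0 crop offsets,
#'   cell_mask/nucleus_mask logical crops, cell_area, nucleus_area, centroid
#'   and image_id. The nucleus mask is a subset of the cell mask.
#' @export
filter_objects <- function(cells, nuclei, params = segmentation_params(),
                           image_id = NA_character_) {
  stopifnot(all(dim(cells) == dim(nuclei)))
  H <- nrow(cells); W <- ncol(cells)
  ids <- sort(setdiff(unique(as.vector(cells)), 0))
  out <- list(); new_id <- 0L
  for (id in ids) {
    idx <- which(cells == id)
    nidx <- which(nuclei == id & cells == id)
    if (!length(nidx)) next
    rr <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    touches <- any(rr == 1L | rr == H | cc == 1L | cc == W)
    if (touches && params$border_policy == "discard") next
    r0 <- min(rr) - 1L; c0 <- min(cc) - 1L
    nr <- max(rr) - r0; nc <- max(cc) - c0
    cm <- matrix(FALSE, nr, nc)
    cm[cbind(rr - r0, cc - c0)] <- TRUE
    nrr <- ((nidx - 1L) %% H) + 1L
    ncc <- ((nidx - 1L) %/% H) + 1L
    nm <- matrix(FALSE, nr, nc)
    nm[cbind(nrr - r0, ncc - c0)] <- TRUE
    new_id <- new_id + 1L
    out[[new_id]] <- tibble(
      object_id = new_id, seed_id = id, row0 = r0, col0 = c0,
      cell_mask = list(cm), nucleus_mask = list(nm),
      cell_area = length(idx), nucleus_area = length(nidx),
      centroid_row = mean(rr), centroid_col = mean(cc),
      image_id = image_id
    )
  }
  if (!length(out)) {
    return(tibble(object_id = integer(), seed_id = integer(),
                  row0 = integer(), col0 = integer(),
                  cell_mask = list(), nucleus_mask = list(),
                  cell_area = numeric(), nucleus_area = numeric(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  image_id = character()))
  }
  bind_rows(out)
}

#' Segment one two-channel image end to end
#'
#' @param dapi,actin Intensity matrices of equal dimension.
#' @param params A [segmentation_params()].
#' @param image_id Provenance string.
#' @return The [filter_objects()] tibble.
#' @export
segment_image <- function(dapi, actin, params = segmentation_params(),
                          image_id = NA_character_) {
  nuclei <- detect_nuclei(dapi, params)
  cells <- detect_cells(actin, nuclei, params)
  filter_objects(cells, nuclei, params, image_id = image_id)
}
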