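# Two-channel scene rendering with per-cell ground truth.

#' Scene configuration for the synthetic generator
#'
#' @param image_height,image_width Scene size in pixels.
#' @param cells_per_image Number of cells to place (>= 0).
#' @param class_mix Named proportions over [phenotype_levels()]; must be
#'   non-negative and sum to 1.
#' @param background_level Background intensity, arbitrary units.
#' @param gaussian_noise_sd Additive Gaussian read-noise sd.
#' @param poisson_noise Apply Poisson shot noise (logical).
#' @param min_cell_separation Minimum gap between cell masks, px.
#' @param brightness_sdlog Log-sd of the per-cell, per-channel staining
#'   brightness factor (lognormal with mean 1), emulating cell-to-cell
#'   variability in stain uptake; 0 disables it.
#' @param brightness_range Truncation bounds of the brightness factor (keeps
#'   every cell bright enough to threshold).
#' @param rng_seed Integer seed, or NULL to use the current RNG state.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(image_height = 512, image_width = 512,
                         cells_per_image = 18,
                         class_mix = setNames(rep(0.2, 5), phenotype_levels()),
                         background_level = 100, gaussian_noise_sd = 5,
                         poisson_noise = TRUE, min_cell_separation = 2,
                         brightness_sdlog = 0.5,
                         brightness_range = c(0.6, 4),
                         rng_seed = NULL) {
  if (is.null(names(class_mix)) && length(class_mix) == 5) {
    names(class_mix) <- phenotype_levels()
  }
  if (any(class_mix < 0)) abort("class_mix entries must be >= 0")
  if (abs(sum(class_mix) - 1) > 1e-9) abort("class_mix must sum to 1")
  if (cells_per_image < 0) abort("cells_per_image must be >= 0")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    cells_per_image = as.integer(cells_per_image),
    class_mix = class_mix, background_level = background_level,
    gaussian_noise_sd = gaussian_noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    min_cell_separation = min_cell_separation,
    brightness_sdlog = brightness_sdlog,
    brightness_range = brightness_range, rng_seed = rng_seed
  ), class = "scene_config")
}

# mean in-mask actin intensity above background, arbitrary units (shared by
# all phenotypes so that classes differ by texture and rim, not by a flat
# level)
ACTIN_LEVEL <- 60

# choose one archetype row for a class; classes modelled as mixtures have
# several rows sampled by weight
pick_archetype <- function(archetypes, class) {
  rows <- archetypes[archetypes$name == class, ]
  if (!nrow(rows)) abort(paste0("no archetype for class ", class))
  if (nrow(rows) == 1) return(rows)
  w <- rows$weight %||% rep(1, nrow(rows))
  rows[sample.int(nrow(rows), 1, prob = w), ]
}

#' Draw one cell geometry for a phenotype class
#'
#' Like [sample_cell_geometry()] but samples the archetype row from the
#' class's (possibly mixed) subpopulations by weight, which is how
#' [render_scene()] draws cells.
#'
#' @param archetypes Archetype table ([phenotype_archetypes()]).
#' @param class Phenotype class name.
#' @return See [sample_cell_geometry()].
#' @export
draw_class_geometry <- function(archetypes, class) {
  sample_cell_geometry(pick_archetype(archetypes, class))
}

# per-cell actin texture: a blurred spot (puncta) process, unit in-mask mean,
# with a multiplicative rim within 2 px of the boundary
actin_texture <- function(cell_mask, archetype) {
  a <- as.list(archetype)
  area <- sum(cell_mask)
  f <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  n_spots <- rpois(1, a$actin_spot_density * area / 100)
  if (n_spots > 0) {
    at <- sample(which(cell_mask), n_spots, replace = TRUE)
    f[as.numeric(names(table(at)))] <- as.numeric(table(at))
    f <- EBImage::gblur(f, sigma = max(a$actin_smoothness, 0.4))
  }
  # intensity floor keeps the whole cell body above background so the
  # foreground is thresholdable; spots ride on top (in-mask mean stays 1)
  m <- mean(f[cell_mask])
  tex <- if (m > 0) 0.7 + 0.3 * f / m else matrix(1, nrow(f), ncol(f))
  dm <- mask_distmap(cell_mask)
  rim <- cell_mask & dm <= 2
  tex[rim] <- tex[rim] * a$edge_rim_gain
  tex[!cell_mask] <- 0
  tex
}

#' Render one two-channel synthetic scene
#'
#' Places cells drawn from the archetype distributions without mask overlap
#' (rejection sampling, at most 1000 attempts per cell), paints the nuclear
#' channel as a constant DNA intensity per nuclear pixel and the actin channel
#' as a per-cell blurred spot texture with a peripheral rim, applies a mild
#' optical blur, and finally adds background and noise (noise last).
#'
#' @param config A [scene_config()].
#' @param archetypes Archetype table covering every class with positive mix
#'   weight; defaults to [phenotype_archetypes()].
#' @return A list with numeric matrices `dapi` and `actin` (arbitrary
#'   fluorescence units) and `truth`, a tibble of per-cell ground truth
#'   (object_id, class, bbox offsets, logical mask crops, true areas).
#' @export
render_scene <- function(config, archetypes = phenotype_archetypes()) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  H <- config$image_height; W <- config$image_width
  need <- names(config$class_mix)[config$class_mix > 0]
  if (!all(need %in% archetypes$name)) {
    abort(paste0("archetypes missing class(es): ",
                 paste(setdiff(need, archetypes$name), collapse = ", ")))
  }
  dapi_sig <- matrix(0, H, W)
  actin_sig <- matrix(0, H, W)
  occupied <- matrix(FALSE, H, W)
  truth <- list()

  n <- config$cells_per_image
  classes <- if (n > 0) {
    sample(names(config$class_mix), n, replace = TRUE, prob = config$class_mix)
  } else character(0)
  sep <- max(0L, as.integer(round(config$min_cell_separation)))
  margin <- 5L  # keeps blur mass and all masks strictly interior

  for (i in seq_len(n)) {
    arch <- pick_archetype(archetypes, classes[i])
    geom <- sample_cell_geometry(arch)
    side <- nrow(geom$cell_mask)
    half <- (side - 1L) %/% 2L
    guard <- if (sep > 0) {
      EBImage::dilate(matrix(as.numeric(geom$cell_mask), side, side),
                      EBImage::makeBrush(2L * sep + 1L, "disc")) > 0.5
    } else geom$cell_mask
    placed <- FALSE
    for (att in seq_len(1000L)) {
      cy <- sample.int(H - 2L * (half + margin), 1) + half + margin
      cx <- sample.int(W - 2L * (half + margin), 1) + half + margin
      rows <- (cy - half):(cy + half)
      cols <- (cx - half):(cx + half)
      if (!any(occupied[rows, cols] & guard)) { placed <- TRUE; break }
    }
    if (!placed) {
      abort(paste0("could not place cell ", i, " of ", n,
                   " after 1000 attempts; placed ", i - 1L, " cells"))
    }
    occupied[rows, cols] <- occupied[rows, cols] | geom$cell_mask
    a <- as.list(arch)
    # per-cell, per-channel staining brightness (lognormal, mean ~1)
    bs <- config$brightness_sdlog
    b <- if (bs > 0) {
      pmin(pmax(stats::rlnorm(2, meanlog = -bs^2 / 2, sdlog = bs),
                config$brightness_range[1]), config$brightness_range[2])
    } else c(1, 1)
    sub <- dapi_sig[rows, cols]
    sub[geom$nucleus_mask] <- sub[geom$nucleus_mask] + b[1] * a$dna_intensity_scale
    dapi_sig[rows, cols] <- sub
    tex <- actin_texture(geom$cell_mask, arch)
    actin_sig[rows, cols] <- actin_sig[rows, cols] + b[2] * ACTIN_LEVEL * tex
    truth[[i]] <- tibble(
      object_id = i, class = classes[i],
      row0 = rows[1] - 1L, col0 = cols[1] - 1L,
      cell_mask = list(geom$cell_mask), nucleus_mask = list(geom$nucleus_mask),
      cell_area = sum(geom$cell_mask), nucleus_area = sum(geom$nucleus_mask),
      centroid_row = cy, centroid_col = cx
    )
  }

  # optical softening of the signal, then background and noise
  if (n > 0) {
    dapi_sig <- EBImage::gblur(dapi_sig, 0.8)
    actin_sig <- EBImage::gblur(actin_sig, 0.8)
  }
  dapi <- config$background_level + dapi_sig
  actin <- config$background_level + actin_sig
  if (config$poisson_noise) {
    dapi <- matrix(rpois(H * W, pmax(dapi, 0)), H, W)
    actin <- matrix(rpois(H * W, pmax(actin, 0)), H, W)
  }
  if (config$gaussian_noise_sd > 0) {
    dapi <- dapi + rnorm(H * W, 0, config$gaussian_noise_sd)
    actin <- actin + rnorm(H * W, 0, config$gaussian_noise_sd)
  }
  list(dapi = pmax(dapi, 0), actin = pmax(actin, 0),
       truth = if (n > 0) bind_rows(truth) else
         tibble(object_id = integer(), class = character(),
                row0 = integer(), col0 = integer(),
                cell_mask = list(), nucleus_mask = list(),
                cell_area = numeric(), nucleus_area = numeric(),
                centroid_row = numeric(), centroid_col = numeric()),
       config = config)
}

# paint ground-truth mask crops into full-size label maps
truth_label_maps <- function(truth, H, W) {
  cells <- matrix(0L, H, W); nuclei <- matrix(0L, H, W)
  for (i in seq_len(nrow(truth))) {
    side <- nrow(truth$cell_mask[[i]])
    rows <- truth$row0[i] + seq_len(side)
    cols <- truth$col0[i] + seq_len(side)
    sub <- cells[rows, cols]
    sub[truth$cell_mask[[i]]] <- truth$object_id[i]
    cells[rows, cols] <- sub
    sub <- nuclei[rows, cols]
    sub[truth$nucleus_mask[[i]]] <- truth$object_id[i]
    nuclei[rows, cols] <- sub
  }
  list(cells = cells, nuclei = nuclei)
}

#' Generate a synthetic two-channel dataset on disk
#'
#' Writes `n_images` image pairs as 16-bit grayscale TIFFs named
#' `<set>_<class>_<idx>_<channel>.tif` (channel `dapi` or `actin`), one
#' phenotype per image so that the class is encoded in the file name, plus
#' ground-truth label TIFFs (`_gtcells` / `_gtnuclei`) and a manifest CSV.
#' Fully reproducible from `config$rng_seed`.
#'
#' @param config A [scene_config()]; its `rng_seed` seeds the whole dataset.
#' @param archetypes Archetype table, default [phenotype_archetypes()].
#' @param n_images Total number of images, distributed round-robin over the
#'   five classes.
#' @param out_dir Output directory (created if needed).
#' @param set_name File-name prefix.
#' @return The manifest tibble (image, class, n_cells, seed), invisibly also
#'   written to `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(config = scene_config(rng_seed = 1),
                             archetypes = phenotype_archetypes(),
                             n_images = 150, out_dir, set_name = "synth") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  classes <- rep_len(phenotype_levels(), n_images)
  idx_within <- stats::ave(seq_len(n_images), classes, FUN = seq_along)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cls <- classes[i]
    cfg_i <- config
    cfg_i$class_mix <- setNames(as.numeric(phenotype_levels() == cls),
                                phenotype_levels())
    cfg_i$rng_seed <- NULL  # draw from the dataset-level stream
    scene <- render_scene(cfg_i, archetypes)
    stem <- sprintf("%s_%s_%03d", set_name, cls, idx_within[i])
    write_image_tiff(scene$dapi, file.path(out_dir, paste0(stem, "_dapi.tif")))
    write_image_tiff(scene$actin, file.path(out_dir, paste0(stem, "_actin.tif")))
    lm <- truth_label_maps(scene$truth, config$image_height, config$image_width)
    write_image_tiff(lm$cells, file.path(out_dir, paste0(stem, "_gtcells.tif")))
    write_image_tiff(lm$nuclei, file.path(out_dir, paste0(stem, "_gtnuclei.tif")))
    rows[[i]] <- tibble(image = stem, class = cls,
                        n_cells = nrow(scene$truth),
                        seed = config$rng_seed %||% NA_integer_)
  }
  manifest <- bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
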