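# Shared fixtures, built in code at test time.

# rasterized disc mask with its analytic radius
disc_mask <- function(r, pad = 3) {
  side <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  rr <- matrix(seq_len(side) - ctr, side, side)
  cc <- t(rr)
  rr^2 + cc^2 <= r^2
}

# noise-free scene configuration (no photon noise, no staining variability)
clean_config <- function(...) {
  scene_config(gaussian_noise_sd = 0, poisson_noise = FALSE,
               brightness_sdlog = 0, ...)
}

# single-class mix vector
one_class_mix <- function(class) {
  setNames(as.numeric(phenotype_levels() == class), phenotype_levels())
}

# intersection-over-union of logical masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# paint an object's mask crop onto a full-size canvas
mask_on_canvas <- function(tbl, i, which = "cell_mask", dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  crop <- tbl[[which]][[i]]
  rows <- tbl$row0[i] + seq_len(nrow(crop))
  cols <- tbl$col0[i] + seq_len(ncol(crop))
  m[rows, cols] <- crop
  m
}

# match segmented objects to ground truth by majority overlap; returns per
# ground-truth-object IoUs for cells and nuclei (NA when undetected)
match_to_truth <- function(objects, truth, dim) {
  lm <- cytoprofiler:::truth_label_maps(truth, dim[1], dim[2])
  cells <- matrix(0L, dim[1], dim[2])
  nucs <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(objects))) {
    cells[mask_on_canvas(objects, i, "cell_mask", dim)] <- objects$object_id[i]
    nucs[mask_on_canvas(objects, i, "nucleus_mask", dim)] <- objects$object_id[i]
  }
  out <- data.frame(cell_iou = rep(NA_real_, nrow(truth)),
                    nucleus_iou = rep(NA_real_, nrow(truth)))
  for (g in seq_len(nrow(truth))) {
    gm <- lm$cells == g
    ids <- cells[gm]; ids <- ids[ids > 0]
    if (!length(ids)) next
    id <- as.integer(names(which.max(table(ids))))
    out$cell_iou[g] <- iou(cells == id, gm)
    out$nucleus_iou[g] <- iou(nucs == id, lm$nuclei == g)
  }
  out
}

# small synthetic labelled feature table for classifier-protocol tests:
# k Gaussian classes, means spaced `sep` sds apart along each informative
# dimension (deterministic spacing, so sep >> 1 guarantees separability)
make_toy_table <- function(n_per_class = 40, p = 12, informative = 3,
                           sep = 3, classes = phenotype_levels(), seed = 1) {
  set.seed(seed)
  k <- length(classes)
  x <- matrix(rnorm(n_per_class * k * p), n_per_class * k, p)
  mu <- outer(seq_len(k) - (k + 1) / 2, rep(sep, informative))
  y <- rep(classes, each = n_per_class)
  for (ci in seq_len(k)) {
    rows <- which(y == classes[ci])
    x[rows, seq_len(informative)] <-
      x[rows, seq_len(informative), drop = FALSE] +
      rep(mu[ci, ], each = length(rows))
  }
  tbl <- tibble::as_tibble(as.data.frame(x))
  names(tbl) <- paste0("f", seq_len(p))
  tbl$class <- y
  tbl$image_id <- "toy"
  tbl$object_id <- seq_len(nrow(tbl))
  tbl
}

# tiny on-disk dataset shared by io/pipeline tests (built once per run)
tiny_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "cytoprofiler-tiny-ds")
      if (!dir.exists(d)) {
        generate_dataset(scene_config(image_height = 256, image_width = 256,
                                      cells_per_image = 6, rng_seed = 11),
                         n_images = 10, out_dir = d, set_name = "tiny")
      }
      dir <<- d
    }
    dir
  }
})
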