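# The 228-measurement cytoprofile: schema and the four feature families.

test_that("the schema has the fixed 228-slot composition and a stable hash", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 228)
  expect_equal(anyDuplicated(sch$name), 0)
  expect_equal(sum(sch$family == "shape"), 28)
  expect_equal(sum(sch$family == "intensity"), 48)
  expect_equal(sum(sch$family == "radial"), 48)
  expect_equal(sum(sch$family == "texture"), 104)
  expect_identical(schema_hash(), schema_hash(feature_schema()))
})

test_that("shape features match closed forms on a square and a disc", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  f <- shape_features(sq)
  expect_equal(unname(f["area"]), 100)
  expect_equal(unname(f["extent"]), 1)
  expect_equal(unname(f["solidity"]), 1)
  expect_equal(unname(f["equivalent_diameter"]), 2 * sqrt(100 / pi), tolerance = 1e-6)
  expect_equal(unname(f["eccentricity"]), 0, tolerance = 1e-9)

  d <- disc_mask(30)
  fd <- shape_features(d)
  expect_lte(unname(fd["eccentricity"]), 0.1)
  expect_lte(abs(unname(fd["form_factor"]) - 1), 0.1)
  expect_error(shape_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("compactness is the reciprocal of form factor on arbitrary masks", {
  set.seed(8)
  for (i in 1:10) {
    g <- sample_cell_geometry(phenotype_archetypes()[sample.int(5, 1), ])
    f <- shape_features(g$cell_mask)
    expect_equal(unname(f["compactness"] * f["form_factor"]), 1, tolerance = 1e-9)
  }
})

test_that("shape features are translation invariant and area scales as s^2", {
  m <- disc_mask(12)
  big <- matrix(FALSE, nrow(m) + 20, ncol(m) + 20)
  big[8 + seq_len(nrow(m)), 13 + seq_len(ncol(m))] <- m
  f1 <- shape_features(m); f2 <- shape_features(big)
  keep <- setdiff(names(f1), "orientation")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-9)
  f4 <- shape_features(disc_mask(24))
  expect_equal(unname(f4["area"] / f1["area"]), 4, tolerance = 0.02)
})

test_that("intensity features match hand computations", {
  m3 <- matrix(TRUE, 3, 1)
  fi <- intensity_features(m3, matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(fi["integrated"]), 6)
  expect_equal(unname(fi["mean"]), 2)
  expect_equal(unname(fi["median"]), 2)
  expect_equal(unname(fi["std"]), sqrt(2 / 3), tolerance = 1e-6)

  mc <- matrix(TRUE, 5, 5)
  fc <- intensity_features(mc, matrix(7, 5, 5))
  expect_equal(unname(fc["integrated"]), 7 * 25)
  expect_equal(unname(fc["std"]), 0)
  expect_equal(unname(fc["mad"]), 0)
  expect_equal(unname(fc["mass_displacement"]), 0)

  # symmetric Gaussian on a disc: intensity centroid at the binary centroid
  d <- disc_mask(15)
  ctr <- (nrow(d) + 1) / 2
  rr <- matrix(seq_len(nrow(d)) - ctr, nrow(d), ncol(d)); cc <- t(rr)
  g <- exp(-(rr^2 + cc^2) / 50)
  expect_lte(unname(intensity_features(d, g)["mass_displacement"]), 0.5)
  expect_error(intensity_features(matrix(FALSE, 2, 2), matrix(0, 2, 2)), "empty")
})

test_that("edge actin intensity per area reduces to v * boundary/area on flat images", {
  d <- disc_mask(10)
  v <- 4.5
  expected <- v * sum(cytoprofiler:::mask_boundary(d)) / sum(d)
  expect_equal(edge_intensity_per_area(d, matrix(v, nrow(d), ncol(d))), expected)
})

test_that("radial distribution behaves on uniform and point-mass images", {
  d <- disc_mask(20)
  fu <- radial_distribution(d, matrix(3, nrow(d), ncol(d)))
  expect_equal(unname(fu[paste0("mean_frac_", 1:4)]), rep(1, 4), tolerance = 1e-6)
  expect_equal(sum(fu[paste0("frac_at_d_", 1:4)]), 1, tolerance = 1e-9)

  # indicator of the innermost bin -> all intensity lands in bin 4
  dm <- cytoprofiler:::mask_distmap(d)
  inner <- d & (dm / max(dm) > 0.75)
  fi <- radial_distribution(d, matrix(as.numeric(inner), nrow(d), ncol(d)))
  expect_equal(unname(fi[paste0("frac_at_d_", 1:4)]), c(0, 0, 0, 1), tolerance = 1e-9)

  # normalization holds for arbitrary non-negative images
  set.seed(2)
  img <- matrix(runif(nrow(d) * ncol(d)), nrow(d))
  fr <- radial_distribution(d, img)
  expect_equal(sum(fr[paste0("frac_at_d_", 1:4)]), 1, tolerance = 1e-9)
})

test_that("Haralick features match the constant and stripe closed forms", {
  mc <- matrix(TRUE, 6, 6)
  fh <- haralick_features(mc, matrix(3, 6, 6))
  expect_equal(unname(fh["asm"]), 1)
  expect_equal(unname(fh["entropy"]), 0)
  expect_equal(unname(fh["contrast"]), 0)
  expect_equal(unname(fh["correlation"]), 0)

  # alternating single-pixel stripes at offset 1: all co-occurrence mass on
  # the (1, 8)/(8, 1) pair -> contrast (8-1)^2 = 49 along that direction
  img <- matrix(rep(c(0, 1), length.out = 16), 8, 16, byrow = TRUE)
  fs <- haralick_features(matrix(TRUE, 8, 16), img, scale = 1,
                          directions = list(c(0, 1)))
  expect_equal(unname(fs["contrast"]), 49)
  expect_equal(unname(fs["asm"]), 0.5)

  # mask smaller than the offset -> constant convention
  tiny <- matrix(TRUE, 2, 2)
  ft <- haralick_features(tiny, matrix(1:4, 2, 2), scale = 8)
  expect_equal(unname(ft["asm"]), 1)
})

test_that("dotted M1 actin has higher texture entropy than smooth M2 actin", {
  set.seed(7)
  cell_entropies <- function(class, n_target) {
    cfg <- scene_config(cells_per_image = 15, class_mix = one_class_mix(class))
    out <- numeric(0)
    while (length(out) < n_target) {
      sc <- render_scene(cfg)
      for (i in seq_len(nrow(sc$truth))) {
        side <- nrow(sc$truth$cell_mask[[i]])
        rows <- sc$truth$row0[i] + seq_len(side)
        cols <- sc$truth$col0[i] + seq_len(side)
        out <- c(out, haralick_features(sc$truth$cell_mask[[i]],
                                        sc$actin[rows, cols], scale = 3)["entropy"])
      }
    }
    out[seq_len(n_target)]
  }
  e_m1 <- cell_entropies("M1", 500)
  e_m2 <- cell_entropies("M2", 500)
  expect_gt(mean(e_m1), mean(e_m2))
})

test_that("the assembled cytoprofile has 228 finite values and is deterministic", {
  cfg <- clean_config(image_height = 256, image_width = 256,
                      cells_per_image = 4, rng_seed = 13)
  sc <- render_scene(cfg)
  obj <- segment_image(sc$dapi, sc$actin, image_id = "t")
  expect_gt(nrow(obj), 0)
  v1 <- assemble_cytoprofile(obj[1, ], sc$dapi, sc$actin)
  v2 <- assemble_cytoprofile(obj[1, ], sc$dapi, sc$actin)
  expect_length(v1, 228)
  expect_true(all(is.finite(v1)))
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_identical(names(v1), feature_schema()$name)

  tbl <- profile_objects(obj, sc$dapi, sc$actin, class = "M1")
  expect_equal(nrow(tbl), nrow(obj))
  expect_equal(length(setdiff(names(tbl), c("image_id", "object_id", "class"))), 228)
})
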