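# Nucleus detection, seeded cell-body detection and QC filtering.

test_that("degenerate inputs are handled", {
  flat <- matrix(100, 64, 64)
  expect_equal(max(detect_nuclei(flat)), 0)
  bad <- flat; bad[5, 5] <- NA
  expect_error(detect_nuclei(bad), "non-finite")
  expect_error(detect_nuclei(flat - 200), "negative")
  # no seeds -> no cells
  expect_equal(max(detect_cells(matrix(runif(64^2, 100, 200), 64), matrix(0L, 64, 64))), 0)
})

test_that("two fused discs are declumped into two nuclei", {
  r <- 16  # the smoothed distance transform keeps both maxima at this scale
  img <- matrix(100, 140, 140)
  cc <- expand.grid(row = 1:140, col = 1:140)
  d1 <- sqrt((cc$row - 70)^2 + (cc$col - 58)^2)
  d2 <- sqrt((cc$row - 70)^2 + (cc$col - 58 - 1.2 * r)^2)
  img[d1 <= r | d2 <= r] <- 180
  lab <- detect_nuclei(img)
  expect_equal(max(lab), 2)
  # and an isolated disc stays one object
  img1 <- matrix(100, 2 * (r + 20) + 1, 2 * (r + 20) + 1)
  img1[disc_mask(r, 20)] <- 180
  expect_equal(max(detect_nuclei(img1)), 1)
})

test_that("noise-free scenes are segmented at high IoU against ground truth", {
  total <- 0; found <- 0; ious <- NULL
  for (s in c(3, 9)) {
    cfg <- clean_config(cells_per_image = 12, rng_seed = s)
    sc <- render_scene(cfg)
    obj <- segment_image(sc$dapi, sc$actin, image_id = paste0("s", s))
    m <- match_to_truth(obj, sc$truth, c(512, 512))
    total <- total + nrow(sc$truth); found <- found + sum(!is.na(m$cell_iou))
    ious <- rbind(ious, m)
  }
  expect_equal(found, total)
  expect_true(all(ious$cell_iou >= 0.9))
  expect_true(all(ious$nucleus_iou >= 0.95))
})

test_that("watershed-grown cells partition the foreground between adjacent seeds", {
  # two touching synthetic cells: every foreground pixel gets exactly one label
  img <- matrix(100, 100, 100)
  cc <- expand.grid(row = 1:100, col = 1:100)
  left <- sqrt((cc$row - 50)^2 + (cc$col - 38)^2) <= 22
  right <- sqrt((cc$row - 50)^2 + (cc$col - 64)^2) <= 22
  img[left | right] <- 160
  nuclei <- matrix(0L, 100, 100)
  d_seed1 <- sqrt((cc$row - 50)^2 + (cc$col - 38)^2) <= 6
  d_seed2 <- sqrt((cc$row - 50)^2 + (cc$col - 64)^2) <= 6
  nuclei[d_seed1] <- 1L; nuclei[d_seed2] <- 2L
  cells <- detect_cells(img, nuclei)
  expect_setequal(sort(unique(as.vector(cells))), c(0L, 1L, 2L))
  expect_false(any(cells == 1 & cells == 2))  # labels are exclusive by construction
  expect_true(all(cells[nuclei == 1] == 1))
  expect_true(all(cells[nuclei == 2] == 2))
})

test_that("border handling and pairing rules are applied", {
  cells <- matrix(0L, 40, 40); nuclei <- matrix(0L, 40, 40)
  cells[1:8, 4:12] <- 1L; nuclei[2:5, 6:9] <- 1L       # touches row 1
  cells[15:26, 15:26] <- 2L; nuclei[18:22, 18:22] <- 2L # interior
  cells[30:36, 4:10] <- 3L                              # no nucleus
  discard <- filter_objects(cells, nuclei, segmentation_params(border_policy = "discard"))
  expect_equal(nrow(discard), 1)
  expect_equal(discard$seed_id, 2L)
  keep <- filter_objects(cells, nuclei, segmentation_params(border_policy = "keep"))
  expect_equal(nrow(keep), 2)
  expect_true(all(discard$seed_id %in% keep$seed_id))
  # nucleus within cell on every record
  for (i in seq_len(nrow(keep))) {
    expect_false(any(keep$nucleus_mask[[i]] & !keep$cell_mask[[i]]))
  }
})

test_that("interior cells are fully recovered on a clean scene", {
  cfg <- clean_config(cells_per_image = 10, rng_seed = 31)
  sc <- render_scene(cfg)
  obj <- segment_image(sc$dapi, sc$actin)
  expect_equal(nrow(obj), nrow(sc$truth))
})

test_that("at default noise at least 95% of cells are recovered over 20 scenes", {
  total <- 0; found <- 0
  for (s in 1:20) {
    cfg <- scene_config(cells_per_image = 8, rng_seed = 100 + s)
    sc <- render_scene(cfg)
    obj <- segment_image(sc$dapi, sc$actin)
    m <- match_to_truth(obj, sc$truth, c(512, 512))
    total <- total + nrow(sc$truth)
    found <- found + sum(!is.na(m$cell_iou))
  }
  expect_gte(found / total, 0.95)
})
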