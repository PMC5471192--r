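# Image and table I/O plus filename-metadata discovery.

# 16-bit grayscale TIFF; intensities stored as value/65535
#' Write an intensity or label matrix as a 16-bit grayscale TIFF
#' @param img Numeric matrix, values in [0, 65535].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img / 65535, 0), 1), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale image back onto the 16-bit intensity scale
#' @param path A `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix with intensities in [0, 65535].
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    abort(paste0("unsupported image format: ", path))
  }
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * 65535
}

#' Discover two-channel image pairs from file names
#'
#' File names follow `<set>_<class>_<idx>_<channel>.<ext>` with channel
#' `dapi` or `actin`; the phenotype class is extracted from the file name.
#' Files with a missing partner channel are excluded with a warning.
#'
#' @param input_dir Directory to scan.
#' @param pattern Regular expression with four capture groups (set, class,
#'   index, channel).
#' @param classes Accepted class tokens; `"blind"` marks unlabelled images.
#' @return Tibble with image_id, class, dapi_path, actin_path.
#' @export
discover_images <- function(input_dir,
                            pattern = NULL,
                            classes = c(phenotype_levels(), "blind")) {
  if (is.null(pattern)) {
    pattern <- paste0("^(.+)_(", paste(classes, collapse = "|"),
                      ")_([0-9]+)_(dapi|actin)\\.(tif|tiff|png)$")
  }
  files <- list.files(input_dir)
  m <- regmatches(files, regexec(pattern, files))
  hit <- lengths(m) >= 5
  if (!any(hit)) abort(paste0("no image files matching the naming pattern in ", input_dir))
  rec <- bind_rows(lapply(m[hit], function(g) {
    tibble(file = g[1], set = g[2], class = g[3], idx = g[4], channel = g[5])
  }))
  rec$image_id <- paste(rec$set, rec$class, rec$idx, sep = "_")
  wide <- tidyr::pivot_wider(rec[, c("image_id", "class", "channel", "file")],
                             names_from = "channel", values_from = "file")
  incomplete <- is.na(wide$dapi %||% NA) | is.na(wide$actin %||% NA)
  if (!("dapi" %in% names(wide))) wide$dapi <- NA_character_
  if (!("actin" %in% names(wide))) wide$actin <- NA_character_
  incomplete <- is.na(wide$dapi) | is.na(wide$actin)
  if (any(incomplete)) {
    warn(paste0("excluding ", sum(incomplete),
                " image(s) with a missing channel: ",
                paste(head(wide$image_id[incomplete], 5), collapse = ", ")))
    wide <- wide[!incomplete, ]
  }
  if (!nrow(wide)) abort("no complete two-channel image pairs found")
  tibble(image_id = wide$image_id, class = wide$class,
         dapi_path = file.path(input_dir, wide$dapi),
         actin_path = file.path(input_dir, wide$actin))
}

#' Read one discovered image pair
#' @param record One row of the [discover_images()] tibble.
#' @return List with `dapi` and `actin` intensity matrices.
#' @export
read_image_pair <- function(record) {
  dapi <- read_image_gray(record$dapi_path)
  actin <- read_image_gray(record$actin_path)
  if (!all(dim(dapi) == dim(actin))) {
    abort(paste0("channel shapes differ for ", record$image_id))
  }
  list(dapi = dapi, actin = actin)
}

#' Write an RGB overlay of detected outlines
#'
#' Burns the nucleus outlines (green) and cell outlines (red) into a
#' grayscale composite of the two channels and writes a PNG.
#'
#' @param dapi,actin Intensity matrices.
#' @param cells,nuclei Label matrices from segmentation.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_outline_overlay <- function(dapi, actin, cells, nuclei, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required for outline overlays")
  }
  label_edges <- function(lab) {
    nr <- nrow(lab); nc <- ncol(lab)
    e <- matrix(FALSE, nr, nc)
    e[-1, ] <- e[-1, ] | (lab[-1, ] != lab[-nr, ])
    e[, -1] <- e[, -1] | (lab[, -1] != lab[, -nc])
    e & (lab > 0)
  }
  base <- (dapi + actin)
  base <- (base - min(base)) / max(diff(range(base)), 1e-9)
  rgb <- array(rep(base, 3), c(nrow(base), ncol(base), 3))
  ce <- label_edges(cells); ne <- label_edges(nuclei)
  rgb[, , 1][ce] <- 1; rgb[, , 2][ce] <- 0; rgb[, , 3][ce] <- 0
  rgb[, , 2][ne] <- 1; rgb[, , 1][ne] <- 0; rgb[, , 3][ne] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
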