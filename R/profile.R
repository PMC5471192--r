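# Assembly of the 228-measurement cytoprofile per segmented cell.

# compute one family block for a (mask, image) pair
profile_block <- function(family, mask, img, scale) {
  switch(family,
         shape = shape_features(mask),
         intensity = intensity_features(mask, img),
         radial = radial_distribution(mask, img),
         texture = haralick_features(mask, img, scale = scale))
}

#' Assemble the 228-measurement cytoprofile of one segmented cell
#'
#' Concatenates, in schema order: shape of the nucleus and of the cell;
#' intensity, radial-distribution and two-scale Haralick texture features of
#' both objects in both stain channels. Non-finite values arising from
#' degenerate geometry are imputed as 0 (the count of imputations is attached
#' as the `n_imputed` attribute).
#'
#' @param object One row of the [filter_objects()] tibble (mask crops and
#'   crop offsets).
#' @param dapi,actin Full-scene intensity matrices the object was segmented
#'   from.
#' @param schema The [feature_schema()]; its `scale` column drives the
#'   texture offsets.
#' @return Named numeric vector of length 228, ordered per schema.
#' @export
assemble_cytoprofile <- function(object, dapi, actin,
                                 schema = feature_schema()) {
  nr <- nrow(object$cell_mask[[1]]); nc <- ncol(object$cell_mask[[1]])
  rows <- object$row0 + seq_len(nr)
  cols <- object$col0 + seq_len(nc)
  imgs <- list(dapi = dapi[rows, cols, drop = FALSE],
               actin = actin[rows, cols, drop = FALSE])
  masks <- list(nucleus = object$nucleus_mask[[1]],
                cell = object$cell_mask[[1]])

  blocks <- unique(schema[, c("object", "channel", "family", "scale")])
  out <- numeric(0)
  for (b in seq_len(nrow(blocks))) {
    ob <- blocks$object[b]; ch <- blocks$channel[b]
    fam <- blocks$family[b]; sc <- blocks$scale[b]
    img <- if (ch == "none") NULL else imgs[[ch]]
    vals <- profile_block(fam, masks[[ob]], img, sc)
    out <- c(out, vals)
  }
  stopifnot(length(out) == nrow(schema))
  names(out) <- schema$name
  n_bad <- sum(!is.finite(out))
  out[!is.finite(out)] <- 0
  attr(out, "n_imputed") <- n_bad
  out
}

#' Profile every segmented object of one image
#'
#' @param objects [filter_objects()] tibble.
#' @param dapi,actin Scene intensity matrices.
#' @param schema The [feature_schema()].
#' @param class Optional phenotype label recorded on every row.
#' @return Tibble: image_id, object_id, class, then the 228 schema-ordered
#'   feature columns. Objects whose extraction fails are dropped with a
#'   warning naming their provenance.
#' @export
profile_objects <- function(objects, dapi, actin, schema = feature_schema(),
                            class = NA_character_) {
  if (!nrow(objects)) {
    empty <- as_tibble(setNames(as.list(rep(list(numeric(0)), nrow(schema))),
                                schema$name))
    return(bind_cols(tibble(image_id = character(), object_id = integer(),
                            class = character()), empty))
  }
  rows <- vector("list", nrow(objects))
  for (i in seq_len(nrow(objects))) {
    obj <- objects[i, ]
    vals <- tryCatch(assemble_cytoprofile(obj, dapi, actin, schema),
                     error = function(e) {
                       warn(paste0("dropping object ", obj$object_id, " of ",
                                   obj$image_id, ": ", conditionMessage(e)))
                       NULL
                     })
    if (is.null(vals)) next
    rows[[i]] <- bind_cols(
      tibble(image_id = obj$image_id, object_id = obj$object_id, class = class),
      as_tibble(as.list(vals)))
  }
  bind_rows(rows)
}

#' Segment and profile a discovered image set
#'
#' Runs [segment_image()] and [profile_objects()] over every record of a
#' [discover_images()] tibble (or a generated-dataset manifest directory) and
#' returns the labelled feature table.
#'
#' @param records [discover_images()] tibble.
#' @param params [segmentation_params()].
#' @param schema [feature_schema()].
#' @param verbose Print per-image progress counters.
#' @return A labelled feature table: image_id, object_id, class plus 228
#'   feature columns, one row per surviving cell.
#' @export
profile_dataset <- function(records, params = segmentation_params(),
                            schema = feature_schema(), verbose = FALSE) {
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    img <- read_image_pair(rec)
    objects <- segment_image(img$dapi, img$actin, params, image_id = rec$image_id)
    out[[i]] <- profile_objects(objects, img$dapi, img$actin, schema,
                                class = rec$class)
    if (verbose) {
      message(sprintf("[%d/%d] %s: %d cells profiled", i, nrow(records),
                      rec$image_id, nrow(out[[i]])))
    }
  }
  bind_rows(out)
}

#' Write / read a feature table as CSV (round-trips to 1e-12 relative)
#' @param table Feature table from [profile_dataset()].
#' @param path CSV path.
#' @return `path` (write) or the feature table tibble (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
}
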