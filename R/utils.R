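# internal helpers shared across modules

# truncated normal draw (simple rejection; bounds are loose physical limits)
rtnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  k <- 0L
  while (length(bad) && k < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    k <- k + 1L
  }
  pmin(pmax(x, lower), upper)
}

stopifnot_finite_nonneg <- function(x, what) {
  if (!all(is.finite(x))) abort(paste0(what, " contains non-finite values"))
  if (any(x < 0)) abort(paste0(what, " contains negative values"))
  invisible(TRUE)
}

# boundary pixels: in-mask pixels with a 4-connected background neighbour
# (the crop border counts as background)
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up    <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

# distance-to-edge transform of a logical mask (0 outside)
mask_distmap <- function(mask) {
  EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

# population standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# stable per-class stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Gaussian-smooth and min-max normalize an intensity map to [0, 1]
smooth_normalize <- function(img, sigma) {
  x <- (img - min(img)) / diff(range(img))
  if (sigma > 0) {
    x <- EBImage::gblur(x, sigma)
    x <- (x - min(x)) / max(diff(range(x)), 1e-12)
  }
  pmin(pmax(x, 0), 1)
}

# log-transformed, smoothed, normalized intensity for global thresholding:
# fluorescence staining brightness varies over cells, and thresholding the
# log image keeps dim objects above a threshold set by the bright ones
threshold_image <- function(img, sigma) {
  smooth_normalize(log1p(pmax(img, 0)), sigma)
}

# global threshold on a threshold_image(): Otsu, floored by a robust
# background statistic — Otsu alone collapses into the background noise when
# the foreground covers only a few percent of the field
global_threshold <- function(x, k_mad = 2.5) {
  max(EBImage::otsu(x), median(x) + k_mad * stats::mad(x))
}
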