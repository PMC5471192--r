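# Haralick gray-level co-occurrence texture features.
#
# In-mask intensities are quantized to n_levels equal-width bins between the
# in-mask min and max; a symmetric co-occurrence matrix is accumulated over
# pixel pairs that are both inside the mask, per direction, and the 13
# classical statistics are averaged over directions that contribute at least
# one pair. Natural logarithms; 0*log(0) = 0.

glcm_direction <- function(q, dr, dc, n_levels) {
  nr <- nrow(q); nc <- ncol(q)
  if (abs(dr) >= nr || abs(dc) >= nc) return(NULL)
  rows <- if (dr >= 0) seq_len(nr - dr) else seq(1 - dr, nr)
  cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + dr, cols + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  counts <- tabulate((a[keep] - 1L) * n_levels + b[keep], nbins = n_levels^2)
  C <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- C + t(C)
  P / sum(P)
}

entropy0 <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

haralick_stats <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(n) * px); muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))

  # p_{x+y}(k), k = 2..2n and p_{x-y}(k), k = 0..n-1
  sums <- as.vector(tapply(as.vector(P), as.vector(i + j), sum))
  ks <- sort(unique(as.vector(i + j)))
  sum_average <- sum(ks * sums)
  sum_variance <- sum((ks - sum_average)^2 * sums)
  sum_entropy <- entropy0(sums)
  diffs <- as.vector(tapply(as.vector(P), abs(as.vector(i - j)), sum))
  kd <- sort(unique(abs(as.vector(i - j))))
  mu_d <- sum(kd * diffs)
  difference_variance <- sum((kd - mu_d)^2 * diffs)
  difference_entropy <- entropy0(diffs)

  hxy <- entropy0(P)
  hx <- entropy0(px); hy <- entropy0(py)
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log(pxy[pos]))
  hxy2 <- entropy0(pxy)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy, entropy = hxy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2)
}

# convention for constant / pair-less regions: a point-mass co-occurrence
haralick_constant <- function() {
  c(asm = 1, contrast = 0, correlation = 0, variance = 0, idm = 1,
    sum_average = 2, sum_variance = 0, sum_entropy = 0, entropy = 0,
    difference_variance = 0, difference_entropy = 0, imc1 = 0, imc2 = 0)
}

#' Haralick texture features of a masked image region
#'
#' Quantizes the in-mask intensities, accumulates symmetric normalized GLCMs
#' at offset `scale` over the given directions (default the 4 standard
#' directions), computes Haralick's 13 statistics per direction and averages
#' over directions with at least one in-mask pixel pair. A constant region
#' (or one with no valid pairs) returns the point-mass convention: ASM = 1,
#' IDM = 1, entropies/contrast/correlation = 0.
#'
#' @param mask Logical matrix, non-empty.
#' @param image Numeric matrix of the same dimension.
#' @param scale Co-occurrence offset in px.
#' @param n_levels Number of gray levels for quantization.
#' @param directions List of (drow, dcol) offsets; default the four standard
#'   directions at the given scale.
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(mask, image, scale = 3, n_levels = 8,
                              directions = NULL) {
  if (!any(mask)) abort("haralick_features: empty mask")
  stopifnot(all(dim(mask) == dim(image)))
  if (is.null(directions)) {
    directions <- list(c(0, scale), c(scale, 0), c(scale, scale), c(scale, -scale))
  }
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(mask), ncol(mask))
  q[mask] <- if (hi > lo) {
    pmin(n_levels, 1L + as.integer(floor((v - lo) / (hi - lo) * n_levels)))
  } else 1L
  acc <- NULL; nd <- 0L
  for (d in directions) {
    P <- glcm_direction(q, d[1], d[2], n_levels)
    if (is.null(P)) next
    st <- haralick_stats(P)
    acc <- if (is.null(acc)) st else acc + st
    nd <- nd + 1L
  }
  if (nd == 0L) return(haralick_constant())
  acc / nd
}
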