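# Shape features of a binary mask.
#
# Perimeter is the length of the closed polygon through the centres of the
# 8-connected outer boundary pixels (unit steps 1, diagonal steps sqrt(2)).
# Solidity uses the convex hull of the pixel *corners* so that a filled
# rectangle scores exactly 1.

# Radial-sweep boundary trace; returns ordered (row, col) boundary pixel
# centres of the outer contour. Assumes a connected mask. At each step the
# 8-neighbourhood is scanned clockwise starting just after the direction of
# the previous boundary pixel; tracing stops when the initial move from the
# start pixel repeats.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  rr <- (idx - 1) %% nr + 1; cc <- (idx - 1) %/% nr + 1
  if (length(idx) == 1) return(cbind(rr, cc))
  o <- order(rr, cc)  # topmost, then leftmost
  s <- c(rr[o[1]], cc[o[1]])
  # clockwise neighbour order starting north
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  is_fg <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  dir_of <- function(d) which(dirs[, 1] == d[1] & dirs[, 2] == d[2])
  path <- list(s)
  cur <- s
  from_dir <- 7L  # pretend we arrived from the west (background at start)
  second <- NULL
  limit <- 8L * length(idx) + 16L
  for (step in seq_len(limit)) {
    nxt <- NULL
    for (k in 1:8) {
      d <- ((from_dir - 1L + k) %% 8L) + 1L
      nb <- cur + dirs[d, ]
      if (is_fg(nb)) { nxt <- nb; break }
    }
    if (is.null(nxt)) break
    if (all(cur == s) && !is.null(second) && all(nxt == second)) break
    if (is.null(second)) second <- nxt
    from_dir <- dir_of(c(sign(cur[1] - nxt[1]), sign(cur[2] - nxt[2])))
    cur <- nxt
    if (all(cur == s)) { path[[length(path) + 1]] <- cur; next }
    path[[length(path) + 1]] <- cur
  }
  # drop a duplicated closing start pixel if present
  p <- do.call(rbind, path)
  if (nrow(p) > 1 && all(p[nrow(p), ] == p[1, ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

polygon_perimeter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  sum(d)
}

# shoelace area of the convex hull of boundary-pixel corners
hull_area <- function(mask) {
  b <- which(mask_boundary(mask))
  nr <- nrow(mask)
  r <- (b - 1) %% nr + 1; c <- (b - 1) %/% nr + 1
  pr <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  pc <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  h <- grDevices::chull(pc, pr)
  x <- pc[h]; y <- pr[h]
  abs(sum(x * y[c(2:length(y), 1)] - x[c(2:length(x), 1)] * y)) / 2
}

#' Shape features of a connected binary mask
#'
#' Returns the 14 canonical shape measurements: area (px^2), perimeter (px,
#' boundary-centre polygon), form factor 4*pi*A/P^2, eccentricity of the
#' second-moment ellipse (0 = circle), solidity (A / convex hull area), extent
#' (A / bounding-box area), compactness (P^2/(4*pi*A), the reciprocal of form
#' factor), equivalent diameter 2*sqrt(A/pi), major/minor axis lengths,
#' orientation in degrees in (-90, 90], and max/mean/median distance from the
#' boundary (radius statistics of the distance transform).
#'
#' @param mask Logical matrix; non-empty and connected.
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask) {
  if (!any(mask)) abort("shape_features: empty mask")
  A <- sum(mask)
  nr <- nrow(mask)
  idx <- which(mask)
  r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1

  P <- if (A < 3) 2 * sqrt(pi * A) else polygon_perimeter(trace_boundary(mask))
  P <- max(P, 1e-9)
  ff <- 4 * pi * A / P^2

  # second central moments of pixel centres (population)
  mr <- mean(r); mc <- mean(c)
  srr <- mean((r - mr)^2); scc <- mean((c - mc)^2); src <- mean((r - mr) * (c - mc))
  tr <- srr + scc
  det_ <- srr * scc - src^2
  disc <- sqrt(max((srr - scc)^2 / 4 + src^2, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  # orientation with x = col, y = -row (counter-clockwise from +x)
  ori <- 0.5 * atan2(-2 * src, scc - srr) * 180 / pi
  if (ori <= -90) ori <- ori + 180
  if (ori > 90) ori <- ori - 180

  hullA <- max(hull_area(mask), A)
  bbA <- (diff(range(r)) + 1) * (diff(range(c)) + 1)

  dm <- mask_distmap(mask)
  radii <- dm[mask]

  c(area = A, perimeter = P, form_factor = ff, eccentricity = ecc,
    solidity = A / hullA, extent = A / bbA, compactness = 1 / ff,
    equivalent_diameter = 2 * sqrt(A / pi),
    major_axis_length = 4 * sqrt(l1), minor_axis_length = 4 * sqrt(l2),
    orientation = ori, max_radius = max(radii), mean_radius = mean(radii),
    median_radius = median(radii))
}
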