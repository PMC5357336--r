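#' @useDynLib fluosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention used throughout the package: continuous (x, y) with
# pixel centers at integer coordinates, origin at the top-left corner of the
# raster and the y axis pointing downward.  A raster is stored as a base R
# matrix indexed [y, x] (row = y).  "Counter-clockwise" refers to positive
# signed (shoelace) area in these coordinates.

#' Signed polygon area (shoelace formula)
#'
#' @param pts n x 2 matrix of polygon vertices (closed implicitly).
#' @return Signed area; positive for counter-clockwise vertex order.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Perimeter of a closed polygon
#' @param pts n x 2 matrix of polygon vertices (closed implicitly).
#' @export
polygon_perimeter <- function(pts) {
  d <- pts - pts[c(2:nrow(pts), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' @param pts n x 2 matrix of vertices.
#' @export
is_simple_polygon <- function(pts) {
  poly_is_simple_cpp(as.matrix(pts))
}

# Binarize and sanity-check a mask raster.
as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.numeric(mask) > 0, nrow(mask), ncol(mask))
  storage.mode(m) <- "integer"
  m
}

# Number of 8-connected foreground components.
n_components <- function(mask) {
  max(EBImage::bwlabel(t(mask)))
}

# Extract the outer iso-0.5 boundary polygon of a binary mask as an n x 2
# (x, y) matrix, counter-clockwise, via marching squares on the padded mask.
mask_boundary_polygon <- function(mask) {
  m <- as_mask(mask)
  h <- nrow(m); w <- ncol(m)
  padded <- matrix(0, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- m
  # contourLines expects z[i, j] at (x[i], y[j]); our matrix is [y, x]
  cl <- grDevices::contourLines(x = 0:(w + 1), y = 0:(h + 1),
                                z = t(padded), levels = 0.5)
  if (length(cl) == 0) stop("invalid patch: no boundary found")
  areas <- vapply(cl, function(cc) abs(polygon_area(cbind(cc$x, cc$y))), 0)
  cc <- cl[[which.max(areas)]]
  pts <- cbind(x = cc$x, y = cc$y)
  # drop duplicated closing vertex if present
  if (nrow(pts) > 1 && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (polygon_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}

# Resample a closed polygon to n arc-length-equidistant points starting at
# vertex 1.
resample_closed <- function(pts, n) {
  m <- nrow(pts)
  seg <- pts[c(2:m, 1), , drop = FALSE] - pts
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  pts <- pts[keep, , drop = FALSE]
  seg <- seg[keep, , drop = FALSE]
  len <- len[keep]
  m <- nrow(pts)
  cum <- c(0, cumsum(len))
  total <- cum[m + 1]
  s <- (seq_len(n) - 1) * total / n
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (s - cum[idx]) / len[idx]
  pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

#' Sample a cell mask's outer boundary as an equally spaced contour
#'
#' Traces the outer boundary of the single foreground component of `mask`
#' (marching squares at the 0.5 iso-level, so the polygon follows the pixel
#' support rather than pixel centers) and resamples it to `n_points`
#' arc-length-equidistant points.  The contour is returned counter-clockwise,
#' starting at the boundary vertex with the largest x coordinate (ties broken
#' by the largest y).
#'
#' @param mask Binary matrix (row = y, col = x) with exactly one 8-connected
#'   foreground component of at least 4 pixels.
#' @param n_points Number of contour points (>= 4).
#' @return `n_points` x 2 matrix of (x, y) coordinates.
#' @export
sample_contour <- function(mask, n_points = 100L) {
  if (n_points < 4) stop("n_points must be >= 4")
  m <- as_mask(mask)
  if (sum(m) < 4) stop("invalid patch: foreground area < 4 pixels")
  nc <- n_components(m)
  if (nc != 1) stop("invalid patch: expected exactly 1 connected component, found ", nc)
  pts <- mask_boundary_polygon(m)
  # start at the vertex with the largest x (ties: largest y)
  ord <- order(pts[, 1], pts[, 2], decreasing = TRUE)
  k <- ord[1]
  pts <- pts[c(k:nrow(pts), seq_len(k - 1)), , drop = FALSE]
  out <- resample_closed(pts, n_points)
  colnames(out) <- c("x", "y")
  out
}
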