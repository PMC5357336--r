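# Clustered cell placement under a Jaccard bound: cells are assigned to
# random clusters; the first cell of a cluster sits at the cluster center,
# each later cell starts at the center and moves outward along a random
# direction in fixed increments until its overlap with every already placed
# cell satisfies the bound.

#' Jaccard index of two binary masks
#'
#' @param a,b Binary matrices in a common coordinate frame (equal extent).
#' @return `|A∩B| / |A∪B|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share a coordinate frame")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) stop("both masks are empty")
  sum(a & b) / u
}

#' Layout specification for cell placement
#'
#' @param n_cells Number of cells (N_c).
#' @param n_clusters Number of cell clusters (1 to `n_cells`).
#' @param j_max Maximum allowed pairwise Jaccard overlap in `[0, 1]`.
#' @param image_size `c(width, height)` in pixels.
#' @param step Movement increment in pixels.
#' @param min_gap Minimum pixel gap between cells (used by the "isolated"
#'   overlap degree; 0 disables).
#' @param rng_seed Optional seed.
#' @param max_retries Random direction retries per cell before the layout is
#'   declared infeasible.
#' @export
layout_spec <- function(n_cells, n_clusters = 1L, j_max = 0.15,
                        image_size = c(256L, 256L), step = 1,
                        min_gap = 0L, rng_seed = NULL, max_retries = 32L) {
  if (n_clusters < 1 || n_clusters > n_cells)
    stop("need 1 <= n_clusters <= n_cells")
  if (j_max < 0 || j_max > 1) stop("j_max must be in [0, 1]")
  if (step <= 0) stop("step must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 j_max = j_max, image_size = as.integer(image_size),
                 step = step, min_gap = as.integer(min_gap),
                 rng_seed = rng_seed, max_retries = as.integer(max_retries)),
            class = "layout_spec")
}

#' Overlap-degree presets
#'
#' The four degrees of cell proximity, all within a single cluster:
#' `isolated` (disjoint with a 2 px minimum gap), `touching` (masks may
#' abut but not intersect), `overlapping` (Jaccard up to 0.15) and
#' `overlaying` (Jaccard up to 0.40).
#'
#' @param degree One of `"isolated"`, `"touching"`, `"overlapping"`,
#'   `"overlaying"`.
#' @return List fragment with `n_clusters`, `j_max`, `min_gap`.
#' @export
overlap_presets <- function(degree) {
  presets <- list(
    isolated    = list(n_clusters = 1L, j_max = 0,    min_gap = 2L),
    touching    = list(n_clusters = 1L, j_max = 0,    min_gap = 0L),
    overlapping = list(n_clusters = 1L, j_max = 0.15, min_gap = 0L),
    overlaying  = list(n_clusters = 1L, j_max = 0.40, min_gap = 0L)
  )
  if (!degree %in% names(presets)) stop("unknown overlap degree: ", degree)
  presets[[degree]]
}

#' Ordered names of the overlap series degrees
#' @export
overlap_degrees <- function() c("isolated", "touching", "overlapping", "overlaying")

# Jaccard between two masks given their scene offsets, computed on the
# intersection of bounding boxes only.
offset_jaccard <- function(mask_a, off_a, mask_b, off_b) {
  inter <- offset_intersection(mask_a, off_a, mask_b, off_b)
  area_a <- sum(mask_a > 0); area_b <- sum(mask_b > 0)
  inter / (area_a + area_b - inter)
}

offset_intersection <- function(mask_a, off_a, mask_b, off_b) {
  # scene coords covered: x in off+1 .. off+ncol
  ax1 <- off_a[1] + 1L; ax2 <- off_a[1] + ncol(mask_a)
  ay1 <- off_a[2] + 1L; ay2 <- off_a[2] + nrow(mask_a)
  bx1 <- off_b[1] + 1L; bx2 <- off_b[1] + ncol(mask_b)
  by1 <- off_b[2] + 1L; by2 <- off_b[2] + nrow(mask_b)
  x1 <- max(ax1, bx1); x2 <- min(ax2, bx2)
  y1 <- max(ay1, by1); y2 <- min(ay2, by2)
  if (x1 > x2 || y1 > y2) return(0L)
  sub_a <- mask_a[(y1 - ay1 + 1):(y2 - ay1 + 1), (x1 - ax1 + 1):(x2 - ax1 + 1), drop = FALSE]
  sub_b <- mask_b[(y1 - by1 + 1):(y2 - by1 + 1), (x1 - bx1 + 1):(x2 - bx1 + 1), drop = FALSE]
  sum(sub_a > 0 & sub_b > 0)
}

# Dilate a binary mask by `r` pixels (disc), growing the raster by r on each
# side; returns the mask and the offset shift.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  big <- matrix(0L, h + 2 * r, w + 2 * r)
  big[(r + 1):(r + h), (r + 1):(r + w)] <- mask
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  as_mask(t(EBImage::dilate(t(big), brush)))
}

#' Place cells under the overlap bound
#'
#' @param masks List of binary cell masks (each in its own bounding box).
#' @param spec A [layout_spec()].
#' @return Object of class `placement`: data frame `cells` with per-cell
#'   cluster index, scene offset (`x0`, `y0`, the mask's top-left corner
#'   minus one) and realized maximum pairwise overlap, plus the cluster
#'   centers and the spec.
#' @export
place_cells <- function(masks, spec) {
  if (!length(masks)) stop("no masks supplied")
  if (length(masks) != spec$n_cells)
    stop("number of masks must equal spec$n_cells")
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  W <- spec$image_size[1]; H <- spec$image_size[2]
  gap <- spec$min_gap
  masks <- lapply(masks, as_mask)
  dil <- if (gap > 0) lapply(masks, dilate_mask, r = gap) else NULL

  half_w <- vapply(masks, function(m) ncol(m) / 2, 0)
  half_h <- vapply(masks, function(m) nrow(m) / 2, 0)
  margin_x <- max(half_w); margin_y <- max(half_h)
  if (2 * margin_x >= W || 2 * margin_y >= H)
    stop("layout infeasible: cells larger than the image")
  centers <- cbind(
    x = stats::runif(spec$n_clusters, 1 + margin_x, W - margin_x),
    y = stats::runif(spec$n_clusters, 1 + margin_y, H - margin_y))
  cluster <- sample.int(spec$n_clusters, spec$n_cells, replace = TRUE)

  placed_masks <- list(); placed_off <- list()
  rows <- vector("list", spec$n_cells)
  first_in_cluster <- rep(TRUE, spec$n_clusters)

  satisfies <- function(i, off) {
    worst <- 0
    for (k in seq_along(placed_masks)) {
      if (spec$j_max == 0) {
        if (offset_intersection(masks[[i]], off, placed_masks[[k]], placed_off[[k]]) > 0)
          return(NULL)
      } else {
        j <- offset_jaccard(masks[[i]], off, placed_masks[[k]], placed_off[[k]])
        if (j > spec$j_max) return(NULL)
        worst <- max(worst, j)
      }
      if (gap > 0 &&
          offset_intersection(dil[[i]], off - gap, placed_masks[[k]], placed_off[[k]]) > 0)
        return(NULL)
    }
    worst
  }
  inside <- function(i, off) {
    off[1] >= 0 && off[2] >= 0 &&
      off[1] + ncol(masks[[i]]) <= W && off[2] + nrow(masks[[i]]) <= H
  }

  for (i in seq_len(spec$n_cells)) {
    cl <- cluster[i]
    base <- c(round(centers[cl, 1] - half_w[i]), round(centers[cl, 2] - half_h[i]))
    done <- FALSE
    # first cell of a cluster sits at the center when unobstructed
    for (try in seq_len(spec$max_retries)) {
      theta <- stats::runif(1, 0, 2 * pi)
      dir <- c(cos(theta), sin(theta))
      t <- 0
      repeat {
        off <- as.integer(base + round(t * dir))
        if (!inside(i, off)) break
        worst <- satisfies(i, off)
        if (!is.null(worst)) {
          rows[[i]] <- data.frame(cell = i, cluster = cl, x0 = off[1],
                                  y0 = off[2], max_overlap = worst)
          placed_masks[[length(placed_masks) + 1]] <- masks[[i]]
          placed_off[[length(placed_off) + 1]] <- off
          done <- TRUE
          break
        }
        t <- t + spec$step
      }
      if (done) break
    }
    if (!done) stop("layout infeasible: cell ", i, " cannot satisfy the overlap bound")
    first_in_cluster[cl] <- FALSE
  }
  structure(list(cells = do.call(rbind, rows), centers = centers, spec = spec),
            class = "placement")
}

#' Recompute all pairwise overlaps of a placement from the masks
#'
#' @param masks The masks given to [place_cells()].
#' @param placement The resulting placement.
#' @return Matrix of pairwise Jaccard indices.
#' @export
audit_placement <- function(masks, placement) {
  n <- length(masks)
  masks <- lapply(masks, as_mask)
  offs <- lapply(seq_len(n), function(i)
    c(placement$cells$x0[i], placement$cells$y0[i]))
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    J[i, j] <- J[j, i] <- offset_jaccard(masks[[i]], offs[[i]], masks[[j]], offs[[j]])
  J
}
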