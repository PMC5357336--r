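# Intensity-weighted elastic texture warping: the texture of an annotated
# reference cell is treated as an elastic tissue spanned between fixation
# points on the target contour.  Three energy terms act on three point
# classes: E_fix between fixation points and their targets, E_border along
# the chain of texture boundary points, and E_bulk between 8-connected
# interior points, with spring stiffness log(1+I(p)) * log(1+I(n)) so that
# bright texture resists distortion more than dim texture.

#' Construct an annotated texture patch
#'
#' @param intensity Grayscale matrix (row = y), values in `[0, 255]`.
#' @param mask Binary matrix of the same extent, one connected cell.
#' @param n_points Contour sample count (must match the shape model's N).
#' @param source_id Provenance string.
#' @return Object of class `texture_patch` with fields `intensity`, `mask`,
#'   `contour`, `area`, `source_id`.  Intensity outside the mask is zeroed.
#' @export
texture_patch <- function(intensity, mask, n_points = 100L, source_id = "") {
  if (!all(dim(intensity) == dim(mask)))
    stop("intensity and mask extents differ")
  if (min(intensity) < 0) stop("negative intensity")
  m <- as_mask(mask)
  intensity[m == 0] <- 0
  structure(list(intensity = intensity, mask = m,
                 contour = sample_contour(m, n_points),
                 area = sum(m), source_id = source_id),
            class = "texture_patch")
}

#' @export
print.texture_patch <- function(x, ...) {
  cat("texture_patch", if (nzchar(x$source_id)) paste0("[", x$source_id, "]"),
      ":", nrow(x$mask), "x", ncol(x$mask), "px, area", x$area, "px^2\n")
  invisible(x)
}

# Moore-neighbor boundary trace: ordered cycle of boundary pixel (x, y)
# coordinates of the single foreground component of `mask`.
trace_boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- function(x, y) x >= 1 && x <= w && y >= 1 && y <= h && mask[y, x] > 0
  # first foreground pixel in raster scan order (its west neighbor is bg)
  hit <- which(t(mask) > 0)[1]
  sx <- (hit - 1) %% w + 1
  sy <- (hit - 1) %/% w + 1
  # clockwise Moore neighborhood starting west
  dirs <- cbind(dx = c(-1, -1, 0, 1, 1, 1, 0, -1),
                dy = c(0, -1, -1, -1, 0, 1, 1, 1))
  cur <- c(sx, sy)
  back_dir <- 1L  # came from the west
  path <- list(cur)
  start_back <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- ((back_dir - 1 + k - 1) %% 8) + 1
      nx <- cur[1] + dirs[d, 1]; ny <- cur[2] + dirs[d, 2]
      if (fg(nx, ny)) {
        # new backtrack: direction of the previously scanned (bg) neighbor
        # as seen from the new pixel
        prev_d <- ((d - 2) %% 8) + 1
        bx <- cur[1] + dirs[prev_d, 1]; by <- cur[2] + dirs[prev_d, 2]
        ddx <- bx - nx; ddy <- by - ny
        back_dir <- which(dirs[, 1] == ddx & dirs[, 2] == ddy)
        cur <- c(nx, ny)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur[1] == sx && cur[2] == sy) {
      if (!is.na(start_back) && back_dir == start_back) break
      if (is.na(start_back)) start_back <- back_dir else break
    } else if (is.na(start_back) && length(path) == 1) {
      start_back <- back_dir
    }
    path[[length(path) + 1]] <- cur
    if (length(path) > 8 * (h * w)) stop("boundary trace failed to close")
    if (cur[1] == sx && cur[2] == sy) { path[[length(path)]] <- NULL; break }
  }
  do.call(rbind, path)
}

default_warp_weights <- function() list(w_fix = 20, w_border = 4, w_bulk = 0.02)

#' Initialize the warping point system
#'
#' Rigidly aligns the texture contour to the target contour (translation +
#' rotation, least squares over cyclic correspondences), classifies the
#' texture's mask pixels into border points (boundary pixels, chained along
#' the traced boundary) and bulk points (interior pixels with 8-connected
#' neighbor springs), and pins every `fix_every`-th contour point to the
#' matching target contour point.
#'
#' @param patch A [texture_patch()].
#' @param target Target contour, N x 2 (same N as `patch$contour`).
#' @param weights List with non-negative `w_fix`, `w_border`, `w_bulk`.
#' @param fix_every Fixation point spacing along the contour.
#' @return Object of class `point_system`.
#' @export
init_point_system <- function(patch, target, weights = default_warp_weights(),
                              fix_every = 4L) {
  if (nrow(patch$contour) != nrow(target))
    stop("contour point counts differ between patch and target")
  if (sum(patch$mask) == 0) stop("empty mask")
  stopifnot(weights$w_fix >= 0, weights$w_border >= 0, weights$w_bulk >= 0)
  N <- nrow(target)

  # rigid alignment with correspondence search
  src <- patch$contour
  ctr_s <- colMeans(src); ctr_t <- colMeans(target)
  n <- N; best <- NULL
  for (rev in c(FALSE, TRUE)) {
    aa <- if (rev) src[n:1, , drop = FALSE] else src
    for (s in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      cand <- kabsch2(sweep(aa[idx, , drop = FALSE], 2, ctr_s),
                      sweep(target, 2, ctr_t))
      if (is.null(best) || cand$rss < best$rss) {
        best <- cand; best$idx <- if (rev) (n:1)[idx] else idx
      }
    }
  }
  rigid <- function(p) sweep(sweep(p, 2, ctr_s) %*% best$R, 2, ctr_t, `+`)

  # nodes: every mask pixel, in the target frame
  pix <- which(patch$mask > 0, arr.ind = TRUE)  # [row, col] = [y, x]
  xy <- cbind(x = pix[, 2], y = pix[, 1])
  pos <- rigid(xy)
  node_id <- matrix(0L, nrow(patch$mask), ncol(patch$mask))
  node_id[pix] <- seq_len(nrow(pix))
  intens <- patch$intensity[pix]

  # border chain from the Moore boundary trace
  bp <- trace_boundary_pixels(patch$mask)
  bidx <- node_id[cbind(bp[, 2], bp[, 1])]
  bidx <- bidx[!duplicated(bidx)]
  nb <- length(bidx)
  chain <- cbind(bidx, bidx[c(2:nb, 1)])
  chain <- chain[chain[, 1] != chain[, 2], , drop = FALSE]
  is_border <- rep(FALSE, nrow(pix))
  is_border[bidx] <- TRUE

  # 8-connected springs with at least one bulk endpoint
  h <- nrow(patch$mask); w <- ncol(patch$mask)
  edges <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    a <- node_id[, , drop = FALSE]
    ys <- seq_len(h - abs(d[2])); xs <- seq_len(w - d[1])
    y2 <- ys + abs(d[2]); x2 <- xs + d[1]
    if (d[2] >= 0) {
      aa <- node_id[ys, xs, drop = FALSE]; bb <- node_id[y2, x2, drop = FALSE]
    } else {
      aa <- node_id[y2, xs, drop = FALSE]; bb <- node_id[ys, x2, drop = FALSE]
    }
    keep <- aa > 0 & bb > 0
    edges <- rbind(edges, cbind(aa[keep], bb[keep]))
  }
  edges <- edges[!(is_border[edges[, 1]] & is_border[edges[, 2]]), , drop = FALSE]

  # fixation pairs: every fix_every-th contour point -> nearest border node
  fix_contour_idx <- seq(1, N, by = fix_every)
  src_aligned <- rigid(src)
  fix_idx <- integer(0); fix_target <- NULL
  used <- rep(FALSE, nrow(pix))
  for (j in fix_contour_idx) {
    tj <- which(best$idx == j)  # target index corresponding to source point j
    d2 <- (pos[bidx, 1] - src_aligned[j, 1])^2 + (pos[bidx, 2] - src_aligned[j, 2])^2
    ord <- bidx[order(d2)]
    pick <- ord[!used[ord]][1]
    if (is.na(pick)) next
    used[pick] <- TRUE
    fix_idx <- c(fix_idx, pick)
    # carry the sub-pixel offset between the fixation pixel and its contour
    # sample over to the target, so coincident shapes are an exact rest state
    fix_target <- rbind(fix_target,
                        target[tj, ] + (pos[pick, ] - src_aligned[j, ]))
  }

  sys <- structure(list(
    pos = pos, rest = pos, intensity = intens, is_border = is_border,
    chain = chain, edges = edges, fix_idx = fix_idx, fix_target = fix_target,
    weights = weights, target = target, pixel = xy,
    source_id = patch$source_id
  ), class = "point_system")
  e0 <- system_energy(sys)
  if (!is.finite(e0)) stop("initial energy not finite")
  sys
}

#' Intensity-weighted bulk interaction term
#'
#' Evaluates the printed bulk term exactly:
#' \deqn{f_{bulk}(p) = \sum_{n \in N} \log(1+I(p))\,\log(1+I(n))\,(p - n)}
#' with the natural logarithm.  This is the gradient of the quadratic bulk
#' energy with respect to `p`; [relax()] descends along its negative.
#'
#' @param p Length-2 point.
#' @param neighbors k x 2 matrix of neighbor positions.
#' @param I_p Intensity at `p` (>= 0).
#' @param I_n Length-k intensities at the neighbors (>= 0).
#' @return Length-2 vector.
#' @export
bulk_force <- function(p, neighbors, I_p, I_n) {
  neighbors <- matrix(neighbors, ncol = 2)
  if (I_p < 0 || any(I_n < 0)) stop("negative intensity")
  w <- log1p(I_p) * log1p(I_n)
  c(sum(w * (p[1] - neighbors[, 1])), sum(w * (p[2] - neighbors[, 2])))
}

#' Linear spring forces of the fixation and border terms
#'
#' Displacement springs with rest length zero: the fixation force on a
#' fixation texture point is `w_fix * (target - current)`; the border force
#' on a border point is `w_border` times the sum of `(neighbor - current)`
#' over its adjacent border chain points.
#'
#' @param system A `point_system`.
#' @return List with `fix` (m x 2) and `border` (n_border x 2, rows in the
#'   order of `which(system$is_border)`).
#' @export
spring_forces <- function(system) {
  w <- system$weights
  fix <- w$w_fix * (system$fix_target - system$pos[system$fix_idx, , drop = FALSE])
  bord_nodes <- which(system$is_border)
  bf <- matrix(0, length(bord_nodes), 2)
  rowmap <- integer(nrow(system$pos)); rowmap[bord_nodes] <- seq_along(bord_nodes)
  for (e in seq_len(nrow(system$chain))) {
    a <- system$chain[e, 1]; b <- system$chain[e, 2]
    bf[rowmap[a], ] <- bf[rowmap[a], ] + w$w_border * (system$pos[b, ] - system$pos[a, ])
    bf[rowmap[b], ] <- bf[rowmap[b], ] + w$w_border * (system$pos[a, ] - system$pos[b, ])
  }
  list(fix = fix, border = bf)
}

# Total elastic energy of a point system at positions `pos` (defaults to the
# system's current positions); mirrors the compiled implementation.
system_energy <- function(system, pos = system$pos, rest_mode = "natural") {
  w <- system$weights
  dvec <- function(pairs) {
    d <- pos[pairs[, 1], , drop = FALSE] - pos[pairs[, 2], , drop = FALSE]
    if (rest_mode == "natural")
      d <- d - (system$rest[pairs[, 1], , drop = FALSE] -
                system$rest[pairs[, 2], , drop = FALSE])
    d
  }
  ec <- log1p(system$intensity[system$edges[, 1]]) *
        log1p(system$intensity[system$edges[, 2]])
  de <- dvec(system$edges); dc <- dvec(system$chain)
  df <- pos[system$fix_idx, , drop = FALSE] - system$fix_target
  0.5 * (w$w_bulk * sum(ec * rowSums(de^2)) +
         w$w_border * sum(rowSums(dc^2)) +
         w$w_fix * sum(rowSums(df^2)))
}

#' Relax a point system by gradient descent on the elastic energy
#'
#' Iterates until the largest per-point displacement in a sweep falls below
#' `tol` or `max_iters` is reached.  Points are visited in a freshly
#' shuffled (seeded) order each iteration; the summed force on the visited
#' point moves it a distance capped at `step_cap`.
#'
#' With `rest = "natural"` (default) the border and bulk springs are at rest
#' in the source configuration, so an untransformed patch is an exact
#' equilibrium and the warp measures deformation away from the source.
#' `rest = "zero"` uses literal zero-rest-length springs.
#'
#' @param system A `point_system`.
#' @param max_iters,step_cap,tol Iteration controls (pixels).
#' @param eta Learning rate; `"auto"` preconditions the step by each point's
#'   total spring stiffness (factor `omega`), a numeric value reproduces the
#'   plain `min(|f| * eta, step_cap)` step.
#' @param omega Relaxation factor for `eta = "auto"` (0 < omega < 2).
#' @param rest `"natural"` or `"zero"` spring rest configuration.
#' @param seed Optional seed for the per-iteration shuffle.
#' @param snap Warn if a fixation point ends farther than this from its
#'   target (pixels).
#' @return The system with updated `pos` plus fields `energy` (per-iteration
#'   trace), `iterations`, `converged`.
#' @export
relax <- function(system, max_iters = 5000L, step_cap = 0.5, tol = 1e-3,
                  eta = "auto", omega = 0.8, rest = c("natural", "zero"),
                  seed = NULL, snap = 2) {
  rest <- match.arg(rest)
  stopifnot(max_iters >= 1, step_cap > 0, tol >= 0)
  if (!is.null(seed)) set.seed(seed)
  eta_num <- if (identical(eta, "auto")) -1 else as.numeric(eta)
  # relax_cpp updates positions in place; pass a copy so `rest` (which may
  # share memory with the initial positions) stays untouched
  res <- relax_cpp(system$pos + 0, system$rest, system$intensity,
                   system$edges - 1L, system$chain - 1L,
                   as.integer(system$fix_idx - 1L),
                   matrix(as.numeric(system$fix_target), ncol = 2),
                   system$weights$w_fix, system$weights$w_border,
                   system$weights$w_bulk, eta_num, omega, step_cap, tol,
                   as.integer(max_iters), identical(rest, "zero"))
  system$pos <- res$pos
  system$energy <- res$energy
  system$iterations <- res$iterations
  system$converged <- res$converged
  resid <- sqrt(rowSums((system$pos[system$fix_idx, , drop = FALSE] -
                         system$fix_target)^2))
  if (length(resid) && max(resid) > snap)
    warning("fixation residual ", format(max(resid), digits = 3),
            " px exceeds snap distance ", snap, " px")
  system
}

#' Rasterize a relaxed point system into the target shape
#'
#' Every point deposits its source intensity at its final continuous
#' position (nearest-pixel splat, averaging multiple deposits); pixels
#' inside the target mask that received no deposit are filled by
#' inverse-distance-weighted interpolation from the 8 nearest deposited
#' pixels.
#'
#' @param system A relaxed `point_system`.
#' @return Object of class `rendered_cell`: `intensity` and `mask` rasters in
#'   the target's bounding box, `offset` (scene coordinate of raster pixel
#'   (1,1) minus (1,1)), and `contour` (target contour in raster
#'   coordinates).
#' @export
rasterize <- function(system) {
  target <- system$target
  x0 <- floor(min(target[, 1])) - 1L
  y0 <- floor(min(target[, 2])) - 1L
  wb <- ceiling(max(target[, 1])) + 1L - x0
  hb <- ceiling(max(target[, 2])) + 1L - y0
  gx <- rep(seq_len(wb), each = hb) + x0
  gy <- rep(seq_len(hb), times = wb) + y0
  inside <- points_in_polygon_cpp(gx, gy, target)
  mask <- matrix(0L, hb, wb)
  mask[cbind(gy - y0, gx - x0)] <- as.integer(inside)

  px <- round(system$pos[, 1]) - x0
  py <- round(system$pos[, 2]) - y0
  keep <- px >= 1 & px <= wb & py >= 1 & py <= hb
  li <- py[keep] + (px[keep] - 1) * hb
  sums <- rowsum(system$intensity[keep], li)
  counts <- rowsum(rep(1, sum(keep)), li)
  img <- matrix(0, hb, wb)
  ids <- as.integer(rownames(sums))
  img[ids] <- sums / counts
  deposited <- matrix(FALSE, hb, wb)
  deposited[ids] <- TRUE

  empty <- which(mask > 0 & !deposited)
  inmask_n <- sum(mask)
  # a healthy warp fills min(#points, #mask pixels) pixels up to splat
  # collisions; well under half of that indicates a collapsed point system
  expected_fill <- min(nrow(system$pos), inmask_n)
  if (inmask_n > 0 && sum(deposited & mask > 0) < expected_fill / 2)
    stop("warp collapsed: only ", sum(deposited & mask > 0), " of ",
         inmask_n, " in-mask pixels received deposits")
  if (length(empty)) {
    dep <- which(deposited)
    dx <- ((dep - 1) %/% hb) + 1; dy <- ((dep - 1) %% hb) + 1
    ex <- ((empty - 1) %/% hb) + 1; ey <- ((empty - 1) %% hb) + 1
    vals <- img[dep]
    k <- min(8L, length(dep))
    for (i in seq_along(empty)) {
      d2 <- (dx - ex[i])^2 + (dy - ey[i])^2
      nn <- order(d2)[seq_len(k)]
      wgt <- 1 / pmax(d2[nn], 1e-9)
      img[empty[i]] <- sum(wgt * vals[nn]) / sum(wgt)
    }
  }
  img[mask == 0] <- 0
  structure(list(intensity = img, mask = mask,
                 offset = c(x = x0, y = y0),
                 contour = sweep(target, 2, c(x0, y0)),
                 source_id = system$source_id),
            class = "rendered_cell")
}

#' Warp a texture patch onto a target contour
#'
#' Convenience wrapper: [init_point_system()], [relax()], [rasterize()].
#'
#' @inheritParams init_point_system
#' @param ... Passed to [relax()].
#' @export
warp_texture <- function(patch, target, weights = default_warp_weights(),
                         fix_every = 4L, ...) {
  sys <- init_point_system(patch, target, weights, fix_every)
  sys <- relax(sys, ...)
  rasterize(sys)
}

# Pick a texture patch for a target shape: uniform among patches whose area
# is within +/-50% of the target polygon area, nearest-area fallback.
select_patch <- function(patches, target_area, tolerance = 0.5) {
  areas <- vapply(patches, function(p) p$area, 0)
  ok <- which(abs(areas - target_area) <= tolerance * target_area)
  if (!length(ok)) ok <- which.min(abs(areas - target_area))
  patches[[if (length(ok) == 1) ok else sample(ok, 1)]]
}
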