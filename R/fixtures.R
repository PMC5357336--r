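# Procedural texture patches: stand-ins for hand-annotated cell patches so
# that training, warping, and the whole simulation pipeline run without any
# external data.  Blob outlines are band-limited radial perturbations of a
# circle (guaranteed simple polygons); textures are uniform, radial-gradient
# or speckled (bright granules on dim plasma).

#' Specification of a procedural patch set
#'
#' @param cell_kind `"disk"`, `"ellipse"` or `"blob"` (radially perturbed
#'   circle).
#' @param radius_range `c(min, max)` mean radius in pixels.
#' @param texture_kind `"uniform"`, `"radial"` (intensity decreasing with
#'   radius) or `"speckle"`.
#' @param intensity_range `c(min, max)` peak intensity in gray levels.
#' @param n_patches Number of patches (>= 1).
#' @param rng_seed Seed.
#' @param n_points Contour sample count.
#' @export
fixture_spec <- function(cell_kind = c("blob", "disk", "ellipse"),
                         radius_range = c(10, 16),
                         texture_kind = c("radial", "uniform", "speckle"),
                         intensity_range = c(80, 200),
                         n_patches = 10L, rng_seed = 1L, n_points = 100L) {
  cell_kind <- match.arg(cell_kind)
  texture_kind <- match.arg(texture_kind)
  if (any(radius_range <= 0)) stop("radius range must be positive")
  if (n_patches < 1) stop("n_patches must be >= 1")
  structure(list(cell_kind = cell_kind, radius_range = radius_range,
                 texture_kind = texture_kind,
                 intensity_range = intensity_range,
                 n_patches = as.integer(n_patches),
                 rng_seed = as.integer(rng_seed),
                 n_points = as.integer(n_points)),
            class = "fixture_spec")
}

# Band-limited star-shaped outline around (cx, cy); amplitude budget keeps
# the radius positive, hence the polygon simple.
fixture_outline <- function(kind, R, cx, cy, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- switch(kind,
    disk = rep(R, n),
    ellipse = {
      b <- R * stats::runif(1, 0.55, 0.9)
      phi <- stats::runif(1, 0, pi)
      a <- R
      (a * b) / sqrt((b * cos(th - phi))^2 + (a * sin(th - phi))^2)
    },
    blob = {
      rr <- rep(R, n)
      for (k in 2:5) {
        amp <- stats::runif(1, 0, 0.22 / k)
        rr <- rr + R * amp * cos(k * th + stats::runif(1, 0, 2 * pi))
      }
      rr
    })
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

rasterize_outline <- function(poly, w, h) {
  gx <- rep(seq_len(w), each = h)
  gy <- rep(seq_len(h), times = w)
  inside <- points_in_polygon_cpp(gx, gy, poly)
  m <- matrix(0L, h, w)
  m[cbind(gy, gx)] <- as.integer(inside)
  m
}

fixture_texture <- function(kind, mask, intensity_range) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  d <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  img <- matrix(0, h, w)
  lo <- intensity_range[1]; hi <- intensity_range[2]
  if (kind == "uniform") {
    img[idx] <- stats::runif(1, lo, hi)
  } else if (kind == "radial") {
    peak <- stats::runif(1, lo, hi)
    img[idx] <- peak * (1 - 0.85 * d / max(max(d), 1))
  } else {  # speckle: Gaussian granules on dim plasma
    peak <- stats::runif(1, lo, hi)
    img[idx] <- 0.2 * peak
    n_gr <- max(3L, round(nrow(idx) / 80))
    pick <- sample(nrow(idx), n_gr, replace = TRUE)
    for (g in pick) {
      gy <- idx[g, 1]; gx <- idx[g, 2]
      s <- stats::runif(1, 1, 2.5)
      amp <- stats::runif(1, 0.5, 1) * peak
      d2 <- (idx[, 1] - gy)^2 + (idx[, 2] - gx)^2
      img[idx] <- img[idx] + amp * exp(-d2 / (2 * s^2))
    }
    img[idx] <- pmin(img[idx], 255)
  }
  img
}

#' Generate procedural texture patches
#'
#' @param spec A [fixture_spec()].
#' @return List of [texture_patch()]es, seeded-deterministic.
#' @export
generate_patches <- function(spec) {
  set.seed(spec$rng_seed)
  out <- vector("list", spec$n_patches)
  for (i in seq_len(spec$n_patches)) {
    R <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    ext <- ceiling(2 * (R * 1.35 + 3))
    poly <- fixture_outline(spec$cell_kind, R, ext / 2, ext / 2)
    mask <- rasterize_outline(poly, ext, ext)
    img <- fixture_texture(spec$texture_kind, mask, spec$intensity_range)
    out[[i]] <- texture_patch(img, mask, n_points = spec$n_points,
                              source_id = sprintf("fixture_%s_%s_%03d",
                                                  spec$cell_kind,
                                                  spec$texture_kind, i))
  }
  out
}

#' Validate a texture patch against the shared invariants
#'
#' Checks the invariants every input patch (procedural or real) must hold:
#' matching extents, a single connected mask component, zero intensity
#' outside the mask, and a simple contour polygon.
#'
#' @param patch A [texture_patch()].
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_patch <- function(patch) {
  stopifnot(inherits(patch, "texture_patch"))
  if (!all(dim(patch$intensity) == dim(patch$mask)))
    stop("intensity/mask extent mismatch")
  if (n_components(patch$mask) != 1) stop("mask is not a single component")
  if (any(patch$intensity[patch$mask == 0] != 0))
    stop("nonzero intensity outside mask")
  if (!is_simple_polygon(patch$contour)) stop("contour self-intersects")
  invisible(TRUE)
}
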