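# PCA statistical shape model (ASM) over corresponded cell contours.
# A contour is an N x 2 matrix of (x, y) points; internally a shape is the
# interleaved length-2N vector (x1, y1, ..., xN, yN).

contour_to_vec <- function(pts) as.vector(t(pts))
vec_to_contour <- function(v) {
  out <- matrix(v, ncol = 2, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

# Center a contour and rotate it so its first/second principal axes align
# with the x/y coordinate axes (proper rotation, scale preserved).
normalize_contour <- function(pts) {
  ctr <- colMeans(pts)
  p <- sweep(pts, 2, ctr)
  cv <- crossprod(p) / nrow(p)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] <= 0 || ev$values[2] / ev$values[1] < 1e-12)
    stop("degenerate contour: points are collinear")
  R <- ev$vectors
  if (det(R) < 0) R[, 2] <- -R[, 2]
  p %*% R
}

# Best proper rotation (2-D Kabsch) of a onto b, both centered; returns the
# rotated points and the residual sum of squares.
kabsch2 <- function(a, b) {
  sxx <- sum(a[, 1] * b[, 1]); syy <- sum(a[, 2] * b[, 2])
  sxy <- sum(a[, 1] * b[, 2]); syx <- sum(a[, 2] * b[, 1])
  theta <- atan2(sxy - syx, sxx + syy)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
              2, 2, byrow = TRUE)
  ar <- a %*% R
  list(pts = ar, rss = sum((ar - b)^2), R = R, theta = theta)
}

# Cyclic-shift / reversal / rotation correspondence search of contour a
# against reference b (both centered).  Exhaustive over all N shifts and both
# traversal orientations; the rotation is solved in closed form per
# candidate.
align_to_reference <- function(a, b) {
  n <- nrow(a)
  best <- NULL
  for (rev in c(FALSE, TRUE)) {
    aa <- if (rev) a[n:1, , drop = FALSE] else a
    for (s in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      cand <- kabsch2(aa[idx, , drop = FALSE], b)
      if (is.null(best) || cand$rss < best$rss) best <- cand
    }
  }
  best
}

#' Normalize and correspond a set of sampled contours
#'
#' Each contour is translated to its centroid, rotated to its principal axes,
#' and cyclically re-indexed (allowing traversal reversal) so that the summed
#' squared point-to-point distance to the running reference is minimal.  The
#' reference is the first contour on the first pass and the mean shape on the
#' second, Procrustes-style pass (rotation re-solved, scale preserved).
#'
#' @param contours List of N x 2 contour matrices, identical N.
#' @return List of aligned length-2N vectors (x1, y1, ..., xN, yN).
#' @export
normalize_and_correspond <- function(contours) {
  if (length(contours) < 2) stop("need at least 2 contours")
  ns <- vapply(contours, nrow, 0L)
  if (length(unique(ns)) != 1) stop("contours have mismatched point counts")
  norm <- lapply(contours, normalize_contour)
  ref <- norm[[1]]
  pass1 <- c(list(ref), lapply(norm[-1], function(p) align_to_reference(p, ref)$pts))
  mean_shape <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- lapply(pass1, function(p) align_to_reference(p, mean_shape)$pts)
  lapply(pass2, contour_to_vec)
}

#' Fit the PCA shape model
#'
#' @param aligned_vectors List (or matrix rows) of aligned length-2N shape
#'   vectors from [normalize_and_correspond()].
#' @param n_modes Number of eigenmodes to keep (1 to count - 1).
#' @param r_min Minimum-size threshold in pixels: generated shapes whose mean
#'   contour radius (mean distance of contour points from their centroid)
#'   falls below `r_min` are rejected.
#' @return Object of class `shape_model` with fields `mean_shape`, `modes`
#'   (orthonormal columns), `eigenvalues` (non-increasing), `n_modes`,
#'   `n_points`, `r_min`.
#' @export
fit_shape_model <- function(aligned_vectors, n_modes = NULL, r_min = 0) {
  X <- if (is.list(aligned_vectors)) do.call(rbind, aligned_vectors) else as.matrix(aligned_vectors)
  m <- nrow(X)
  if (m < 2) stop("need at least 2 shapes")
  if (r_min < 0) stop("r_min must be >= 0")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (is.null(n_modes)) {
    # smallest number of modes explaining 98% of the variance
    cum <- cumsum(ev) / sum(ev)
    n_modes <- min(which(cum >= 0.98))
  }
  n_modes <- as.integer(n_modes)
  if (n_modes < 1 || n_modes > m - 1)
    stop("n_modes must be between 1 and number of shapes - 1")
  structure(list(
    mean_shape = as.numeric(pc$center),
    modes = pc$rotation[, seq_len(n_modes), drop = FALSE],
    eigenvalues = ev[seq_len(n_modes)],
    n_modes = n_modes,
    n_points = ncol(X) / 2,
    r_min = r_min
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("PCA cell shape model:", x$n_points, "contour points,",
      x$n_modes, "modes, r_min =", x$r_min, "px\n")
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

mean_contour_radius <- function(pts) {
  ctr <- colMeans(pts)
  mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
}

#' Generate a new cell shape from a shape model
#'
#' Mode coefficients are drawn independently from zero-mean Gaussians with
#' variance equal to the mode eigenvalue and clamped to +/- 3 standard
#' deviations.  A candidate is rejected and redrawn if it violates the
#' minimum-size constraint or if its polygon self-intersects.
#'
#' @param model A `shape_model`.
#' @param rng_seed Optional integer seed for reproducible generation.
#' @param constraint `"mean_radius"` (default) rejects shapes whose mean
#'   contour radius is below `r_min`; `"coefficient"` applies the
#'   coefficient-space test \eqn{\lVert b - P^+ x_m \rVert > r_{min}} (with
#'   the pseudo-inverse \eqn{P^+ = P^T} for orthonormal modes).
#' @param max_tries Consecutive rejections before giving up.
#' @return Object of class `shape_sample`: list with `coefficients` (length
#'   n) and `contour` (N x 2 matrix).
#' @export
generate_shape <- function(model, rng_seed = NULL,
                           constraint = c("mean_radius", "coefficient"),
                           max_tries = 1000L) {
  constraint <- match.arg(constraint)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sd3 <- 3 * sqrt(model$eigenvalues)
  for (tries in seq_len(max_tries)) {
    b <- stats::rnorm(model$n_modes, 0, sqrt(model$eigenvalues))
    b <- pmin(pmax(b, -sd3), sd3)
    v <- model$mean_shape + as.numeric(model$modes %*% b)
    pts <- vec_to_contour(v)
    ok <- if (constraint == "mean_radius") {
      mean_contour_radius(pts) >= model$r_min
    } else {
      sqrt(sum((b - as.numeric(crossprod(model$modes, model$mean_shape)))^2)) > model$r_min
    }
    if (ok && is_simple_polygon(pts)) {
      return(structure(list(coefficients = b, contour = pts),
                       class = "shape_sample"))
    }
  }
  stop("model/r_min incompatible: ", max_tries, " consecutive rejections")
}

#' Persist a shape model to a JSON file
#' @param model A `shape_model`.
#' @param path Output file.
#' @export
write_shape_model <- function(model, path) {
  obj <- list(format = "fluosim-shape-model", version = 1L,
              n_points = model$n_points, n_modes = model$n_modes,
              r_min = model$r_min, mean_shape = model$mean_shape,
              eigenvalues = model$eigenvalues,
              modes = as.vector(model$modes))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a shape model written by [write_shape_model()]
#' @param path JSON file.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fluosim-shape-model"))
    stop("not a fluosim shape model file: ", path)
  structure(list(
    mean_shape = as.numeric(obj$mean_shape),
    modes = matrix(as.numeric(obj$modes), ncol = obj$n_modes),
    eigenvalues = as.numeric(obj$eigenvalues),
    n_modes = as.integer(obj$n_modes),
    n_points = as.integer(obj$n_points),
    r_min = as.numeric(obj$r_min)
  ), class = "shape_model")
}

#' Train a shape model directly from binary masks
#'
#' Convenience wrapper: samples each mask's contour, corresponds the
#' contours, and fits the PCA model.
#'
#' @param masks List of binary mask matrices (one cell each).
#' @inheritParams fit_shape_model
#' @param n_points Contour points per shape.
#' @export
train_shape_model <- function(masks, n_points = 100L, n_modes = NULL, r_min = 0) {
  contours <- lapply(masks, sample_contour, n_points = n_points)
  fit_shape_model(normalize_and_correspond(contours), n_modes = n_modes,
                  r_min = r_min)
}
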