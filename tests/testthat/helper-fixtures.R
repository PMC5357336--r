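# Shared procedural fixtures, built in code at test time.

# Disk mask of radius r (pixel centers within r of the center).
mk_disk_mask <- function(r, ext = 2 * r + 7) {
  cx <- (ext + 1) / 2
  (outer(seq_len(ext), seq_len(ext),
         function(y, x) (x - cx)^2 + (y - cx)^2) <= r^2) + 0
}

# Filled rectangle mask inside a zero frame.
mk_rect_mask <- function(h, w, pad = 3) {
  m <- matrix(0, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- 1
  m
}

# Scale a contour about its centroid.
scale_contour <- function(pts, s) {
  ctr <- colMeans(pts)
  sweep(sweep(pts, 2, ctr) * s, 2, ctr, `+`)
}

# Small shared pool of blob patches and a trained shape model (used by the
# scene and segmentation tests; modest sizes keep the suite fast).
shared_patch_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool))
      pool <<- generate_patches(fixture_spec("blob", c(9, 13), "radial",
                                             c(60, 140), n_patches = 8,
                                             rng_seed = 2, n_points = 64))
    pool
  }
})

shared_shape_model <- local({
  model <- NULL
  function() {
    if (is.null(model))
      model <<- train_shape_model(lapply(shared_patch_pool(), `[[`, "mask"),
                                  n_points = 64, r_min = 6)
    model
  }
})

# Independent boundary-pixel count: foreground pixels with a background (or
# out-of-frame) pixel among their 4 neighbors (the inner boundary).
count_boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  n_bg <- (pad[1:h, 2:(w + 1)] == 0) + (pad[3:(h + 2), 2:(w + 1)] == 0) +
          (pad[2:(h + 1), 1:w] == 0) + (pad[2:(h + 1), 3:(w + 2)] == 0)
  sum(mask > 0 & n_bg > 0)
}
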