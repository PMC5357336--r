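#' Perlin gradient-noise background
#'
#' Classic lattice gradient noise with smoothstep interpolation, summed over
#' octaves with per-octave frequency doubling and amplitude halving, then
#' rescaled linearly to `[offset, offset + amplitude]` gray levels.  Used to
#' emulate smooth background fluorescence artifacts.
#'
#' @param size `c(width, height)` in pixels.
#' @param octaves Number of octaves (>= 1).
#' @param frequency Base lattice frequency in cycles per pixel (> 0).
#' @param amplitude Peak-to-peak output range in gray levels.
#' @param offset Minimum output level in gray levels.
#' @param seed Optional seed.
#' @return `height` x `width` matrix.
#' @export
perlin_background <- function(size, octaves = 4L, frequency = 1 / 64,
                              amplitude = 20, offset = 10, seed = NULL) {
  if (octaves < 1) stop("octaves must be >= 1")
  if (frequency <= 0) stop("frequency must be positive")
  if (amplitude < 0 || offset < 0) stop("amplitude and offset must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  W <- size[1]; H <- size[2]
  if (amplitude == 0) return(matrix(offset, H, W))
  field <- matrix(0, H, W)
  for (o in seq_len(octaves)) {
    f <- frequency * 2^(o - 1)
    amp <- 0.5^(o - 1)
    field <- field + amp * perlin_octave(W, H, f)
  }
  rng <- range(field)
  if (diff(rng) < 1e-12) return(matrix(offset, H, W))
  offset + amplitude * (field - rng[1]) / diff(rng)
}

# One octave of 2-D Perlin noise on an H x W pixel grid at lattice frequency
# f; consumes the current RNG stream for the lattice gradients.
perlin_octave <- function(W, H, f) {
  gx <- floor(W * f) + 2L  # lattice nodes in x
  gy <- floor(H * f) + 2L
  ang <- matrix(stats::runif(gx * gy, 0, 2 * pi), gy, gx)
  grad_x <- cos(ang); grad_y <- sin(ang)

  u <- (seq_len(W) - 1) * f   # lattice coordinates of pixel columns
  v <- (seq_len(H) - 1) * f
  iu <- pmin(floor(u), gx - 2); iv <- pmin(floor(v), gy - 2)
  fu <- u - iu; fv <- v - iv
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  su <- fade(fu); sv <- fade(fv)

  # corner dot products, vectorized over the pixel grid (rows = y)
  IU <- matrix(iu + 1L, H, W, byrow = TRUE)   # lattice col index (1-based)
  IV <- matrix(iv + 1L, H, W)
  FU <- matrix(fu, H, W, byrow = TRUE)
  FV <- matrix(fv, H, W)
  dot <- function(dx, dy) {
    idx <- cbind(as.vector(IV + dy), as.vector(IU + dx))
    matrix(grad_x[idx], H, W) * (FU - dx) + matrix(grad_y[idx], H, W) * (FV - dy)
  }
  n00 <- dot(0L, 0L); n10 <- dot(1L, 0L)
  n01 <- dot(0L, 1L); n11 <- dot(1L, 1L)
  SU <- matrix(su, H, W, byrow = TRUE)
  SV <- matrix(sv, H, W)
  nx0 <- n00 + SU * (n10 - n00)
  nx1 <- n01 + SU * (n11 - n01)
  nx0 + SV * (nx1 - nx0)
}
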