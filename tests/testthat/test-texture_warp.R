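test_that("bulk term evaluates the intensity-weighted formula exactly", {
  # single neighbor at unit distance, both intensities e - 1
  f <- bulk_force(c(0, 0), c(1, 0), exp(1) - 1, exp(1) - 1)
  expect_equal(f, c(-1, 0), tolerance = 1e-12)

  # zero intensity zeroes the force
  expect_equal(bulk_force(c(3, 4), rbind(c(1, 0), c(0, 2)), 0, c(5, 7)), c(0, 0))
  expect_equal(bulk_force(c(3, 4), rbind(c(1, 0), c(0, 2)), 5, c(0, 0)), c(0, 0))

  # symmetric neighbors cancel
  f <- bulk_force(c(0, 0), rbind(c(1, 0), c(-1, 0)), 10, c(4, 4))
  expect_equal(f, c(0, 0), tolerance = 1e-12)

  expect_error(bulk_force(c(0, 0), c(1, 0), -1, 5), "negative")
})

test_that("point system construction counts and pins points correctly", {
  m <- mk_disk_mask(15, ext = 30)  # 30 x 30 disk patch
  p <- texture_patch(m * 100, m, n_points = 64)
  sys <- init_point_system(p, p$contour, fix_every = 4L)
  expect_length(sys$fix_idx, 16)                      # 64 / 4 fixation pairs
  expect_equal(sum(sys$is_border), count_boundary_pixels(m))
  expect_equal(nrow(sys$pos), sum(m))
  expect_equal(sum(!sys$is_border), sum(m) - count_boundary_pixels(m))
  # symmetric neighbor relation: each undirected spring appears once
  expect_true(all(sys$edges[, 1] != sys$edges[, 2]))
  expect_true(all(!(sys$is_border[sys$edges[, 1]] & sys$is_border[sys$edges[, 2]])))

  # identity target: fixation pairs start coincident
  d <- sqrt(rowSums((sys$pos[sys$fix_idx, ] - sys$fix_target)^2))
  expect_lt(max(d), 1e-9)

  # translated target: rigid alignment removes the offset
  sys2 <- init_point_system(p, sweep(p$contour, 2, c(10, 0), `+`))
  d2 <- sqrt(rowSums((sys2$pos[sys2$fix_idx, ] - sys2$fix_target)^2))
  expect_lt(max(d2), 1e-9)

  expect_error(init_point_system(p, p$contour[1:32, ]), "point count")
})

test_that("spring forces are linear displacement springs", {
  m <- mk_disk_mask(10)
  p <- texture_patch(m * 50, m, n_points = 32)
  sys <- init_point_system(p, p$contour,
                           weights = list(w_fix = 2, w_border = 1, w_bulk = 0.1))
  f0 <- spring_forces(sys)
  expect_lt(max(abs(f0$fix)), 1e-9)  # coincident pairs: zero fix force

  # offset one fixation point by (3, 4) with w_fix = 2: force (6, 8)
  sys$pos[sys$fix_idx[1], ] <- sys$fix_target[1, ] - c(3, 4)
  f1 <- spring_forces(sys)
  expect_equal(unname(f1$fix[1, ]), c(6, 8), tolerance = 1e-12)

  # a border point equidistant between its chain neighbors on a line
  mid <- sys$chain[1, ]
  other <- sys$chain[sys$chain[, 1] == mid[2] | sys$chain[, 2] == mid[2], ]
  nbrs <- setdiff(unique(as.vector(other)), mid[2])
  sys$pos[nbrs[1], ] <- c(0, 0); sys$pos[nbrs[2], ] <- c(2, 2)
  sys$pos[mid[2], ] <- c(1, 1)
  f2 <- spring_forces(sys)
  row <- match(mid[2], which(sys$is_border))
  expect_equal(unname(f2$border[row, ]), c(0, 0), tolerance = 1e-12)
})

test_that("relaxation: equilibrium exit, reproducibility, divergence guard", {
  m <- mk_disk_mask(12)
  p <- texture_patch(m * 120, m, n_points = 64)
  sys <- init_point_system(p, p$contour)

  # identical target with uniform intensity: already at equilibrium
  r0 <- relax(sys, seed = 1)
  expect_equal(r0$iterations, 1)
  expect_lt(max(abs(r0$pos - sys$pos)), 1e-12)

  # reproducibility: same seed, bit-identical result
  target <- scale_contour(p$contour, 1.3)
  sysb <- init_point_system(p, target)
  ra <- relax(sysb, seed = 7)
  rb <- relax(sysb, seed = 7)
  expect_identical(ra$pos, rb$pos)

  # a learning rate beyond the stability limit makes the energy grow every
  # sweep; the guard reports it after ten consecutive increases
  two <- structure(list(
    pos = rbind(c(0, 0), c(1, 0)), rest = rbind(c(0, 0), c(1, 0)),
    intensity = c(10, 10), is_border = c(TRUE, TRUE),
    chain = matrix(c(1L, 2L), 1), edges = matrix(c(1L, 2L), 1),
    fix_idx = 1L, fix_target = matrix(c(5, 0), 1),
    weights = list(w_fix = 20, w_border = 1, w_bulk = 0.01),
    target = rbind(c(5, 0), c(6, 0)), source_id = ""), class = "point_system")
  expect_error(suppressWarnings(relax(two, eta = 0.2, step_cap = 1e12, seed = 1)),
               "step too large")
})

test_that("uniform disk warped to a 1.5x disk approaches the similarity map", {
  m <- mk_disk_mask(16)
  p <- texture_patch(m * 120, m, n_points = 64)
  ctr <- colMeans(p$contour)
  target <- scale_contour(p$contour, 1.5)
  sys <- init_point_system(p, target)
  sr <- relax(sys, seed = 2)
  expect_true(sr$converged)
  # energy non-increasing along the trace
  e <- sr$energy
  expect_true(all(diff(e) <= 1e-6 * pmax(abs(e[-length(e)]), 1) + 1e-9))
  expected <- sweep(sweep(sys$rest, 2, ctr) * 1.5, 2, ctr, `+`)
  r_got <- sqrt(rowSums(sweep(sr$pos, 2, ctr)^2))
  r_want <- sqrt(rowSums(sweep(expected, 2, ctr)^2))
  expect_lt(mean(abs(r_got - r_want)) / 24, 0.05)
})

test_that("rasterization reproduces the identity and constant textures", {
  m <- mk_disk_mask(14)
  idx <- which(m > 0, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  img <- matrix(0, nrow(m), ncol(m))
  img[idx] <- 200 * (1 - 0.04 * sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2))
  p <- texture_patch(img, m, n_points = 64)

  # identity warp: exact round trip inside the mask
  rc <- warp_texture(p, p$contour, seed = 1)
  ys <- (rc$offset[2] + 1):(rc$offset[2] + nrow(rc$mask))
  xs <- (rc$offset[1] + 1):(rc$offset[1] + ncol(rc$mask))
  src <- img[ys, xs]
  expect_lte(max(abs(rc$intensity[rc$mask > 0] - src[rc$mask > 0])), 1)

  # uniform texture stays uniform for any target shape
  pu <- texture_patch(m * 77, m, n_points = 64)
  blob <- generate_patches(fixture_spec("blob", c(12, 14), "uniform",
                                        n_patches = 1, rng_seed = 31,
                                        n_points = 64))[[1]]
  rcu <- warp_texture(pu, blob$contour, seed = 1)
  expect_lte(max(abs(rcu$intensity[rcu$mask > 0] - 77)), 1)
  expect_true(all(rcu$intensity[rcu$mask == 0] == 0))
  # intensity range is preserved (interpolation is convex)
  expect_gte(min(rcu$intensity[rcu$mask > 0]), 77 - 1e-9)
  expect_lte(max(rcu$intensity), 77 + 1e-9)
})

test_that("radial gradients survive a 1.5x warp monotonically", {
  m <- mk_disk_mask(14)
  idx <- which(m > 0, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  rr <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  img <- matrix(0, nrow(m), ncol(m))
  img[idx] <- 200 * (1 - 0.8 * rr / 16)
  p <- texture_patch(img, m, n_points = 64)
  expect_lt(stats::cor(rr, img[idx], method = "spearman"), -0.95)

  rc <- warp_texture(p, scale_contour(p$contour, 1.5), seed = 3)
  ii <- which(rc$mask > 0, arr.ind = TRUE)
  ctr <- c(mean(ii[, 1]), mean(ii[, 2]))
  rw <- sqrt((ii[, 1] - ctr[1])^2 + (ii[, 2] - ctr[2])^2)
  expect_lt(stats::cor(rw, rc$intensity[ii], method = "spearman"), -0.95)
})

test_that("stronger bulk weight shrinks bright-region distortion", {
  m <- mk_disk_mask(14)
  ext <- nrow(m); cx <- (ext + 1) / 2
  d2 <- outer(seq_len(ext), seq_len(ext), function(y, x) (x - cx)^2 + (y - cx)^2)
  img <- m * (40 + 180 * (d2 <= 25))  # bright core on dim plasma
  p <- texture_patch(img, m, n_points = 64)
  target <- scale_contour(p$contour, 1.5)
  src_bright <- sum(img > 100)
  ratios <- vapply(c(0.002, 0.02, 0.2), function(wb) {
    rc <- warp_texture(p, target,
                       weights = list(w_fix = 20, w_border = 4, w_bulk = wb),
                       seed = 1)
    sum(rc$intensity > 100) / src_bright
  }, 0)
  expect_true(all(ratios > 1))          # the warp stretches the bright core
  expect_true(all(diff(ratios) < 0))    # higher w_bulk moves the ratio to 1
})
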