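test_that("sample_contour meets its geometric contracts", {
  # circular symmetry: all points near the nominal radius
  m <- mk_disk_mask(20)
  ct <- sample_contour(m, 64)
  ctr <- colMeans(ct)
  d <- sqrt(rowSums(sweep(ct, 2, ctr)^2))
  expect_true(all(abs(d - 20) < 0.75))
  expect_gt(polygon_area(ct), 0)  # counter-clockwise

  # equal arc-length spacing on a square
  sq <- mk_rect_mask(10, 10)
  c4 <- sample_contour(sq, 4)
  seps <- sqrt(rowSums((c4 - c4[c(2:4, 1), ])^2))
  expect_true(max(abs(seps - mean(seps))) < 1e-6 * sum(seps))

  # start point convention: largest x, ties largest y
  c100 <- sample_contour(sq, 100)
  expect_equal(unname(c100[1, 1]), max(c100[, 1]))

  # area of a 40 x 20 rectangle within 5% of the pixel count
  rc <- mk_rect_mask(20, 40)
  cr <- sample_contour(rc, 100)
  expect_lt(abs(abs(polygon_area(cr)) - 800) / 800, 0.05)
})

test_that("sample_contour rejects invalid patches", {
  m <- matrix(0, 20, 20)
  expect_error(sample_contour(m, 16), "invalid patch")
  m[3:6, 3:6] <- 1; m[12:15, 12:15] <- 1
  expect_error(sample_contour(m, 16), "invalid patch")
  expect_error(sample_contour(mk_disk_mask(10), 3), "n_points")
})

test_that("normalization removes rigid transforms and index shifts", {
  ct <- sample_contour(mk_disk_mask(15), 64)
  blob <- generate_patches(fixture_spec("blob", c(12, 14), "uniform",
                                        n_patches = 1, rng_seed = 9,
                                        n_points = 64))[[1]]$contour

  # translation invariance
  v <- normalize_and_correspond(list(blob, sweep(blob, 2, c(50, -30), `+`)))
  expect_lt(max(abs(v[[1]] - v[[2]])), 1e-9)

  # rotation by 90 degrees is removed up to axis ambiguity
  rot <- blob %*% matrix(c(0, 1, -1, 0), 2, 2)
  v <- normalize_and_correspond(list(blob, rot))
  expect_lt(sum((v[[1]] - v[[2]])^2), 1e-6 * polygon_perimeter(blob)^2)

  # cyclic shift recovery (the brute-force search covers all N shifts)
  sh <- blob[c(33:64, 1:32), ]
  v <- normalize_and_correspond(list(blob, sh))
  expect_lt(max(abs(v[[1]] - v[[2]])), 1e-9)

  expect_error(normalize_and_correspond(list(blob[1:32, ], blob)), "mismatch")
  line <- cbind(seq_len(16), 2 * seq_len(16) + 1)
  expect_error(normalize_and_correspond(list(line, line)), "degenerate")
})

test_that("PCA fit recovers structure of the training set", {
  set.seed(4)
  # rank-1 family: mean + t * d has exactly one nonzero eigenvalue along d
  d <- stats::rnorm(32); d <- d / sqrt(sum(d^2))
  base <- stats::rnorm(32)
  vecs <- lapply(seq(-2, 2, length.out = 10), function(t) base + t * d)
  mod <- fit_shape_model(vecs, n_modes = 2)
  expect_gt(mod$eigenvalues[1], 1e-6)
  expect_lt(mod$eigenvalues[2] / mod$eigenvalues[1], 1e-12)
  expect_gt(abs(sum(mod$modes[, 1] * d)), 1 - 1e-9)

  # identical shapes: zero variance, mean equals the shape
  same <- replicate(5, base, simplify = FALSE)
  mod0 <- fit_shape_model(same, n_modes = 1)
  expect_lt(mod0$eigenvalues[1], 1e-20)
  expect_equal(mod0$mean_shape, base)

  # full-rank reconstruction of random training shapes
  vecs <- lapply(1:20, function(i) stats::rnorm(40))
  modf <- fit_shape_model(vecs, n_modes = 19)
  X <- do.call(rbind, vecs)
  recon <- sweep(sweep(X, 2, modf$mean_shape) %*% modf$modes %*% t(modf$modes),
                 2, modf$mean_shape, `+`)
  expect_lt(mean(abs(recon - X)), 1e-8)

  expect_error(fit_shape_model(vecs, n_modes = 20), "n_modes")
  expect_error(fit_shape_model(vecs, n_modes = 0), "n_modes")
})

test_that("model invariants: orthonormal modes, sorted eigenvalues, rigid invariance", {
  masks <- lapply(c(10, 11, 12, 13, 12, 11), mk_disk_mask)
  pool <- generate_patches(fixture_spec("blob", c(10, 14), "uniform",
                                        n_patches = 10, rng_seed = 5,
                                        n_points = 64))
  contours <- lapply(pool, `[[`, "contour")
  mod <- fit_shape_model(normalize_and_correspond(contours), n_modes = 5)
  expect_lt(max(abs(crossprod(mod$modes) - diag(5))), 1e-9)
  expect_true(all(diff(mod$eigenvalues) <= 1e-12))
  expect_true(all(mod$eigenvalues >= 0))

  # rigidly transformed training set yields the same eigenvalues
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
  moved <- lapply(contours, function(p) sweep(p %*% R, 2, c(17, -4), `+`))
  mod2 <- fit_shape_model(normalize_and_correspond(moved), n_modes = 5)
  expect_lt(max(abs(mod2$eigenvalues - mod$eigenvalues) /
                pmax(mod$eigenvalues, 1e-12)), 1e-6)
})

test_that("generate_shape is reproducible and honors the size constraint", {
  mod <- shared_shape_model()
  s1 <- generate_shape(mod, rng_seed = 42)
  s2 <- generate_shape(mod, rng_seed = 42)
  expect_identical(s1, s2)
  expect_true(is_simple_polygon(s1$contour))

  # degenerate model (zero variance): generated shape equals the mean shape
  base <- as.numeric(t(sample_contour(mk_disk_mask(12), 32)))
  mod0 <- fit_shape_model(replicate(4, base, simplify = FALSE), n_modes = 1,
                          r_min = 0)
  g <- generate_shape(mod0, rng_seed = 1)
  expect_lt(max(abs(as.numeric(t(g$contour)) - base)), 1e-9)

  # Monte-Carlo parameter recovery: circles of radii 15..25
  masks <- lapply(seq(15, 25, length.out = 20), mk_disk_mask)
  circ <- train_shape_model(masks, n_points = 48, r_min = 5)
  train_radius <- mean(vapply(masks, function(m)
    fluosim:::mean_contour_radius(sample_contour(m, 48)), 0))
  set.seed(99)
  radii <- replicate(2000, fluosim:::mean_contour_radius(
    generate_shape(circ)$contour))
  se <- stats::sd(radii) / sqrt(length(radii))
  expect_lt(abs(mean(radii) - train_radius), 3 * se + 1e-9)
  expect_true(all(radii >= 5))

  # an unsatisfiable constraint is reported
  tiny <- circ; tiny$r_min <- 100
  expect_error(generate_shape(tiny, rng_seed = 1), "incompatible")
})

test_that("shape model JSON persistence round-trips", {
  mod <- shared_shape_model()
  path <- tempfile(fileext = ".json")
  write_shape_model(mod, path)
  back <- read_shape_model(path)
  expect_equal(back$mean_shape, mod$mean_shape)
  expect_equal(back$eigenvalues, mod$eigenvalues)
  expect_equal(unname(back$modes), unname(mod$modes))
  expect_equal(generate_shape(back, rng_seed = 3)$contour,
               generate_shape(mod, rng_seed = 3)$contour, tolerance = 1e-12)
  unlink(path)
})
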