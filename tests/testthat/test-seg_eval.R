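make_two_disk_scene <- function(touching = FALSE) {
  dm <- mk_disk_mask(12) * 150
  sc <- matrix(0, 80, 80)
  if (touching) {
    sc[28:58, 8:38] <- sc[28:58, 8:38] + dm
    sc[28:58, 31:61] <- pmax(sc[28:58, 31:61], dm)
    gt <- list(list(mask = (dm > 0) + 0, offset = c(7, 27)),
               list(mask = (dm > 0) + 0, offset = c(30, 27)))
  } else {
    sc[10:40, 8:38] <- sc[10:40, 8:38] + dm
    sc[30:60, 36:66] <- sc[30:60, 36:66] + dm
    gt <- list(list(mask = (dm > 0) + 0, offset = c(7, 9)),
               list(mask = (dm > 0) + 0, offset = c(35, 29)))
  }
  list(image = sc, gt_cells = gt)
}

test_that("seg_params validates its invariants", {
  expect_error(seg_params(sigma_low = 4, sigma_high = 2), "sigma_high")
  expect_error(seg_params(k = 1), "k must")
  expect_error(seg_params(w = 1.2), "w must")
  expect_error(seg_params(a_min = 0), "a_min")
  expect_error(segment(matrix(0, 10, 10),
                       seg_params(mode = "seeded")), "seed")
})

test_that("segmentation recovers well-separated and touching disks", {
  expect_warning(blank <- segment(matrix(0, 60, 60), seg_params()),
                 "no foreground")
  expect_equal(max(blank), 0)
  d <- make_two_disk_scene()
  lab <- segment(d$image, seg_params(1, 6, 2, 0.3, 2, 30))
  expect_equal(max(lab), 2)
  # each disk recovered with Jaccard > 0.9 against its ground truth
  sets <- fluosim:::gt_pixel_sets(d$gt_cells, dim(lab))
  for (l in 1:2) {
    p <- which(lab == l)
    best <- max(vapply(sets, function(g)
      length(intersect(p, g)) / length(union(p, g)), 0))
    expect_gt(best, 0.9)
  }
  # determinism
  expect_identical(lab, segment(d$image, seg_params(1, 6, 2, 0.3, 2, 30)))

  # hybrid watershed splits the touching pair at the neck
  dt <- make_two_disk_scene(touching = TRUE)
  labt <- segment(dt$image, seg_params(1, 10, 2, 0.3, 2, 30))
  expect_equal(max(labt), 2)

  # seeded mode with ground-truth centroids
  seeds <- rbind(c(23, 25), c(51, 45))
  labs <- segment(d$image, seg_params(1, 6, 2, 0.3, 2, 30, mode = "seeded"),
                  seeds = seeds)
  expect_equal(max(labs), 2)
  expect_gt(combined_jaccard(labs, d$gt_cells), 0.9)
})

test_that("combined Jaccard matches, penalizes merges, detects identity", {
  d <- make_two_disk_scene()
  # perfect segmentation: build labels from the ground truth itself
  lab <- matrix(0L, 80, 80)
  sets <- fluosim:::gt_pixel_sets(d$gt_cells, c(80, 80))
  lab[sets[[1]]] <- 1L; lab[sets[[2]]] <- 2L
  expect_equal(combined_jaccard(lab, d$gt_cells), 1)
  # relabeling does not change the score
  lab2 <- lab; lab2[lab == 1] <- 2L; lab2[lab == 2] <- 1L
  expect_equal(combined_jaccard(lab2, d$gt_cells), 1)

  expect_equal(combined_jaccard(matrix(0L, 80, 80), d$gt_cells), 0)
  expect_error(combined_jaccard(lab, list()), "no ground-truth")

  # merging two equal disjoint cells into their union: 0.5 / 2 = 0.25
  merged <- matrix(0L, 80, 80)
  merged[c(sets[[1]], sets[[2]])] <- 1L
  expect_equal(combined_jaccard(merged, d$gt_cells), 0.25)
})

test_that("coordinate descent finds the grid optimum of a toy objective", {
  # separable concave surface with its peak inside the grids
  toy <- function(p) -((p$sigma_low - 2)^2) - ((p$w - 0.6)^2) - ((p$k - 3)^2)
  grids <- list(sigma_low = seq(0.5, 4, 0.5), w = seq(0, 1, 0.2), k = 2:4)
  opt <- optimize_params(NULL, seg_params(sigma_low = 1, sigma_high = 8, w = 0),
                         grids, objective = toy)
  # exhaustive oracle over the full grid
  best <- -Inf
  for (sl in grids$sigma_low) for (w in grids$w) for (k in grids$k)
    best <- max(best, toy(list(sigma_low = sl, w = w, k = k)))
  expect_equal(opt$score, best)
  expect_equal(opt$params$sigma_low, 2)
  expect_equal(opt$params$w, 0.6)
  expect_equal(opt$params$k, 3L)

  # a grid-wise local max returns the initial parameters after one cycle
  opt2 <- optimize_params(NULL, opt$params, grids, objective = toy)
  expect_equal(max(opt2$trace$cycle), 1L)
  expect_equal(opt2$params$sigma_low, 2)

  expect_error(optimize_params(NULL, seg_params(), list(), objective = toy),
               "empty grid")
})

test_that("the optimizer never regresses and learns to reject specks", {
  # images with 12 px disks plus sub-10 px noise specks
  mk <- function(seed) {
    set.seed(seed)
    img <- matrix(0, 90, 90)
    dm <- mk_disk_mask(10) * 140
    img[5:31, 5:31] <- img[5:31, 5:31] + dm
    img[55:81, 50:76] <- img[55:81, 50:76] + dm
    for (s in 1:6) {
      y <- sample(85, 1); x <- sample(85, 1)
      img[y:(y + 1), x:(x + 1)] <- 160  # 4 px specks
    }
    gt <- list(list(mask = (dm > 0) + 0, offset = c(4, 4)),
               list(mask = (dm > 0) + 0, offset = c(49, 54)))
    list(image = img, gt_cells = gt)
  }
  ds <- list(mk(1), mk(2))
  init <- seg_params(1, 6, 2, 0.3, 2, a_min = 2)
  grids <- list(a_min = c(2, 5, 20, 60))
  base <- fluosim:::seg_objective(ds, init)
  opt <- optimize_params(ds, init, grids)
  expect_gte(opt$score, base)
  expect_gte(opt$params$a_min, 20)
})

test_that("cross-validation partitions correctly and scores homogeneously", {
  d <- make_two_disk_scene()
  ds <- rep(list(d), 9)
  grids <- list(sigma_high = c(4, 6), w = c(0.2, 0.4))
  cv <- cross_validated_score(ds, folds = 3, initial = seg_params(1, 6, 2, 0.3, 2, 30),
                              grids = grids, seed = 2, max_cycles = 1)
  expect_length(cv$fold_scores, 3)
  expect_equal(as.vector(table(cv$assignment)), c(3, 3, 3))
  # identical images: identical per-fold scores
  expect_lt(diff(range(cv$fold_scores)), 1e-12)
  expect_true(all(cv$per_image > 0))
  expect_error(cross_validated_score(ds[1:2], folds = 3), "fewer images")
})
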