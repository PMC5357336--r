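# Reference segmentation harness: DoG band-pass conditioning, k-means
# figure-ground separation, marker-based watershed cell separation (hybrid
# markers from distance-transform maxima, or external seed points), scored
# with the combined Jaccard metric, with coordinate-descent parameter
# optimization and k-fold cross-validated evaluation.

#' Segmentation pipeline parameters
#'
#' @param sigma_low,sigma_high DoG scales in pixels (`sigma_high > sigma_low > 0`).
#' @param k Cluster count for the figure-ground k-means (>= 2).
#' @param w Weight of edge strength against the inverted distance transform
#'   in the watershed relief, in `[0, 1]`.
#' @param sigma_ws Scale of the derivative-of-Gaussian edge filter (pixels).
#' @param a_min Minimum cell area in pixels.
#' @param mode `"hybrid"` (markers from distance-transform maxima) or
#'   `"seeded"` (markers from supplied seed points, e.g. nuclei positions).
#' @param fg_clusters Number of brightest k-means clusters taken as
#'   foreground.
#' @export
seg_params <- function(sigma_low = 1, sigma_high = 4, k = 3L, w = 0.5,
                       sigma_ws = 2, a_min = 30L,
                       mode = c("hybrid", "seeded"), fg_clusters = 1L) {
  mode <- match.arg(mode)
  if (!(sigma_high > sigma_low && sigma_low > 0))
    stop("need sigma_high > sigma_low > 0")
  if (k < 2) stop("k must be >= 2")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (a_min < 1) stop("a_min must be >= 1")
  structure(list(sigma_low = sigma_low, sigma_high = sigma_high,
                 k = as.integer(k), w = w, sigma_ws = sigma_ws,
                 a_min = as.integer(a_min), mode = mode,
                 fg_clusters = as.integer(fg_clusters)),
            class = "seg_params")
}

# Deterministic 1-D k-means on pixel values: quantile-seeded centers.
kmeans_fg <- function(values, k, fg_clusters) {
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = k), names = FALSE)
  if (length(unique(qs)) < k) {
    # degenerate intensity distribution: threshold at the midpoint
    return(values > (max(values) + min(values)) / 2)
  }
  km <- suppressWarnings(stats::kmeans(values, centers = matrix(qs), iter.max = 100))
  fg_ids <- order(km$centers, decreasing = TRUE)[seq_len(fg_clusters)]
  km$cluster %in% fg_ids
}

#' Segment a fluorescence micrograph
#'
#' DoG band-pass, k-means figure-ground separation on the filtered
#' intensity, then marker-based watershed on a relief mixing edge strength
#' and the inverted distance transform; components below `a_min` pixels are
#' removed.  Deterministic (the k-means is quantile-seeded).
#'
#' @param image Grayscale matrix (row = y).
#' @param params A [seg_params()].
#' @param seeds Optional n x 2 matrix of (x, y) seed points, required for
#'   `mode = "seeded"`.
#' @param ws_tolerance Watershed merging tolerance on the unit-scaled relief.
#' @return Integer label matrix (0 = background).
#' @export
segment <- function(image, params, seeds = NULL, ws_tolerance = 0.1) {
  if (params$mode == "seeded" && is.null(seeds))
    stop("seeded mode requires seed points")
  ximg <- t(image)  # EBImage frame: [x, y]
  dog <- EBImage::gblur(ximg, sigma = params$sigma_low) -
         EBImage::gblur(ximg, sigma = params$sigma_high)
  fg_vec <- kmeans_fg(as.vector(dog), params$k, params$fg_clusters)
  if (!any(fg_vec)) {
    warning("no foreground pixels")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  fg <- matrix(as.integer(fg_vec), nrow(ximg), ncol(ximg))

  dist <- EBImage::distmap(fg)
  sm <- EBImage::gblur(ximg, sigma = params$sigma_ws)
  gx <- sm; gy <- sm
  gx[] <- 0; gy[] <- 0
  n1 <- nrow(sm); n2 <- ncol(sm)
  gx[2:(n1 - 1), ] <- (sm[3:n1, ] - sm[1:(n1 - 2), ]) / 2
  gy[, 2:(n2 - 1)] <- (sm[, 3:n2] - sm[, 1:(n2 - 2)]) / 2
  edge <- sqrt(gx^2 + gy^2)
  ndist <- if (max(dist) > 0) dist / max(dist) else dist
  nedge <- if (max(edge) > 0) edge / max(edge) else edge
  relief <- ((1 - params$w) * ndist + params$w * (1 - nedge)) * fg

  if (params$mode == "hybrid") {
    labels <- EBImage::watershed(relief, tolerance = ws_tolerance, ext = 1)
  } else {
    seed_img <- matrix(0L, nrow(ximg), ncol(ximg))
    sx <- pmin(pmax(round(seeds[, 1]), 1), nrow(ximg))
    sy <- pmin(pmax(round(seeds[, 2]), 1), ncol(ximg))
    fg_idx <- which(fg > 0, arr.ind = TRUE)
    for (s in seq_len(nrow(seeds))) {
      if (fg[sx[s], sy[s]] == 0) {
        # snap a seed landing outside the foreground to the nearest fg pixel
        nn <- which.min((fg_idx[, 1] - sx[s])^2 + (fg_idx[, 2] - sy[s])^2)
        sx[s] <- fg_idx[nn, 1]; sy[s] <- fg_idx[nn, 2]
      }
      seed_img[sx[s], sy[s]] <- s
    }
    labels <- EBImage::propagate(ximg, seeds = seed_img, mask = fg > 0)
  }
  lab <- as.matrix(labels)
  sizes <- tabulate(lab)
  drop <- which(sizes < params$a_min)
  lab[lab %in% drop] <- 0L
  kept <- sort(unique(lab[lab > 0]))
  relab <- integer(max(c(kept, 0L)) + 1L)
  relab[kept + 1L] <- seq_along(kept)
  lab[lab > 0] <- relab[lab[lab > 0] + 1L]
  t(lab)
}

# Full-frame pixel index sets of ground-truth cells (lists with mask/offset
# or full-frame matrices).
gt_pixel_sets <- function(gt_cells, dim_img) {
  H <- dim_img[1]; W <- dim_img[2]
  lapply(gt_cells, function(cc) {
    if (is.matrix(cc)) return(which(cc > 0))
    m <- cc$mask; off <- cc$offset
    idx <- which(m > 0, arr.ind = TRUE)
    (off[1] + idx[, 2] - 1) * H + (off[2] + idx[, 1])
  })
}

#' Combined Jaccard score of a predicted labeling
#'
#' Predicted and ground-truth cells are matched one-to-one greedily by
#' descending pairwise Jaccard; the score is the sum of matched Jaccard
#' indices divided by `max(n_pred, n_gt)`, so both false splits and false
#' merges are penalized.  Equals 1 exactly when the labelings are
#' pixel-identical up to relabeling.
#'
#' @param pred_labels Integer label matrix (0 = background).
#' @param gt_cells List of ground-truth cell masks (full-frame matrices or
#'   entries with `mask` and `offset`).
#' @return Score in `[0, 1]`.
#' @export
combined_jaccard <- function(pred_labels, gt_cells) {
  if (!length(gt_cells)) stop("no ground-truth cells")
  gt_sets <- gt_pixel_sets(gt_cells, dim(pred_labels))
  n_gt <- length(gt_sets)
  labs <- sort(unique(pred_labels[pred_labels > 0]))
  n_pred <- length(labs)
  if (n_pred == 0) return(0)
  pred_sets <- lapply(labs, function(l) which(pred_labels == l))
  J <- matrix(0, n_pred, n_gt)
  for (i in seq_len(n_pred)) for (j in seq_len(n_gt)) {
    inter <- length(intersect(pred_sets[[i]], gt_sets[[j]]))
    if (inter > 0)
      J[i, j] <- inter / (length(pred_sets[[i]]) + length(gt_sets[[j]]) - inter)
  }
  total <- 0
  Jm <- J
  for (m in seq_len(min(n_pred, n_gt))) {
    best <- which.max(Jm)
    if (Jm[best] <= 0) break
    i <- (best - 1) %% n_pred + 1; j <- (best - 1) %/% n_pred + 1
    total <- total + Jm[best]
    Jm[i, ] <- -1; Jm[, j] <- -1
  }
  total / max(n_pred, n_gt)
}

#' Default coordinate-descent parameter grids
#' @export
default_seg_grids <- function() list(
  sigma_low = seq(0.5, 8, by = 0.5),
  sigma_high = seq(0.5, 8, by = 0.5),
  k = 2:4,
  w = seq(0, 1, by = 0.1),
  sigma_ws = seq(0.5, 4, by = 0.5),
  a_min = unique(round(exp(seq(log(10), log(500), length.out = 10))))
)

# Mean combined Jaccard of a parameter set over a dataset (list of
# list(image, gt_cells, seeds)).
seg_objective <- function(dataset, params, ws_tolerance = 0.1) {
  mean(vapply(dataset, function(d) {
    lab <- segment(d$image, params, seeds = d$seeds, ws_tolerance = ws_tolerance)
    combined_jaccard(lab, d$gt_cells)
  }, 0))
}

#' Optimize segmentation parameters by coordinate descent
#'
#' Cyclic coordinate descent: each parameter in turn is swept over its grid
#' with the others held fixed and set to the grid argmax of the mean
#' combined Jaccard; cycles repeat until no cycle improves the score by more
#' than `tol`.  Candidates violating `sigma_high > sigma_low` are skipped.
#' The returned parameters never score below the initial ones.
#'
#' @param dataset List of `list(image, gt_cells, seeds = NULL)` entries
#'   (>= 2 with ground truth), e.g. from [seg_dataset()].
#' @param initial Starting [seg_params()].
#' @param grids Named list of candidate grids (see [default_seg_grids()]).
#' @param tol Minimum per-cycle improvement to continue.
#' @param max_cycles Hard cycle cap.
#' @param objective Optional replacement objective `function(params)`
#'   returning a score to maximize (used for optimizer verification);
#'   defaults to the mean combined Jaccard over `dataset`.
#' @return List with `params`, `score`, and the optimization `trace`.
#' @export
optimize_params <- function(dataset, initial = seg_params(),
                            grids = default_seg_grids(), tol = 1e-4,
                            max_cycles = 5L, objective = NULL) {
  if (is.null(objective) && length(dataset) < 2)
    stop("need at least 2 images with ground truth")
  if (!length(grids) || !all(lengths(grids) > 0)) stop("empty grid")
  if (is.null(objective)) objective <- function(p) seg_objective(dataset, p)
  cache <- new.env(parent = emptyenv())
  eval_p <- function(p) {
    key <- paste(p$sigma_low, p$sigma_high, p$k, p$w, p$sigma_ws, p$a_min,
                 p$mode, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- objective(p)
    cache[[key]] <- v
    v
  }
  cur <- initial
  cur_score <- eval_p(cur)
  trace <- list(data.frame(cycle = 0L, param = "init", value = NA_real_,
                           score = cur_score))
  for (cycle in seq_len(max_cycles)) {
    start_score <- cur_score
    for (pn in names(grids)) {
      for (val in grids[[pn]]) {
        cand <- cur
        cand[[pn]] <- if (pn %in% c("k", "a_min")) as.integer(val) else val
        if (!(cand$sigma_high > cand$sigma_low)) next
        sc <- eval_p(cand)
        if (sc > cur_score) { cur <- cand; cur_score <- sc }
      }
      trace[[length(trace) + 1]] <-
        data.frame(cycle = cycle, param = pn, value = as.numeric(cur[[pn]]),
                   score = cur_score)
    }
    if (cur_score - start_score <= tol) break
  }
  list(params = cur, score = cur_score, trace = do.call(rbind, trace))
}

#' Cross-validated segmentation score
#'
#' Images are split into `folds` seeded partitions of near-equal size; for
#' each fold the parameters are optimized on the training split and the
#' held-out split is scored, so every image is tested exactly once.
#'
#' @inheritParams optimize_params
#' @param folds Number of folds.
#' @param seed Seed for the partition.
#' @return List with `mean_score`, `fold_scores`, `per_image` (score of each
#'   image in its test fold), and `fold_params`.
#' @export
cross_validated_score <- function(dataset, folds = 3L, initial = seg_params(),
                                  grids = default_seg_grids(), seed = 1L,
                                  tol = 1e-4, max_cycles = 5L) {
  n <- length(dataset)
  if (n < folds) stop("fewer images than folds")
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(folds), n))
  fold_scores <- numeric(folds)
  per_image <- numeric(n)
  fold_params <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- dataset[assignment != f]
    test_idx <- which(assignment == f)
    opt <- optimize_params(train, initial, grids, tol = tol,
                           max_cycles = max_cycles)
    fold_params[[f]] <- opt$params
    sc <- vapply(test_idx, function(i) {
      d <- dataset[[i]]
      combined_jaccard(segment(d$image, opt$params, seeds = d$seeds),
                       d$gt_cells)
    }, 0)
    per_image[test_idx] <- sc
    fold_scores[f] <- mean(sc)
  }
  list(mean_score = mean(fold_scores), fold_scores = fold_scores,
       per_image = per_image, fold_params = fold_params,
       assignment = assignment)
}

#' Convert simulated scenes into a segmentation evaluation dataset
#'
#' @param scenes A `simulated_dataset` or list of `simulated_scene`s.
#' @param with_seeds Attach ground-truth cell centroids as seed points (the
#'   stand-in for a nuclei seed channel in seeded-watershed mode).
#' @export
seg_dataset <- function(scenes, with_seeds = FALSE) {
  if (inherits(scenes, "simulated_dataset")) scenes <- scenes$scenes
  lapply(scenes, function(s) {
    seeds <- NULL
    if (with_seeds) {
      seeds <- do.call(rbind, lapply(s$cells, function(cc) {
        idx <- which(cc$mask > 0, arr.ind = TRUE)
        c(cc$offset[1] + mean(idx[, 2]), cc$offset[2] + mean(idx[, 1]))
      }))
    }
    list(image = s$image, gt_cells = s$cells, seeds = seeds)
  })
}
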