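# Objective image measurements: mean in-cell intensity and the summed mean
# difference (SMD) edge/texture proxy,
#   SMD = (1/N_C) * sum_c (1/N_c) * sum_{p in c} |I(p) - A_c|,
# with A_c the mean intensity of cell c.  Cells are weighted equally
# regardless of size, and a pixel covered by two cells contributes to both.

# Pixel values of one cell: accepts a full-frame mask matrix or a ground
# truth entry list(mask, offset).
cell_pixel_values <- function(image, cell) {
  if (is.matrix(cell)) {
    if (!all(dim(cell) == dim(image))) stop("mask extent mismatch")
    v <- image[cell > 0]
  } else {
    m <- cell$mask; off <- cell$offset
    ys <- (off[2] + 1):(off[2] + nrow(m)); xs <- (off[1] + 1):(off[1] + ncol(m))
    sub <- image[ys, xs, drop = FALSE]
    v <- sub[m > 0]
  }
  if (!length(v)) stop("empty cell mask")
  v
}

#' Mean in-cell intensity
#'
#' Mean over cells of the mean intensity inside each cell's mask; every cell
#' counts equally regardless of its size.
#'
#' @param image Grayscale matrix.
#' @param cell_masks List of cell masks (full-frame matrices or ground truth
#'   entries with `mask` and `offset`).
#' @export
mean_cell_intensity <- function(image, cell_masks) {
  if (!length(cell_masks)) stop("no cell masks")
  mean(vapply(cell_masks, function(cc) mean(cell_pixel_values(image, cc)), 0))
}

#' Summed mean difference (SMD)
#'
#' Per-cell mean absolute deviation of pixel intensities from the cell's own
#' mean, averaged over cells.
#'
#' @inheritParams mean_cell_intensity
#' @export
smd <- function(image, cell_masks) {
  if (!length(cell_masks)) stop("no cell masks")
  mean(vapply(cell_masks, function(cc) {
    v <- cell_pixel_values(image, cc)
    mean(abs(v - mean(v)))
  }, 0))
}

#' Per-image and dataset-level metrics report
#'
#' @param scenes A `simulated_dataset`, or a list of `simulated_scene`s, or
#'   a list of `list(image =, cells =)` pairs.
#' @return Object of class `metrics_report`: data frame `per_image` with
#'   `mean_cell_intensity` and `smd`, plus `dataset_mean` and
#'   `n_cells_total`.
#' @export
summarize_dataset <- function(scenes) {
  if (inherits(scenes, "simulated_dataset")) scenes <- scenes$scenes
  if (!length(scenes)) stop("no scenes supplied")
  rows <- lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    data.frame(image = i, n_cells = length(s$cells),
               mean_cell_intensity = mean_cell_intensity(s$image, s$cells),
               smd = smd(s$image, s$cells))
  })
  per_image <- do.call(rbind, rows)
  structure(list(
    per_image = per_image,
    dataset_mean = c(mean_cell_intensity = mean(per_image$mean_cell_intensity),
                     smd = mean(per_image$smd)),
    n_cells_total = sum(per_image$n_cells)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics over", nrow(x$per_image), "images,", x$n_cells_total, "cells:\n")
  cat(sprintf("  mean cell intensity: %.2f\n", x$dataset_mean["mean_cell_intensity"]))
  cat(sprintf("  SMD:                 %.2f\n", x$dataset_mean["smd"]))
  invisible(x)
}

#' Metrics table over an overlap series
#'
#' One row per metric, one column per overlap degree (the layout of the
#' intensity/SMD comparison tables).
#'
#' @param series Named list of datasets as from [simulate_overlap_series()].
#' @return Data frame with columns `metric` and one column per degree.
#' @export
series_table <- function(series) {
  reps <- lapply(series, summarize_dataset)
  out <- data.frame(metric = c("mean_cell_intensity", "smd"))
  for (d in names(series))
    out[[d]] <- c(reps[[d]]$dataset_mean["mean_cell_intensity"],
                  reps[[d]]$dataset_mean["smd"])
  out
}
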