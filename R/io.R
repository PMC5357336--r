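# Dataset readers/writers.  Layout per dataset directory:
#   img_0001.tif         grayscale intensity (8/16 bit)
#   img_0001_labels.tif  instance label map (16 bit; 32-bit float on demand)
#   img_0001_gt.json     per-cell ground truth sidecar (masks RLE-encoded)
#   manifest.json        files, seeds, config, format version

FORMAT_VERSION <- 1L

mask_to_rle <- function(mask) {
  r <- rle(as.integer(as.vector(mask > 0)))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

rle_to_mask <- function(obj) {
  v <- inverse.rle(structure(list(lengths = as.integer(obj$lengths),
                                  values = as.integer(obj$values)),
                             class = "rle"))
  matrix(v, obj$dim[1], obj$dim[2])
}

write_gray_tiff <- function(img, path, bits) {
  maxval <- 2^bits - 1
  tiff::writeTIFF(img / maxval, path, bits.per.sample = bits)
  invisible(path)
}

read_gray_tiff <- function(path, bits) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * (2^bits - 1))
}

#' Write a simulated dataset to a directory
#'
#' @param dataset A `simulated_dataset` (or list of scenes).
#' @param dir Output directory (created if needed).
#' @param label_bits 16 (default) or 32; label maps with more than 65535
#'   cells require 32.
#' @export
write_dataset <- function(dataset, dir, label_bits = 16L) {
  scenes <- if (inherits(dataset, "simulated_dataset")) dataset$scenes else dataset
  manifest <- if (inherits(dataset, "simulated_dataset")) dataset$manifest else list()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    s <- scenes[[i]]
    stem <- sprintf("img_%04d", i)
    bit <- s$config$bit_depth
    max_label <- max(s$label_map)
    if (label_bits == 16L && max_label > 65535)
      stop("label overflow: ", max_label,
           " labels exceed 16-bit capacity; use label_bits = 32")
    write_gray_tiff(s$image, file.path(dir, paste0(stem, ".tif")), bit)
    if (label_bits == 16L) {
      write_gray_tiff(s$label_map, file.path(dir, paste0(stem, "_labels.tif")), 16L)
    } else {
      tiff::writeTIFF(s$label_map / 2^31, file.path(dir, paste0(stem, "_labels.tif")),
                      bits.per.sample = 32)
    }
    gt <- list(
      format_version = FORMAT_VERSION,
      bit_depth = bit,
      image_size = c(ncol(s$image), nrow(s$image)),
      clipped_frac = s$clipped_frac,
      cells = lapply(s$cells, function(cc) list(
        id = cc$id, cluster = cc$cluster, offset = cc$offset,
        source_id = cc$source_id, contour = cc$contour,
        mask_rle = mask_to_rle(cc$mask)))
    )
    jsonlite::write_json(gt, file.path(dir, paste0(stem, "_gt.json")),
                         digits = NA, auto_unbox = TRUE)
    files[[i]] <- list(stem = stem, n_cells = length(s$cells))
  }
  manifest$format_version <- FORMAT_VERSION
  manifest$label_bits <- label_bits
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `simulated_dataset` with images, label maps and per-cell ground
#'   truth reconstructed bit-exactly.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing file: ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (is.null(manifest$format_version) ||
      manifest$format_version > FORMAT_VERSION)
    stop("unknown format version in ", mpath)
  label_bits <- manifest$label_bits %||% 16L
  scenes <- lapply(manifest$files, function(f) {
    stem <- f$stem
    gpath <- file.path(dir, paste0(stem, "_gt.json"))
    if (!file.exists(gpath)) stop("missing file: ", gpath)
    gt <- jsonlite::read_json(gpath, simplifyVector = FALSE)
    bit <- as.integer(gt$bit_depth)
    img <- read_gray_tiff(file.path(dir, paste0(stem, ".tif")), bit)
    lab <- if (label_bits == 16L) {
      read_gray_tiff(file.path(dir, paste0(stem, "_labels.tif")), 16L)
    } else {
      round(tiff::readTIFF(file.path(dir, paste0(stem, "_labels.tif"))) * 2^31)
    }
    sz <- unlist(gt$image_size)
    if (ncol(img) != sz[1] || nrow(img) != sz[2])
      stop("extent mismatch in ", file.path(dir, paste0(stem, ".tif")))
    cells <- lapply(gt$cells, function(cc) {
      rle_obj <- list(dim = unlist(cc$mask_rle$dim),
                      lengths = unlist(cc$mask_rle$lengths),
                      values = unlist(cc$mask_rle$values))
      list(id = cc$id, cluster = cc$cluster,
           offset = unlist(cc$offset),
           mask = rle_to_mask(rle_obj),
           contour = do.call(rbind, lapply(cc$contour, unlist)),
           source_id = cc$source_id)
    })
    structure(list(image = img, label_map = lab, cells = cells,
                   clipped_frac = gt$clipped_frac,
                   config = list(bit_depth = bit)),
              class = "simulated_scene")
  })
  structure(list(scenes = scenes, manifest = manifest),
            class = "simulated_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metrics report as CSV (and optionally JSON)
#'
#' Decimal points are written with `.` regardless of locale.
#'
#' @param report A `metrics_report`.
#' @param csv_path Output CSV.
#' @param json_path Optional JSON mirror.
#' @export
write_metrics_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(per_image = report$per_image,
                              dataset_mean = as.list(report$dataset_mean),
                              n_cells_total = report$n_cells_total),
                         json_path, digits = NA, auto_unbox = TRUE)
  invisible(csv_path)
}
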