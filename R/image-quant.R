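# Single-cell image quantification pipeline. The measurement principle:
# contrast stretching is used ONLY to prepare the image for segmentation;
# per-cell mean intensities are always extracted from the raw, unadjusted
# image, then expressed as relative intensity (0-100%) by per-image min-max
# scaling.

#' Percentile contrast stretch
#'
#' Rescales an image so values at or below the `p_low` percentile map to 0
#' and values at or above the `p_high` percentile map to 1, linearly in
#' between (percentiles via the shared linear-interpolation convention,
#' [percentile()]). Used only as segmentation input; intensity measurement
#' always reads the raw image.
#'
#' @param image numeric matrix (rows = y, cols = x), non-negative.
#' @param p_low,p_high percentile bounds, `p_low < p_high`; defaults 2 and 98.
#' @return numeric matrix in \[0, 1\]. A constant image yields all zeros with
#'   a warning.
#' @export
contrast_stretch <- function(image, p_low = 2, p_high = 98) {
  stopifnot(is.matrix(image), p_low < p_high)
  lo <- percentile(as.vector(image), p_low)
  hi <- percentile(as.vector(image), p_high)
  if (hi <= lo) {
    warning("contrast_stretch: degenerate image (p_low and p_high percentiles coincide); returning zeros")
    return(matrix(0, nrow = nrow(image), ncol = ncol(image)))
  }
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}

# Internal: summarize a label matrix into an objects table.
# Coordinates are 0-based pixel indices (x = column, y = row).
summarize_labels <- function(label_map) {
  idx <- which(label_map > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(0), area_px = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      bbox_x0 = numeric(0), bbox_y0 = numeric(0),
                      bbox_x1 = numeric(0), bbox_y1 = numeric(0)))
  }
  lab <- label_map[idx]
  nr <- nrow(label_map)
  row0 <- (idx - 1) %% nr          # 0-based y
  col0 <- (idx - 1) %/% nr         # 0-based x
  labs <- sort(unique(lab))
  f <- factor(lab, levels = labs)
  data.frame(label = as.integer(labs),
             area_px = as.numeric(tabulate(f)),
             centroid_x = as.numeric(tapply(col0, f, mean)),
             centroid_y = as.numeric(tapply(row0, f, mean)),
             bbox_x0 = as.numeric(tapply(col0, f, min)),
             bbox_y0 = as.numeric(tapply(row0, f, min)),
             bbox_x1 = as.numeric(tapply(col0, f, max)),
             bbox_y1 = as.numeric(tapply(row0, f, max)),
             row.names = NULL)
}

new_segmentation <- function(label_map, objects = summarize_labels(label_map),
                             removed = NULL) {
  structure(list(label_map = label_map, objects = objects, removed = removed),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d object(s) on a %dx%d field\n",
              nrow(x$objects), ncol(x$label_map), nrow(x$label_map)))
  invisible(x)
}

#' Segment cells in a contrast-stretched image
#'
#' Default classical method: Gaussian smoothing, global Otsu threshold,
#' Euclidean distance transform, and peak-seeded watershed (all via EBImage).
#' `method` is an adapter seam: any function taking the stretched image and
#' returning an integer label matrix of the same shape (0 = background)
#' conforms to the contract, so an external segmenter such as a pretrained
#' star-convex deep-learning model can be plugged in without changing the
#' rest of the pipeline; no such model is required by this package.
#'
#' @param stretched numeric matrix in \[0, 1\] (output of
#'   [contrast_stretch()]).
#' @param method `"classical"` (default) or a function
#'   `(matrix) -> integer label matrix`.
#' @param sigma Gaussian smoothing sd in pixels (classical method).
#' @param tolerance,ext watershed parameters (see [EBImage::watershed]).
#' @return a `segmentation` object: `label_map` (integer matrix) and
#'   `objects` (data.frame: label, area_px, centroid_x/y, bounding box;
#'   0-based pixel coordinates).
#' @export
segment_cells <- function(stretched, method = "classical", sigma = 2,
                          tolerance = 1, ext = 1) {
  stopifnot(is.matrix(stretched))
  if (min(stretched) < 0 || max(stretched) > 1) {
    abort_comphet("segment_cells: input must lie in [0, 1]; run contrast_stretch() first")
  }
  if (is.function(method)) {
    lm <- method(stretched)
    stopifnot(is.matrix(lm), all(dim(lm) == dim(stretched)))
    storage.mode(lm) <- "integer"
    return(new_segmentation(lm))
  }
  if (!identical(method, "classical")) {
    abort_comphet(sprintf("segment_cells: unknown method '%s'", method))
  }
  if (diff(range(stretched)) == 0) {       # blank image -> no objects
    return(new_segmentation(matrix(0L, nrow(stretched), ncol(stretched))))
  }
  smooth <- as.matrix(EBImage::gblur(EBImage::as.Image(stretched),
                                     sigma = sigma))
  thr <- EBImage::otsu(EBImage::as.Image(pmin(pmax(smooth, 0), 1)))
  mask <- smooth > thr
  if (!any(mask)) {
    return(new_segmentation(matrix(0L, nrow(stretched), ncol(stretched))))
  }
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  lm <- matrix(as.integer(as.matrix(labels)),
               nrow = nrow(stretched), ncol = ncol(stretched))
  new_segmentation(lm)
}

#' Remove the smallest objects by area
#'
#' Removes exactly `floor(excluded_fraction * N)` objects with the smallest
#' areas (debris and partial detections). Area ties are broken by label
#' order: among equal areas, lower labels are removed first. Removed objects
#' are zeroed from the label map and reported on the `removed` element.
#'
#' @param seg a `segmentation` object.
#' @param excluded_fraction fraction of objects to drop, in \[0, 1);
#'   default 0.03 (smallest 3%).
#' @return a `segmentation` with the retained objects; `seg$removed` holds
#'   the removed objects table.
#' @export
filter_small_objects <- function(seg, excluded_fraction = 0.03) {
  stopifnot(inherits(seg, "segmentation"),
            excluded_fraction >= 0, excluded_fraction < 1)
  n <- nrow(seg$objects)
  n_remove <- floor(excluded_fraction * n)
  if (n == 0 || n_remove == 0) {
    return(new_segmentation(seg$label_map, seg$objects,
                            removed = seg$objects[0, ]))
  }
  ord <- order(seg$objects$area_px, seg$objects$label)
  removed <- seg$objects[ord[seq_len(n_remove)], , drop = FALSE]
  retained <- seg$objects[sort(ord[-seq_len(n_remove)]), , drop = FALSE]
  lm <- seg$label_map
  lm[lm %in% removed$label] <- 0L
  new_segmentation(lm, retained, removed = removed)
}

#' Keep objects inside the central circular region of interest
#'
#' Retains an object iff its centroid lies strictly inside the circle
#' centered at `(width/2, height/2)` with radius
#' `fraction * min(width, height)` (default 0.5, the inscribed circle).
#' For non-square images the radius uses the shorter side so the circle
#' always fits in the frame. The test is applied to centroids after
#' segmentation rather than masking pixels beforehand, so boundary cells
#' are wholly included or excluded and no truncated-cell intensity bias is
#' introduced.
#'
#' @param seg a `segmentation` object.
#' @param width,height image size in pixels.
#' @param fraction radius as a fraction of `min(width, height)`, in (0, 1].
#' @return a `segmentation` with the retained objects; `seg$removed` holds
#'   the objects outside the region.
#' @export
central_roi_filter <- function(seg, width, height, fraction = 0.5) {
  stopifnot(inherits(seg, "segmentation"), fraction > 0, fraction <= 1)
  if (nrow(seg$objects) == 0) {
    return(new_segmentation(seg$label_map, seg$objects,
                            removed = seg$objects[0, ]))
  }
  r <- fraction * min(width, height)
  d2 <- (seg$objects$centroid_x - width / 2)^2 +
        (seg$objects$centroid_y - height / 2)^2
  inside <- d2 < r^2
  removed <- seg$objects[!inside, , drop = FALSE]
  retained <- seg$objects[inside, , drop = FALSE]
  lm <- seg$label_map
  if (nrow(removed) > 0) lm[lm %in% removed$label] <- 0L
  new_segmentation(lm, retained, removed = removed)
}

#' Mean raw intensity per segmented object
#'
#' Means are taken over the raw (unstretched, unadjusted) image under each
#' label, preserving raw signal integrity; the contrast-stretched image is
#' never measured.
#'
#' @param raw numeric matrix, the raw image.
#' @param seg a `segmentation` object with a label map congruent to `raw`.
#' @return `seg$objects` with an added `mean_raw_intensity` column.
#' @export
measure_intensities <- function(raw, seg) {
  stopifnot(inherits(seg, "segmentation"))
  if (!all(dim(raw) == dim(seg$label_map))) {
    abort_comphet("measure_intensities: raw image and label map shapes differ")
  }
  obj <- seg$objects
  if (nrow(obj) == 0) {
    obj$mean_raw_intensity <- numeric(0)
    return(obj)
  }
  idx <- which(seg$label_map > 0)
  lab <- seg$label_map[idx]
  means <- tapply(as.numeric(raw[idx]), factor(lab, levels = obj$label), mean)
  obj$mean_raw_intensity <- as.numeric(means)
  obj
}

#' Per-image min-max normalization to relative intensity
#'
#' Expresses each cell's mean raw intensity as relative intensity on a 0-100%
#' scale within its image: the dimmest cell maps to 0, the brightest to 100,
#' linearly in between. This removes between-image illumination and exposure
#' differences at the cost of making values comparable only within an image.
#'
#' @param records data.frame with a `mean_raw_intensity` column (cells of
#'   one image).
#' @return `records` with an added `relative_intensity` column in \[0, 100\].
#'   If all intensities are equal the column is all zeros, with a warning.
#' @export
normalize_per_image <- function(records) {
  if (nrow(records) == 0) {
    records$relative_intensity <- numeric(0)
    return(records)
  }
  v <- records$mean_raw_intensity
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("normalize_per_image: all intensities equal; relative intensities set to 0")
    records$relative_intensity <- rep(0, nrow(records))
  } else {
    records$relative_intensity <- 100 * (v - rng[1]) / diff(rng)
  }
  records
}

#' Image-quantification configuration
#'
#' @param p_low,p_high contrast-stretch percentiles (default 2/98).
#' @param excluded_fraction smallest-area fraction to drop (default 0.03).
#' @param roi_fraction central-ROI radius fraction (default 0.5).
#' @param segmentation `"classical"` or a segmenter function (see
#'   [segment_cells()]).
#' @param sigma,tolerance,ext classical-segmentation parameters.
#' @return a list of class `quant_config`.
#' @export
quant_config <- function(p_low = 2, p_high = 98, excluded_fraction = 0.03,
                         roi_fraction = 0.5, segmentation = "classical",
                         sigma = 2, tolerance = 1, ext = 1) {
  structure(list(p_low = p_low, p_high = p_high,
                 excluded_fraction = excluded_fraction,
                 roi_fraction = roi_fraction, segmentation = segmentation,
                 sigma = sigma, tolerance = tolerance, ext = ext),
            class = "quant_config")
}

#' Quantify single-cell fluorescence in one image
#'
#' Fixed stage order: contrast stretch (segmentation input only) ->
#' segmentation -> smallest-fraction area filter -> central-ROI centroid
#' filter -> mean raw intensity on the unmodified image -> per-image min-max
#' normalization. The size filter precedes the ROI filter because debris
#' exclusion is a global property of the image while the ROI is purely
#' geometric.
#'
#' @param raw integer/numeric matrix, the raw single-channel image.
#' @param config a [quant_config()].
#' @param source_id identifier recorded on each record.
#' @param strain,timepoint_h sample metadata recorded on each record.
#' @return data.frame of cell records: source_id, strain, timepoint_h,
#'   label, area_px, centroid_x, centroid_y, mean_raw_intensity,
#'   relative_intensity. Empty for a blank image.
#' @export
quantify_image <- function(raw, config = quant_config(), source_id = "image",
                           strain = NA_character_, timepoint_h = NA_real_) {
  stopifnot(is.matrix(raw), inherits(config, "quant_config"))
  if (nrow(raw) < 16 || ncol(raw) < 16) {
    abort_comphet("quantify_image: image must be at least 16x16 pixels")
  }
  stretched <- withCallingHandlers(
    contrast_stretch(raw, config$p_low, config$p_high),
    warning = function(w) invokeRestart("muffleWarning"))
  seg <- segment_cells(stretched, method = config$segmentation,
                       sigma = config$sigma, tolerance = config$tolerance,
                       ext = config$ext)
  seg <- filter_small_objects(seg, config$excluded_fraction)
  seg <- central_roi_filter(seg, width = ncol(raw), height = nrow(raw),
                            fraction = config$roi_fraction)
  obj <- measure_intensities(raw, seg)
  obj <- normalize_per_image(obj)
  if (nrow(obj) == 0) {
    return(data.frame(source_id = character(0), strain = character(0),
                      timepoint_h = numeric(0), label = integer(0),
                      area_px = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), mean_raw_intensity = numeric(0),
                      relative_intensity = numeric(0)))
  }
  data.frame(source_id = source_id, strain = strain, timepoint_h = timepoint_h,
             label = obj$label, area_px = obj$area_px,
             centroid_x = obj$centroid_x, centroid_y = obj$centroid_y,
             mean_raw_intensity = obj$mean_raw_intensity,
             relative_intensity = obj$relative_intensity,
             row.names = NULL)
}
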