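#' Segmentation parameters
#'
#' Tunables of the dual-threshold morphological-reconstruction segmentation.
#' The high threshold (a fraction of the maximal thickness) seeds the
#' thickest central core of each cell; the low threshold (an absolute
#' thickness near the noise floor) delimits the full spatial extent
#' including pseudopodia. When `low_thresh_um` is NULL it is derived per
#' image as background median + 3 MAD of the thickness map.
#'
#' @param high_frac seed threshold as a fraction of the maximum thickness,
#'   in (0, 1) (default 0.5).
#' @param low_thresh_um absolute boundary threshold in micrometres, or NULL
#'   for the automatic robust noise floor.
#' @param min_area_px area-opening size: components smaller than this are
#'   discarded (default 64).
#' @param closing_radius_px disk radius of the final morphological closing
#'   (default 5); 0 disables it.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(high_frac = 0.5, low_thresh_um = NULL,
                                min_area_px = 64, closing_radius_px = 5) {
  stopifnot(high_frac > 0, high_frac < 1, min_area_px >= 1,
            closing_radius_px >= 0)
  structure(list(high_frac = high_frac, low_thresh_um = low_thresh_um,
                 min_area_px = min_area_px,
                 closing_radius_px = closing_radius_px),
            class = "segmentation_params")
}

resolve_low_threshold <- function(thickness, params) {
  params$low_thresh_um %||%
    # floored at machine epsilon so a noise-free map's boundary mask is the
    # support, not the whole raster
    max(stats::median(thickness) + 3 * stats::mad(thickness),
        .Machine$double.eps)
}

#' Dual thresholding of a thickness map
#'
#' Produces the seed mask (`thickness >= high_frac * max`) marking cell
#' cores, and the boundary mask (`thickness >= low_thresh_um`) capturing
#' the full cell extent along with possible background noise. The seed is
#' a subset of the boundary by construction.
#'
#' @param thickness non-negative thickness matrix (micrometres).
#' @param params a [segmentation_params()].
#' @return list with logical matrices `seed` and `boundary`, and the
#'   resolved `low_thresh_um` / `high_thresh_um` values.
#' @export
dual_threshold <- function(thickness, params = segmentation_params()) {
  stopifnot(is.matrix(thickness))
  check_finite(thickness, "thickness map")
  hmax <- max(thickness)
  if (hmax <= 0)
    stop("empty field: the thickness map has no positive values")
  high <- params$high_frac * hmax
  low <- min(resolve_low_threshold(thickness, params), high)
  list(seed = thickness >= high,
       boundary = thickness >= low,
       low_thresh_um = low,
       high_thresh_um = high)
}

#' Morphological reconstruction of the boundary mask from the seed
#'
#' Keeps exactly those 8-connected components of the boundary mask that
#' intersect the seed mask (constrained region growing); boundary
#' components untouched by any seed -- typically noise specks passed by the
#' low threshold -- are discarded.
#'
#' @param seed logical seed mask (cell cores); must be a subset of
#'   `boundary`.
#' @param boundary logical boundary mask (full extent + noise).
#' @return a [cell_mask()].
#' @export
reconstruct_by_dilation <- function(seed, boundary) {
  stopifnot(is.matrix(seed), is.matrix(boundary),
            identical(dim(seed), dim(boundary)))
  if (any(seed & !boundary))
    stop("seed mask must be a subset of the boundary mask")
  lab <- label_components(boundary)
  keep <- sort(unique(lab[seed & lab > 0]))
  cell_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)))
}

#' Clean a segmentation mask
#'
#' Area opening (components below `min_area_px` removed) followed by
#' morphological closing with a disk of `closing_radius_px`, which fills
#' fully enclosed holes smaller than the closing scale and smooths ragged
#' boundaries. Idempotent.
#'
#' @param mask a [cell_mask()] or logical matrix.
#' @param params a [segmentation_params()].
#' @return a [cell_mask()].
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  lab <- label_components(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= params$min_area_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (params$closing_radius_px > 0 && any(m)) {
    brush <- EBImage::makeBrush(2 * params$closing_radius_px + 1, "disc")
    m <- as.matrix(EBImage::closing(m + 0, brush)) > 0.5
  }
  cell_mask(m)
}

#' Cell mask container
#'
#' A boolean segmentation raster with its 8-connected component count and
#' per-component pixel areas.
#'
#' @param mask logical matrix.
#' @return object of class `cell_mask` with elements `mask`,
#'   `n_components`, `areas_px` and the internal label raster `labels`.
#' @export
cell_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  lab <- label_components(mask)
  n <- max(lab)
  structure(
    list(mask = mask,
         n_components = n,
         areas_px = if (n > 0) tabulate(lab[lab > 0], n) else integer(0),
         labels = lab),
    class = "cell_mask"
  )
}

#' @export
print.cell_mask <- function(x, ...) {
  cat("<cell_mask> ", nrow(x$mask), " x ", ncol(x$mask), " px, ",
      x$n_components, " component(s)\n", sep = "")
  if (x$n_components > 0)
    cat("  areas (px): ", paste(x$areas_px, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Segment cells from a thickness map
#'
#' Full segmentation chain: [dual_threshold()], [reconstruct_by_dilation()],
#' [clean_mask()].
#'
#' @inheritParams dual_threshold
#' @return a [cell_mask()], with the resolved thresholds attached as
#'   attribute `thresholds`.
#' @export
segment_cells <- function(thickness, params = segmentation_params()) {
  dt <- dual_threshold(thickness, params)
  cm <- reconstruct_by_dilation(dt$seed, dt$boundary)
  out <- clean_mask(cm, params)
  attr(out, "thresholds") <- list(low_thresh_um = dt$low_thresh_um,
                                  high_thresh_um = dt$high_thresh_um)
  out
}
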