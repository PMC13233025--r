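# Raster IO. The tiff package stores [0,1] data as 32-bit unsigned
# integers, so rasters are written scaled into [0,1] with the affine
# transform recorded in a JSON sidecar (<path>.json) and restored on read.
# A write-read cycle is exact to one part in 2^32 (relative ~2e-10, far
# beyond 32-bit-float precision).

sidecar_path <- function(path) paste0(path, ".json")

write_raster_tiff <- function(x, path, extra = list()) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (min(x) >= 0) {
    # power-of-two scaling is exact in binary floating point, so the only
    # loss is the 32-bit storage quantization itself
    offset <- 0
    scale <- if (max(x) > 0) 2^ceiling(log2(max(x))) else 1
  } else {
    offset <- min(x)
    scale <- max(x) - offset
  }
  v <- if (scale > 0) (x - offset) / scale else x * 0
  tiff::writeTIFF(v, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    c(list(offset = offset, scale = scale), extra),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_raster_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] > 1)
      stop("multi-channel (RGB) TIFF is not a hologram or phase raster: ",
           path)
    x <- x[, , 1]
  }
  sp <- sidecar_path(path)
  meta <- if (file.exists(sp)) jsonlite::read_json(sp) else NULL
  if (!is.null(meta) && !is.null(meta$scale))
    x <- x * meta$scale + meta$offset
  list(data = x, meta = meta)
}

#' Read a hologram from a TIFF file
#'
#' Accepts single-channel 8/16/32-bit integer or 32-bit float TIFFs.
#' Integer data are cast to float with their raw range preserved. TIFFs
#' written by [write_hologram()] carry a JSON sidecar restoring the
#' original intensity scale; a write-read cycle is exact to one part in
#' 2^32 of the intensity range.
#'
#' @param path TIFF file path.
#' @param config an [optical_config()], supplying the pixel calibration.
#' @param timestamp_min optional frame time.
#' @return a [hologram()].
#' @export
read_hologram <- function(path, config, timestamp_min = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  config <- as_optical_config(config)
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3 && dim(raw)[3] > 1)
    stop("multi-channel (RGB) TIFF cannot be interpreted as a hologram: ",
         path)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    r <- read_raster_tiff(path)
    x <- r$data
    ts <- timestamp_min %||%
      (if (!is.null(r$meta$timestamp_min)) r$meta$timestamp_min else NULL)
  } else {
    x <- raw
    if (length(dim(x)) == 3) x <- x[, , 1]
    storage.mode(x) <- "double"
    ts <- timestamp_min
  }
  hologram(x, config, timestamp_min = ts)
}

#' Write a hologram to a 32-bit TIFF (with scale sidecar)
#'
#' @param holo a [hologram()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_hologram <- function(holo, path) {
  stopifnot(inherits(holo, "hologram"))
  extra <- list(kind = "hologram", pixel_um = holo$pixel_um)
  if (!is.null(holo$timestamp_min)) extra$timestamp_min <- holo$timestamp_min
  write_raster_tiff(holo$intensity, path, extra)
}

#' Write a phantom's ground truth to disk
#'
#' Thickness map as float TIFF, mask as 8-bit TIFF, and a JSON sidecar with
#' the volume, pixel calibration and phantom parameters.
#'
#' @param gt a `ground_truth` from [make_phantom()].
#' @param prefix output path prefix; writes `<prefix>_thickness.tif`,
#'   `<prefix>_mask.tif`, `<prefix>_truth.json`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_ground_truth <- function(gt, prefix) {
  stopifnot(inherits(gt, "ground_truth"))
  paths <- c(thickness = paste0(prefix, "_thickness.tif"),
             mask = paste0(prefix, "_mask.tif"),
             truth = paste0(prefix, "_truth.json"))
  write_raster_tiff(gt$thickness_um, paths["thickness"],
                    list(kind = "thickness_um"))
  tiff::writeTIFF(gt$mask + 0, paths["mask"], bits.per.sample = 8,
                  reduce = FALSE)
  jsonlite::write_json(
    list(kind = gt$kind, volume_um3 = gt$volume_um3,
         pixel_um = gt$pixel_um, center_um = gt$center_um,
         params = gt$params[!vapply(gt$params, is.null, logical(1))]),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
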