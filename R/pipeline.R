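#' Pipeline configuration
#'
#' Validated bundle of every stage's parameters: optics, sideband filtering,
#' focusing, phase flattening, segmentation and series association. Written
#' to and read back from YAML round-trip-identically; unknown keys are
#' rejected on load so a config file cannot silently misspell a parameter.
#'
#' @param optical an [optical_config()] (or the list of its fields).
#' @param carrier_cyc_um fixed carrier (2-vector, cycles/um) or NULL to
#'   locate the sideband automatically per frame.
#' @param radius_frac sideband filter radius as a fraction of the
#'   DC-to-sideband distance (default 0.5).
#' @param dc_exclusion_frac DC exclusion disk fraction (default 0.1).
#' @param focus either NULL (hologram assumed in focus), a fixed distance
#'   (scalar, um), or `list(min =, max =, step =)` for autofocus.
#' @param zernike_order Zernike radial order of the background fit
#'   (default 4).
#' @param median_kernel_px median-compensation window (odd, default 51).
#' @param segmentation a [segmentation_params()].
#' @param association_radius_um frame-to-frame tracking radius (default 10).
#' @param seed optional integer seed recorded for provenance.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(optical,
                            carrier_cyc_um = NULL,
                            radius_frac = 0.5,
                            dc_exclusion_frac = 0.1,
                            focus = NULL,
                            zernike_order = 4,
                            median_kernel_px = 51,
                            segmentation = segmentation_params(),
                            association_radius_um = 10,
                            seed = NULL) {
  optical <- as_optical_config(optical)
  stopifnot(radius_frac > 0, dc_exclusion_frac > 0, zernike_order >= 0,
            association_radius_um > 0)
  if (!is.null(carrier_cyc_um)) stopifnot(length(carrier_cyc_um) == 2)
  if (!is.null(focus) && !is.numeric(focus)) {
    if (!is.list(focus) || !all(c("min", "max", "step") %in% names(focus)))
      stop("focus must be NULL, a fixed distance, or list(min, max, step)")
  }
  if (!inherits(segmentation, "segmentation_params"))
    segmentation <- do.call(segmentation_params, segmentation)
  structure(
    list(optical = optical, carrier_cyc_um = carrier_cyc_um,
         radius_frac = radius_frac, dc_exclusion_frac = dc_exclusion_frac,
         focus = focus, zernike_order = zernike_order,
         median_kernel_px = median_kernel_px, segmentation = segmentation,
         association_radius_um = association_radius_um, seed = seed),
    class = "pipeline_config"
  )
}

config_as_list <- function(cfg) {
  list(
    optical = cfg$optical[c("wavelength_um", "n_object", "n_medium",
                            "magnification", "camera_pixel_um")],
    carrier_cyc_um = cfg$carrier_cyc_um,
    radius_frac = cfg$radius_frac,
    dc_exclusion_frac = cfg$dc_exclusion_frac,
    focus = cfg$focus,
    zernike_order = cfg$zernike_order,
    median_kernel_px = cfg$median_kernel_px,
    segmentation = unclass(cfg$segmentation),
    association_radius_um = cfg$association_radius_um,
    seed = cfg$seed
  )
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(config_as_list(cfg), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Strict: unknown keys (top-level or nested) are rejected.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("optical", "carrier_cyc_um", "radius_frac",
             "dc_exclusion_frac", "focus", "zernike_order",
             "median_kernel_px", "segmentation", "association_radius_um",
             "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown pipeline_config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$optical)) {
    bad_o <- setdiff(names(raw$optical),
                     c("wavelength_um", "n_object", "n_medium",
                       "magnification", "camera_pixel_um"))
    if (length(bad_o) > 0)
      stop("unknown optical key(s): ", paste(bad_o, collapse = ", "))
  }
  if (!is.null(raw$segmentation)) {
    bad_s <- setdiff(names(raw$segmentation),
                     c("high_frac", "low_thresh_um", "min_area_px",
                       "closing_radius_px"))
    if (length(bad_s) > 0)
      stop("unknown segmentation key(s): ", paste(bad_s, collapse = ", "))
    raw$segmentation <- do.call(segmentation_params, raw$segmentation)
  }
  if (!is.null(raw$carrier_cyc_um))
    raw$carrier_cyc_um <- as.numeric(unlist(raw$carrier_cyc_um))
  do.call(pipeline_config, raw)
}

#' Reconstruct the compensated phase of a single hologram
#'
#' One frame of the full workflow: Fourier spectrum, sideband isolation and
#' demodulation, (auto)focusing, phase extraction, quality-guided
#' unwrapping, Zernike + median background compensation.
#'
#' @param holo a [hologram()] or a TIFF path.
#' @param cfg a [pipeline_config()].
#' @return list with the compensated [phase_map()] (`phase`), the focused
#'   `field`, and a `log` list of every auto-chosen parameter (carrier,
#'   filter radius, focus distance).
#' @export
reconstruct_phase <- function(holo, cfg) {
  if (is.character(holo)) holo <- read_hologram(holo, cfg$optical)
  sp <- fourier_spectrum(holo)
  if (is.null(cfg$carrier_cyc_um)) {
    sb <- locate_sideband(sp, cfg$dc_exclusion_frac)
    carrier <- sb$f_cyc_um
  } else {
    carrier <- cfg$carrier_cyc_um
  }
  field <- filter_plus_one(sp, center = carrier,
                           radius_frac = cfg$radius_frac,
                           dc_exclusion_frac = cfg$dc_exclusion_frac)
  d <- 0
  if (is.numeric(cfg$focus) && length(cfg$focus) == 1) {
    d <- cfg$focus
  } else if (is.list(cfg$focus)) {
    d <- as.numeric(autofocus(field, c(cfg$focus$min, cfg$focus$max),
                              cfg$focus$step))
  }
  if (d != 0) field <- angular_spectrum_propagate(field, d)
  ap <- extract_amplitude_phase(field)
  uw <- unwrap_quality_guided(ap$phase)
  # amplitude rim detections augment the phase-threshold exclusion rule:
  # the rim signature is independent of the phase background (robust under
  # strong aberrations), the phase rule catches smooth objects whose rims
  # stay inside the filter band
  obj <- object_mask_from_amplitude(field)
  if (sum(!obj) < 0.25 * length(obj)) obj <- NULL
  comp <- compensate_background(uw, augment_mask = obj,
                                order = cfg$zernike_order,
                                median_kernel_px = cfg$median_kernel_px)
  list(phase = comp, field = field,
       log = list(carrier_cyc_um = carrier,
                  filter_radius_bins = attr(field, "filter_radius_bins"),
                  focus_distance_um = d,
                  zernike_rms_residual =
                    attr(comp, "zernike_fit")$rms_residual))
}

#' Run the full hologram-to-volume pipeline
#'
#' Executes, per frame: spectrum, +1-order filtering, reconstruction,
#' unwrapping, background compensation, thickness conversion, segmentation
#' and per-cell morphometry; for multi-frame input, associates cells across
#' frames and analyzes the volume time series. A run manifest records the
#' configuration echo, input hashes and every auto-chosen parameter, so a
#' run can be reproduced exactly.
#'
#' @param holos list of [hologram()] objects or character vector of TIFF
#'   paths (one or more frames).
#' @param cfg a [pipeline_config()].
#' @param times_min optional frame times; defaults to hologram timestamps
#'   or 0, 1, 2, ... when absent.
#' @return object of class `pipeline_result`: list with `records` (tibble,
#'   one row per cell per frame), `series` (a [analyze_series()] result,
#'   or NULL for single-frame input), and `manifest`.
#' @export
run_pipeline <- function(holos, cfg, times_min = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(holos)) holos <- as.list(holos)
  if (inherits(holos, "hologram")) holos <- list(holos)
  if (length(holos) == 0)
    stop("run_pipeline needs at least one hologram")

  frame_logs <- vector("list", length(holos))
  records <- vector("list", length(holos))
  hashes <- rep(NA_character_, length(holos))
  px <- cfg$optical$object_pixel_um

  for (i in seq_along(holos)) {
    t0 <- proc.time()[["elapsed"]]
    h <- holos[[i]]
    if (is.character(h)) {
      hashes[i] <- unname(tools::md5sum(h))
      h <- read_hologram(h, cfg$optical)
    }
    t_i <- if (!is.null(times_min)) times_min[i]
           else h$timestamp_min %||% (i - 1)
    res <- tryCatch({
      rec <- reconstruct_phase(h, cfg)
      thick <- phase_to_thickness(rec$phase, cfg$optical)
      seg <- segment_cells(thick, cfg$segmentation)
      cells <- measure_cells(thick, seg, px, timestamp_min = t_i)
      list(rec = rec, thick = thick, seg = seg, cells = cells)
    }, error = function(e) {
      stop("pipeline failed at frame ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    records[[i]] <- res$cells
    frame_logs[[i]] <- c(
      res$rec$log,
      attr(res$seg, "thresholds"),
      list(clipped_px = attr(res$thick, "clipped_px"),
           n_cells = nrow(res$cells),
           elapsed_s = proc.time()[["elapsed"]] - t0)
    )
  }

  records <- dplyr::bind_rows(records)
  series <- NULL
  if (length(holos) > 1 && nrow(records) > 0)
    series <- analyze_series(records,
                             association_radius_um =
                               cfg$association_radius_um)

  manifest <- list(
    package = "holovol",
    version = as.character(utils::packageVersion("holovol")),
    config = config_as_list(cfg),
    n_frames = length(holos),
    input_md5 = hashes,
    frames = frame_logs
  )
  structure(list(records = records, series = series, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$manifest$n_frames, " frame(s), ",
      nrow(x$records), " cell record(s)\n", sep = "")
  print(x$records)
  invisible(x)
}

#' Write a run manifest to JSON
#'
#' @param result a `pipeline_result` (or its `manifest` element).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  m <- if (inherits(result, "pipeline_result")) result$manifest else result
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write cell records to CSV
#'
#' @param result a `pipeline_result` or a records tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(result, path) {
  rec <- if (inherits(result, "pipeline_result")) result$records else result
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}
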