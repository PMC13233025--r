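#' Hologram container
#'
#' A real-valued off-axis interference raster with its object-plane pixel
#' calibration and optical configuration. Dimensions must be even (the
#' Fourier stages assume symmetric spectra) and intensities non-negative.
#'
#' @param intensity non-negative numeric matrix with even dimensions.
#' @param config an [optical_config()].
#' @param timestamp_min optional acquisition time in minutes (time series).
#' @param pixel_um object-plane sampling in micrometres; defaults to
#'   `config$object_pixel_um`.
#' @return object of class `hologram`.
#' @export
hologram <- function(intensity, config, timestamp_min = NULL,
                     pixel_um = NULL) {
  config <- as_optical_config(config)
  check_even_raster(intensity, "hologram intensity")
  check_finite(intensity, "hologram intensity")
  if (any(intensity < 0))
    stop("hologram intensities must be non-negative")
  structure(
    list(intensity = intensity,
         pixel_um = pixel_um %||% config$object_pixel_um,
         config = config,
         timestamp_min = timestamp_min),
    class = "hologram"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hologram <- function(x, ...) {
  cat("<hologram> ", nrow(x$intensity), " x ", ncol(x$intensity),
      " px at ", format(x$pixel_um), " um/px\n", sep = "")
  if (!is.null(x$timestamp_min))
    cat("  t = ", x$timestamp_min, " min\n", sep = "")
  if (!is.null(attr(x, "carrier_cyc_um")))
    cat("  carrier ", paste(format(attr(x, "carrier_cyc_um"), digits = 4),
                            collapse = ", "), " cycles/um\n", sep = "")
  invisible(x)
}

default_carrier <- function(config) {
  fs <- 1 / config$object_pixel_um
  c(fs / 8, fs / 8)
}

#' Render an off-axis hologram of a phase object
#'
#' Simulates the two-beam interference recording `I = |O + R|^2`, the sum of
#' object and reference intensities plus the two conjugate cross terms that
#' carry the object information on the spatial-frequency carrier. The object
#' wave is a unit-amplitude phase object `O = exp(i * phase)`, optionally
#' propagated out of focus by the angular-spectrum method and multiplied by
#' a Zernike background aberration; the reference is a unit plane wave
#' tilted by `carrier_cyc_um`. The reference amplitude equals the mean
#' object amplitude, giving near-unity fringe contrast.
#'
#' @param true_phase matrix of object phase in radians (even dimensions),
#'   e.g. from [thickness_to_phase()].
#' @param config an [optical_config()].
#' @param carrier_cyc_um 2-vector of carrier frequencies in cycles/um along
#'   the two array dimensions. Default: 1/8 of the sampling frequency along
#'   both axes. The carrier vector magnitude must stay below half the
#'   Nyquist frequency so the sideband separates from the zero order.
#' @param defocus_um distance in micrometres from the recording plane to
#'   the object (focal) plane; the rendered hologram then requires
#'   numerical refocusing by `+defocus_um`.
#' @param zernike_coeffs optional coefficient vector of a Zernike background
#'   aberration (OSA ordering, radians; see [zernike_surface()]) applied to
#'   the object beam at the recording plane.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise, relative to the mean intensity (default 0.01). Noise is added
#'   after interference and the result clipped at zero.
#' @param seed integer seed; required whenever `noise_sigma > 0` so that
#'   identical arguments give bit-identical holograms.
#' @param timestamp_min optional acquisition time.
#' @return a [hologram()] with the carrier recorded in attribute
#'   `carrier_cyc_um` and the applied defocus in `defocus_um`.
#' @export
#' @examples
#' cfg <- optical_config(n_object = 1.46, n_medium = 1.34)
#' gt <- make_phantom("sphere", cfg, grid_shape = c(256, 256))
#' holo <- render_hologram(thickness_to_phase(gt, cfg), cfg, noise_sigma = 0)
render_hologram <- function(true_phase, config,
                            carrier_cyc_um = NULL,
                            defocus_um = 0,
                            zernike_coeffs = NULL,
                            noise_sigma = 0.01,
                            seed = NULL,
                            timestamp_min = NULL) {
  config <- as_optical_config(config)
  check_even_raster(true_phase, "true_phase")
  check_finite(true_phase, "true_phase")
  stopifnot(noise_sigma >= 0)
  px <- config$object_pixel_um
  carrier <- carrier_cyc_um %||% default_carrier(config)
  stopifnot(length(carrier) == 2)
  fmax <- 1 / (4 * px) # half the Nyquist frequency
  if (sqrt(sum(carrier^2)) >= fmax)
    stop("carrier magnitude ", format(sqrt(sum(carrier^2))),
         " cycles/um is not separable from the zero order; the maximum ",
         "admissible magnitude is ", format(fmax), " cycles/um")
  if (noise_sigma > 0 && is.null(seed))
    stop("a seed is required when noise_sigma > 0 (determinism)")

  O <- exp(1i * true_phase)
  if (defocus_um != 0)
    O <- propagate_matrix(O, -defocus_um, config$wavelength_um, px)
  if (!is.null(zernike_coeffs))
    O <- O * exp(1i * zernike_surface(zernike_coeffs, dim(true_phase)))

  nr <- nrow(true_phase); nc <- ncol(true_phase)
  # reference tilt sign chosen so the object term O * Conj(R) lands at
  # +carrier, the sideband the reconstruction selects
  phiR <- outer(2 * pi * carrier[1] * (seq_len(nr) - 1) * px,
                2 * pi * carrier[2] * (seq_len(nc) - 1) * px, "+")
  I <- Mod(O + exp(-1i * phiR))^2

  if (noise_sigma > 0) {
    I <- I + with_seed(seed, matrix(stats::rnorm(length(I),
                                                 sd = noise_sigma * mean(I)),
                                    nr, nc))
    I <- pmax(I, 0)
  }

  out <- hologram(I, config, timestamp_min = timestamp_min, pixel_um = px)
  attr(out, "carrier_cyc_um") <- carrier
  attr(out, "defocus_um") <- defocus_um
  out
}

#' Render a hologram time series of shrinking or growing phantoms
#'
#' Generates one cell phantom per time point, each scaled to the requested
#' ground-truth volume, and renders its hologram, emulating continuous
#' volume monitoring (e.g. osmotic cell death or division). Per-frame seeds
#' are derived deterministically from `seed`.
#'
#' @param volumes_um3 vector of ground-truth volumes, one per time point.
#' @param config an [optical_config()].
#' @param kind phantom family passed to [make_phantom()] (default
#'   `"spherical_cap"`).
#' @param times_min acquisition times; default `interval_min` spacing from 0.
#' @param interval_min frame interval used when `times_min` is NULL.
#' @param grid_shape raster dimensions per frame.
#' @param noise_sigma relative intensity noise per frame (default 0.01).
#' @param seed base integer seed.
#' @param ... further phantom parameters for [make_phantom()].
#' @return list with elements `holograms` (list of [hologram()]),
#'   `ground_truths` (list of `ground_truth`), and `times_min`.
#' @export
render_timeseries <- function(volumes_um3, config,
                              kind = "spherical_cap",
                              times_min = NULL,
                              interval_min = 10,
                              grid_shape = c(768, 768),
                              noise_sigma = 0.01,
                              seed = 1,
                              ...) {
  if (length(volumes_um3) < 1)
    stop("volumes_um3 must contain at least one time point")
  if (any(volumes_um3 <= 0)) stop("all volumes must be > 0")
  times_min <- times_min %||% ((seq_along(volumes_um3) - 1) * interval_min)
  stopifnot(length(times_min) == length(volumes_um3))

  gts <- vector("list", length(volumes_um3))
  holos <- vector("list", length(volumes_um3))
  for (i in seq_along(volumes_um3)) {
    gts[[i]] <- make_phantom(kind, config, grid_shape = grid_shape,
                             target_volume_um3 = volumes_um3[i],
                             seed = seed + i, ...)
    holos[[i]] <- render_hologram(
      thickness_to_phase(gts[[i]], config), config,
      noise_sigma = noise_sigma,
      seed = if (noise_sigma > 0) seed + 10000L + i else NULL,
      timestamp_min = times_min[i]
    )
  }
  list(holograms = holos, ground_truths = gts, times_min = times_min)
}
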