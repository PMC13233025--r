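#' Optical configuration of the holographic microscope
#'
#' Bundles the physical constants that govern every unit conversion in the
#' pipeline: vacuum wavelength, the refractive indices of the object and the
#' surrounding medium, the lateral magnification, and the camera pixel pitch.
#' The object-plane sampling is derived as `camera_pixel_um / magnification`
#' (3.45/60 = 0.0575 um/pixel at the defaults).
#'
#' The refractive-index contrast `n_object - n_medium` converts optical phase
#' to physical thickness: one 2*pi phase fringe corresponds to
#' `wavelength_um / (n_object - n_medium)` micrometres of thickness.
#'
#' @param wavelength_um vacuum wavelength in micrometres (default 0.633,
#'   a HeNe laser line).
#' @param n_object refractive index of the imaged object (e.g. 1.46 for
#'   silica microspheres, 1.38 for a typical mammalian cell).
#' @param n_medium refractive index of the surrounding medium (e.g. 1.34 for
#'   PBS, 1.33 for culture medium). Must satisfy `n_object > n_medium > 1`.
#' @param magnification lateral magnification of the imaging objective
#'   (default 60).
#' @param camera_pixel_um detector pixel pitch in micrometres (default 3.45).
#' @return an object of class `optical_config`.
#' @export
#' @examples
#' cfg <- optical_config(n_object = 1.46, n_medium = 1.34)
#' cfg$object_pixel_um # 0.0575
optical_config <- function(wavelength_um = 0.633,
                           n_object,
                           n_medium,
                           magnification = 60,
                           camera_pixel_um = 3.45) {
  stopifnot(is.numeric(wavelength_um), length(wavelength_um) == 1,
            is.numeric(n_object), length(n_object) == 1,
            is.numeric(n_medium), length(n_medium) == 1,
            is.numeric(magnification), length(magnification) == 1,
            is.numeric(camera_pixel_um), length(camera_pixel_um) == 1)
  if (wavelength_um <= 0) stop("wavelength_um must be > 0")
  if (magnification <= 0) stop("magnification must be > 0")
  if (camera_pixel_um <= 0) stop("camera_pixel_um must be > 0")
  if (!(n_object > n_medium))
    stop("n_object (", n_object, ") must exceed n_medium (", n_medium,
         "): zero or negative refractive-index contrast")
  if (!(n_medium > 1))
    stop("n_medium must exceed 1 (immersion media are denser than vacuum)")
  structure(
    list(
      wavelength_um = wavelength_um,
      n_object = n_object,
      n_medium = n_medium,
      magnification = magnification,
      camera_pixel_um = camera_pixel_um,
      object_pixel_um = camera_pixel_um / magnification
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength      %.4g um\n", x$wavelength_um))
  cat(sprintf("  n_object        %.4g\n", x$n_object))
  cat(sprintf("  n_medium        %.4g   (contrast %.4g)\n",
              x$n_medium, x$n_object - x$n_medium))
  cat(sprintf("  magnification   %.4g x\n", x$magnification))
  cat(sprintf("  camera pixel    %.4g um  ->  object plane %.6g um/px\n",
              x$camera_pixel_um, x$object_pixel_um))
  invisible(x)
}

index_contrast <- function(config) {
  config$n_object - config$n_medium
}

as_optical_config <- function(x) {
  if (inherits(x, "optical_config")) return(x)
  if (is.list(x))
    return(do.call(optical_config, x[setdiff(names(x), "object_pixel_um")]))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an optical_config")
}
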