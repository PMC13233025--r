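# angular-spectrum transfer-function propagation on a raw complex matrix
propagate_matrix <- function(U, d_um, wavelength_um, pixel_um) {
  if (d_um == 0) return(U)
  nr <- nrow(U); nc <- ncol(U)
  f1 <- fft_freqs(nr, pixel_um)
  f2 <- fft_freqs(nc, pixel_um)
  rad <- outer(1 - (wavelength_um * f1)^2, (wavelength_um * f2)^2, "-")
  prop <- rad > 0
  H <- matrix(0i, nr, nc)
  H[prop] <- exp(2i * pi * d_um / wavelength_um * sqrt(rad[prop]))
  matrix(stats::fft(stats::fft(U) * H, inverse = TRUE) / (nr * nc), nr, nc)
}

#' Propagate a complex field by the angular-spectrum method
#'
#' Multiplies the field's spatial-frequency spectrum by the exact scalar
#' diffraction transfer function
#' `exp(i * 2 * pi * d / lambda * sqrt(1 - (lambda f1)^2 - (lambda f2)^2))`.
#' Evanescent components (negative radicand) are zeroed, which prevents
#' exponential blow-up and makes propagation unitary on the propagating
#' band. `d_um = 0` is an exact identity.
#'
#' @param field a [complex_field()].
#' @param d_um signed propagation distance in micrometres.
#' @return a [complex_field()] at the updated distance.
#' @export
angular_spectrum_propagate <- function(field, d_um) {
  if (!inherits(field, "complex_field"))
    stop("field must be a complex_field")
  check_finite(field$data, "complex field")
  stopifnot(is.numeric(d_um), length(d_um) == 1, is.finite(d_um))
  if (d_um == 0) return(field)
  field$data <- propagate_matrix(field$data, d_um,
                                 field$config$wavelength_um, field$pixel_um)
  field$distance_um <- field$distance_um + d_um
  field
}

# high-frequency energy ratio of the amplitude image: energy of the
# amplitude's spectrum outside a disk of radius 1/8 Nyquist over total.
# For a phase object the amplitude is structureless at focus, so the ratio
# is minimal there.
amplitude_hf_ratio <- function(A) {
  S2 <- Mod(stats::fft(A))^2
  nr <- nrow(A); nc <- ncol(A)
  b1 <- c(0:(nr / 2 - 1), -(nr / 2):-1)
  b2 <- c(0:(nc / 2 - 1), -(nc / 2):-1)
  rho2 <- outer(b1^2, b2^2, "+")
  r <- min(nr, nc) / 16 # 1/8 of the Nyquist bin radius
  tot <- sum(S2)
  1 - sum(S2[rho2 <= r^2]) / tot
}

#' Autofocus by the frequency energy of the amplitude image
#'
#' Scans reconstruction distances, computing at each the high-frequency
#' energy ratio of the propagated amplitude image, and returns the distance
#' of best focus. The phantoms and cells imaged here are phase objects, so
#' the amplitude is flat in focus and acquires diffraction structure out of
#' focus: the metric is minimized at focus. After the coarse scan the
#' estimate is refined by golden-section search within one step.
#'
#' @param field a [complex_field()] (typically the demodulated baseband
#'   field at distance 0).
#' @param d_range numeric 2-vector, scan range in micrometres; must bracket
#'   the focus.
#' @param step_um scan step in micrometres (> 0).
#' @param refine logical; golden-section refinement within +/- one step
#'   (default TRUE).
#' @return the best-focus distance (scalar, micrometres) with the scanned
#'   metric curve attached as attribute `curve` (a tibble).
#' @export
autofocus <- function(field, d_range, step_um, refine = TRUE) {
  if (!inherits(field, "complex_field"))
    stop("field must be a complex_field")
  stopifnot(length(d_range) == 2, step_um > 0)
  if (d_range[2] <= d_range[1])
    stop("empty autofocus range: d_range must satisfy min < max")
  ds <- seq(d_range[1], d_range[2], by = step_um)
  if (ds[length(ds)] < d_range[2]) ds <- c(ds, d_range[2])

  nr <- nrow(field$data); nc <- ncol(field$data)
  lam <- field$config$wavelength_um
  F0 <- stats::fft(field$data)
  f1 <- fft_freqs(nr, field$pixel_um)
  f2 <- fft_freqs(nc, field$pixel_um)
  rad <- outer(1 - (lam * f1)^2, (lam * f2)^2, "-")
  prop <- rad > 0
  sq <- sqrt(pmax(rad, 0))
  metric_at <- function(d) {
    H <- matrix(0i, nr, nc)
    H[prop] <- exp(2i * pi * d / lam * sq[prop])
    A <- Mod(matrix(stats::fft(F0 * H, inverse = TRUE) / (nr * nc), nr, nc))
    amplitude_hf_ratio(A)
  }

  metrics <- vapply(ds, metric_at, numeric(1))
  curve <- tibble::tibble(distance_um = ds, metric = metrics)
  if (diff(range(metrics)) <= 1e-12 * max(abs(metrics), 1e-300)) {
    warning("autofocus metric is constant (no object?); ",
            "returning the range minimum")
    return(structure(d_range[1], curve = curve))
  }
  best <- ds[which.min(metrics)]

  if (refine) {
    lo <- max(d_range[1], best - step_um)
    hi <- min(d_range[2], best + step_um)
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1v <- metric_at(c1); f2v <- metric_at(c2)
    for (i in seq_len(30)) {
      if (f1v < f2v) {
        b <- c2; c2 <- c1; f2v <- f1v
        c1 <- b - gr * (b - a); f1v <- metric_at(c1)
      } else {
        a <- c1; c1 <- c2; f1v <- f2v
        c2 <- a + gr * (b - a); f2v <- metric_at(c2)
      }
    }
    best <- (a + b) / 2
  }
  structure(best, curve = curve)
}

#' Object mask from the reconstructed amplitude
#'
#' Band-limited reconstruction of a phase object leaves a distinct
#' amplitude signature: dips along the object rim where steep phase
#' gradients fall outside the sideband filter. Thresholding those dips
#' (background median minus 3 one-sided MAD), dilating, and filling the
#' enclosed region yields an object mask that is entirely independent of
#' the phase background -- which is what makes it a safe exclusion mask
#' for background fitting even under strong aberrations or when the cell
#' covers much of the field.
#'
#' @param field a [complex_field()] (demodulated, in focus).
#' @param dilate_px dilation radius applied to the rim detections
#'   (default 5).
#' @return logical matrix marking object pixels.
#' @export
object_mask_from_amplitude <- function(field, dilate_px = 5) {
  if (!inherits(field, "complex_field"))
    stop("field must be a complex_field")
  A <- Mod(field$data)
  med <- stats::median(A)
  dev <- A - med
  scl <- 1.4826 * stats::median(dev[dev >= 0]) # upper half: background ripple
  m <- dev < -3 * scl
  if (any(m)) {
    if (dilate_px > 0) {
      brush <- EBImage::makeBrush(2 * dilate_px + 1, "disc")
      m <- as.matrix(EBImage::dilate(m + 0, brush)) > 0.5
    }
    m <- as.matrix(EBImage::fillHull(m + 0)) > 0.5
  }
  m
}

#' Extract intensity and wrapped phase from a complex field
#'
#' The reconstructed intensity is the squared modulus `|U|^2`; the phase is
#' the four-quadrant arctangent of `Im(U)/Re(U)`, confined to `(-pi, pi]`
#' (the negative real axis maps to `+pi`).
#'
#' @param field a [complex_field()].
#' @return list with `intensity` (matrix) and `phase` (a [phase_map()] in
#'   state `"wrapped"`).
#' @export
extract_amplitude_phase <- function(field) {
  if (!inherits(field, "complex_field"))
    stop("field must be a complex_field")
  check_finite(field$data, "complex field")
  list(intensity = Mod(field$data)^2,
       phase = phase_map(Arg(field$data), "wrapped", field$pixel_um))
}
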