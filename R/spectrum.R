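#' Centered Fourier spectrum of a hologram
#'
#' Computes the 2-D discrete Fourier transform of the hologram intensity
#' with the zero-frequency bin moved to the raster centre
#' (`(n/2 + 1, n/2 + 1)` in 1-based indices). An off-axis hologram shows the
#' zero-order term at DC and the two conjugate +/-1-order sidebands at the
#' carrier frequency.
#'
#' @param holo a [hologram()].
#' @return object of class `spectrum` with complex matrix `data`,
#'   `freq_step_per_um` (frequency bin size along both axes),
#'   `source_shape`, `pixel_um` and the hologram's `config`.
#' @export
fourier_spectrum <- function(holo) {
  if (!inherits(holo, "hologram")) stop("holo must be a hologram object")
  I <- holo$intensity
  check_even_raster(I, "hologram intensity")
  check_finite(I, "hologram intensity")
  S <- fftshift2(stats::fft(I))
  structure(
    list(data = S,
         freq_step_per_um = 1 / (dim(I) * holo$pixel_um),
         source_shape = dim(I),
         pixel_um = holo$pixel_um,
         config = holo$config),
    class = "spectrum"
  )
}

# centered bin offsets of every element of a spectrum, as two matrices
spectrum_bins <- function(spec) {
  nr <- spec$source_shape[1]; nc <- spec$source_shape[2]
  k1 <- matrix(seq_len(nr) - (nr / 2 + 1), nr, nc)
  k2 <- matrix(seq_len(nc) - (nc / 2 + 1), nr, nc, byrow = TRUE)
  list(k1 = k1, k2 = k2)
}

dc_exclusion_radius <- function(spec, dc_exclusion_frac) {
  dc_exclusion_frac * min(spec$source_shape) / 2
}

#' Locate the +1-order sideband
#'
#' Finds the magnitude-maximal spectral bin outside a DC exclusion disk,
#' restricted to the upper half-plane (positive frequency along the second
#' axis; on that axis' zero line, positive along the first). The two
#' sidebands are conjugate mirror images, so one deterministic choice
#' suffices. Ties are broken lexicographically by (second, first) bin index.
#'
#' @param spec a [fourier_spectrum()].
#' @param dc_exclusion_frac radius of the DC exclusion disk as a fraction of
#'   the Nyquist bin radius (default 0.1).
#' @return list with `f_cyc_um` (carrier estimate, cycles/um), `bin`
#'   (integer bin offsets from DC), and `magnitude`.
#' @export
locate_sideband <- function(spec, dc_exclusion_frac = 0.1) {
  if (!inherits(spec, "spectrum")) stop("spec must be a spectrum object")
  mag <- Mod(spec$data)
  k <- spectrum_bins(spec)
  rho2 <- k$k1^2 + k$k2^2
  r_dc <- dc_exclusion_radius(spec, dc_exclusion_frac)
  outside <- rho2 > r_dc^2
  med <- stats::median(mag[outside])
  upper <- outside & (k$k2 > 0 | (k$k2 == 0 & k$k1 > 0))
  peak <- max(mag[upper])
  if (peak <= 3 * med)
    stop("no sideband found: no bin outside the DC exclusion disk exceeds ",
         "3x the median spectral magnitude")
  idx <- which(upper & mag == peak)
  if (length(idx) > 1) {
    ord <- order(k$k2[idx], k$k1[idx])
    idx <- idx[ord[1]]
  }
  bin <- c(k$k1[idx], k$k2[idx])
  list(f_cyc_um = bin * spec$freq_step_per_um,
       bin = bin,
       magnitude = peak)
}

#' Isolate and demodulate the +1-order sideband
#'
#' Applies a circular low-pass mask (hard disk with a 3-bin raised-cosine
#' rim) about the sideband centre, recentres the spectrum so the carrier
#' maps to zero frequency (demodulation by spectral shift, exactly
#' invertible on the grid), and inverse-transforms to the complex object
#' field at propagation distance zero.
#'
#' @param spec a [fourier_spectrum()].
#' @param center sideband centre in cycles/um (2-vector); default: located
#'   automatically with [locate_sideband()].
#' @param radius_frac filter radius as a fraction of the DC-to-sideband
#'   distance (default 0.5). Must leave the DC exclusion disk untouched.
#' @param dc_exclusion_frac DC exclusion disk fraction used for the radius
#'   admissibility check (default 0.1).
#' @return a `complex_field` at `distance_um = 0`.
#' @export
filter_plus_one <- function(spec, center = NULL, radius_frac = 0.5,
                            dc_exclusion_frac = 0.1) {
  if (!inherits(spec, "spectrum")) stop("spec must be a spectrum object")
  if (radius_frac <= 0)
    stop("radius_frac must be > 0 (a zero-radius filter keeps nothing)")
  if (is.null(center)) {
    sb <- locate_sideband(spec, dc_exclusion_frac)
    kc <- sb$bin
  } else {
    stopifnot(length(center) == 2)
    kc <- round(center / spec$freq_step_per_um)
  }
  dist <- sqrt(sum(kc^2))
  r_dc <- dc_exclusion_radius(spec, dc_exclusion_frac)
  radius <- radius_frac * dist
  max_frac <- (dist - r_dc) / dist
  if (radius > dist - r_dc)
    stop("filter radius overlaps the DC exclusion disk; the maximal ",
         "admissible radius_frac for this carrier is ",
         format(max_frac, digits = 4))

  k <- spectrum_bins(spec)
  d <- sqrt((k$k1 - kc[1])^2 + (k$k2 - kc[2])^2)
  taper <- min(3, radius)
  w <- ifelse(d <= radius - taper, 1,
              ifelse(d <= radius, 0.5 * (1 + cos(pi * (d - (radius - taper)) / taper)),
                     0))
  S <- spec$data * w

  nr <- spec$source_shape[1]; nc <- spec$source_shape[2]
  i1 <- ((seq_len(nr) - 1 + kc[1]) %% nr) + 1
  i2 <- ((seq_len(nc) - 1 + kc[2]) %% nc) + 1
  S <- S[i1, i2]

  U <- stats::fft(ifftshift2(S), inverse = TRUE) / (nr * nc)
  out <- complex_field(U, spec$pixel_um, distance_um = 0,
                       config = spec$config)
  attr(out, "carrier_cyc_um") <- kc * spec$freq_step_per_um
  attr(out, "filter_radius_bins") <- radius
  out
}

#' Complex reconstructed wavefront
#'
#' @param data complex matrix.
#' @param pixel_um object-plane sampling.
#' @param distance_um propagation distance from the hologram plane.
#' @param config an [optical_config()].
#' @return object of class `complex_field`.
#' @export
complex_field <- function(data, pixel_um, distance_um = 0, config) {
  stopifnot(is.matrix(data), pixel_um > 0)
  check_finite(data, "complex field")
  structure(
    list(data = data, pixel_um = pixel_um, distance_um = distance_um,
         config = as_optical_config(config)),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat("<complex_field> ", nrow(x$data), " x ", ncol(x$data), " px at ",
      format(x$pixel_um), " um/px, d = ", format(x$distance_um), " um\n",
      sep = "")
  invisible(x)
}
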