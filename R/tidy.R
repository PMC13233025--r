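# broom-style tidiers

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Zernike background fit
#'
#' One row per OSA/ANSI term with its radial order `n`, azimuthal
#' frequency `m`, and fitted coefficient (radians).
#'
#' @param x a `zernike_fit`.
#' @param ... unused.
#' @return a tibble with columns `term`, `j`, `n`, `m`, `estimate`.
#' @exportS3Method generics::tidy
tidy.zernike_fit <- function(x, ...) {
  idx <- zernike_indices(x$order)
  tibble::tibble(term = names(x$coeffs), j = idx$j, n = idx$n, m = idx$m,
                 estimate = unname(x$coeffs))
}

#' @rdname tidy.zernike_fit
#' @return for `glance`: a one-row tibble with `order`, `n_terms`,
#'   `n_pixels`, `rms_residual`.
#' @exportS3Method generics::glance
glance.zernike_fit <- function(x, ...) {
  tibble::tibble(order = x$order, n_terms = length(x$coeffs),
                 n_pixels = x$n_pixels, rms_residual = x$rms_residual)
}

#' Tidy a volume series
#'
#' @param x a `volume_series` from [analyze_series()].
#' @param ... unused.
#' @return for `tidy`: the per-interval slope table (track_id, t_start,
#'   t_end, dV_dt_um3_per_min, stage); for `glance`: the per-track summary
#'   (n_points, monotone_decreasing flag, peak location).
#' @exportS3Method generics::tidy
tidy.volume_series <- function(x, ...) x$slopes

#' @rdname tidy.volume_series
#' @exportS3Method generics::glance
glance.volume_series <- function(x, ...) x$summary
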