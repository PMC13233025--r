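# Zernike polynomials in OSA/ANSI single-index ordering over the unit disk.

# OSA index table up to a maximal radial order
zernike_indices <- function(order) {
  stopifnot(order >= 0)
  n <- rep(0:order, 0:order + 1)
  m <- unlist(lapply(0:order, function(k) seq(-k, k, by = 2)))
  data.frame(j = seq_along(n) - 1L, n = n, m = m)
}

# radial polynomial R_n^{|m|}(rho)
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

# basis matrix: one column per OSA term, orthonormal over the unit disk
zernike_basis <- function(rho, theta, order) {
  idx <- zernike_indices(order)
  B <- matrix(0, length(rho), nrow(idx))
  for (t in seq_len(nrow(idx))) {
    n <- idx$n[t]; m <- idx$m[t]
    norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
    ang <- if (m >= 0) cos(m * theta) else sin(-m * theta)
    B[, t] <- norm * zernike_radial(n, m, rho) * ang
  }
  colnames(B) <- sprintf("Z%d", idx$j)
  B
}

# affine map from raster coordinates to the inscribed unit disk
disk_coords <- function(dim) {
  nr <- dim[1]; nc <- dim[2]
  c1 <- (nr + 1) / 2; c2 <- (nc + 1) / 2
  radius <- min(nr, nc) / 2
  u <- matrix(seq_len(nr) - c1, nr, nc) / radius
  v <- matrix(seq_len(nc) - c2, nr, nc, byrow = TRUE) / radius
  list(rho = sqrt(u^2 + v^2), theta = atan2(v, u),
       center_px = c(c1, c2), radius_px = radius)
}

#' Evaluate a Zernike surface on a raster
#'
#' Reconstructs a phase surface from OSA/ANSI-ordered Zernike coefficients
#' (orthonormal over the unit disk inscribed in the raster). Pixels outside
#' the inscribed disk are polynomial extrapolations of the same terms. Used
#' both to inject synthetic background aberrations and to subtract fitted
#' ones, so injection and compensation share one convention.
#'
#' @param coeffs numeric coefficient vector whose length is a triangular
#'   number `(order + 1)(order + 2)/2`, or a `zernike_fit`.
#' @param dim raster dimensions (ignored when `coeffs` is a fit).
#' @return numeric matrix of the surface in the coefficients' units.
#' @export
#' @examples
#' tilt <- zernike_surface(c(0, 0, 1, 0, 0, 0), dim = c(64, 64))
zernike_surface <- function(coeffs, dim = NULL) {
  if (inherits(coeffs, "zernike_fit")) {
    dim <- coeffs$dim
    coeffs <- coeffs$coeffs
  }
  stopifnot(!is.null(dim), length(dim) == 2)
  nt <- length(coeffs)
  order <- (sqrt(8 * nt + 1) - 3) / 2
  if (abs(order - round(order)) > 1e-9)
    stop("length(coeffs) = ", nt, " is not a triangular number ",
         "(complete OSA orders required)")
  dc <- disk_coords(dim)
  B <- zernike_basis(as.vector(dc$rho), as.vector(dc$theta), round(order))
  matrix(B %*% coeffs, dim[1], dim[2])
}

#' Fit a Zernike background surface to an unwrapped phase map
#'
#' Least-squares fit of Zernike terms up to the given radial order over all
#' non-excluded pixels, with raster coordinates normalized to the inscribed
#' unit disk. Corner pixels (normalized radius > 1) participate in the fit
#' -- evaluating the polynomial terms there is well defined, and fitting
#' them avoids the large extrapolation errors a disk-restricted fit would
#' produce at the raster corners. The excluded region (typically the cell)
#' must leave at least 20% of the raster as background.
#'
#' @param phase a [phase_map()] in state `"unwrapped"` (or
#'   `"compensated"`, for residual checks).
#' @param exclude_mask logical matrix marking pixels to exclude from the
#'   fit (e.g. the object); NULL fits everywhere.
#' @param order maximal radial order (default 4, i.e. 15 terms: up to
#'   spherical aberration).
#' @return object of class `zernike_fit`: `coeffs` (named, OSA order),
#'   `order`, `dim`, `center_px`, `radius_px`, `rms_residual` (radians, over
#'   the fitted pixels) and `n_pixels`.
#' @export
fit_zernike_background <- function(phase, exclude_mask = NULL, order = 4) {
  check_state(phase, c("unwrapped", "compensated"), "fit_zernike_background")
  x <- phase$data
  dc <- disk_coords(dim(x))
  use <- matrix(TRUE, nrow(x), ncol(x))
  if (!is.null(exclude_mask)) {
    stopifnot(identical(dim(exclude_mask), dim(x)))
    use <- use & !exclude_mask
  }
  if (sum(use) < 0.2 * length(x))
    stop("insufficient background: the exclusion mask leaves fewer than ",
         "20% of the pixels for the fit")
  B <- zernike_basis(dc$rho[use], dc$theta[use], order)
  fit <- stats::.lm.fit(B, x[use])
  coeffs <- stats::setNames(fit$coefficients, colnames(B))
  structure(
    list(coeffs = coeffs, order = order, dim = dim(x),
         center_px = dc$center_px, radius_px = dc$radius_px,
         rms_residual = sqrt(mean(fit$residuals^2)),
         n_pixels = sum(use), fitted_mask = use),
    class = "zernike_fit"
  )
}

#' @export
print.zernike_fit <- function(x, ...) {
  cat("<zernike_fit> order ", x$order, " (", length(x$coeffs), " terms), ",
      x$n_pixels, " pixels\n", sep = "")
  cat(sprintf("  rms residual %.4g rad\n", x$rms_residual))
  top <- sort(abs(x$coeffs), decreasing = TRUE)[1:min(3, length(x$coeffs))]
  cat("  largest |coeffs|: ",
      paste(names(top), format(x$coeffs[names(top)], digits = 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# robust automatic object mask: pixels above background median + 3 MAD,
# dilated by 5 px so fringe skirts are excluded too. Estimated iteratively:
# a raw threshold seeds the mask, then two rounds of background Zernike fit
# (excluding the current mask) and re-thresholding of the residual. The
# iteration is what makes the rule robust both to strong background
# curvature (which swamps the MAD of the raw map) and to large objects
# (which contaminate an unexcluded fit).
auto_object_mask <- function(pm, order = 4, dilate_px = 5,
                             augment_mask = NULL) {
  x <- pm$data
  brush <- if (dilate_px > 0) EBImage::makeBrush(2 * dilate_px + 1, "disc")

  # One-sided MAD threshold: cells are positive-phase, so spread is
  # estimated from the background-dominated lower half and large objects
  # cannot inflate their own detection threshold.
  one_sided <- function(dev) {
    scl <- 1.4826 * stats::median(abs(dev[dev <= 0]))
    dev > 3 * scl
  }

  # The refinement iterations run on a pixel subsample: the background
  # surface has 15 degrees of freedom, so ~1e5 pixels constrain it as well
  # as 1e6 do, at a tenth of the cost.
  dc <- disk_coords(dim(x))
  stride <- max(1L, ceiling(length(x) / 150000))
  idx <- seq(1, length(x), by = stride)
  B <- zernike_basis(dc$rho[idx], dc$theta[idx], order)
  xs <- x[idx]
  aug <- if (is.null(augment_mask)) rep(FALSE, length(idx))
         else augment_mask[idx]

  # raw threshold (exact when the background is already near-flat), then
  # refinement rounds against the fitted background residual until the
  # mask stabilizes
  m <- one_sided(xs - stats::median(xs)) | aug
  coef <- NULL
  for (i in 1:8) {
    keep <- if (sum(!m) < 0.25 * length(xs)) rep(TRUE, length(xs)) else !m
    coef <- stats::.lm.fit(B[keep, , drop = FALSE], xs[keep])$coefficients
    r <- xs - as.vector(B %*% coef)
    m_new <- one_sided(r - stats::median(r[!m])) | aug
    if (identical(m_new, m)) break
    m <- m_new
  }

  # final mask at full resolution from the converged background surface
  r_full <- x - zernike_surface(coef, dim(x))
  med <- stats::median(r_full[idx][!m])
  dev <- r_full[idx][!m] - med
  scl <- 1.4826 * stats::median(abs(dev[dev <= 0]))
  obj <- r_full - med > 3 * scl
  if (any(obj) && dilate_px > 0)
    obj <- as.matrix(EBImage::dilate(obj + 0, brush)) > 0.5
  if (!is.null(augment_mask)) obj <- obj | augment_mask
  obj
}

#' Flatten the phase background (Zernike + median compensation)
#'
#' Two-stage background removal yielding a flat-background continuous
#' phase: (1) global compensation -- fit and subtract a Zernike surface
#' (radial order `order`) over the background pixels; (2) local
#' compensation -- estimate the remaining slowly varying background as a
#' wide-kernel median of the Zernike-subtracted map (with object pixels
#' replaced by their nearest background value so the cell does not leak
#' into its own background estimate) and subtract it. Object-to-background
#' phase differences are preserved; only the background surface moves.
#'
#' @param phase a [phase_map()] in state `"unwrapped"` (re-compensating a
#'   `"compensated"` map is allowed and is a near no-op).
#' @param exclude_mask logical object mask; NULL (default) derives one
#'   automatically: pixels above background median + 3 MAD (one-sided,
#'   refined against the fitted background residual), dilated 5 px. The
#'   automatic rule is reliable when the object is a modest fraction of
#'   the field; [run_pipeline()] instead supplies a mask derived from the
#'   reconstructed amplitude, which is independent of the phase
#'   background.
#' @param order Zernike radial order for the global fit (default 4).
#' @param median_kernel_px odd width of the median window in pixels
#'   (default 51, about 2.9 um at the default sampling: wider than
#'   pseudopodia, narrower than field curvature).
#' @param augment_mask optional logical mask of pixels known to be object
#'   (e.g. from [object_mask_from_amplitude()]), unioned with the
#'   automatic exclusion rule; ignored when `exclude_mask` is given.
#' @return a [phase_map()] in state `"compensated"`, with the
#'   [fit_zernike_background()] result attached as attribute
#'   `zernike_fit`.
#' @export
compensate_background <- function(phase, exclude_mask = NULL, order = 4,
                                  median_kernel_px = 51,
                                  augment_mask = NULL) {
  check_state(phase, c("unwrapped", "compensated"), "compensate_background")
  x <- phase$data
  if (median_kernel_px %% 2 != 1 || median_kernel_px < 3)
    stop("median_kernel_px must be an odd integer >= 3")
  if (median_kernel_px > min(dim(x)))
    stop("median kernel (", median_kernel_px,
         " px) exceeds the raster size (", min(dim(x)), " px)")
  obj <- exclude_mask %||%
    auto_object_mask(phase, order = order, augment_mask = augment_mask)
  stopifnot(identical(dim(obj), dim(x)))

  fit <- fit_zernike_background(phase, exclude_mask = obj, order = order)
  r <- x - zernike_surface(fit)

  bg_src <- if (any(obj)) .inpaint_nearest_cpp(r, obj) else r
  rng <- range(bg_src)
  if (diff(rng) > 0) {
    nrm <- (bg_src - rng[1]) / diff(rng)
    med <- as.matrix(EBImage::medianFilter(nrm, (median_kernel_px - 1) / 2))
    bg <- med * diff(rng) + rng[1]
  } else {
    bg <- bg_src
  }
  out <- phase_map(r - bg, "compensated", phase$pixel_um)
  attr(out, "zernike_fit") <- fit
  out
}
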