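#' Generate a ground-truthed phase phantom
#'
#' Builds a thickness map (in micrometres) of a known test object on the
#' object-plane pixel grid, together with its support mask and exactly
#' integrated volume, so that every downstream reconstruction stage can be
#' validated against a known answer.
#'
#' Three phantom families are provided:
#' \describe{
#'   \item{`sphere`}{a solid sphere of diameter `diameter_um`; the thickness
#'     is the chord function `h(r) = 2 * sqrt((d/2)^2 - r^2)`, mimicking a
#'     silica calibration microsphere.}
#'   \item{`spherical_cap`}{a hemi-ellipsoidal cap (height =
#'     `cap_height_ratio` times the footprint radius), the smooth, rounded
#'     morphology of an adherent unpolarized or M2-like cell.}
#'   \item{`pancake_pseudopodia`}{a flattened ellipsoidal cap (height =
#'     `pancake_height_ratio` times the footprint radius) with
#'     `n_pseudopodia` tapered radial protrusions placed with seeded angular
#'     jitter, emulating the spread, irregular morphology of an activated
#'     (M1-like) cell.}
#' }
#'
#' The raw thickness map is smoothed with a Gaussian blur of
#' `edge_blur_px` pixels before anything else is derived from it: sphere and
#' cap rims otherwise carry unbounded thickness gradients which would make
#' the rendered phase locally undersampled and unwrapping ill-posed. Values
#' below `support_floor_frac` of the blurred maximum are zeroed so the
#' support mask is finite, and the ground-truth volume is the pixel-area
#' weighted sum of the final map (exact by construction). When
#' `target_volume_um3` is given the map is linearly rescaled so its
#' integral hits the target exactly.
#'
#' @param kind phantom family, one of `"sphere"`, `"spherical_cap"`,
#'   `"pancake_pseudopodia"`.
#' @param config an [optical_config()]; sets the object-plane sampling.
#' @param grid_shape integer 2-vector of raster dimensions (even).
#' @param diameter_um sphere diameter (required for `kind = "sphere"`,
#'   default 10).
#' @param target_volume_um3 ground-truth volume to scale the phantom to
#'   (required for the two cell phantoms; optional for the sphere).
#' @param center_um phantom centre in object-plane micrometres; default is
#'   the grid centre.
#' @param cap_height_ratio cap height / footprint radius for
#'   `spherical_cap` (default 0.8).
#' @param pancake_height_ratio body height / footprint radius for
#'   `pancake_pseudopodia` (default 0.3).
#' @param n_pseudopodia number of protrusions (default 5).
#' @param pseudopod_amp protrusion length as a fraction of the footprint
#'   radius (default 0.15).
#' @param seed integer seed for the stochastic pseudopod placement; required
#'   for `pancake_pseudopodia`.
#' @param edge_blur_px Gaussian edge-smoothing sigma in pixels (default 2).
#' @param support_floor_frac relative thickness below which the blurred map
#'   is zeroed (default 0.002).
#' @return an object of class `ground_truth` with elements `thickness_um`
#'   (matrix), `mask` (logical matrix, exactly `thickness_um > 0`),
#'   `volume_um3`, `pixel_um`, `kind`, `center_um` and `params`.
#' @export
#' @examples
#' cfg <- optical_config(n_object = 1.46, n_medium = 1.34)
#' gt <- make_phantom("sphere", cfg, grid_shape = c(256, 256))
#' gt$volume_um3 # ~523.6, the analytic 4/3 * pi * 5^3
make_phantom <- function(kind = c("sphere", "spherical_cap",
                                  "pancake_pseudopodia"),
                         config,
                         grid_shape = c(1024, 1024),
                         diameter_um = if (identical(kind[1], "sphere")) 10 else NULL,
                         target_volume_um3 = NULL,
                         center_um = NULL,
                         cap_height_ratio = 0.8,
                         pancake_height_ratio = 0.3,
                         n_pseudopodia = 5,
                         pseudopod_amp = 0.15,
                         seed = NULL,
                         edge_blur_px = 2,
                         support_floor_frac = 0.002) {
  kind <- match.arg(kind)
  config <- as_optical_config(config)
  stopifnot(length(grid_shape) == 2, all(grid_shape %% 2 == 0),
            all(grid_shape >= 16))
  px <- config$object_pixel_um
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  if (!is.null(target_volume_um3) && target_volume_um3 <= 0)
    stop("target_volume_um3 must be > 0")
  if (is.null(center_um))
    center_um <- c((nr - 1) / 2, (nc - 1) / 2) * px

  x1 <- (seq_len(nr) - 1) * px - center_um[1]
  x2 <- (seq_len(nc) - 1) * px - center_um[2]
  r2 <- outer(x1^2, x2^2, "+")

  h <- switch(kind,
    sphere = {
      if (is.null(diameter_um) || diameter_um <= px)
        stop("sphere diameter_um must exceed one pixel (",
             format(px), " um); got ", format(diameter_um))
      rad <- diameter_um / 2
      2 * sqrt(pmax(rad^2 - r2, 0))
    },
    spherical_cap = {
      if (is.null(target_volume_um3))
        stop("spherical_cap requires target_volume_um3")
      rc <- (3 * target_volume_um3 / (2 * pi * cap_height_ratio))^(1 / 3)
      hc <- cap_height_ratio * rc
      hc * sqrt(pmax(1 - r2 / rc^2, 0))
    },
    pancake_pseudopodia = {
      if (is.null(target_volume_um3))
        stop("pancake_pseudopodia requires target_volume_um3")
      if (is.null(seed))
        stop("pancake_pseudopodia requires a seed for pseudopod placement")
      rc <- (3 * target_volume_um3 / (2 * pi * pancake_height_ratio))^(1 / 3)
      hc <- pancake_height_ratio * rc
      jit <- with_seed(seed, list(
        dphi = stats::runif(n_pseudopodia, -0.3, 0.3),
        damp = stats::runif(n_pseudopodia, 0.7, 1.3)
      ))
      phik <- 2 * pi * (seq_len(n_pseudopodia) - 1) / n_pseudopodia + jit$dphi
      phi <- outer(x1, x2, function(a, b) atan2(b, a))
      bump <- matrix(0, nr, nc)
      for (k in seq_len(n_pseudopodia)) {
        d <- atan2(sin(phi - phik[k]), cos(phi - phik[k]))
        bump <- bump + jit$damp[k] * pseudopod_amp * exp(-0.5 * (d / 0.25)^2)
      }
      rloc <- rc * (1 + bump)
      hc * sqrt(pmax(1 - r2 / rloc^2, 0))
    }
  )

  # grid-fit check: support must keep a >= 10% margin on every side
  supp <- h > 0
  if (!any(supp)) stop("phantom support is empty; increase its size")
  rows <- range(which(rowSums(supp) > 0))
  cols <- range(which(colSums(supp) > 0))
  margin_needed <- 0.1 * c(nr, nc)
  margins <- c(rows[1] - 1, nr - rows[2], cols[1] - 1, nc - cols[2])
  if (any(margins < margin_needed - 1e-9)) {
    ext <- max(rows[2] - rows[1] + 1, cols[2] - cols[1] + 1)
    stop("phantom does not fit the ", nr, " x ", nc,
         " grid with a 10% margin; a grid of at least ",
         2 * ceiling(ext / 0.8 / 2), " pixels per side is required")
  }

  if (edge_blur_px > 0)
    h <- as.matrix(EBImage::gblur(h, sigma = edge_blur_px))
  h[h < support_floor_frac * max(h)] <- 0
  if (!is.null(target_volume_um3))
    h <- h * (target_volume_um3 / (sum(h) * px^2))

  volume <- sum(h) * px^2
  structure(
    list(
      thickness_um = h,
      mask = h > 0,
      volume_um3 = volume,
      pixel_um = px,
      kind = kind,
      center_um = center_um,
      params = list(diameter_um = diameter_um,
                    target_volume_um3 = target_volume_um3,
                    cap_height_ratio = cap_height_ratio,
                    pancake_height_ratio = pancake_height_ratio,
                    n_pseudopodia = n_pseudopodia,
                    pseudopod_amp = pseudopod_amp,
                    seed = seed,
                    edge_blur_px = edge_blur_px,
                    support_floor_frac = support_floor_frac),
      config = config
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$kind, "\n", sep = "")
  cat(sprintf("  grid     %d x %d px (%.4g um/px)\n",
              nrow(x$thickness_um), ncol(x$thickness_um), x$pixel_um))
  cat(sprintf("  volume   %.2f um^3 over %d support pixels\n",
              x$volume_um3, sum(x$mask)))
  cat(sprintf("  max h    %.3f um\n", max(x$thickness_um)))
  invisible(x)
}

#' Convert a thickness map to optical phase
#'
#' Applies the phase-thickness relation of quantitative phase imaging:
#' `phase = 2 * pi * (n_object - n_medium) * h / wavelength`. This is the
#' forward model whose inverse, [phase_to_thickness()], recovers thickness
#' from the compensated phase.
#'
#' @param x a `ground_truth` phantom or a thickness matrix in micrometres.
#' @param config an [optical_config()]; its index contrast and wavelength
#'   set the conversion factor.
#' @return matrix of unwrapped ("wrap-free") phase in radians.
#' @export
#' @examples
#' cfg <- optical_config(n_object = 1.46, n_medium = 1.34)
#' # one full fringe: h = lambda / contrast
#' thickness_to_phase(matrix(0.633 / 0.12, 2, 2), cfg) / (2 * pi)
thickness_to_phase <- function(x, config) {
  config <- as_optical_config(config)
  h <- if (inherits(x, "ground_truth")) x$thickness_um else x
  stopifnot(is.matrix(h), all(is.finite(h)))
  2 * pi * index_contrast(config) * h / config$wavelength_um
}
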