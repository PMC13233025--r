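#' Phase map container
#'
#' A 2-D phase raster in radians with an explicit processing-state flag:
#' `"wrapped"` (values confined to `(-pi, pi]`), `"unwrapped"` (continuous),
#' or `"compensated"` (continuous with flattened background). Stage
#' functions check the state so that, e.g., thickness is never computed from
#' a still-wrapped map.
#'
#' @param data numeric matrix of phase values in radians.
#' @param state one of `"wrapped"`, `"unwrapped"`, `"compensated"`.
#' @param pixel_um object-plane sampling in micrometres.
#' @return object of class `phase_map`.
#' @export
phase_map <- function(data, state = c("wrapped", "unwrapped", "compensated"),
                      pixel_um) {
  state <- match.arg(state)
  stopifnot(is.matrix(data), pixel_um > 0)
  check_finite(data, "phase map")
  if (state == "wrapped") data <- wrap_phase(data)
  structure(list(data = data, state = state, pixel_um = pixel_um),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map> ", nrow(x$data), " x ", ncol(x$data), " px, state: ",
      x$state, "\n", sep = "")
  cat(sprintf("  range [%.3f, %.3f] rad\n", min(x$data), max(x$data)))
  invisible(x)
}

check_state <- function(pm, allowed, fn) {
  if (!inherits(pm, "phase_map"))
    stop(fn, "() expects a phase_map", call. = FALSE)
  if (!pm$state %in% allowed)
    stop(fn, "() requires a phase_map in state ",
         paste(sQuote(allowed), collapse = " or "), ", got ",
         sQuote(pm$state), call. = FALSE)
  invisible(pm)
}

# mean over the 3x3 neighborhood, edges replicated
box3_mean <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2)
    for (dc in 0:2)
      acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
  acc / 9
}

#' Phase quality map
#'
#' Scores each pixel's local phase reliability as
#' `1 / (1 + v)`, where `v` is the variance of the wrapped phase gradients
#' (both axes) over the pixel's 3x3 neighborhood. Smooth regions score near
#' 1; noisy pixels and genuine discontinuities score lower, so the
#' quality-guided unwrapper visits them last.
#'
#' @param wrapped a [phase_map()] in state `"wrapped"`.
#' @return numeric matrix of qualities in `[0, 1]`.
#' @export
quality_map <- function(wrapped) {
  check_state(wrapped, "wrapped", "quality_map")
  x <- wrapped$data
  nr <- nrow(x); nc <- ncol(x)
  gx <- wrap_phase(x[c(2:nr, nr), ] - x)   # forward differences
  gy <- wrap_phase(x[, c(2:nc, nc)] - x)
  gx[nr, ] <- gx[nr - 1, ]                 # replicate the last gradient row
  gy[, nc] <- gy[, nc - 1]                 # (not a zero row) at the border
  vx <- pmax(box3_mean(gx^2) - box3_mean(gx)^2, 0)
  vy <- pmax(box3_mean(gy^2) - box3_mean(gy)^2, 0)
  1 / (1 + vx + vy)
}

#' Quality-guided phase unwrapping
#'
#' Restores the continuous phase surface from a wrapped map by flood fill in
#' descending quality order: starting from the highest-quality pixel
#' (ties broken lexicographically by row then column), pixels are visited
#' through a priority queue and each receives the integer multiple of 2*pi
#' that brings it within pi of its already-unwrapped predecessor. Errors are
#' thereby confined to low-quality regions instead of propagating along scan
#' lines. Every output pixel is congruent to its input modulo 2*pi by
#' construction.
#'
#' @param wrapped a [phase_map()] in state `"wrapped"`.
#' @param quality optional precomputed quality raster; default
#'   [quality_map()] of the input.
#' @return a [phase_map()] in state `"unwrapped"`.
#' @export
unwrap_quality_guided <- function(wrapped, quality = NULL) {
  check_state(wrapped, "wrapped", "unwrap_quality_guided")
  q <- quality %||% quality_map(wrapped)
  stopifnot(identical(dim(q), dim(wrapped$data)))
  out <- .unwrap_qg_cpp(wrapped$data, q)
  phase_map(out, "unwrapped", wrapped$pixel_um)
}
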