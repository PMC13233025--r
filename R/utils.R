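# shared internal helpers

#' Wrap phase into (-pi, pi]
#'
#' Reduces phase values modulo 2*pi into the principal interval, with the
#' branch-point convention that pi maps to pi (not -pi), matching the
#' four-quadrant arctangent used throughout.
#'
#' @param theta numeric vector or matrix of phase values in radians.
#' @return object of the same shape with all values in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(theta) {
  r <- theta %% (2 * pi)
  out <- ifelse(r > pi, r - 2 * pi, r)
  if (is.matrix(theta)) dim(out) <- dim(theta)
  out
}

# run `expr` with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# centered FFT index swap for even-dimension matrices
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((nr / 2 + 1):nr, 1:(nr / 2)), c((nc / 2 + 1):nc, 1:(nc / 2))]
}

ifftshift2 <- fftshift2 # self-inverse for even dimensions

# fft bin frequencies in natural (unshifted) order, cycles per unit
fft_freqs <- function(n, pixel) {
  c(0:(n / 2 - 1), -(n / 2):-1) / (n * pixel)
}

check_even_raster <- function(x, what = "raster") {
  if (!is.matrix(x)) stop(what, " must be a 2-D matrix", call. = FALSE)
  if (any(dim(x) %% 2 != 0))
    stop(what, " must have even dimensions, got ",
         paste(dim(x), collapse = " x "), call. = FALSE)
  invisible(x)
}

check_finite <- function(x, what = "raster") {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# 8-connected labeling (wraps compiled kernel)
label_components <- function(mask) {
  storage.mode(mask) <- "logical"
  .label8_cpp(mask)
}
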