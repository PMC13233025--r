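# shared fixtures; expensive ones are built lazily and cached per test run

silica_config <- function(...) {
  optical_config(n_object = 1.46, n_medium = 1.34, ...)
}

cell_config <- function(...) {
  optical_config(n_object = 1.38, n_medium = 1.33, ...)
}

# 2x2-binned camera: halves the linear problem size of end-to-end runs
# while keeping the optics physical
binned_cell_config <- function() cell_config(camera_pixel_um = 6.9)

.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 10 um silica sphere on a 256 px grid with its true phase
sphere_fixture <- function() fixture("sphere256", {
  cfg <- silica_config()
  gt <- make_phantom("sphere", cfg, grid_shape = c(256, 256))
  list(cfg = cfg, gt = gt, phi = thickness_to_phase(gt, cfg))
})

# default-carrier noise-free reconstruction of the sphere
recon_fixture <- function() fixture("recon256", {
  fx <- sphere_fixture()
  holo <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0)
  spec <- fourier_spectrum(holo)
  field <- filter_plus_one(spec)
  ap <- extract_amplitude_phase(field)
  c(fx, list(holo = holo, spec = spec, field = field,
             wrapped = ap$phase, intensity = ap$intensity))
})

# high-carrier / wide-filter reconstruction: carrier near the separability
# limit so the filter passband covers the sphere's full edge bandwidth;
# used for pixelwise phase-fidelity checks
hires_recon_fixture <- function() fixture("recon256hi", {
  fx <- sphere_fixture()
  carrier <- c(45, 45) / (256 * fx$cfg$object_pixel_um)
  holo <- render_hologram(fx$phi, fx$cfg, carrier_cyc_um = carrier,
                          noise_sigma = 0)
  field <- filter_plus_one(fourier_spectrum(holo), radius_frac = 0.75)
  ap <- extract_amplitude_phase(field)
  c(fx, list(holo = holo, field = field, wrapped = ap$phase))
})

# 5 um sphere on 256 px: a cell-scale object occupying ~5% of the field,
# for phase-level background-compensation tests where the object must be
# separable from low-order background curvature
small_sphere_fixture <- function() fixture("sphere256small", {
  cfg <- silica_config()
  gt <- make_phantom("sphere", cfg, grid_shape = c(256, 256),
                     diameter_um = 5)
  list(cfg = cfg, gt = gt, phi = thickness_to_phase(gt, cfg))
})

# band-limited random complex field (evanescent-free by construction)
band_limited_field <- function(n = 128, seed = 1, config = silica_config()) {
  set.seed(seed)
  z <- matrix(complex(real = stats::rnorm(n^2), imaginary = stats::rnorm(n^2)),
              n, n)
  Z <- stats::fft(z)
  b <- c(0:(n / 2 - 1), -(n / 2):-1)
  keep <- outer(b^2, b^2, "+") <= (n / 16)^2
  u <- stats::fft(Z * keep, inverse = TRUE) / n^2
  complex_field(matrix(u, n, n), config$object_pixel_um, 0, config)
}

# compensated thickness + segmentation from a hologram, as the pipeline
# chains the stages
thickness_from_hologram <- function(holo, config) {
  field <- filter_plus_one(fourier_spectrum(holo))
  uw <- unwrap_quality_guided(extract_amplitude_phase(field)$phase)
  obj <- object_mask_from_amplitude(field)
  if (sum(!obj) < 0.25 * length(obj)) obj <- NULL
  comp <- compensate_background(uw, augment_mask = obj)
  suppressMessages(phase_to_thickness(comp, config))
}
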