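test_that("a flat-phase hologram is a pure two-beam fringe pattern", {
  cfg <- silica_config()
  holo <- render_hologram(matrix(0, 128, 128), cfg, noise_sigma = 0)
  expect_true(all(holo$intensity >= 0))
  S <- Mod(fourier_spectrum(holo)$data)
  ord <- order(S, decreasing = TRUE)
  # exactly three significant peaks: DC and the two conjugate carriers
  expect_gt(S[ord[3]], 1e6 * S[ord[4]])
  k <- which(S == max(S), arr.ind = TRUE)
  expect_equal(unname(k[1, ]), c(65, 65)) # DC at n/2 + 1
})

test_that("rendering is deterministic for a fixed seed", {
  fx <- sphere_fixture()
  a <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0.02, seed = 9)
  b <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0.02, seed = 9)
  c <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0.02, seed = 10)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
  # noiseless renders are bit-identical without any seed
  d <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0)
  e <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0)
  expect_identical(d$intensity, e$intensity)
})

test_that("noise requires a seed and intensities are clipped at zero", {
  fx <- sphere_fixture()
  expect_error(render_hologram(fx$phi, fx$cfg, noise_sigma = 0.05),
               "seed is required")
  h <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0.5, seed = 1)
  expect_true(all(h$intensity >= 0))
})

test_that("inadmissible carriers are rejected with the admissible maximum", {
  fx <- sphere_fixture()
  fs <- 1 / fx$cfg$object_pixel_um
  expect_error(render_hologram(fx$phi, fx$cfg, noise_sigma = 0,
                               carrier_cyc_um = c(fs / 4, fs / 4)),
               "maximum admissible magnitude")
})

test_that("the +1 sideband dominates all non-DC, non-sideband bins", {
  fx <- recon_fixture()
  S <- Mod(fx$spec$data)
  n <- 256
  k1 <- matrix(seq_len(n) - (n / 2 + 1), n, n)
  k2 <- t(k1)
  near <- function(c1, c2, r) (k1 - c1)^2 + (k2 - c2)^2 <= r^2
  # spectral regions: DC, +-1 orders (carrier at 32,32 bins), each with the
  # default filter radius around them
  r <- 0.5 * sqrt(2) * 32
  peak <- max(S[near(32, 32, 2)])
  elsewhere <- S[!near(0, 0, r) & !near(32, 32, r) & !near(-32, -32, r)]
  expect_gt(peak, 10 * max(elsewhere))
})

test_that("time series rendering preserves volume order and validates", {
  cfg <- binned_cell_config()
  expect_error(render_timeseries(numeric(0), cfg), "at least one")
  expect_error(render_timeseries(c(100, -5), cfg), "volumes must be > 0")
  one <- render_timeseries(1500, cfg, grid_shape = c(256, 256),
                           noise_sigma = 0, seed = 1)
  expect_length(one$holograms, 1)
  vols <- c(2531.60, 2374.27, 2328.13, 2230.26, 2063.68, 2020.04)
  sim <- render_timeseries(vols, cfg, grid_shape = c(256, 256),
                           times_min = c(0, 15, 20, 30, 50, 60),
                           noise_sigma = 0, seed = 1)
  gt_vols <- vapply(sim$ground_truths, `[[`, numeric(1), "volume_um3")
  expect_equal(gt_vols, vols, tolerance = 1e-9)
  expect_true(all(diff(gt_vols) < 0))
})
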