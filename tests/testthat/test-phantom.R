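test_that("optical config derives the object-plane sampling and validates", {
  cfg <- silica_config()
  expect_equal(cfg$object_pixel_um, cfg$camera_pixel_um / cfg$magnification,
               tolerance = 1e-12)
  expect_equal(cfg$object_pixel_um, 0.0575)
  expect_error(optical_config(n_object = 1.30, n_medium = 1.34),
               "contrast")
  expect_error(optical_config(n_object = 1.38, n_medium = 0.9), "n_medium")
  expect_error(optical_config(wavelength_um = -1, n_object = 1.4,
                              n_medium = 1.33), "wavelength")
})

test_that("sphere phantom integrates to the analytic chord volume", {
  fx <- sphere_fixture()
  v_analytic <- 4 / 3 * pi * 5^3
  expect_equal(fx$gt$volume_um3, v_analytic, tolerance = 0.005)
  # center thickness equals the diameter (slightly reduced by edge blur)
  expect_equal(max(fx$gt$thickness_um), 10, tolerance = 0.02)
  # chord profile: thickness at r = 3 um is 2*sqrt(25 - 9) = 8 um
  ctr <- (dim(fx$gt$thickness_um) + 1) / 2
  r_px <- 3 / fx$cfg$object_pixel_um
  expect_equal(fx$gt$thickness_um[round(ctr[1] + r_px), round(ctr[2])],
               8, tolerance = 0.02)
})

test_that("phantom ground truth satisfies its own volume/mask contract", {
  cfg <- cell_config()
  for (gt in list(sphere_fixture()$gt,
                  make_phantom("spherical_cap", binned_cell_config(),
                               c(256, 256), target_volume_um3 = 970.54),
                  make_phantom("pancake_pseudopodia", binned_cell_config(),
                               c(512, 512), target_volume_um3 = 3822,
                               seed = 1))) {
    expect_equal(sum(gt$thickness_um[gt$mask]) * gt$pixel_um^2,
                 gt$volume_um3, tolerance = 1e-9)
    expect_true(all(gt$mask[gt$thickness_um > 0]))
  }
})

test_that("cap and pancake phantoms hit their target volume exactly", {
  gt <- make_phantom("spherical_cap", binned_cell_config(), c(256, 256),
                     target_volume_um3 = 970.54)
  expect_equal(gt$volume_um3, 970.54, tolerance = 1e-9)
  gt2 <- make_phantom("pancake_pseudopodia", binned_cell_config(),
                      c(512, 512), target_volume_um3 = 3822, seed = 7)
  expect_equal(gt2$volume_um3, 3822, tolerance = 1e-9)
})

test_that("degenerate and oversized phantoms are rejected", {
  cfg <- silica_config()
  expect_error(make_phantom("sphere", cfg, c(256, 256), diameter_um = 0.01),
               "exceed one pixel")
  expect_error(make_phantom("sphere", cfg, c(64, 64)), "grid of at least")
  expect_error(make_phantom("spherical_cap", cfg, c(256, 256),
                            target_volume_um3 = -5), "must be > 0")
  expect_error(make_phantom("spherical_cap", cfg, c(256, 256)),
               "requires target_volume_um3")
  expect_error(make_phantom("spherical_cap", cell_config(), c(256, 256),
                            target_volume_um3 = 970.54), "grid of at least")
})

test_that("pancake pseudopod jitter is seeded and deterministic", {
  cfg <- binned_cell_config()
  a <- make_phantom("pancake_pseudopodia", cfg, c(512, 512),
                    target_volume_um3 = 3000, seed = 4)
  b <- make_phantom("pancake_pseudopodia", cfg, c(512, 512),
                    target_volume_um3 = 3000, seed = 4)
  c <- make_phantom("pancake_pseudopodia", cfg, c(512, 512),
                    target_volume_um3 = 3000, seed = 5)
  expect_identical(a$thickness_um, b$thickness_um)
  expect_false(identical(a$thickness_um, c$thickness_um))
})

test_that("thickness-to-phase conversion matches the fringe relation", {
  cfg <- optical_config(n_object = 1.39, n_medium = 1.34) # contrast 0.05
  # one full fringe: h = lambda / contrast = 12.66 um -> 2*pi
  expect_equal(thickness_to_phase(matrix(0.633 / 0.05, 2, 2), cfg),
               matrix(2 * pi, 2, 2))
  expect_equal(thickness_to_phase(matrix(0, 4, 4), cfg), matrix(0, 4, 4))
  # sphere peak: 2*pi * 0.12 * 10 / 0.633, evaluated independently
  fx <- sphere_fixture()
  expect_equal(max(fx$phi), 2 * pi * (1.46 - 1.34) * max(fx$gt$thickness_um) /
                 0.633, tolerance = 1e-12)
  expect_equal(max(fx$phi), 11.913, tolerance = 0.01)
})

test_that("phantom edges stay unwrappable after edge smoothing", {
  fx <- sphere_fixture()
  gx <- abs(diff(fx$phi))
  gy <- abs(t(diff(t(fx$phi))))
  expect_lt(max(gx, gy), pi)
})
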