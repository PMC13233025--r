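test_that("a pure tilt plane is fitted by the tilt terms alone", {
  n <- 100
  x <- matrix(seq(-1, 1, length.out = n), n, n) # varies along dim 1
  pm <- phase_map(2.5 * x, "unwrapped", 1)
  fit <- fit_zernike_background(pm, order = 4)
  tilt <- abs(fit$coeffs["Z2"]) # OSA j=2: cos tilt along the first axis
  others <- abs(fit$coeffs[setdiff(names(fit$coeffs), "Z2")])
  expect_gt(tilt, 1)
  expect_lt(max(others), 1e-8 * tilt)
  expect_lt(fit$rms_residual, 1e-8)
})

test_that("zero phase fits to zero coefficients", {
  fit <- fit_zernike_background(phase_map(matrix(0, 64, 64), "unwrapped", 1))
  expect_lt(max(abs(fit$coeffs)), 1e-10)
  expect_lt(fit$rms_residual, 1e-10)
})

test_that("an injected defocus coefficient of 2.0 is recovered", {
  co <- rep(0, 15)
  co[5] <- 2 # OSA j=4: defocus
  surf <- zernike_surface(co, c(128, 128))
  fit <- fit_zernike_background(phase_map(surf, "unwrapped", 1),
                                exclude_mask = matrix(FALSE, 128, 128),
                                order = 4)
  expect_equal(unname(fit$coeffs["Z4"]), 2, tolerance = 1e-6)
})

test_that("the reconstructed fit reproduces its stated rms residual", {
  set.seed(8)
  x <- zernike_surface(stats::runif(15, -1, 1), c(96, 96)) +
    matrix(stats::rnorm(96^2, sd = 0.1), 96, 96)
  pm <- phase_map(x, "unwrapped", 1)
  fit <- fit_zernike_background(pm, order = 4)
  resid <- (x - zernike_surface(fit))[fit$fitted_mask]
  expect_equal(sqrt(mean(resid^2)), fit$rms_residual, tolerance = 1e-9)
})

test_that("fit residual is non-increasing in the radial order", {
  set.seed(9)
  x <- zernike_surface(stats::runif(10, -2, 2), c(96, 96)) +
    matrix(stats::rnorm(96^2, sd = 0.3), 96, 96)
  pm <- phase_map(x, "unwrapped", 1)
  rms <- vapply(0:5, function(o)
    fit_zernike_background(pm, order = o)$rms_residual, numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("excessive exclusion is rejected as insufficient background", {
  m <- matrix(TRUE, 64, 64)
  m[1:10, 1:10] <- FALSE
  expect_error(
    fit_zernike_background(phase_map(matrix(1, 64, 64), "unwrapped", 1),
                           exclude_mask = m),
    "insufficient background")
})

test_that("a known aberration over a flat field compensates to ~ zero", {
  co <- c(0.3, -1, 2, 1.5, -0.6, 0.4, 0.2, -0.2, 0.1, 0.3, -0.1, 0.2,
          0.15, -0.25, 0.1)
  pm <- phase_map(zernike_surface(co, c(192, 192)), "unwrapped", 0.0575)
  comp <- compensate_background(pm)
  expect_lt(sqrt(mean(comp$data^2)), 0.02)
  expect_equal(comp$state, "compensated")
})

test_that("zero input compensates to zero output", {
  comp <- compensate_background(phase_map(matrix(0, 96, 96), "unwrapped", 1))
  expect_equal(comp$data, matrix(0, 96, 96))
})

test_that("compensation is idempotent", {
  fx <- small_sphere_fixture()
  pm <- phase_map(fx$phi + zernike_surface(c(0.5, -0.3, 0.8, 1.2, -0.4, 0.2),
                                           dim(fx$phi)),
                  "unwrapped", fx$cfg$object_pixel_um)
  c1 <- compensate_background(pm)
  c2 <- compensate_background(c1)
  expect_lt(sqrt(mean((c2$data - c1$data)^2)), 0.01)
})

test_that("compensation preserves the object's phase content", {
  # aberration-free sphere: the integrated object phase moves by < 2%
  fx <- sphere_fixture()
  pm <- phase_map(fx$phi, "unwrapped", fx$cfg$object_pixel_um)
  comp <- compensate_background(pm)
  expect_equal(sum(comp$data[fx$gt$mask]), sum(fx$phi[fx$gt$mask]),
               tolerance = 0.02)
})

test_that("oversized median kernels are rejected", {
  pm <- phase_map(matrix(0, 32, 32), "unwrapped", 1)
  expect_error(compensate_background(pm, median_kernel_px = 51),
               "exceeds the raster")
  expect_error(compensate_background(pm, median_kernel_px = 10),
               "odd integer")
})

test_that("random aberrations over a phantom flatten below 0.05 rad rms", {
  # the recovery property at a reduced problem size (cell-scale object on
  # 256 px, 4 seeds); the acceptance suite runs 10 seeds at 512 px
  fx <- small_sphere_fixture()
  set.seed(10)
  for (i in 1:4) {
    co <- stats::runif(15, -3, 3)
    pm <- phase_map(fx$phi + zernike_surface(co, dim(fx$phi)),
                    "unwrapped", fx$cfg$object_pixel_um)
    comp <- compensate_background(pm)
    expect_lt(sqrt(mean(comp$data[!fx$gt$mask]^2)), 0.05)
    expect_equal(sum(comp$data[fx$gt$mask]), sum(fx$phi[fx$gt$mask]),
                 tolerance = 0.02)
  }
})

test_that("zernike tidiers expose terms and fit quality", {
  fit <- fit_zernike_background(
    phase_map(zernike_surface(rep(0.1, 6), c(64, 64)), "unwrapped", 1),
    order = 2)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 6)
  expect_equal(td$n, c(0, 1, 1, 2, 2, 2))
  expect_equal(td$m, c(0, -1, 1, -2, 0, 2))
  gl <- generics::glance(fit)
  expect_equal(gl$n_terms, 6)
  expect_lt(gl$rms_residual, 1e-8)
})
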