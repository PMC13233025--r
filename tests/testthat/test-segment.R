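test_that("dual thresholds follow the chord geometry of a sphere", {
  # analytic (unblurred) chord map: seed at h >= 5 um has radius
  # sqrt(3)/2 of the support radius
  px <- 0.0575
  xx <- ((1:256) - 128.5) * px
  h <- 2 * sqrt(pmax(25 - outer(xx^2, xx^2, "+"), 0))
  dt <- dual_threshold(h, segmentation_params(low_thresh_um = 1e-9))
  expect_true(all(dt$boundary[dt$seed]))
  expect_equal(sqrt(sum(dt$seed) / sum(dt$boundary)), sqrt(3) / 2,
               tolerance = 0.01)
  expect_equal(dt$high_thresh_um, 5, tolerance = 0.01)
})

test_that("uniform rasters give seed = boundary = everything", {
  dt <- dual_threshold(matrix(2, 32, 32), segmentation_params())
  expect_true(all(dt$seed) && all(dt$boundary))
})

test_that("all-zero thickness maps are an empty-field error", {
  expect_error(dual_threshold(matrix(0, 16, 16)), "empty field")
})

test_that("morphological reconstruction keeps seeded components only", {
  b <- matrix(FALSE, 64, 64)
  b[10:30, 10:30] <- TRUE  # blob A
  b[45:55, 45:55] <- TRUE  # blob B (noise)
  s <- matrix(FALSE, 64, 64)
  s[18:22, 18:22] <- TRUE  # seed inside A only
  cm <- reconstruct_by_dilation(s, b)
  expect_equal(cm$n_components, 1)
  expect_true(all(cm$mask[10:30, 10:30]))
  expect_false(any(cm$mask[45:55, 45:55]))
  expect_error(reconstruct_by_dilation(b, s), "subset")
})

test_that("seeded reconstruction isolates the phantom from noise specks", {
  fx <- sphere_fixture()
  set.seed(12)
  noisy <- fx$gt$thickness_um
  specks <- matrix(stats::runif(length(noisy)) < 0.001, 256, 256)
  noisy[specks] <- pmax(noisy[specks], 0.5)
  dt <- dual_threshold(noisy, segmentation_params(low_thresh_um = 0.05))
  cm <- clean_mask(reconstruct_by_dilation(dt$seed, dt$boundary),
                   segmentation_params())
  iou <- sum(cm$mask & fx$gt$mask) / sum(cm$mask | fx$gt$mask)
  expect_gt(iou, 0.9)
  expect_equal(cm$n_components, 1)
})

test_that("mask cleaning removes specks, fills holes, and is idempotent", {
  m <- matrix(FALSE, 96, 96)
  m[20:70, 20:70] <- TRUE
  m[40:42, 40:42] <- FALSE           # 3x3 interior hole
  m[5, 5] <- m[90, 90] <- m[5, 90] <- TRUE # 1-px specks
  cm <- clean_mask(m, segmentation_params())
  expect_equal(cm$n_components, 1)
  expect_true(all(cm$mask[40:42, 40:42]))  # hole filled
  expect_false(cm$mask[5, 5])
  cm2 <- clean_mask(cm, segmentation_params())
  expect_identical(cm2$mask, cm$mask)
})

test_that("raising the low threshold never grows the final mask", {
  fx <- sphere_fixture()
  areas <- vapply(c(0.02, 0.1, 0.5, 1, 2), function(lt)
    sum(segment_cells(fx$gt$thickness_um,
                      segmentation_params(low_thresh_um = lt))$mask),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("pipeline segmentation reaches the ground-truth IoU targets", {
  fx <- sphere_fixture()
  # noise-free
  holo0 <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0)
  h0 <- thickness_from_hologram(holo0, fx$cfg)
  m0 <- segment_cells(h0)$mask
  expect_gt(sum(m0 & fx$gt$mask) / sum(m0 | fx$gt$mask), 0.95)
  # default noise, several seeds (acceptance runs more)
  for (s in 1:5) {
    holo <- render_hologram(fx$phi, fx$cfg, noise_sigma = 0.01, seed = s)
    h <- thickness_from_hologram(holo, fx$cfg)
    m <- segment_cells(h)$mask
    expect_gt(sum(m & fx$gt$mask) / sum(m | fx$gt$mask), 0.90)
  }
})

test_that("cell_mask reports 8-connected components and areas", {
  m <- matrix(FALSE, 16, 16)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch: one component
  m[10:12, 10:12] <- TRUE
  cm <- cell_mask(m)
  expect_equal(cm$n_components, 2)
  expect_setequal(cm$areas_px, c(2, 9))
})
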