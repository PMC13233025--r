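test_that("phase converts to thickness by the fringe relation", {
  cfg <- optical_config(n_object = 1.38, n_medium = 1.33) # contrast 0.05
  pm <- phase_map(matrix(2 * pi, 4, 4), "compensated", 0.0575)
  h <- phase_to_thickness(pm, cfg)
  expect_equal(unclass(h)[1, 1], 0.633 / 0.05) # 12.66 um per fringe
  pm0 <- phase_map(matrix(0, 4, 4), "compensated", 0.0575)
  expect_true(all(phase_to_thickness(pm0, cfg) == 0))
  # state guard: wrapped maps cannot be converted
  pmw <- phase_map(matrix(0.5, 4, 4), "wrapped", 0.0575)
  expect_error(phase_to_thickness(pmw, cfg), "requires a phase_map")
})

test_that("negative phases clip to zero with a reported count", {
  cfg <- cell_config()
  pm <- phase_map(matrix(c(-0.2, 0.4, -0.1, 1), 2, 2), "compensated", 1)
  expect_message(h <- phase_to_thickness(pm, cfg), "clipped 2")
  expect_equal(attr(h, "clipped_px"), 2)
  expect_true(all(h >= 0))
})

test_that("sphere thickness round-trips through phase and back", {
  fx <- sphere_fixture()
  pm <- phase_map(fx$phi, "compensated", fx$cfg$object_pixel_um)
  h <- phase_to_thickness(pm, fx$cfg)
  expect_lt(max(abs(h - fx$gt$thickness_um)), 0.05)
})

test_that("cell volume is an exact Riemann sum with exact properties", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE
  h <- matrix(0, 20, 20); h[m] <- 1
  v <- cell_volume(h, m, 0.1)
  expect_equal(v$volume_um3, 100 * 0.01 * 1) # 1.0 um^3
  # linearity
  expect_equal(cell_volume(3.7 * h, m, 0.1)$volume_um3, 3.7 * v$volume_um3)
  # additivity over disjoint components
  m[15:18, 15:18] <- TRUE
  h[15:18, 15:18] <- 2
  v2 <- cell_volume(h, m, 0.1)
  expect_equal(sum(v2$volume_um3),
               sum(h[m]) * 0.01)
  expect_equal(nrow(v2), 2)
  # empty mask: zero volume
  v0 <- cell_volume(h, matrix(FALSE, 20, 20), 0.1)
  expect_equal(nrow(v0), 0)
  expect_equal(sum(v0$volume_um3), 0)
  # shape mismatch
  expect_error(cell_volume(h, matrix(TRUE, 4, 4), 0.1), "dimensions differ")
})

test_that("circularity matches closed forms for disks and squares", {
  m <- matrix(FALSE, 128, 128)
  disk <- (row(m) - 64.5)^2 + (col(m) - 64.5)^2 <= 50^2
  cd <- shape_descriptors(matrix(1, 128, 128), disk, 0.1)$circularity
  expect_gt(cd, 0.95); expect_lt(cd, 1.05)
  sq <- matrix(FALSE, 140, 140); sq[21:120, 21:120] <- TRUE
  cs <- shape_descriptors(matrix(1, 140, 140), sq, 0.1)$circularity
  expect_equal(cs, pi / 4, tolerance = 0.05 / (pi / 4))
})

test_that("caps are more spherical than equal-volume pancakes", {
  cfg <- binned_cell_config()
  g1 <- make_phantom("spherical_cap", cfg, c(512, 512),
                     target_volume_um3 = 2000)
  g2 <- make_phantom("pancake_pseudopodia", cfg, c(512, 512),
                     target_volume_um3 = 2000, seed = 3)
  s1 <- shape_descriptors(g1$thickness_um, g1$mask, g1$pixel_um)
  s2 <- shape_descriptors(g2$thickness_um, g2$mask, g2$pixel_um)
  expect_gt(s1$sphericity, s2$sphericity)
  expect_gt(s1$circularity, s2$circularity)
  for (s in c(s1$sphericity, s2$sphericity, s1$circularity, s2$circularity)) {
    expect_gt(s, 0); expect_lte(s, 1.1)
  }
})

test_that("tiny components yield NA descriptors with a message", {
  m <- matrix(FALSE, 32, 32); m[5:6, 5:6] <- TRUE
  expect_message(s <- shape_descriptors(matrix(1, 32, 32), m, 0.1),
                 "fewer than 16 px")
  expect_true(is.na(s$circularity))
})

test_that("a death-like series is monotone with all-negative slopes", {
  vols <- c(2531.60, 2374.27, 2328.13, 2230.26, 2063.68, 2020.04)
  t <- c(0, 15, 20, 30, 50, 60)
  rec <- tibble::tibble(t_min = t, cell_id = 1L, volume_um3 = vols,
                        centroid_x_um = 30, centroid_y_um = 30)
  vs <- analyze_series(rec)
  expect_true(vs$summary$monotone_decreasing)
  expect_true(all(vs$slopes$dV_dt_um3_per_min < 0))
  expect_equal(nrow(vs$slopes), length(vols) - 1)
})

test_that("a constant series has zero slopes and a single slow stage", {
  rec <- tibble::tibble(t_min = c(0, 10, 20), cell_id = 1L,
                        volume_um3 = 1500, centroid_x_um = 10,
                        centroid_y_um = 10)
  vs <- analyze_series(rec)
  expect_true(all(vs$slopes$dV_dt_um3_per_min == 0))
  expect_true(all(vs$slopes$stage == "slow"))
  expect_false(vs$summary$monotone_decreasing)
})

test_that("a division-like rise-then-fall flags the peak", {
  vols <- c(3375.43, 2890.84, 3481.43, 2042.90)
  rec <- tibble::tibble(t_min = c(0, 10, 40, 120), cell_id = 1L,
                        volume_um3 = vols, centroid_x_um = 25,
                        centroid_y_um = 25)
  vs <- analyze_series(rec)
  expect_equal(vs$summary$peak_t_min, 40)
  expect_equal(vs$summary$peak_volume_um3, 3481.43)
})

test_that("ambiguous associations are an error naming the candidates", {
  rec <- tibble::tibble(
    t_min = c(0, 10, 10),
    cell_id = c(1L, 1L, 2L),
    volume_um3 = c(1000, 990, 1010),
    centroid_x_um = c(20, 22, 18),
    centroid_y_um = c(20, 20, 20))
  expect_error(analyze_series(rec), "ambiguous association")
  expect_error(analyze_series(rec[1, ]), "at least 2 time points")
})

test_that("series tidiers return slopes and per-track summaries", {
  rec <- tibble::tibble(t_min = c(0, 10, 20), cell_id = 1L,
                        volume_um3 = c(1000, 1100, 1500),
                        centroid_x_um = 10, centroid_y_um = 10)
  vs <- analyze_series(rec)
  expect_equal(generics::tidy(vs), vs$slopes)
  expect_equal(generics::glance(vs), vs$summary)
  expect_equal(generics::tidy(vs)$stage, c("slow", "rapid"))
})
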