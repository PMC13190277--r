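test_that("trapezoid boundaries are recovered exactly without smoothing", {
  p <- simulate_ais_profile(start_um = 5, plateau_um = 20, edge_um = 1)
  b <- detect_ais_bounds(p, smooth_window_um = 0)
  truth <- attr(p, "truth")
  expect_equal(b$start_um, truth$start_um, tolerance = 1e-9)
  expect_equal(b$end_um, truth$end_um, tolerance = 1e-9)
  expect_equal(b$length_um, 21.34, tolerance = 1e-9)
})

test_that("rectangular profiles are measured to within the sampling step", {
  p <- simulate_ais_profile(plateau_um = 20, edge_um = 0, dx_um = 0.1)
  b <- detect_ais_bounds(p, smooth_window_um = 0)
  expect_lt(abs(b$length_um - 20), 0.1)
})

test_that("bounds are invariant under positive intensity scaling", {
  set.seed(31)
  for (k in 1:200) {
    p <- simulate_ais_profile(start_um = runif(1, 2, 10),
                              plateau_um = runif(1, 8, 35),
                              edge_um = runif(1, 0.2, 4),
                              f_max = runif(1, 100, 5000),
                              dx_um = 0.1)
    scale <- exp(runif(1, -3, 3))
    ps <- fluorescence_profile(p$arc_length_um, p$intensity * scale)
    b1 <- detect_ais_bounds(p, smooth_window_um = 0)
    b2 <- detect_ais_bounds(ps, smooth_window_um = 0)
    expect_equal(b1$start_um, b2$start_um, tolerance = 1e-9)
    expect_equal(b1$end_um, b2$end_um, tolerance = 1e-9)
  }
})

test_that("noiseless boundary error stays within the sampling step", {
  set.seed(32)
  for (k in 1:50) {
    dx <- sample(c(0.05, 0.1, 0.2), 1)
    p <- simulate_ais_profile(start_um = runif(1, 3, 8),
                              plateau_um = runif(1, 10, 30),
                              edge_um = runif(1, 0.5, 3), dx_um = dx)
    b <- detect_ais_bounds(p, smooth_window_um = 0)
    truth <- attr(p, "truth")
    expect_lt(abs(b$start_um - truth$start_um), dx)
    expect_lt(abs(b$end_um - truth$end_um), dx)
  }
})

test_that("boundary recovery at SNR 10 stays within half a micron", {
  errs <- vapply(1:200, function(r) {
    p <- simulate_ais_profile(start_um = 5, plateau_um = 20, edge_um = 1,
                              f_max = 1000, noise_sd = 100, seed = 600 + r)
    b <- detect_ais_bounds(p)   # default 1 um smoothing
    truth <- attr(p, "truth")
    max(abs(b$start_um - truth$start_um), abs(b$end_um - truth$end_um))
  }, 0)
  expect_lt(mean(errs), 0.5)
  expect_gt(mean(errs > 0), 0)   # noise does move the boundaries
})

test_that("profiles that never reach the threshold are flagged no-AIS", {
  flat <- fluorescence_profile(seq(0, 10, 0.1), rep(5, 101))
  b <- detect_ais_bounds(flat, smooth_window_um = 0)
  expect_true(b$no_ais)
  expect_true(is.na(b$length_um))
})

test_that("baseline offsets are removed before thresholding", {
  p0 <- simulate_ais_profile(start_um = 5, plateau_um = 20, edge_um = 1)
  p_off <- fluorescence_profile(p0$arc_length_um, p0$intensity + 300)
  b0 <- detect_ais_bounds(p0, smooth_window_um = 0)
  boff <- detect_ais_bounds(p_off, smooth_window_um = 0)
  expect_equal(boff$start_um, b0$start_um, tolerance = 0.05)
  expect_equal(boff$end_um, b0$end_um, tolerance = 0.05)
})

test_that("image sampling reproduces painted intensities", {
  # vertical bright band: columns 20 um wide at 1000, background 10
  px <- 0.2
  img <- matrix(10, nrow = 200, ncol = 200)
  img[, 60:160] <- 1000                    # x in [11.8, 32.0] um approx
  poly <- cbind(c(2, 38), c(20, 20))       # horizontal trace at y = 20 um
  prof <- sample_profile_from_image(img, poly, pixel_size_um = px,
                                    spacing_um = 0.1)
  expect_s3_class(prof, "fluorescence_profile")
  expect_equal(max(prof$intensity), 1000)
  expect_equal(min(prof$intensity), 10)
  # constant image -> constant profile
  cimg <- matrix(7, 50, 50)
  cprof <- sample_profile_from_image(cimg, cbind(c(1, 8), c(4, 4)),
                                     pixel_size_um = px)
  expect_true(all(cprof$intensity == 7))
  # single-point polyline and out-of-bounds tracing are errors
  expect_error(sample_profile_from_image(img, cbind(2, 20)), "two points")
  expect_error(sample_profile_from_image(img, cbind(c(-5, 40), c(20, 20)),
                                         pixel_size_um = px), "bounds")
})

test_that("detected band width matches the painted band", {
  px <- 0.2
  img <- matrix(0, nrow = 200, ncol = 200)
  img[, 60:160] <- 1000
  poly <- cbind(c(2, 38), c(20, 20))
  prof <- sample_profile_from_image(img, poly, pixel_size_um = px)
  b <- detect_ais_bounds(prof, smooth_window_um = 0,
                         baseline_flank_fraction = 0)
  # band spans 101 pixels = 20.2 um (bilinear edges add < 1 pixel)
  expect_equal(b$length_um, 20.2, tolerance = 0.3)
})

test_that("distance from soma is a signed difference with overlap flag", {
  expect_equal(distance_from_soma(5, 8.78), 3.78)
  expect_equal(distance_from_soma(5, 5), 0)
  d <- distance_from_soma(5, 3)
  expect_equal(as.numeric(d), -2)
  expect_true(attr(d, "overlap"))
})

test_that("per-stratum aggregation averages cells and flags small strata", {
  dat <- data.frame(
    animal_id = c("m1", "m1", "m1", "m1", "m2"),
    group = "stroke", sex = "male",
    hemisphere = c("contralesional", "contralesional", "contralesional",
                   "ipsilesional", "contralesional"),
    layer = c("L2/3", "L2/3", "L2/3", "L2/3", "L5"),
    value = c(20, 21, 22, 30, 25))
  agg <- aggregate_per_stratum(dat, min_n = 2)
  r1 <- agg[agg$animal_id == "m1" & agg$hemisphere == "contralesional", ]
  expect_equal(r1$mean_value, 21)
  expect_equal(r1$n_cells, 3)
  expect_false(r1$below_min_n)
  r2 <- agg[agg$animal_id == "m2", ]
  expect_true(r2$below_min_n)
  # grand mean of stratum means matches a brute-force group-by
  brute <- tapply(dat$value,
                  interaction(dat$animal_id, dat$hemisphere, dat$layer,
                              drop = TRUE), mean)
  expect_equal(sort(agg$mean_value), sort(as.numeric(brute)))
  expect_equal(nrow(agg), length(brute))   # empty strata absent
})

test_that("lesion volume follows the thickness/series formula and is additive", {
  expect_equal(lesion_volume(lesion_series(1e6)), 0.09)
  expect_equal(lesion_volume(lesion_series(numeric(0))), 0)
  a <- c(5e5, 8e5, 1.2e6, 3e5)
  v_all <- lesion_volume(lesion_series(a))
  v_split <- lesion_volume(lesion_series(a[1:2])) +
    lesion_volume(lesion_series(a[3:4]))
  expect_equal(v_all, v_split)
  expect_equal(lesion_volume(lesion_series(2 * a)), 2 * v_all)
  expect_error(lesion_series(-1), "non-negative")
  expect_error(lesion_series(1e6, series_factor = 2.5), "integer")
})

test_that("3D path length dominates its 2D projection", {
  # pure z segment: projection has zero length
  z <- cbind(c(0, 0), c(0, 0), c(0, 10))
  expect_equal(compare_projection_length(z)$length2d_um, 0)
  expect_equal(compare_projection_length(z)$length3d_um, 10)
  # planar path: equal lengths
  pl <- cbind(c(0, 3, 7), c(0, 4, 1), c(2, 2, 2))
  cp <- compare_projection_length(pl)
  expect_equal(cp$length3d_um, cp$length2d_um)
  # helix: 3D strictly longer, matching the arc-length integral
  t <- seq(0, 4 * pi, length.out = 2000)
  r <- 5; pitch <- 2
  helix <- cbind(r * cos(t), r * sin(t), pitch * t)
  ch <- compare_projection_length(helix)
  expect_gt(ch$length3d_um, ch$length2d_um)
  expect_equal(ch$length3d_um, sqrt(r^2 + pitch^2) * 4 * pi,
               tolerance = 1e-4)
  expect_equal(ch$length2d_um, r * 4 * pi, tolerance = 1e-4)
  # property: never shorter in 3D, random paths
  set.seed(41)
  for (k in 1:50) {
    p <- matrix(rnorm(30), ncol = 3)
    cpk <- compare_projection_length(p)
    expect_gte(cpk$length3d_um, cpk$length2d_um)
  }
})
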