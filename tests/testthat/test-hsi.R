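# Hyperspectral cubes, intensity maps, localization and depth lookup.

test_that("ENVI round trip is lossless and interleave-independent", {
  set.seed(4)
  cb <- hsi_cube(array(round(runif(8 * 8 * 16) * 1000), c(8, 8, 16)),
                 (0:7) * 5, (0:7) * 5, 500 + (0:15) * 0.1)
  f1 <- tempfile(); f2 <- tempfile()
  write_envi(cb, f1, "bsq", data_type = 12)
  write_envi(cb, f2, "bil", data_type = 12)
  r1 <- read_envi(f1); r2 <- read_envi(f2)
  expect_identical(r1$data, r2$data)
  expect_equal(r1$data, cb$data)                 # bit-exact integer counts
  expect_equal(r1$wavelength_nm, cb$wavelength_nm)
  expect_equal(r1$x_um, cb$x_um)
})

test_that("a header without wavelengths is rejected by name", {
  cb <- hsi_cube(array(1, c(2, 2, 3)), 0:1, 0:1, 1:3)
  f <- tempfile()
  write_envi(cb, f)
  hdr <- readLines(paste0(f, ".hdr"))
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(f, ".hdr"))
  expect_error(read_envi(f), "wavelength")
})

test_that("spectral_sum is linear and respects regions", {
  a <- array(0, c(4, 4, 10))
  a[2, 3, ] <- 1:10
  cb <- hsi_cube(a, (0:3) * 5, (0:3) * 5, 500 + (0:9))
  s <- spectral_sum(cb, subtract = FALSE)
  expect_equal(s$intensity, 1:10)
  u <- hsi_cube(array(2, c(4, 4, 10)), (0:3) * 5, (0:3) * 5, 500 + (0:9))
  reg <- matrix(FALSE, 4, 4); reg[1:2, 1] <- TRUE
  expect_equal(spectral_sum(u, reg, subtract = FALSE)$intensity, rep(4, 10))
  expect_error(spectral_sum(u, matrix(FALSE, 4, 4)), "empty region")
})

test_that("slice_at_peak isolates one bead and is ~0 between peaks", {
  rc <- small_scene_cube(14.2, 1.34, 150, 160, 150, noise = FALSE,
                         background_counts = 50)
  lam0 <- rc$manifest$modes[[1]]$wavelength_nm
  m <- slice_at_peak(rc$cube, lam0[6])
  expect_gt(max(m$intensity), 100)
  peak_px <- which(m$intensity == max(m$intensity), arr.ind = TRUE)[1, ]
  expect_lt(abs(m$x_um[peak_px[1]] - 150), 15)
  # a band in the middle of the widest gap between any two teeth
  i <- which.max(diff(lam0))
  gap <- mean(lam0[i:(i + 1)])
  mg <- slice_at_peak(rc$cube, gap)
  expect_lt(max(abs(mg$intensity)), 0.05 * max(m$intensity))
  expect_error(slice_at_peak(rc$cube, 499, 1), "outside")
})

test_that("fit_gaussian2d recovers exact parameters and resists Poisson noise", {
  xs <- (0:40) * 5; ys <- (0:40) * 5
  z <- 200 * outer(dnorm(xs, 101, 30), dnorm(ys, 97, 40)) * 2 * pi * 30 * 40 + 3
  f <- fit_gaussian2d(list(intensity = z, x_um = xs, y_um = ys))
  expect_true(f$converged)
  expect_equal(c(f$x0_um, f$y0_um), c(101, 97), tolerance = 1e-6)
  expect_equal(c(f$sigma_x_um, f$sigma_y_um), c(30, 40), tolerance = 1e-5)
  # Poisson noise at peak SNR ~ 10
  set.seed(7)
  errs <- replicate(25, {
    zn <- matrix(rpois(length(z), 100 * z / max(z) + 5), nrow(z))
    fn <- fit_gaussian2d(list(intensity = zn, x_um = xs, y_um = ys))
    sqrt((fn$x0_um - 101)^2 + (fn$y0_um - 97)^2)
  })
  expect_lt(median(errs), 0.1 * 5)   # 0.1 pixel at 5 um pitch
})

test_that("two comparable blobs are flagged as a poor fit", {
  xs <- (0:40) * 5; ys <- (0:40) * 5
  z <- outer(dnorm(xs, 60, 20), dnorm(ys, 100, 20)) +
       outer(dnorm(xs, 120, 20), dnorm(ys, 100, 20))   # 3 sigma apart
  f <- fit_gaussian2d(list(intensity = z / max(z) * 100, x_um = xs, y_um = ys))
  expect_true(f$poor)
})

test_that("surface_width returns the Gaussian sigma in all directions", {
  xs <- (0:80) * 5; ys <- (0:80) * 5
  z <- outer(dnorm(xs, 200, 50), dnorm(ys, 200, 50))
  w <- surface_width(list(intensity = z, x_um = xs, y_um = ys))
  expect_equal(as.numeric(w), 50, tolerance = 0.01)
  expect_equal(unname(attr(w, "directions")), rep(50, 4), tolerance = 0.01)
  # invariant under intensity rescaling
  w2 <- surface_width(list(intensity = 37.5 * z, x_um = xs, y_um = ys))
  expect_equal(as.numeric(w2), as.numeric(w), tolerance = 1e-6)
  # fwhm metric
  wf <- surface_width(list(intensity = z, x_um = xs, y_um = ys),
                      metric = "fwhm")
  expect_equal(as.numeric(wf), 50 * 2 * sqrt(2 * log(2)), tolerance = 0.02)
})

test_that("anisotropic widths agree with direct 1D fits along each direction", {
  xs <- (0:80) * 5; ys <- (0:80) * 5
  z <- outer(dnorm(xs, 200, 40), dnorm(ys, 200, 60))
  w <- surface_width(list(intensity = z, x_um = xs, y_um = ys))
  dirs <- attr(w, "directions")
  expect_equal(dirs[1], 40, tolerance = 0.02)   # along x
  expect_equal(dirs[3], 60, tolerance = 0.02)   # along y
  # the diagonal of a separable Gaussian: 1/s^2 = cos^2/sx^2 + sin^2/sy^2
  s45 <- 1 / sqrt(0.5 / 40^2 + 0.5 / 60^2)
  expect_equal(dirs[2], s45, tolerance = 0.02)
  expect_error(surface_width(matrix(1, 10, 10)), "flat")
})

test_that("depth lookup interpolates monotonically and clamps out of range", {
  cal <- calibration_curve(c(50, 150, 250, 350), c(40, 95, 152, 210))
  expect_equal(depth_from_width(95, cal), 150)
  w <- seq(40, 210, length.out = 50)
  d <- depth_from_width(w, cal)
  expect_true(all(diff(d) >= 0))
  expect_warning(dd <- depth_from_width(300, cal), "clamped")
  expect_equal(dd, 350)
  expect_error(calibration_curve(c(50, 150, 250), c(40, 95, 80)),
               "increase strictly")
})

test_that("multi-peak localization beats a single peak and binning commutes", {
  errs <- sapply(1:4, function(seed) {
    rc <- small_scene_cube(14.2, 1.34, 152, 163, 150, seed = seed,
                           q_range = c(7000, 7000))
    lams <- rc$manifest$modes[[1]]
    lams <- lams$wavelength_nm[lams$radial_order == 1]
    all_pk <- localize_microcavity(rc$cube, lams)
    one_pk <- localize_microcavity(rc$cube, lams[6])
    c(all = sqrt((all_pk$x0_um - 152)^2 + (all_pk$y0_um - 163)^2),
      one = sqrt((one_pk$x0_um - 152)^2 + (one_pk$y0_um - 163)^2))
  })
  expect_lt(mean(errs["all", ]), mean(errs["one", ]))
  message(sprintf("multi-peak vs single-peak mean error ratio: %.2f",
                  mean(errs["one", ]) / mean(errs["all", ])))
  # fast-scan binning: localization commutes within a pixel
  rc <- small_scene_cube(14.2, 1.34, 152, 163, 150, seed = 9,
                         q_range = c(7000, 7000))
  lams <- rc$manifest$modes[[1]]$wavelength_nm
  full <- localize_microcavity(rc$cube, lams)
  binned <- localize_microcavity(bin_cube(rc$cube, 2, 2, 2), lams)
  expect_lt(sqrt((full$x0_um - binned$x0_um)^2 +
                 (full$y0_um - binned$y0_um)^2), 10)
})
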