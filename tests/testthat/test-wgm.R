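# Eigenmode solver and comb fitting.

test_that("index-matched sphere has no confined resonance", {
  p <- suppressWarnings(sphere_params(15, 1.4, 1.4))
  r <- characteristic_residual(p, "TE", 140, seq(500, 540, by = 0.05))
  expect_false(any(diff(sign(r)) != 0, na.rm = TRUE))
  expect_message(ms <- find_modes(p, c(500, 540)), "no confined")
  expect_equal(nrow(ms), 0)
})

test_that("residual is scale invariant: residual(d, lambda) = residual(2d, 2lambda)", {
  p1 <- sphere_params(15, 1.59, 1.34)
  p2 <- sphere_params(30, 1.59, 1.34)
  lam <- seq(515, 525, by = 0.5)
  expect_equal(characteristic_residual(p1, "TE", 140, lam),
               characteristic_residual(p2, "TE", 140, 2 * lam),
               tolerance = 1e-10)
  expect_equal(characteristic_residual(p1, "TM", 140, lam),
               characteristic_residual(p2, "TM", 140, 2 * lam),
               tolerance = 1e-10)
})

test_that("find_modes agrees with a dense-grid sign-change scan", {
  p <- sphere_params(15, 1.59, 1.34)
  win <- c(516, 524)
  ms <- find_modes(p, win)
  expect_gt(nrow(ms), 3)
  for (k in seq_len(nrow(ms))) {
    grid <- seq(ms$wavelength_nm[k] - 0.5, ms$wavelength_nm[k] + 0.5,
                by = 0.001)
    r <- characteristic_residual(p, ms$polarization[k], ms$angular_order[k],
                                 grid)
    idx <- which(diff(sign(r)) != 0)
    expect_true(any(abs(grid[idx] - ms$wavelength_nm[k]) <= 0.001),
                info = sprintf("mode %s l=%d q=%d at %.4f nm",
                               ms$polarization[k], ms$angular_order[k],
                               ms$radial_order[k], ms$wavelength_nm[k]))
  }
})

test_that("mode spacing matches the analytic FSR near 520 nm", {
  ms <- find_modes(sphere_params(15, 1.59, 1.34), c(505, 535),
                   max_radial_order = 1)
  te <- ms$wavelength_nm[ms$polarization == "TE"]
  mid <- diff(te)[which.min(abs(te[-length(te)] - 520))]
  expect_equal(mid, fsr_estimate(15, 1.59, 520)$dlambda_nm, tolerance = 0.05)
})

test_that("doubling the diameter doubles every mode wavelength", {
  m1 <- find_modes(sphere_params(15, 1.59, 1.34), c(515, 525))
  m2 <- find_modes(sphere_params(30, 1.59, 1.34), c(1030, 1050))
  expect_equal(sort(m2$wavelength_nm), sort(2 * m1$wavelength_nm),
               tolerance = 1e-7)
})

test_that("mode list is stable under bracketing-grid refinement", {
  p <- sphere_params(13.5, 1.59, 1.36)
  m1 <- find_modes(p, c(515, 525), grid_step = 0.05)
  m2 <- find_modes(p, c(515, 525), grid_step = 0.02)
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(m1$wavelength_nm, m2$wavelength_nm, tolerance = 1e-6)
})

test_that("every mode red-shifts monotonically with the external index", {
  lam_by_n <- sapply(c(1.33, 1.35, 1.37, 1.39), function(ne) {
    ms <- find_modes(sphere_params(15, 1.59, ne), c(517, 523),
                     max_radial_order = 1)
    ms$wavelength_nm[ms$polarization == "TE"][1]
  })
  expect_true(all(diff(lam_by_n) > 0))
})

test_that("layered solver reduces to the bare solver in degenerate limits", {
  bare <- find_modes(sphere_params(15, 1.59, 1.34), c(515, 525))
  invis <- find_modes(layered_sphere_params(c(7.5, 7.9), c(1.59, 1.34, 1.34)),
                      c(515, 525))
  merged <- find_modes(layered_sphere_params(c(7.1, 7.5), c(1.59, 1.59, 1.34)),
                       c(515, 525))
  expect_equal(sort(invis$wavelength_nm), sort(bare$wavelength_nm),
               tolerance = 1e-5)
  expect_equal(sort(merged$wavelength_nm), sort(bare$wavelength_nm),
               tolerance = 1e-5)
})

test_that("a 400 nm coating red-shifts all modes monotonically with its index", {
  # follow identified mode families (polarization, l, q) across the sweep
  base <- find_modes(layered_sphere_params(c(7.5, 7.9), c(1.59, 1.40, 1.34)),
                     c(518, 523))
  fam <- base[1:4, c("polarization", "angular_order", "radial_order")]
  lam <- sapply(seq(1.40, 1.44, by = 0.01), function(nc) {
    ms <- find_modes(layered_sphere_params(c(7.5, 7.9), c(1.59, nc, 1.34)),
                     c(516, 525))
    vapply(seq_len(nrow(fam)), function(k) {
      sel <- ms$polarization == fam$polarization[k] &
        ms$angular_order == fam$angular_order[k] &
        ms$radial_order == fam$radial_order[k]
      if (any(sel)) ms$wavelength_nm[sel][1] else NA_real_
    }, numeric(1))
  })
  expect_true(all(apply(lam, 1, function(w)
    all(diff(w[!is.na(w)]) > 0))))
})

test_that("fsr_estimate obeys its analytic identities", {
  f <- fsr_estimate(15, 1.59, 520)
  expect_equal(f$dlambda_nm, 3.6088, tolerance = 1e-3)
  expect_equal(fsr_estimate(30, 1.59, 520)$dlambda_nm, f$dlambda_nm / 2)
  expect_lt(fsr_estimate(1e6, 1.59, 520)$dlambda_nm, 1e-4)
})

test_that("size_from_fsr recovers the diameter from an exact comb", {
  ms <- find_modes(sphere_params(15, 1.59, 1.34), c(500, 540),
                   max_radial_order = 1)
  sz <- size_from_fsr(ms$wavelength_nm[ms$polarization == "TE"], 1.59)
  expect_equal(sz$diameter_um, 15, tolerance = 1.5e-3)
  # mixed-polarization comb
  sz2 <- size_from_fsr(ms$wavelength_nm, 1.59)
  expect_equal(sz2$diameter_um, 15, tolerance = 2e-3)
})

test_that("size_from_fsr handles minimal and gappy combs", {
  ms <- find_modes(sphere_params(15, 1.59, 1.34), c(505, 535),
                   max_radial_order = 1)
  te <- ms$wavelength_nm[ms$polarization == "TE"]
  expect_error(size_from_fsr(te[1]), "at least 2")
  two <- size_from_fsr(te[1:2], 1.59)
  expect_equal(two$diameter_um, 15, tolerance = 0.05)
  expect_gt(two$sd_um, 0)
  # one missing tooth does not bias the estimate
  full <- size_from_fsr(te, 1.59)
  gappy <- size_from_fsr(te[-3], 1.59)
  expect_equal(gappy$diameter_um, full$diameter_um, tolerance = 2e-3)
})

test_that("fit round trip recovers diameter and index on a noiseless comb", {
  truth <- sphere_params(13.0189, 1.59, 1.37)
  peaks <- find_modes(truth, c(505, 535), max_radial_order = 1)$wavelength_nm
  fit <- fit_size_index(peaks, 1.59)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$diameter_um - 13.0189) * 1e3, 0.01)   # nm
  expect_lt(abs(fit$n_external - 1.37), 1e-5)
  expect_lt(fit$residual_nm, 1e-4)
})

test_that("a wrong assumed internal index biases the diameter but fits well", {
  truth <- sphere_params(13.0189, 1.59, 1.37)
  peaks <- find_modes(truth, c(505, 535), max_radial_order = 1)$wavelength_nm
  fit <- fit_size_index(peaks, 1.58)
  expect_equal(fit$status, "ok")
  expect_gt(abs(fit$diameter_um - 13.0189) * 1e3, 5)  # systematic bias
  expect_lt(fit$residual_nm, 0.05)                    # but small residual
})

test_that("too few peaks yield an explicit underdetermined status", {
  fit <- fit_size_index(c(518.2, 521.8, 525.5), 1.59)
  expect_equal(fit$status, "underdetermined")
  expect_true(is.na(fit$n_external))
})

test_that("polystyrene dispersion is ~1.59 at the sodium D line", {
  expect_equal(polystyrene_index(589), 1.59, tolerance = 3e-3)
  expect_gt(polystyrene_index(500), polystyrene_index(600))
})
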