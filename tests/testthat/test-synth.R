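# Synthetic scene generator: populations, capacity, rendering, manifests.

test_that("population sampling honors mean, CV and seed", {
  p0 <- sample_population(50, cv = 0, seed = 1)
  expect_true(all(p0$diameter_um == 15))
  p1 <- sample_population(20, seed = 7)
  p2 <- sample_population(20, seed = 7)
  expect_identical(p1, p2)
  big <- sample_population(1e5, mean_um = 15, cv = 0.14, seed = 2)
  expect_equal(mean(big$diameter_um), 15, tolerance = 0.01 * 15)
  expect_equal(sd(big$diameter_um) / mean(big$diameter_um), 0.14,
               tolerance = 0.01)
})

test_that("environment rule sets the external index scales", {
  p <- sample_population(3000, environment = c("medium", "cytoplasm"),
                         seed = 3)
  med <- p$n_external[p$environment == "medium"]
  cyt <- p$n_external[p$environment == "cytoplasm"]
  expect_equal(mean(med), 1.34, tolerance = 1e-3)
  expect_equal(mean(cyt), 1.37, tolerance = 1e-3)
  expect_lt(sd(med), sd(cyt))
})

test_that("pair indistinguishability has the right closed form", {
  expect_equal(pair_indistinguishability_probability(15, 0.14, 0), 0)
  p <- pair_indistinguishability_probability(15, 0.14, 3)
  expect_equal(p, 8e-4, tolerance = 0.1)
  # sampling oracle
  set.seed(5)
  d1 <- rnorm(1e6, 15, 2.1); d2 <- rnorm(1e6, 15, 2.1)
  phat <- mean(abs(d1 - d2) < 3e-3)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1e6))
})

test_that("capacity estimate reproduces the field arithmetic", {
  expect_equal(capacity_estimate(9, 200, 5), 1400)
  # spot as large as the field: just the per-spot count
  expect_equal(capacity_estimate(pi * 0.1^2, 200, 5), 5)
  expect_equal(capacity_estimate(9, 200, 10),
               signif(10 * 9 / (pi * 0.1^2), 2))
})

test_that("rendering is deterministic under a fixed seed", {
  r1 <- small_scene_cube(14.2, 1.34, 150, 150, 120, seed = 3)
  r2 <- small_scene_cube(14.2, 1.34, 150, 150, 120, seed = 3)
  expect_identical(r1$cube$data, r2$cube$data)
})

test_that("a noiseless single-bead cube factorizes as footprint x spectrum", {
  rc <- small_scene_cube(14.2, 1.34, 150, 150, 120, noise = FALSE,
                         background_counts = 0,
                         wavelength_nm = seq(515, 525, 0.023))
  d <- dim(rc$cube$data)
  m <- matrix(rc$cube$data, d[1] * d[2], d[3])
  sv <- svd(m, nu = 0, nv = 0)$d
  expect_lt(sv[2] / sv[1], 1e-8)   # numerically rank one
})

test_that("every detectable peak in a noiseless cube is a manifest mode", {
  rc <- small_scene_cube(c(14.2, 15.32), c(1.34, 1.37), c(100, 220),
                         c(120, 200), c(120, 200), noise = FALSE,
                         max_radial_order = 1)
  s <- subtract_background(spectral_sum(rc$cube, subtract = FALSE))
  pk <- detect_peaks(s)
  truth <- sort(unlist(lapply(rc$manifest$modes, `[[`, "wavelength_nm")))
  mism <- vapply(pk$wavelength_nm,
                 function(l) min(abs(1e3 / truth - 1e3 / l)), numeric(1))
  ok <- mism < 2 * default_match_tolerance()
  # a detected maximum may also be the blend of two modes closer than about
  # two linewidths; it must then lie between them
  for (b in which(!ok)) {
    near <- truth[order(abs(truth - pk$wavelength_nm[b]))][1:2]
    expect_lt(abs(diff(near)), 0.16)
    expect_true(pk$wavelength_nm[b] > min(near) &&
                pk$wavelength_nm[b] < max(near))
  }
  expect_gt(mean(ok), 0.9)
})

test_that("a five-bead spot yields the field-scale peak count end to end", {
  rc <- small_scene_cube(c(13.4, 14.1, 14.8, 15.5, 16.2), rep(1.34, 5),
                         c(80, 240, 95, 235, 160), c(85, 90, 235, 240, 160),
                         c(120, 160, 200, 240, 180), seed = 17,
                         max_radial_order = 1)
  s <- spectral_sum(rc$cube, subtract = TRUE)
  pk <- detect_peaks(dsli_spectrum(s$wavelength_nm, s$intensity))
  expect_gt(nrow(pk), 60)
  tol <- noise_match_tolerance(pk$sigma_nm, median(pk$wavelength_nm))
  g <- group_peaks(pk, match_tolerance = tol)
  merged <- pair_te_tm(g, n_internal = 1.59, coarse_dn = 2e-3, nm_maxit = 20)
  expect_gte(length(merged[vapply(merged, function(x)
    length(x$members), numeric(1)) >= 6]), 4)
})

test_that("two near-identical beads merge into one comb (designed failure)", {
  # 1 nm apart: the 0.037 nm tooth separation is half a linewidth at the
  # batch-average Q of 7000, so the teeth blend into single maxima
  rc <- small_scene_cube(c(14.2, 14.201), c(1.34, 1.34), c(120, 180),
                         c(150, 150), c(120, 120), noise = FALSE,
                         max_radial_order = 1, q_range = c(7000, 7000))
  s <- subtract_background(spectral_sum(rc$cube, subtract = FALSE))
  pk <- detect_peaks(s)
  g <- group_peaks(pk)
  expect_equal(length(pair_te_tm(g, n_internal = 1.59, coarse_dn = 2e-3,
                                 nm_maxit = 20)), 1)
})
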