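# Peak detection and FSR comb unmixing.

grid <- seq(505, 535, by = 0.023)

test_that("background subtraction removes a smooth envelope and keeps zero", {
  bg <- 500 * exp(-0.5 * ((grid - 520) / 12)^2)
  s <- subtract_background(dsli_spectrum(grid, bg))
  expect_lt(max(abs(s$intensity)), 0.02 * max(bg))
  z <- subtract_background(dsli_spectrum(grid, rep(0, length(grid))))
  expect_equal(z$intensity, rep(0, length(grid)))
})

test_that("background subtraction preserves comb amplitudes within 5%", {
  centers <- ideal_comb(1.92, 0.0133, 8)
  centers <- centers[centers > min(grid) + 2 & centers < max(grid) - 2]
  bg <- 500 * exp(-0.5 * ((grid - 520) / 12)^2)
  y <- comb_spectrum(grid, centers, amp = 300) + bg
  s <- subtract_background(dsli_spectrum(grid, y))
  pk <- detect_peaks(s, prominence_threshold = 100)
  expect_equal(nrow(pk), length(centers))
  expect_true(all(abs(pk$amplitude - 300) / 300 < 0.05))
})

test_that("background subtraction errors on a too-short spectrum", {
  expect_error(subtract_background(dsli_spectrum(grid[1:20], rep(1, 20))),
               "shorter than")
})

test_that("Lorentzian refinement recovers a noiseless peak center to < 0.001 nm", {
  y <- comb_spectrum(grid, 520.000, amp = 1000, q = 7000)
  pk <- detect_peaks(dsli_spectrum(grid, y), 100)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$wavelength_nm - 520), 0.001)
  expect_equal(pk$q_factor, 7000, tolerance = 0.02)
})

test_that("two peaks separated by 5x fwhm are both recovered", {
  fwhm <- 520 / 7000
  y <- comb_spectrum(grid, c(520, 520 + 5 * fwhm), amp = 800)
  pk <- detect_peaks(dsli_spectrum(grid, y), 100)
  expect_equal(nrow(pk), 2)
  expect_lt(max(abs(sort(pk$wavelength_nm) - c(520, 520 + 5 * fwhm))), 0.005)
})

test_that("no maxima above the threshold gives an empty peak list", {
  set.seed(1)
  pk <- detect_peaks(dsli_spectrum(grid, rnorm(length(grid))), 1e6)
  expect_equal(nrow(pk), 0)
})

test_that("a single perfect comb gets one FSR with full support", {
  lam <- ideal_comb(1.92, 0.0133, 10)
  a <- assign_fsr(lam)
  expect_true(all(abs(a$fsr_per_um - 0.0133) < 1e-9))
  expect_true(all(a$support == 10))
})

test_that("two interleaved combs match the brute-force oracle", {
  lam <- sort(c(ideal_comb(1.920, 0.0130, 8), ideal_comb(1.9235, 0.0138, 8)))
  tol <- default_match_tolerance()
  a <- assign_fsr(lam, tol)
  bf <- brute_force_fsr(lam, tol)
  expect_equal(a$fsr_per_um, bf$fsr, tolerance = 1e-12)
  expect_equal(a$support, bf$support)
  truth <- ifelse(lam %in% ideal_comb(1.920, 0.0130, 8), 0.0130, 0.0138)
  expect_equal(a$fsr_per_um, truth, tolerance = 1e-9)
})

test_that("three incommensurate peaks stay unassigned at min_support 4", {
  lam <- c(507.3, 516.9, 528.1)
  a <- assign_fsr(lam, min_support = 4)
  expect_true(all(is.na(a$fsr_per_um)))
})

test_that("grouping separates the two-comb fixture exactly", {
  c1 <- ideal_comb(1.920, 0.0130, 8)
  c2 <- ideal_comb(1.9235, 0.0138, 8)
  lam <- sort(c(c1, c2))
  g <- group_peaks(lam)
  expect_equal(length(g), 2)
  members <- lapply(g, function(x) sort(x$wavelength_nm))
  expect_true(any(vapply(members, function(m) isTRUE(all.equal(m, c1)),
                         logical(1))))
  expect_true(any(vapply(members, function(m) isTRUE(all.equal(m, c2)),
                         logical(1))))
})

test_that("a shared tooth may belong to both combs", {
  c1 <- ideal_comb(1.920, 0.0130, 8)
  c2 <- sort(1e3 / (1e3 / c1[4] + 0.0138 * (-3:4)))   # crosses c1 at one tooth
  lam <- sort(unique(c(c1, c2)))
  g <- group_peaks(lam)
  expect_equal(length(g), 2)
  counts <- table(unlist(lapply(g, `[[`, "members")))
  expect_true(any(counts == 2))   # the shared tooth is claimed twice
})

test_that("TE/TM pairing merges sub-combs of one sphere, validated by the solver", {
  truth <- sphere_params(14.5, 1.59, 1.35)
  ms <- find_modes(truth, c(505, 535), max_radial_order = 1)
  g <- group_peaks(ms$wavelength_nm)
  expect_equal(length(g), 2)   # TE and TM sub-combs
  merged <- pair_te_tm(g, n_internal = 1.59, coarse_dn = 2e-3, nm_maxit = 20)
  expect_equal(length(merged), 1)
  expect_equal(length(merged[[1]]$members), nrow(ms))
  expect_setequal(unique(merged[[1]]$polarization), c("TE", "TM"))
})

test_that("single-polarization group passes through pairing unchanged", {
  lam <- ideal_comb(1.92, 0.0133, 8)
  g <- group_peaks(lam)
  expect_equal(length(pair_te_tm(g)), 1)
})

test_that("combs of two different spheres with near-equal FSR are not merged", {
  p1 <- find_modes(sphere_params(14.50, 1.59, 1.35), c(505, 535),
                   max_radial_order = 1)
  p2 <- find_modes(sphere_params(14.55, 1.59, 1.35), c(505, 535),
                   max_radial_order = 1)
  te1 <- p1$wavelength_nm[p1$polarization == "TE"]
  te2 <- p2$wavelength_nm[p2$polarization == "TE"]
  g <- group_peaks(sort(c(te1, te2)))
  merged <- pair_te_tm(g, n_internal = 1.59, coarse_dn = 2e-3, nm_maxit = 20)
  # the solver check rejects the cross-sphere merge
  expect_equal(length(merged), length(g))
})

test_that("fill_missing_peaks predicts a deleted tooth and nothing else", {
  lam <- ideal_comb(1.92, 0.0133, 10)
  g <- group_peaks(lam[-4])[[1]]
  g <- fill_missing_peaks(g, window = range(lam))
  expect_equal(length(g$filled_in), 1)
  expect_lt(abs(1e3 / g$filled_in - 1e3 / lam[4]), default_match_tolerance())
  g2 <- fill_missing_peaks(group_peaks(lam)[[1]], window = range(lam))
  expect_equal(length(g2$filled_in), 0)
})

test_that("a two-member group predicts every other comb position in window", {
  lam <- ideal_comb(1.92, 0.0133, 10)
  g <- group_peaks(lam)[[1]]
  g$members <- g$members[5:6]
  g$wavelength_nm <- g$wavelength_nm[5:6]
  g <- fill_missing_peaks(g, window = range(lam))
  expect_equal(length(g$filled_in), 8)
})

test_that("reconstructed combs are self-consistent in 1/lambda", {
  lam <- sort(c(ideal_comb(1.920, 0.0130, 8), ideal_comb(1.9235, 0.0138, 8)))
  tol <- default_match_tolerance()
  for (g in group_peaks(lam)) {
    g <- fill_missing_peaks(g, window = range(lam))
    pos <- 1e3 / sort(c(g$wavelength_nm, g$filled_in))
    N <- round((pos - g$anchor_per_um) / g$fsr_per_um)
    expect_true(all(abs(pos - (g$anchor_per_um + N * g$fsr_per_um)) < tol))
  }
})

test_that("groups export to CSV with observed and predicted teeth", {
  lam <- ideal_comb(1.92, 0.0133, 8)
  g <- fill_missing_peaks(group_peaks(lam[-4])[[1]], window = range(lam))
  path <- tempfile(fileext = ".csv")
  write_groups_csv(list(g), path)
  df <- read.csv(path)
  expect_equal(sum(df$observed), 7)
  expect_equal(sum(!df$observed), 1)
})
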