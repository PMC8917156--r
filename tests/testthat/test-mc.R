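# Photon transport, Mie optics, calibration and inversion.

test_that("transport length follows the closed form", {
  expect_equal(transport_length(optical_medium(76, 0.2, 0.87, 1.41))$lstar_um,
               1e3 / (0.2 + 76 * 0.13))
  expect_equal(transport_length(optical_medium(10, 0, 0, 1.0))$lstar_um, 100)
  expect_equal(transport_length(optical_medium(10, 0, 0, 1.0))$ls_um, 100)
  expect_warning(transport_length(optical_medium(0, 0, 0.5, 1.0)), "infinite")
})

test_that("Mie anisotropy of the phantom scatterers is ~0.87", {
  mie <- mie_single_particle(0.51, 1.60, 1.41, 532)
  expect_equal(mie$g, 0.87, tolerance = 0.01)
  # Rayleigh limit
  expect_lt(abs(mie_single_particle(0.01, 1.60, 1.41, 532)$g), 0.02)
})

test_that("phase-function quadrature reproduces the series asymmetry", {
  tab <- mie_phase_table(0.51, 1.60, 1.41, 532)
  mu <- tab[, 1]; p <- tab[, 2]
  g_quad <- sum(diff(mu) * (mu[-1] * p[-1] + mu[-length(mu)] * p[-length(p)]) / 2)
  expect_equal(g_quad, mie_single_particle(0.51, 1.60, 1.41, 532)$g,
               tolerance = 1e-4)
})

test_that("bulk scattering scales linearly with particle density", {
  m1 <- medium_from_particles(0.51, 1.60, 1.41, 532, 1e5, mu_a = 0.2)
  m2 <- medium_from_particles(0.51, 1.60, 1.41, 532, 2e5, mu_a = 0.2)
  expect_equal(m2$mu_s, 2 * m1$mu_s)
  expect_equal(m1$g, m2$g)
  expect_equal(medium_from_particles(0.51, 1.60, 1.41, 532, 0)$mu_s, 0)
  # density solved for the phantom's mu_s = 63/mm reproduces it
  dens <- 63 / m1$mu_s * 1e5
  expect_equal(medium_from_particles(0.51, 1.60, 1.41, 532, dens)$mu_s, 63)
})

test_that("scatter-angle samplers match their distributions", {
  set.seed(11)
  u <- sample_scatter_angle(1e5, g = 0)
  expect_gt(suppressWarnings(ks.test(u, "punif", -1, 1))$p.value, 1e-3)
  hg <- sample_scatter_angle(1e5, g = 0.87)
  expect_equal(mean(hg), 0.87, tolerance = 0.005)
  tab <- mie_phase_table(0.51, 1.60, 1.41, 532)
  mie <- sample_scatter_angle(2e5, phase_table = tab)
  expect_equal(mean(mie), mie_single_particle(0.51, 1.60, 1.41, 532)$g,
               tolerance = 0.01)
})

test_that("a non-interacting matched slab transmits everything ballistically", {
  med <- optical_medium(0, 0, 0, 1.0)
  rt <- suppressWarnings(integrating_sphere_rt(med, 200, 1e4, seed = 1))
  expect_equal(rt$total_transmittance, 1)
  expect_equal(rt$ballistic_transmittance, 1)
  expect_equal(rt$diffuse_reflectance, 0)
})

test_that("ballistic transmittance follows Beer-Lambert", {
  med <- optical_medium(10, 0.5, 0.8, 1.0)
  rt <- integrating_sphere_rt(med, 200, 5e4, seed = 2)
  theory <- exp(-(10 + 0.5) * 0.2)
  se <- sqrt(theory * (1 - theory) / 5e4)
  expect_lt(abs(rt$ballistic_transmittance - theory), 4 * se)
})

test_that("energy is conserved in every geometry", {
  med <- optical_medium(63, 0.2, 0.87, 1.41)
  for (g in list(mc_geometry("embedded", source_depth_um = 200, nbin = 101),
                 mc_geometry("slab_overlayer", thickness_um = 250,
                             source_depth_um = 250, nbin = 101),
                 mc_geometry("beam", thickness_um = 150, nbin = 3,
                             bin_um = 1e5))) {
    r <- run_mc(med, g, 2e4, seed = 5)
    total <- r$r_top + r$t_bottom + r$absorbed + r$lost_down + r$specular
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("identical seeds give identical tallies, different seeds differ", {
  med <- optical_medium(63, 0.2, 0.87, 1.41)
  g <- mc_geometry("embedded", source_depth_um = 150, nbin = 101)
  r1 <- run_mc(med, g, 1e4, seed = 42)
  r2 <- run_mc(med, g, 1e4, seed = 42)
  r3 <- run_mc(med, g, 1e4, seed = 43)
  expect_identical(r1$map, r2$map)
  expect_identical(r1$r_top, r2$r_top)
  expect_false(identical(r1$map, r3$map))
})

test_that("an embedded source produces a wider footprint than an overlayer", {
  med <- optical_medium(63, 0.2, 0.87, 1.41)
  depth <- 2.3 * transport_length(med)$lstar_um
  ge <- mc_geometry("embedded", source_depth_um = depth, n_below = 1.34,
                    nbin = 501)
  go <- mc_geometry("slab_overlayer", thickness_um = depth,
                    source_depth_um = depth, n_below = 1.34, nbin = 501)
  we <- surface_width(with(run_mc(med, ge, 5e4, seed = 6),
                           list(intensity = map, x_um = x_um, y_um = y_um)),
                      metric = "fwhm")
  wo <- surface_width(with(run_mc(med, go, 5e4, seed = 7),
                           list(intensity = map, x_um = x_um, y_um = y_um)),
                      metric = "fwhm")
  expect_gt(we, wo)
  message(sprintf("embedded footprint wider by %.1f%%", 100 * (we / wo - 1)))
})

test_that("calibration widths grow monotonically with depth and reproduce", {
  med <- optical_medium(63, 0.2, 0.87, 1.41)
  g <- mc_geometry("slab_overlayer", thickness_um = 100,
                   source_depth_um = 100, n_below = 1.34, nbin = 201)
  cal1 <- build_calibration(med, c(100, 200, 300, 400), n_photons = 1e5,
                            seed = 1, geometry = g)
  cal2 <- build_calibration(med, c(100, 200, 300, 400), n_photons = 1e5,
                            seed = 100, geometry = g)
  expect_true(all(diff(cal1$width_um) > 0))
  expect_equal(cal1$width_um, cal2$width_um, tolerance = 0.1)
})

test_that("depth round trip through simulation and calibration", {
  med <- optical_medium(63, 0.2, 0.87, 1.41)
  g <- mc_geometry("slab_overlayer", thickness_um = 100,
                   source_depth_um = 100, n_below = 1.34, nbin = 201)
  cal <- build_calibration(med, c(100, 175, 250, 325), n_photons = 5e4,
                           seed = 1, geometry = g)
  g$thickness_um <- g$source_depth_um <- 212
  r <- run_mc(med, g, 5e4, seed = 9)
  w <- surface_width(list(intensity = r$map, x_um = r$x_um, y_um = r$y_um))
  expect_lt(abs(depth_from_width(w, cal) - 212), 40)
})

test_that("thicker non-absorbing slabs transmit monotonically less", {
  med <- optical_medium(40, 0, 0.8, 1.41)
  tt <- vapply(c(100, 250, 400), function(L)
    integrating_sphere_rt(med, L, 2e4, seed = 3)$total_transmittance,
    numeric(1))
  expect_true(all(diff(tt) < 0))
})

test_that("inversion recovers the phantom scattering parameters", {
  med <- optical_medium(63, 0.2, 0.87, 1.41)
  rt <- integrating_sphere_rt(med, 200, 4e4, seed = 11)
  inv <- invert_optical_properties(rt$diffuse_reflectance,
                                   rt$total_transmittance, 200,
                                   mu_s_range = c(33, 93),
                                   g_range = c(0.77, 0.97),
                                   n_mu_s = 5, n_g = 5,
                                   n_photons = 1e4, seed = 12)
  expect_equal(inv$status, "ok")
  expect_lt(abs(inv$mu_s - 63), 15)      # grid step
  expect_lt(abs(inv$g - 0.87), 0.05)
  # inconsistent target lands on the boundary
  inv2 <- invert_optical_properties(0.9, 0.05, 200,
                                    mu_s_range = c(40, 80),
                                    g_range = c(0.8, 0.95),
                                    n_mu_s = 3, n_g = 3,
                                    n_photons = 5e3, seed = 13)
  expect_equal(inv2$status, "range too narrow")
})

test_that("weak absorption barely moves transmittance near the operating point", {
  # around the phantom's mu_a = 0.2/mm the transmittance of a thin slab is
  # insensitive to the exact absorption value
  rt0 <- integrating_sphere_rt(optical_medium(63, 0, 0.87, 1.41), 50,
                               3e4, seed = 14)
  rt1 <- integrating_sphere_rt(optical_medium(63, 0.4, 0.87, 1.41), 50,
                               3e4, seed = 14)
  expect_lt(abs(rt1$total_transmittance - rt0$total_transmittance) /
              rt0$total_transmittance, 0.05)
})
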