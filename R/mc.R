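# Photon-transport Monte Carlo in scattering layers, Mie-theory optical
# properties, depth-calibration construction and integrating-sphere R/T with
# inverse optical-property estimation.
#
# Units: scattering/absorption coefficients in 1/mm at the user surface,
# lengths in um, wavelengths in nm. Internally the transport kernel works in
# um and 1/um.

#' Describe a turbid medium
#'
#' @param mu_s scattering coefficient (1/mm).
#' @param mu_a absorption coefficient (1/mm; default 0.2, a typical weakly
#'   absorbing phantom value).
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   angle), -1 < g < 1.
#' @param n refractive index of the medium.
#' @param phase "hg" (Henyey-Greenstein with this g) or "mie" (tabulated
#'   phase function; supply `phase_table` from [mie_phase_table()]).
#' @param phase_table optional 2-column matrix (cos_theta, pdf) for
#'   `phase = "mie"`.
#' @return object of class `optical_medium` with derived `ls_um` (scattering
#'   mean free path) and `lstar_um` (transport length).
#' @export
optical_medium <- function(mu_s, mu_a = 0.2, g = 0.87, n = 1.41,
                           phase = c("hg", "mie"), phase_table = NULL) {
  phase <- match.arg(phase)
  stopifnot(mu_s >= 0, mu_a >= 0, g > -1, g < 1, n >= 1)
  if (phase == "mie" && is.null(phase_table))
    stop("phase = \"mie\" requires a phase_table")
  structure(list(mu_s = mu_s, mu_a = mu_a, g = g, n = n, phase = phase,
                 phase_table = phase_table),
            class = "optical_medium")
}

#' @export
print.optical_medium <- function(x, ...) {
  tl <- transport_length(x)
  cat(sprintf(
    "optical medium: mu_s = %g /mm, mu_a = %g /mm, g = %g, n = %g (%s)\n  ls = %.1f um, l* = %.1f um\n",
    x$mu_s, x$mu_a, x$g, x$n, x$phase, tl$ls_um, tl$lstar_um))
  invisible(x)
}

#' Transport length and scattering mean free path
#'
#' `l* = 1/(mu_a + mu_s (1 - g))` is the depth scale over which photon
#' direction randomizes; `ls = 1/mu_s` is the scattering mean free path.
#'
#' @param medium an [optical_medium()] (or list with `mu_s`, `mu_a`, `g` in
#'   1/mm).
#' @return list with `lstar_um` and `ls_um`.
#' @export
transport_length <- function(medium) {
  mu_t <- medium$mu_a + medium$mu_s * (1 - medium$g)   # 1/mm
  if (mu_t <= 0) {
    warning("mu_a + mu_s(1-g) = 0: transport length is infinite")
    return(list(lstar_um = Inf,
                ls_um = if (medium$mu_s > 0) 1e3 / medium$mu_s else Inf))
  }
  list(lstar_um = 1e3 / mu_t,
       ls_um = if (medium$mu_s > 0) 1e3 / medium$mu_s else Inf)
}

# Mie series coefficients a_n, b_n for a homogeneous sphere, real indices
.mie_ab <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  bx <- .riccati_all_cpp(nmax, x)
  bm <- .riccati_all_cpp(nmax, m * x)
  n <- seq_len(nmax)
  psix <- bx$psi[n + 1]; dpsix <- bx$dpsi[n + 1]
  chix <- bx$chi[n + 1]; dchix <- bx$dchi[n + 1]
  xix <- complex(real = psix, imaginary = -chix)
  dxix <- complex(real = dpsix, imaginary = -dchix)
  psim <- bm$psi[n + 1]; dpsim <- bm$dpsi[n + 1]
  a <- (m * psim * dpsix - psix * dpsim) / (m * psim * dxix - xix * dpsim)
  b <- (psim * dpsix - m * psix * dpsim) / (psim * dxix - m * xix * dpsim)
  list(a = a, b = b, n = n)
}

#' Mie scattering of a single spherical particle
#'
#' Scattering cross-section and anisotropy factor of a homogeneous sphere
#' from the Mie series (truncated at the standard `x + 4 x^(1/3) + 2` order).
#'
#' @param diameter_um particle diameter (um).
#' @param n_particle particle refractive index.
#' @param n_medium surrounding index.
#' @param wavelength_nm vacuum wavelength (nm).
#' @return list: `cross_section_um2` (scattering cross-section),
#'   `g` (asymmetry parameter), `qsca` (efficiency), `size_parameter`.
#' @export
mie_single_particle <- function(diameter_um, n_particle, n_medium,
                                wavelength_nm) {
  stopifnot(diameter_um > 0, wavelength_nm > 0, n_particle > 0, n_medium > 0)
  x <- pi * diameter_um * n_medium / (wavelength_nm / 1e3)
  m <- n_particle / n_medium
  ab <- .mie_ab(m, x)
  n <- ab$n; a <- ab$a; b <- ab$b
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  n1 <- n[-length(n)]
  t1 <- sum(n1 * (n1 + 2) / (n1 + 1) *
              Re(a[n1] * Conj(a[n1 + 1]) + b[n1] * Conj(b[n1 + 1])))
  t2 <- sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- (4 / x^2) * (t1 + t2) / qsca
  geom <- pi * (diameter_um / 2)^2
  list(cross_section_um2 = qsca * geom, g = g, qsca = qsca,
       size_parameter = x)
}

#' Mie phase function (and sampling table)
#'
#' Unpolarized single-scattering phase function from the Mie amplitude
#' functions S1, S2, normalized as a pdf over cos(theta).
#'
#' @inheritParams mie_single_particle
#' @param n_angles number of angular samples.
#' @return matrix with columns `cos_theta`, `pdf`.
#' @export
mie_phase_table <- function(diameter_um, n_particle, n_medium, wavelength_nm,
                            n_angles = 1801) {
  x <- pi * diameter_um * n_medium / (wavelength_nm / 1e3)
  m <- n_particle / n_medium
  ab <- .mie_ab(m, x)
  theta <- seq(0, pi, length.out = n_angles)
  mu <- cos(theta)
  nmax <- length(ab$n)
  # angular functions pi_n, tau_n by upward recurrence
  S1 <- rep(0 + 0i, n_angles); S2 <- S1
  pin_m1 <- rep(0, n_angles); pin <- rep(1, n_angles)
  for (n in seq_len(nmax)) {
    taun <- n * mu * pin - (n + 1) * pin_m1
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (ab$a[n] * pin + ab$b[n] * taun)
    S2 <- S2 + f * (ab$a[n] * taun + ab$b[n] * pin)
    pin_p1 <- ((2 * n + 1) * mu * pin - (n + 1) * pin_m1) / n
    pin_m1 <- pin; pin <- pin_p1
  }
  p <- (Mod(S1)^2 + Mod(S2)^2) / 2
  o <- order(mu)
  mu <- mu[o]; p <- p[o]
  norm <- sum(diff(mu) * (p[-1] + p[-length(p)]) / 2)  # trapezoid over mu
  cbind(cos_theta = mu, pdf = p / norm)
}

#' Bulk optical properties from a particle suspension
#'
#' Independent-scattering (dilute) approximation: `mu_s` = number density x
#' single-particle scattering cross-section, `g` from Mie theory; absorption
#' is supplied separately (the particles are non-absorbing).
#'
#' @param diameter_um,n_particle,n_medium,wavelength_nm see
#'   [mie_single_particle()].
#' @param number_density_mm3 particles per mm^3.
#' @param mu_a absorption coefficient (1/mm).
#' @param phase "hg" or "mie".
#' @return an [optical_medium()].
#' @export
medium_from_particles <- function(diameter_um, n_particle, n_medium,
                                  wavelength_nm, number_density_mm3,
                                  mu_a = 0.2, phase = c("hg", "mie")) {
  phase <- match.arg(phase)
  mie <- mie_single_particle(diameter_um, n_particle, n_medium, wavelength_nm)
  vol_frac <- number_density_mm3 * (pi / 6) * (diameter_um * 1e-3)^3
  if (vol_frac > 0.10)
    warning(sprintf(
      "volume fraction %.2f > 0.10: independent-scattering assumption weak",
      vol_frac))
  mu_s <- number_density_mm3 * mie$cross_section_um2 * 1e-6  # um^2/mm^3 -> 1/mm
  tab <- if (phase == "mie")
    mie_phase_table(diameter_um, n_particle, n_medium, wavelength_nm) else NULL
  optical_medium(mu_s = mu_s, mu_a = mu_a, g = mie$g, n = n_medium,
                 phase = phase, phase_table = tab)
}

# inverse-CDF table (cos theta at uniform quantiles) from a phase table
.phase_inverse_cdf <- function(phase_table, n = 4096) {
  mu <- phase_table[, 1]; p <- phase_table[, 2]
  cdf <- c(0, cumsum(diff(mu) * (p[-1] + p[-length(p)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  approx(cdf, mu, xout = seq(0, 1, length.out = n), ties = "ordered")$y
}

#' Sample single-scattering deflection cosines
#'
#' Henyey-Greenstein: closed-form inverse CDF. Mie: inverse CDF of the
#' tabulated phase function.
#'
#' @param n number of samples.
#' @param g anisotropy (HG).
#' @param phase_table optional Mie phase table (overrides `g`).
#' @return numeric vector of cos(theta) samples.
#' @export
sample_scatter_angle <- function(n, g = 0.87, phase_table = NULL) {
  u <- runif(n)
  if (!is.null(phase_table)) {
    inv <- .phase_inverse_cdf(phase_table)
    return(approx(seq(0, 1, length.out = length(inv)), inv, xout = u)$y)
  }
  if (abs(g) < 1e-6) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(pmax((1 + g^2 - t^2) / (2 * g), -1), 1)
}

#' Simulation geometry
#'
#' @param configuration "slab_overlayer" (isotropic source beneath a finite
#'   scattering slab, transparent below), "embedded" (isotropic source inside
#'   a thick medium) or "beam" (collimated pencil beam from above, for
#'   integrating-sphere runs).
#' @param thickness_um slab thickness (overlayer/beam). For "embedded" the
#'   medium is treated as semi-infinite: it is truncated at
#'   `source_depth_um + cutoff_lstar` transport lengths, where returning
#'   photons are negligible.
#' @param source_depth_um source depth below the detection surface (um).
#' @param n_above index above the detection surface (air, 1.0).
#' @param n_below index beneath the slab (overlayer: the transparent host of
#'   the microcavities, ~1.34).
#' @param na collection numerical aperture for the surface map (default 1 =
#'   accept all exit angles).
#' @param bin_um surface-map bin size (default 5, camera pixel scale).
#' @param nbin surface map size (nbin x nbin bins, centered on the source).
#' @param cutoff_lstar depth cut for "embedded" (default 8 l* beyond source).
#' @export
mc_geometry <- function(configuration = c("embedded", "slab_overlayer",
                                          "beam"),
                        thickness_um = NULL, source_depth_um = 0,
                        n_above = 1.0, n_below = 1.34, na = 1.0,
                        bin_um = 5, nbin = 201, cutoff_lstar = 8) {
  configuration <- match.arg(configuration)
  if (configuration != "embedded" && is.null(thickness_um))
    stop("thickness_um required for configuration ", configuration)
  if (configuration == "slab_overlayer" &&
      source_depth_um < thickness_um - 1e-9)
    stop("slab_overlayer expects the source at or below the slab bottom")
  stopifnot(source_depth_um >= 0, na > 0, na <= 1)
  structure(list(configuration = configuration, thickness_um = thickness_um,
                 source_depth_um = source_depth_um, n_above = n_above,
                 n_below = n_below, na = na, bin_um = bin_um, nbin = nbin,
                 cutoff_lstar = cutoff_lstar),
            class = "mc_geometry")
}

#' Run the photon-transport Monte Carlo
#'
#' Standard photon-packet random walk: exponential free paths with
#' `mu_t = mu_s + mu_a`, absorption by packet weight with Russian-roulette
#' termination, Henyey-Greenstein (or tabulated Mie) scattering, and Fresnel
#' refraction/reflection at index-mismatched boundaries. Isotropic point
#' source for fluorescent microcavities; collimated pencil beam for
#' integrating-sphere runs. Reproducible for a fixed `seed`.
#'
#' @param medium an [optical_medium()].
#' @param geometry an [mc_geometry()].
#' @param n_photons number of photon packets.
#' @param seed RNG seed (integer); `NULL` uses the current RNG state.
#' @return `mc_result`: `map` (surface fluence, photons/bin), `x_um`/`y_um`
#'   bin centers, tallies `r_top`, `t_bottom`, `absorbed`, `lost_down`,
#'   `ballistic`, `specular` (fractions of launched packets), `seed`.
#' @export
run_mc <- function(medium, geometry, n_photons = 1e5, seed = NULL) {
  stopifnot(inherits(medium, "optical_medium"),
            inherits(geometry, "mc_geometry"), n_photons >= 1)
  if (!is.null(seed)) set.seed(seed)
  cfg <- match(geometry$configuration, c("slab_overlayer", "embedded",
                                         "beam")) - 1L
  L <- if (geometry$configuration == "embedded") {
    tl <- transport_length(medium)
    geometry$source_depth_um + geometry$cutoff_lstar * tl$lstar_um
  } else geometry$thickness_um
  inv_cdf <- if (medium$phase == "mie")
    .phase_inverse_cdf(medium$phase_table) else numeric(0)
  res <- .mc_run_cpp(medium$mu_s * 1e-3, medium$mu_a * 1e-3, medium$g,
                     medium$n, geometry$n_above, geometry$n_below,
                     L, geometry$source_depth_um, cfg, as.integer(n_photons),
                     geometry$bin_um, as.integer(geometry$nbin),
                     geometry$na, 1e-4, 0.1, inv_cdf)
  half <- geometry$bin_um * geometry$nbin / 2
  centers <- -half + (seq_len(geometry$nbin) - 0.5) * geometry$bin_um
  structure(list(map = res$map, x_um = centers, y_um = centers,
                 r_top = res$r_top, t_bottom = res$t_bottom,
                 absorbed = res$absorbed, lost_down = res$lost_down,
                 ballistic = res$ballistic, specular = res$specular,
                 n_photons = n_photons, seed = seed,
                 medium = medium, geometry = geometry),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "MC result (%s, %g photons): R_top = %.4f, T_bottom = %.4f, A = %.4f, lost = %.4f\n",
    x$geometry$configuration, x$n_photons, x$r_top, x$t_bottom, x$absorbed,
    x$lost_down))
  invisible(x)
}

#' Build a depth calibration curve by Monte Carlo
#'
#' Runs the transport simulation with the source at each depth, measures the
#' surface footprint width (same metric as the later lookup), and returns a
#' [calibration_curve()]. Widths must come out strictly increasing with
#' depth; if not (counting noise), an error advises more photons.
#'
#' @param medium an [optical_medium()].
#' @param depths_um source depths (>= 3 values).
#' @param n_photons photons per depth.
#' @param seed RNG seed (each depth uses `seed + index`).
#' @param metric width metric, "sigma" or "fwhm".
#' @param geometry template [mc_geometry()]; its source depth (and, for
#'   overlayer, thickness) is replaced by each calibration depth.
#' @export
build_calibration <- function(medium, depths_um, n_photons = 1e5, seed = 1,
                              metric = "sigma",
                              geometry = mc_geometry("embedded")) {
  stopifnot(length(depths_um) >= 3)
  depths_um <- sort(depths_um)
  widths <- vapply(seq_along(depths_um), function(i) {
    g <- geometry
    g$source_depth_um <- depths_um[i]
    if (g$configuration == "slab_overlayer") g$thickness_um <- depths_um[i]
    r <- run_mc(medium, g, n_photons, seed = seed + i)
    surface_width(list(intensity = r$map, x_um = r$x_um, y_um = r$y_um),
                  metric = metric)
  }, numeric(1))
  if (is.unsorted(widths, strictly = TRUE))
    stop("calibration widths not strictly increasing with depth; ",
         "increase n_photons")
  calibration_curve(depths_um, widths, metric = metric,
                    geometry = geometry$configuration)
}

#' Integrating-sphere reflectance and transmittance
#'
#' Collimated normal-incidence beam on a slab: total transmittance (including
#' ballistic) and diffuse reflectance (excluding the specular entry
#' reflection), with Fresnel boundaries at the medium/air interfaces.
#'
#' @param medium an [optical_medium()].
#' @param thickness_um slab thickness.
#' @param n_photons photon packets.
#' @param seed RNG seed.
#' @param n_below index below the slab (default air).
#' @return list: `total_transmittance`, `diffuse_reflectance`,
#'   `ballistic_transmittance`, `specular_reflectance`, `absorbed`.
#' @export
integrating_sphere_rt <- function(medium, thickness_um, n_photons = 1e5,
                                  seed = NULL, n_below = 1.0) {
  g <- mc_geometry("beam", thickness_um = thickness_um, source_depth_um = 0,
                   n_above = 1.0, n_below = n_below, nbin = 3, bin_um = 1e5)
  r <- run_mc(medium, g, n_photons, seed)
  list(total_transmittance = r$t_bottom,
       diffuse_reflectance = r$r_top,
       ballistic_transmittance = r$ballistic,
       specular_reflectance = r$specular,
       absorbed = r$absorbed)
}

#' Estimate scattering properties from measured R and T
#'
#' Reverse of the integrating-sphere simulation: grid search over (mu_s, g)
#' minimizing the squared mismatch of simulated vs measured (diffuse
#' reflectance, total transmittance), with mu_a fixed. The full residual
#' surface is returned (the solution can be a valley). A best point on the
#' grid boundary yields status "range too narrow".
#'
#' @param r_meas,t_meas measured diffuse reflectance and total transmittance
#'   (fractions in (0,1)).
#' @param thickness_um sample thickness.
#' @param mu_s_range,g_range search ranges.
#' @param n_mu_s,n_g grid sizes.
#' @param mu_a fixed absorption (1/mm).
#' @param n,n_below medium and substrate refractive indices.
#' @param n_photons photons per grid point.
#' @param seed RNG seed.
#' @return list: `mu_s`, `g`, `status`, `residual` (matrix), `mu_s_grid`,
#'   `g_grid`.
#' @export
invert_optical_properties <- function(r_meas, t_meas, thickness_um,
                                      mu_s_range = c(20, 120),
                                      g_range = c(0.5, 0.95),
                                      n_mu_s = 7, n_g = 7, mu_a = 0.2,
                                      n = 1.41, n_below = 1.0,
                                      n_photons = 2e4, seed = 1) {
  stopifnot(r_meas > 0, r_meas < 1, t_meas > 0, t_meas < 1)
  mu_s_grid <- seq(mu_s_range[1], mu_s_range[2], length.out = n_mu_s)
  g_grid <- seq(g_range[1], g_range[2], length.out = n_g)
  resid <- matrix(NA_real_, n_mu_s, n_g,
                  dimnames = list(signif(mu_s_grid, 4), signif(g_grid, 4)))
  for (i in seq_len(n_mu_s)) {
    for (j in seq_len(n_g)) {
      med <- optical_medium(mu_s_grid[i], mu_a, g_grid[j], n)
      rt <- integrating_sphere_rt(med, thickness_um, n_photons,
                                  seed = seed + i * 1000L + j,
                                  n_below = n_below)
      resid[i, j] <- (rt$diffuse_reflectance - r_meas)^2 +
        (rt$total_transmittance - t_meas)^2
    }
  }
  k <- which(resid == min(resid), arr.ind = TRUE)[1, ]
  on_edge <- k[1] %in% c(1, n_mu_s) || k[2] %in% c(1, n_g)
  list(mu_s = mu_s_grid[k[1]], g = g_grid[k[2]],
       status = if (on_edge) "range too narrow" else "ok",
       residual = resid, mu_s_grid = mu_s_grid, g_grid = g_grid)
}
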