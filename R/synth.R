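# Ground-truthed synthetic scenes and hyperspectral cubes.
#
# The generator composes the eigenmode solver (per-bead combs), a depth-
# dependent diffuse surface footprint, Lorentzian line shapes, a smooth
# fluorescence background and Poisson noise, and records everything in a
# manifest so every pipeline stage can be tested against known truth.

#' Sample a microcavity bead population
#'
#' Diameters are Gaussian (truncated at > 0) with the stated mean and
#' coefficient of variation; the per-bead external index is drawn per
#' environment: growth medium 1.34 (sd 0.001), cytoplasm 1.37 (sd 0.004, a
#' slow-drift scale), interstitial 1.355 (sd 0.004).
#'
#' @param n number of beads.
#' @param mean_um mean diameter (um).
#' @param cv coefficient of variation of the diameter.
#' @param environment one of "medium", "cytoplasm", "interstitial", or a
#'   vector (recycled to length n).
#' @param n_internal internal refractive index.
#' @param seed RNG seed.
#' @return `bead_population` data.frame: `diameter_um`, `n_internal`,
#'   `n_external`, `environment`.
#' @export
sample_population <- function(n, mean_um = 15, cv = 0.14,
                              environment = "medium", n_internal = 1.59,
                              seed = NULL) {
  stopifnot(n >= 1, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  env <- rep(environment, length.out = n)
  d <- rnorm(n, mean_um, cv * mean_um)
  while (any(d <= 0)) d[d <= 0] <- rnorm(sum(d <= 0), mean_um, cv * mean_um)
  pars <- list(medium = c(1.34, 0.001), cytoplasm = c(1.37, 0.004),
               interstitial = c(1.355, 0.004))
  ne <- vapply(seq_len(n), function(i) {
    p <- pars[[env[i]]]
    if (is.null(p)) stop("unknown environment: ", env[i])
    rnorm(1, p[1], p[2])
  }, numeric(1))
  structure(data.frame(diameter_um = d, n_internal = n_internal,
                       n_external = ne, environment = env),
            class = c("bead_population", "data.frame"))
}

#' Probability that two beads are spectrally indistinguishable
#'
#' Closed form for P(|D1 - D2| < t) with independent D ~ N(mean, (cv mean)^2):
#' the difference is N(0, 2 sigma^2), so P = 2 Phi(t / (sigma sqrt(2))) - 1.
#' Two beads whose diameters differ by less than ~3 nm produce overlapping
#' combs and cannot be told apart.
#'
#' @param mean_um population mean diameter (um).
#' @param cv coefficient of variation.
#' @param threshold_nm diameter-difference threshold (nm).
#' @return probability.
#' @export
pair_indistinguishability_probability <- function(mean_um = 15, cv = 0.14,
                                                  threshold_nm = 3) {
  stopifnot(threshold_nm >= 0)
  sigma <- cv * mean_um
  2 * pnorm((threshold_nm * 1e-3) / (sigma * sqrt(2))) - 1
}

#' Theoretical tagging capacity of a scanned field
#'
#' Number of resolvable microcavities = (scan area / collection spot area) x
#' beads reliably identified per spot, rounded to 2 significant figures.
#'
#' @param scan_area_mm2 scanned area (mm^2).
#' @param spot_diameter_um collection spot diameter (um).
#' @param beads_per_spot microcavities reliably identified per spot.
#' @return estimated count.
#' @export
capacity_estimate <- function(scan_area_mm2 = 9, spot_diameter_um = 200,
                              beads_per_spot = 5) {
  stopifnot(scan_area_mm2 > 0, spot_diameter_um > 0, beads_per_spot > 0)
  spot_mm2 <- pi * (spot_diameter_um / 2e3)^2
  signif(scan_area_mm2 / spot_mm2 * beads_per_spot, 2)
}

#' Define a synthetic scene
#'
#' @param beads a `bead_population` (or data.frame with `diameter_um`,
#'   `n_internal`, `n_external`, `environment`).
#' @param x_um,y_um,depth_um per-bead positions (recycled if scalar).
#' @param medium an [optical_medium()] describing the scattering layer.
#' @param geometry an [mc_geometry()].
#' @return `dsli_scene` list.
#' @export
make_scene <- function(beads, x_um, y_um, depth_um,
                       medium = optical_medium(63, 0.2, 0.87, 1.41),
                       geometry = mc_geometry("embedded")) {
  n <- nrow(beads)
  sc <- data.frame(beads,
                   x_um = rep(x_um, length.out = n),
                   y_um = rep(y_um, length.out = n),
                   depth_um = rep(depth_um, length.out = n))
  structure(list(beads = sc, medium = medium, geometry = geometry),
            class = "dsli_scene")
}

# stylized footprint width (sigma, um) vs depth when no calibration is given:
# linear growth on the transport-length scale with a finite width at depth 0
.default_psf_sigma <- function(depth_um) 15 + 0.55 * depth_um

#' Render a synthetic hyperspectral cube with ground truth
#'
#' Each bead contributes its WGM comb (Lorentzian lines at the eigenmode
#' wavelengths of its diameter and indices, under a smooth dye-emission
#' envelope), spatially weighted by a depth-dependent diffuse footprint.
#' A shared smooth fluorescence background and Poisson shot noise complete
#' the cube. Everything rendered is recorded in the manifest.
#'
#' @param scene a [make_scene()] result.
#' @param x_um,y_um pixel-center axes of the cube (um).
#' @param wavelength_nm spectral axis (nm; default 500-540 at 0.023 nm).
#' @param psf "gaussian" (width from `calibration` or a stylized linear
#'   depth law) or "mc" (footprint simulated by [run_mc()] per bead).
#' @param calibration optional [calibration_curve()] used for Gaussian psf
#'   widths (depth -> sigma).
#' @param q_range per-bead Q-factor range (uniform draw).
#' @param peak_counts peak amplitude scale (counts at the envelope maximum).
#' @param background_counts background level at the envelope maximum
#'   (0 disables).
#' @param noise logical: apply Poisson noise.
#' @param mc_photons photons per bead for `psf = "mc"`.
#' @param seed RNG seed.
#' @param max_radial_order passed to [find_modes()].
#' @return list: `cube` (a [hsi_cube()]) and `manifest` (list with the scene
#'   table, per-bead mode tables with amplitudes, psf widths, settings).
#' @export
render_cube <- function(scene, x_um = seq(0, 315, by = 5),
                        y_um = seq(0, 315, by = 5),
                        wavelength_nm = seq(500, 540, by = 0.023),
                        psf = c("gaussian", "mc"), calibration = NULL,
                        q_range = c(5000, 10000), peak_counts = 400,
                        background_counts = 100, noise = TRUE,
                        mc_photons = 2e5, seed = 1,
                        max_radial_order = 2) {
  psf <- match.arg(psf)
  set.seed(seed)
  b <- scene$beads
  nx <- length(x_um); ny <- length(y_um); nl <- length(wavelength_nm)
  cube <- array(0, dim = c(nx, ny, nl))
  envelope <- exp(-0.5 * ((wavelength_nm - 520) / 18)^2)
  modes_list <- vector("list", nrow(b))
  widths <- numeric(nrow(b))
  ok <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    params <- sphere_params(b$diameter_um[i], b$n_internal[i],
                            b$n_external[i])
    ms <- tryCatch(
      find_modes(params, range(wavelength_nm),
                 max_radial_order = max_radial_order),
      error = function(e) NULL)
    if (is.null(ms) || !nrow(ms)) {
      warning("bead ", i, ": mode solver returned nothing; bead excluded")
      ok[i] <- FALSE
      next
    }
    q_bead <- runif(1, q_range[1], q_range[2])
    amp <- peak_counts * envelope[
      vapply(ms$wavelength_nm, function(l) which.min(abs(wavelength_nm - l)),
             integer(1))]
    # second-radial-order modes are weaker
    amp <- amp * ifelse(ms$radial_order > 1, 0.5, 1)
    gam <- ms$wavelength_nm / q_bead / 2          # HWHM, nm
    spec <- rep(0, nl)
    for (k in seq_len(nrow(ms)))
      spec <- spec + amp[k] * gam[k]^2 /
        ((wavelength_nm - ms$wavelength_nm[k])^2 + gam[k]^2)
    # spatial footprint
    if (psf == "mc") {
      g <- scene$geometry
      g$source_depth_um <- b$depth_um[i]
      if (g$configuration == "slab_overlayer")
        g$thickness_um <- b$depth_um[i]
      r <- run_mc(scene$medium, g, mc_photons, seed = seed + i)
      fp <- .resample_map(r$map, r$x_um + b$x_um[i], r$y_um + b$y_um[i],
                          x_um, y_um)
      widths[i] <- surface_width(list(intensity = r$map, x_um = r$x_um,
                                      y_um = r$y_um))
    } else {
      widths[i] <- if (!is.null(calibration))
        approx(calibration$depth_um, calibration$width_um,
               xout = b$depth_um[i], rule = 2)$y
      else .default_psf_sigma(b$depth_um[i])
      fp <- outer(dnorm(x_um, b$x_um[i], widths[i]),
                  dnorm(y_um, b$y_um[i], widths[i]))
    }
    fp <- fp / max(fp, 1e-300)   # peak_counts = amplitude at the footprint max
    sig <- outer(as.numeric(fp), spec)            # (nx*ny) x nl
    dim(sig) <- c(nx, ny, nl)
    cube <- cube + sig
    ms$amplitude <- amp
    modes_list[[i]] <- ms
  }
  if (background_counts > 0) {
    bg_spec <- background_counts * envelope
    cube <- cube + rep(bg_spec, each = nx * ny)
  }
  if (noise) cube[] <- rpois(length(cube), pmax(cube, 0))
  list(cube = hsi_cube(cube, x_um, y_um, wavelength_nm),
       manifest = list(beads = cbind(b, psf_sigma_um = widths,
                                     rendered = ok),
                       modes = modes_list,
                       settings = list(psf = psf, q_range = q_range,
                                       peak_counts = peak_counts,
                                       background_counts = background_counts,
                                       noise = noise, seed = seed),
                       seed = seed))
}

# nearest-bin resampling of an MC map (bin centers mx, my) onto pixel axes
.resample_map <- function(map, mx, my, x_um, y_um) {
  ix <- findInterval(x_um, mx - diff(mx[1:2]) / 2)
  iy <- findInterval(y_um, my - diff(my[1:2]) / 2)
  out <- matrix(0, length(x_um), length(y_um))
  okx <- ix >= 1 & ix <= length(mx)
  oky <- iy >= 1 & iy <= length(my)
  out[okx, oky] <- map[ix[okx], iy[oky]]
  out
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest manifest from [render_cube()].
#' @param path output file.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
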