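# WGM eigenmode solver for bare and layered dielectric microspheres, and
# comb fitting to retrieve diameter and external refractive index.
#
# Mode convention: the interior regular solution (Riccati psi) is matched to
# the exterior evanescent solution (Riccati chi) at each interface; sign
# changes of the (normalized) boundary mismatch in wavelength mark the real
# eigenwavelengths. All wavelengths are vacuum wavelengths in nm.

#' Bare microsphere parameters
#'
#' @param diameter sphere diameter in um.
#' @param n_internal refractive index of the sphere material. Either a single
#'   number (default convention: polystyrene, constant 1.59) or a function of
#'   vacuum wavelength in nm (see [polystyrene_index()]).
#' @param n_external refractive index of the surrounding medium.
#' @return An object of class `sphere_params`.
#' @export
sphere_params <- function(diameter, n_internal = 1.59, n_external = 1.33) {
  stopifnot(is.numeric(diameter), length(diameter) == 1, diameter > 0)
  ni <- if (is.function(n_internal)) n_internal(589) else n_internal
  stopifnot(is.numeric(ni), is.numeric(n_external))
  if (ni <= n_external)
    warning("n_internal <= n_external: no confined whispering-gallery modes")
  if (n_external < 1)
    warning("n_external < 1 is unphysical for dielectric media")
  structure(list(diameter = diameter, n_internal = n_internal,
                 n_external = n_external),
            class = "sphere_params")
}

#' Layered (coated) microsphere parameters
#'
#' @param layer_radii strictly increasing outer radii of the layers in um;
#'   the last value is the total (coated) sphere radius.
#' @param layer_indices refractive indices: one per layer (inside out) plus a
#'   final value for the surrounding medium, i.e.
#'   `length(layer_indices) == length(layer_radii) + 1`.
#' @return An object of class `layered_sphere_params`.
#' @export
layered_sphere_params <- function(layer_radii, layer_indices) {
  stopifnot(is.numeric(layer_radii), all(layer_radii > 0),
            !is.unsorted(layer_radii, strictly = TRUE),
            length(layer_indices) == length(layer_radii) + 1)
  structure(list(layer_radii = layer_radii, layer_indices = layer_indices),
            class = "layered_sphere_params")
}

#' @export
print.sphere_params <- function(x, ...) {
  ni <- if (is.function(x$n_internal)) "dispersive" else
    format(x$n_internal)
  cat(sprintf("WGM microsphere: d = %.4f um, n_in = %s, n_out = %.4f\n",
              x$diameter, ni, x$n_external))
  invisible(x)
}

#' @export
print.layered_sphere_params <- function(x, ...) {
  cat(sprintf("Layered WGM microsphere: %d layer(s), outer radius %.4f um\n",
              length(x$layer_radii), max(x$layer_radii)))
  cat("  radii (um):  ", paste(format(x$layer_radii), collapse = ", "), "\n")
  cat("  indices:     ", paste(format(x$layer_indices), collapse = ", "),
      " (last = surrounding)\n")
  invisible(x)
}

#' Refractive index of polystyrene (Sellmeier dispersion)
#'
#' One-term Sellmeier fit for polystyrene in the visible; returns ~1.59 at
#' 589 nm, the value usually quoted for microsphere probes.
#'
#' @param lambda_nm vacuum wavelength(s) in nm.
#' @return refractive index (same length as `lambda_nm`).
#' @export
polystyrene_index <- function(lambda_nm) {
  l2 <- (lambda_nm / 1000)^2
  sqrt(1 + 1.4435 * l2 / (l2 - 0.020216))
}

.n_at <- function(n, lambda_nm) if (is.function(n)) n(lambda_nm) else n

#' Boundary-condition mismatch of the WGM characteristic equation
#'
#' Evaluates the (normalized) residual of the eigenvalue condition for a
#' spherical resonator at given wavelengths: zero crossings in wavelength are
#' eigenmodes of the given polarization and angular order. For the bare sphere
#' the TE/TM conditions are the classic Riccati-Bessel matching of the
#' interior regular solution onto the exterior evanescent solution; for
#' layered spheres the interior solution is propagated through each coating
#' by a transfer matrix before matching.
#'
#' @param params a [sphere_params()] or [layered_sphere_params()] object.
#' @param polarization "TE" or "TM".
#' @param angular_order positive integer angular mode number l.
#' @param wavelength_nm vector of vacuum wavelengths (nm).
#' @return numeric vector of residuals; unevaluable points (special-function
#'   overflow) are returned as `NA` with a warning.
#' @export
characteristic_residual <- function(params, polarization, angular_order,
                                    wavelength_nm) {
  stopifnot(polarization %in% c("TE", "TM"),
            angular_order >= 1, all(wavelength_nm > 0))
  r <- if (inherits(params, "layered_sphere_params")) {
    .layered_residual(wavelength_nm, params$layer_radii, params$layer_indices,
                      angular_order, polarization)
  } else {
    ni <- params$n_internal
    if (is.function(ni)) {
      .bare_residual_r(wavelength_nm, params$diameter, ni(wavelength_nm),
                       params$n_external, angular_order, polarization)
    } else {
      .wgm_residual_cpp(wavelength_nm, angular_order, params$diameter,
                        ni, params$n_external, polarization == "TE")
    }
  }
  if (anyNA(r))
    warning("characteristic residual unevaluable at some wavelengths ",
            "(special-function overflow); returned as NA")
  r
}

# bare-sphere residual in R, supporting per-wavelength n_internal
.bare_residual_r <- function(lambda_nm, d_um, n_in, n_out, l, pol) {
  xo <- pi * d_um * 1e3 * n_out / lambda_nm
  xi <- pi * d_um * 1e3 * n_in / lambda_nm
  m <- n_in / n_out
  bi <- .riccati_cpp(l, xi)
  bo <- .riccati_cpp(l, xo)
  r <- if (pol == "TE") bi$psi * bo$dchi - m * bo$chi * bi$dpsi
       else             m * bi$psi * bo$dchi - bo$chi * bi$dpsi
  r / (sqrt(bi$psi^2 + bi$dpsi^2) * sqrt(bo$chi^2 + bo$dchi^2))
}

# layered-sphere residual: propagate (u, v) outward through the layers, where
# u = r R(r) and v = u' (TE) or u'/n^2 (TM) are the continuous quantities.
.layered_residual <- function(lambda_nm, radii_um, indices, l, pol) {
  k <- 2 * pi * 1e3 / lambda_nm               # 1/um, vector over lambda
  K <- length(radii_um)
  cfac <- function(n) if (pol == "TE") n * k else k / n
  b <- .riccati_cpp(l, indices[1] * k * radii_um[1])
  u <- b$psi
  v <- cfac(indices[1]) * b$dpsi
  if (K > 1) {
    for (i in 2:K) {
      ci <- cfac(indices[i])
      bi <- .riccati_cpp(l, indices[i] * k * radii_um[i - 1])
      w <- v / ci
      A <- bi$chi * w - u * bi$dchi       # Wronskian psi chi' - chi psi' = -1
      B <- bi$psi * w - u * bi$dpsi
      B <- -B
      sc <- pmax(abs(A), abs(B), 1e-300)  # keep magnitudes bounded
      A <- A / sc; B <- B / sc
      bo <- .riccati_cpp(l, indices[i] * k * radii_um[i])
      u <- A * bo$psi + B * bo$chi
      v <- ci * (A * bo$dpsi + B * bo$dchi)
    }
  }
  ns <- indices[K + 1]
  bs <- .riccati_cpp(l, ns * k * radii_um[K])
  uo <- bs$chi
  vo <- cfac(ns) * bs$dchi
  (u * vo - v * uo) / (sqrt(u^2 + (v / cfac(1))^2) * sqrt(uo^2 + (vo / cfac(1))^2))
}

# first Airy-function zeros; radial order q of a WGM at angular order l sits
# near size parameter nu + a_q (nu/2)^(1/3), nu = l + 1/2
.airy_zeros <- c(2.338107, 4.087949, 5.520560, 6.786708, 7.944134,
                 9.022651, 10.040174, 11.008524, 11.936016, 12.828777)

#' Find WGM eigenwavelengths in a window
#'
#' Numerically solves the characteristic equation for all TE and TM modes of
#' radial order up to `max_radial_order` whose wavelength falls inside
#' `window`. Roots are bracketed by sign changes on a wavelength grid of step
#' `grid_step` and polished by bisection/Brent to `tol`. Radial orders are
#' assigned by counting roots downward from each angular order's cutoff
#' wavelength.
#'
#' @param params [sphere_params()] or [layered_sphere_params()].
#' @param window wavelength interval (nm), e.g. `c(500, 540)`.
#' @param max_radial_order keep modes with radial order q up to this value
#'   (default 2: higher orders have low Q and are rarely observed).
#' @param grid_step root-bracketing grid step in nm (default 0.05; safe, the
#'   free spectral range is about 3.6 nm for a 15 um probe).
#' @param tol root refinement tolerance in nm.
#' @return A `mode_set`: data.frame with columns `wavelength_nm`,
#'   `polarization`, `angular_order`, `radial_order`, sorted by wavelength.
#'   Empty (with a message) if no confined modes exist in the window.
#' @export
find_modes <- function(params, window = c(500, 540), max_radial_order = 2,
                       grid_step = 0.05, tol = 1e-6) {
  UseMethod("find_modes")
}

.empty_modes <- function(params, window) {
  structure(data.frame(wavelength_nm = numeric(0),
                       polarization = character(0),
                       angular_order = integer(0),
                       radial_order = integer(0)),
            params = params, window = window,
            class = c("mode_set", "data.frame"))
}

# shared scan: given a residual closure res_both(lambda, l) returning
# list(TE = ..., TM = ...) and a size scale pdn = 2 pi a n_ref (nm)
# controlling cutoffs, enumerate roots.
.scan_modes <- function(res_both, pdn, window, max_radial_order, grid_step,
                        tol, params) {
  w1 <- window[1]; w2 <- window[2]
  stopifnot(w1 < w2)
  q_est <- function(l, q) {
    nu <- l + 0.5
    pdn / (nu + .airy_zeros[q] * (nu / 2)^(1 / 3))
  }
  l_hi <- max(1, floor(pdn / w1 - 0.5) + 1)
  out <- vector("list", 64); nout <- 0
  l <- l_hi
  while (l >= 1) {
    lam_c <- pdn / (l + 0.5)
    if (q_est(l, max_radial_order) > w2 + 4) break
    hi <- lam_c * 1.02 + 1
    if (hi > w1 + grid_step) {
      grid <- seq(w1, hi, by = grid_step)
      rb <- res_both(grid, l)
      for (pol in c("TE", "TM")) {
        r <- rb[[pol]]
        ok <- is.finite(r)
        sgn <- sign(r)
        idx <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0 &
                       ok[-1] & ok[-length(ok)])
        if (!length(idx)) next
        roots <- vapply(idx, function(i) {
          uniroot(function(x) res_both(x, l)[[pol]], lower = grid[i],
                  upper = grid[i + 1], tol = tol)$root
        }, numeric(1))
        roots <- sort(roots, decreasing = TRUE)
        q <- seq_along(roots)
        keep <- roots >= w1 & roots <= w2 & q <= max_radial_order
        if (any(keep)) {
          nout <- nout + 1
          out[[nout]] <- data.frame(wavelength_nm = roots[keep],
                                    polarization = pol,
                                    angular_order = l,
                                    radial_order = q[keep])
        }
      }
    }
    l <- l - 1
  }
  if (nout == 0) {
    message("no confined WGM modes found in window [",
            w1, ", ", w2, "] nm")
    return(.empty_modes(params, window))
  }
  modes <- do.call(rbind, out[seq_len(nout)])
  modes <- modes[order(modes$wavelength_nm), , drop = FALSE]
  rownames(modes) <- NULL
  structure(modes, params = params, window = window,
            class = c("mode_set", "data.frame"))
}

#' @export
find_modes.sphere_params <- function(params, window = c(500, 540),
                                     max_radial_order = 2, grid_step = 0.05,
                                     tol = 1e-6) {
  ni_mid <- .n_at(params$n_internal, mean(window))
  if (ni_mid <= params$n_external) {
    message("index-matched or inverted sphere: no confined modes")
    return(.empty_modes(params, window))
  }
  d <- params$diameter
  ne <- params$n_external
  ni <- params$n_internal
  if (is.function(ni)) {
    res_both <- function(lam, l)
      list(TE = .bare_residual_r(lam, d, ni(lam), ne, l, "TE"),
           TM = .bare_residual_r(lam, d, ni(lam), ne, l, "TM"))
  } else {
    res_both <- function(lam, l)
      .wgm_residual_both_cpp(lam, l, d, ni, ne)
  }
  pdn <- pi * d * 1e3 * max(.n_at(ni, window))
  .scan_modes(res_both, pdn, window, max_radial_order, grid_step, tol, params)
}

#' @export
find_modes.layered_sphere_params <- function(params, window = c(500, 540),
                                             max_radial_order = 2,
                                             grid_step = 0.05, tol = 1e-6) {
  radii <- params$layer_radii
  idx <- params$layer_indices
  if (max(idx[-length(idx)]) <= idx[length(idx)]) {
    message("no layer index exceeds the surrounding index: no confined modes")
    return(.empty_modes(params, window))
  }
  res_both <- function(lam, l)
    list(TE = .layered_residual(lam, radii, idx, l, "TE"),
         TM = .layered_residual(lam, radii, idx, l, "TM"))
  # confinement scale: a mode guided in layer i has its cutoff near
  # 2 pi r_i n_i; take the largest over the layers
  pdn <- 2 * pi * 1e3 * max(radii * idx[-length(idx)])
  .scan_modes(res_both, pdn, window, max_radial_order, grid_step, tol, params)
}

#' Eigenmodes of a layered (coated) microsphere
#'
#' Convenience wrapper: identical to calling [find_modes()] on a
#' [layered_sphere_params()] object.
#'
#' @inheritParams find_modes
#' @export
find_modes_layered <- function(params, window = c(500, 540),
                               max_radial_order = 2, grid_step = 0.05,
                               tol = 1e-6) {
  stopifnot(inherits(params, "layered_sphere_params"))
  find_modes(params, window, max_radial_order, grid_step, tol)
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("WGM mode set: %d modes in [%g, %g] nm\n", nrow(x),
              attr(x, "window")[1], attr(x, "window")[2]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Analytic free-spectral-range estimate
#'
#' The comb of WGM resonances of one microsphere is (to leading order) equally
#' spaced in 1/lambda with spacing `1/(pi n d)`; near a wavelength `lambda`
#' the corresponding local wavelength spacing is `lambda^2/(pi n d)`.
#'
#' @param diameter sphere diameter (um).
#' @param n_internal sphere refractive index.
#' @param wavelength_nm reference wavelength (nm).
#' @return list with `fsr_per_um` (spacing in 1/lambda, 1/um) and
#'   `dlambda_nm` (local wavelength spacing, nm).
#' @export
fsr_estimate <- function(diameter, n_internal, wavelength_nm) {
  stopifnot(diameter > 0, n_internal > 0, wavelength_nm > 0)
  list(fsr_per_um = 1 / (pi * n_internal * diameter),
       dlambda_nm = wavelength_nm^2 / (pi * n_internal * diameter * 1e3))
}

.peak_lambdas <- function(peaks) {
  if (is.data.frame(peaks)) peaks$wavelength_nm else as.numeric(peaks)
}

#' Diameter from the free spectral range alone
#'
#' Robust comb-spacing estimate: adjacent spacings in 1/lambda are divided by
#' their nearest integer multiple of the smallest spacing (so missing comb
#' teeth do not bias the result), and the median spacing is inverted through
#' the analytic FSR relation. Lower accuracy than the full fit (~6 nm class);
#' used as a fallback and as the seed for [fit_size_index()].
#'
#' @param peaks peak wavelengths (nm), or a data.frame with `wavelength_nm`.
#' @param n_internal sphere refractive index (known in advance).
#' @param match_tolerance comb-matching tolerance in 1/um (see
#'   [default_match_tolerance()]).
#' @param fsr_range admissible FSR range in 1/um.
#' @return list with `diameter_um`, `sd_um` (uncertainty estimate),
#'   `fsr_per_um` and `n_teeth`.
#' @export
size_from_fsr <- function(peaks, n_internal = 1.59,
                          match_tolerance = default_match_tolerance(),
                          fsr_range = c(0.005, 0.05)) {
  lam <- sort(.peak_lambdas(peaks))
  if (length(lam) < 2) stop("size_from_fsr needs at least 2 peaks")
  inv <- sort(1e3 / lam)                        # 1/um
  if (length(lam) == 2) {
    fsr <- diff(inv)
    vals <- fsr
  } else {
    # the comb may contain both polarization sub-combs (same FSR, offset
    # phase): score every pairwise spacing by how many peaks its propagated
    # comb matches, per anchor, and pool the winners
    vals <- rep(NA_real_, length(inv))
    for (i in seq_along(inv)) {
      best_s <- 0L; best_f <- NA_real_
      for (j in seq_along(inv)) {
        if (j == i) next
        f <- abs(inv[i] - inv[j])
        if (f < fsr_range[1] || f > fsr_range[2]) next
        s <- .comb_support(inv, inv[i], f, match_tolerance)
        if (s > best_s || (s == best_s && !is.na(best_f) && f < best_f)) {
          best_s <- s; best_f <- f
        }
      }
      if (best_s >= min(3, length(inv))) vals[i] <- best_f
    }
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("no consistent comb spacing found")
    fsr <- median(vals)
  }
  ni <- .n_at(n_internal, median(lam))
  lam_ref <- median(lam)
  # leading-order inversion, then an Airy-expansion correction for the slow
  # growth of the mode spacing with angular order
  d <- 1 / (pi * ni * fsr)
  for (it in 1:3) {
    nu <- pi * d * ni * 1e3 / lam_ref
    fcorr <- 1 + (.airy_zeros[1] / 6) * (nu / 2)^(-2 / 3) -
      (.airy_zeros[1]^2 / 40) * (nu / 2)^(-4 / 3)
    d <- fcorr / (pi * ni * fsr)
  }
  # consistency refinement against the eigenmode solver: by scale invariance
  # the local q = 1 spacing is solved once and the diameter rescaled
  d <- tryCatch(.fsr_solver_refine(d, ni, fsr, lam_ref), error = function(e) d)
  sd_fsr <- if (length(vals) > 1) max(sd(vals), 1e-12) / sqrt(length(vals))
    else fsr * 2e-3   # two peaks: spectrometer-resolution-limited
  list(diameter_um = d, sd_um = d * sd_fsr / fsr,
       fsr_per_um = fsr, n_teeth = length(lam))
}

# local solver spacing: adjacent q=1 TE modes around lambda_ref for (d, n_in)
# with a nominal external index; iterate d <- d * fsr_solver / fsr_measured
.fsr_solver_refine <- function(d, n_in, fsr_meas, lam_ref, n_ext = 1.35,
                               iters = 2) {
  for (it in seq_len(iters)) {
    dl <- lam_ref^2 * fsr_meas * 1e-3            # local spacing estimate, nm
    ms <- find_modes(sphere_params(d, n_in, n_ext),
                     window = lam_ref + c(-1.4, 1.4) * dl,
                     max_radial_order = 1)
    te <- ms$wavelength_nm[ms$polarization == "TE"]
    if (length(te) < 2) return(d)
    k <- which.min(abs(te - lam_ref))
    k2 <- if (k < length(te)) k + 1 else k - 1
    fsr_solver <- abs(1e3 / te[k] - 1e3 / te[k2])
    d_new <- d * fsr_solver / fsr_meas
    if (abs(d_new - d) < 1e-5) return(d_new)
    d <- d_new
  }
  d
}

# fast non-exclusive nearest-mode metric (coarse grid search only)
.comb_metric_nearest <- function(peaks, mode_lam, penalty = 1.0) {
  if (!length(mode_lam)) return(penalty)
  ms <- sort(mode_lam)
  i <- findInterval(peaks, ms, all.inside = TRUE)
  d <- pmin(abs(peaks - ms[i]), abs(peaks - ms[pmin(i + 1, length(ms))]))
  mean(pmin(d, penalty))
}

# greedy one-to-one nearest assignment of peaks to modes; mean |mismatch| in
# nm, unmatched peaks penalized. Ties broken toward smaller wavelength
# (order() is stable on the wavelength-sorted inputs).
.comb_metric <- function(peaks, mode_lam, penalty = 1.0, want_pairs = FALSE) {
  np <- length(peaks); nm <- length(mode_lam)
  if (nm == 0) {
    return(if (want_pairs) list(score = penalty, pairs = integer(0))
           else penalty)
  }
  dm <- abs(outer(peaks, mode_lam, "-"))
  ord <- order(dm)
  used_p <- logical(np); used_m <- logical(nm)
  pairs <- rep(NA_integer_, np)
  n_assigned <- 0
  for (k in ord) {
    i <- (k - 1) %% np + 1
    j <- (k - 1) %/% np + 1
    if (used_p[i] || used_m[j]) next
    used_p[i] <- TRUE; used_m[j] <- TRUE
    pairs[i] <- j
    n_assigned <- n_assigned + 1
    if (n_assigned == min(np, nm)) break
  }
  err <- ifelse(is.na(pairs), penalty, dm[cbind(seq_len(np), pairs)])
  score <- mean(pmin(err, penalty))
  if (want_pairs) list(score = score, pairs = pairs) else score
}

#' Fit diameter and external index to a measured WGM comb
#'
#' Retrieves the microsphere diameter and the surrounding refractive index by
#' overlapping the measured peak wavelengths with the theoretical eigenmode
#' wavelengths over a grid of candidate (d, n_ext) values, followed by local
#' refinement (Nelder-Mead plus a Gauss-Newton polish on the matched-mode
#' residuals). The internal refractive index must be known. The fit metric is
#' the mean absolute peak-to-mode mismatch under a greedy one-to-one nearest
#' assignment.
#'
#' The diameter search is seeded by [size_from_fsr()] and restricted to a
#' +/- `d_window` neighbourhood of the seed (the residual landscape is
#' multimodal in d with period ~lambda/(pi n): comb aliasing); set
#' `d_window = Inf` to search the full `d_range`.
#'
#' @param peaks peak wavelengths (nm) of one microcavity's comb, or a
#'   data.frame with a `wavelength_nm` column (e.g. from [detect_peaks()]).
#' @param n_internal known internal refractive index (number or function).
#' @param d_range diameter search range (um).
#' @param n_ext_range external-index search range.
#' @param window wavelength window for the theoretical modes; default spans
#'   the peaks plus one FSR margin.
#' @param max_radial_order see [find_modes()].
#' @param coarse_dd,coarse_dn coarse grid steps (um and RIU).
#' @param d_window half-width (um) of the diameter neighbourhood around the
#'   FSR seed searched on the coarse grid.
#' @param refine logical: run local refinement after the grid search.
#' @param nm_maxit Nelder-Mead iteration cap in the refinement (lower it for
#'   cheap validation fits; the Gauss-Newton polish still runs).
#' @return A `wgm_fit` list: `diameter_um`, `n_external`, `residual_nm`,
#'   `matched_modes` (data.frame), `status` ("ok" or "underdetermined"),
#'   `n_peaks`, `seed`.
#' @export
fit_size_index <- function(peaks, n_internal = 1.59, d_range = c(12, 18),
                           n_ext_range = c(1.33, 1.40), window = NULL,
                           max_radial_order = 2, coarse_dd = 0.005,
                           coarse_dn = 5e-4, d_window = 0.12, refine = TRUE,
                           nm_maxit = 60) {
  lam <- sort(.peak_lambdas(peaks))
  if (is.null(window)) {
    fsr_nm <- if (length(lam) >= 2)
      median(diff(lam)) else 3.6
    window <- range(lam) + c(-1, 1) * max(1, fsr_nm / 2)
  }
  seed <- tryCatch(size_from_fsr(lam, n_internal), error = function(e) NULL)
  if (length(lam) < 4) {
    return(structure(list(
      diameter_um = if (!is.null(seed)) seed$diameter_um else NA_real_,
      diameter_sd_um = if (!is.null(seed)) seed$sd_um else NA_real_,
      n_external = NA_real_, residual_nm = NA_real_,
      matched_modes = NULL, status = "underdetermined",
      n_peaks = length(lam), seed = seed), class = "wgm_fit"))
  }
  d0 <- seed$diameter_um
  dlo <- max(d_range[1], d0 - d_window)
  dhi <- min(d_range[2], d0 + d_window)
  if (dlo >= dhi) { dlo <- d_range[1]; dhi <- d_range[2] }
  d_grid <- seq(dlo, dhi, by = coarse_dd)
  n_grid <- seq(n_ext_range[1], n_ext_range[2], by = coarse_dn)
  dref <- median(d_grid)
  # modes scale linearly with diameter at fixed indices: compute the mode set
  # once per candidate index at dref, then rescale for each candidate d
  wref <- c(window[1] * dref / max(d_grid), window[2] * dref / min(d_grid))
  scores <- matrix(Inf, length(d_grid), length(n_grid))
  mode_cache <- vector("list", length(n_grid))
  for (jn in seq_along(n_grid)) {
    ms <- find_modes(sphere_params(dref, n_internal, n_grid[jn]), wref,
                     max_radial_order = max_radial_order)
    mode_cache[[jn]] <- ms$wavelength_nm
    if (!nrow(ms)) next
    mlam <- ms$wavelength_nm
    for (jd in seq_along(d_grid))
      scores[jd, jn] <- .comb_metric_nearest(lam, mlam * (d_grid[jd] / dref))
  }
  if (!any(is.finite(scores))) {
    return(structure(list(diameter_um = d0, diameter_sd_um = seed$sd_um,
                          n_external = NA_real_, residual_nm = NA_real_,
                          matched_modes = NULL, status = "underdetermined",
                          n_peaks = length(lam), seed = seed),
                     class = "wgm_fit"))
  }
  # the mode comb is dense when both radial orders are modelled, so distinct
  # (d, n) basins can score alike on the coarse grid, and the within-cell
  # quantization error in d (a coherent comb shift) exceeds the across-basin
  # contrast. Exact scale invariance (modes(d s, n) = modes(d, n) s) lets
  # each candidate cell be polished to its basin floor in d at no solver
  # cost; basins are then ranked by floor.
  floor_polish <- function(jd, jn) {
    mlam <- mode_cache[[jn]]
    if (!length(mlam)) return(list(score = Inf, d = d_grid[jd]))
    s <- d_grid[jd] / dref
    for (it in 1:4) {
      a <- .comb_metric(lam, mlam * s, want_pairs = TRUE)
      ok <- !is.na(a$pairs)
      if (!any(ok)) return(list(score = Inf, d = d_grid[jd]))
      s <- s * median(lam[ok] / (mlam[a$pairs[ok]] * s))
    }
    list(score = .comb_metric(lam, mlam * s), d = dref * s)
  }
  ord <- order(scores)
  ncell <- min(30, sum(is.finite(scores)))
  best <- list(score = Inf, d = dref, n = n_grid[1])
  for (k in ord[seq_len(ncell)]) {
    jd <- (k - 1) %% length(d_grid) + 1
    jn <- (k - 1) %/% length(d_grid) + 1
    fp <- floor_polish(jd, jn)
    if (fp$score < best$score)
      best <- list(score = fp$score, d = fp$d, n = n_grid[jn])
  }
  obj <- function(p) {
    if (p[1] <= 0 || p[2] < 1 || p[2] >= .n_at(n_internal, mean(window)))
      return(10)
    ms <- find_modes(sphere_params(p[1], n_internal, p[2]), window,
                     max_radial_order = max_radial_order)
    .comb_metric(lam, ms$wavelength_nm)
  }
  par <- c(best$d, best$n)
  if (refine) {
    opt <- optim(par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-9, maxit = nm_maxit,
                                parscale = c(1e-3, 1e-4)))
    par <- .fit_polish_gn(opt$par, lam, n_internal, window, max_radial_order)
  }
  ms <- find_modes(sphere_params(par[1], n_internal, par[2]), window,
                   max_radial_order = max_radial_order)
  fin <- .comb_metric(lam, ms$wavelength_nm, want_pairs = TRUE)
  matched <- data.frame(peak_nm = lam,
                        mode_nm = ms$wavelength_nm[fin$pairs],
                        polarization = ms$polarization[fin$pairs],
                        angular_order = ms$angular_order[fin$pairs],
                        radial_order = ms$radial_order[fin$pairs])
  structure(list(diameter_um = par[1], n_external = par[2],
                 residual_nm = fin$score, matched_modes = matched,
                 status = "ok", n_peaks = length(lam), seed = seed),
            class = "wgm_fit")
}

# Gauss-Newton polish with frozen peak-to-mode assignment: drives (d, n_ext)
# to the least-squares optimum of the matched residual vector.
.fit_polish_gn <- function(par, lam, n_internal, window, max_radial_order,
                           iters = 6, hd = 2e-5, hn = 2e-5) {
  resid_vec <- function(p, pairs = NULL) {
    ms <- find_modes(sphere_params(p[1], n_internal, p[2]), window,
                     max_radial_order = max_radial_order)
    if (!nrow(ms)) return(NULL)
    if (is.null(pairs)) {
      a <- .comb_metric(lam, ms$wavelength_nm, want_pairs = TRUE)
      pairs <- a$pairs
    }
    if (anyNA(pairs)) return(NULL)
    list(r = lam - ms$wavelength_nm[pairs], pairs = pairs)
  }
  a0 <- resid_vec(par)
  if (is.null(a0)) return(par)
  pairs <- a0$pairs
  for (it in seq_len(iters)) {
    r0 <- resid_vec(par, pairs); if (is.null(r0)) break
    rd <- resid_vec(par + c(hd, 0), pairs)
    rn <- resid_vec(par + c(0, hn), pairs)
    if (is.null(rd) || is.null(rn)) break
    J <- cbind((rd$r - r0$r) / hd, (rn$r - r0$r) / hn)
    step <- tryCatch(qr.solve(J, -r0$r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # damp absurd steps
    step[1] <- max(min(step[1], 0.01), -0.01)
    step[2] <- max(min(step[2], 0.005), -0.005)
    par2 <- par + step
    r2 <- resid_vec(par2, pairs)
    if (is.null(r2) || mean(abs(r2$r)) > mean(abs(r0$r))) break
    par <- par2
    if (max(abs(step / c(1e-6, 1e-7))) < 1) break
  }
  par
}

#' Retrieve the external index with the diameter held fixed
#'
#' The diameter of a bead is a physical constant, so once it is known (from a
#' full [fit_size_index()] or from fabrication), time-series sensing of the
#' surroundings should fit only the external index. This removes the strong
#' (r ~ -0.99) diameter-index degeneracy of the joint fit and improves the
#' index precision by nearly an order of magnitude at fixed peak noise.
#'
#' @param peaks peak wavelengths (nm) of the bead's comb.
#' @param diameter_um known diameter (um).
#' @param n_internal known internal index.
#' @param n_ext_range search interval.
#' @param window,max_radial_order see [fit_size_index()].
#' @return list: `n_external`, `residual_nm`, `diameter_um`.
#' @export
fit_index_fixed_d <- function(peaks, diameter_um, n_internal = 1.59,
                              n_ext_range = c(1.33, 1.40), window = NULL,
                              max_radial_order = 2) {
  lam <- sort(.peak_lambdas(peaks))
  if (is.null(window)) window <- range(lam) + c(-1, 1) * 2
  obj <- function(n_ext) {
    ms <- find_modes(sphere_params(diameter_um, n_internal, n_ext), window,
                     max_radial_order = max_radial_order)
    .comb_metric(lam, ms$wavelength_nm)
  }
  # coarse scan to avoid local minima, then golden-section polish
  ngrid <- seq(n_ext_range[1], n_ext_range[2], by = 5e-4)
  v <- vapply(ngrid, obj, numeric(1))
  j <- which.min(v)
  lo <- ngrid[max(1, j - 1)]; hi <- ngrid[min(length(ngrid), j + 1)]
  op <- optimize(obj, c(lo, hi), tol = 1e-8)
  n_ext <- op$minimum
  # least-squares polish on the matched residuals (frozen assignment)
  modes_at <- function(n) {
    find_modes(sphere_params(diameter_um, n_internal, n), window,
               max_radial_order = max_radial_order)$wavelength_nm
  }
  m0 <- modes_at(n_ext)
  a <- .comb_metric(lam, m0, want_pairs = TRUE)
  if (!anyNA(a$pairs)) {
    hn <- 1e-5
    for (it in 1:3) {
      r0 <- lam - modes_at(n_ext)[a$pairs]
      Jn <- (modes_at(n_ext + hn)[a$pairs] - (lam - r0)) / hn
      step <- sum(Jn * r0) / sum(Jn^2)
      if (!is.finite(step)) break
      n_ext <- n_ext + step
      if (abs(step) < 1e-8) break
    }
  }
  list(n_external = n_ext, residual_nm = obj(n_ext),
       diameter_um = diameter_um)
}

#' @export
print.wgm_fit <- function(x, ...) {
  if (x$status == "underdetermined") {
    cat(sprintf("WGM fit (underdetermined, %d peaks): d = %.4f um (FSR only, sd %.4g um)\n",
                x$n_peaks, x$diameter_um, x$diameter_sd_um))
  } else {
    cat(sprintf("WGM fit: d = %.5f um, n_ext = %.5f, residual = %.4g nm (%d peaks)\n",
                x$diameter_um, x$n_external, x$residual_nm, x$n_peaks))
  }
  invisible(x)
}

#' Export a mode set to CSV
#'
#' @param modes a `mode_set` from [find_modes()].
#' @param path output file.
#' @export
write_modes_csv <- function(modes, path) {
  write.csv(as.data.frame(modes), path, row.names = FALSE)
  invisible(path)
}
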