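# Spectral peak detection and free-spectral-range comb unmixing.
#
# A mixed spectrum collected through a scattering layer contains the combs of
# several microcavities. Peaks of one microcavity are equally spaced in
# 1/lambda; the spacing (FSR) and the comb phase identify the cavity. All
# comb arithmetic is done in 1/lambda (units 1/um), never in wavelength.

#' Construct a spectrum object
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param intensity intensity (counts), same length.
#' @param background optional stored baseline (same grid).
#' @return object of class `dsli_spectrum` (a data.frame).
#' @export
dsli_spectrum <- function(wavelength_nm, intensity, background = NULL) {
  stopifnot(length(wavelength_nm) == length(intensity),
            !is.unsorted(wavelength_nm, strictly = TRUE),
            all(is.finite(intensity)))
  df <- data.frame(wavelength_nm = wavelength_nm, intensity = intensity)
  if (!is.null(background)) df$background <- background
  class(df) <- c("dsli_spectrum", "data.frame")
  df
}

#' Read a two-column spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `intensity` (or the first two columns
#' are taken in that order).
#' @param path CSV file.
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    names(df)[1:2] <- c("wavelength_nm", "intensity")
  dsli_spectrum(df$wavelength_nm, df$intensity)
}

#' Subtract the smooth fluorescence background from a spectrum
#'
#' The dye emission underneath the WGM comb is a smooth curve spanning tens of
#' nm, while the resonance peaks are ~0.1 nm wide. The baseline is estimated
#' with a wide running median (which is blind to the narrow peaks) followed by
#' light smoothing, and subtracted. Negative residual noise is deliberately
#' not clipped.
#'
#' @param spec a [dsli_spectrum()] (or data.frame with `wavelength_nm`,
#'   `intensity`).
#' @param window_nm running-median window width in nm (default 5; must be much
#'   wider than a peak and much narrower than the emission envelope).
#' @return the spectrum with `intensity` baseline-subtracted and the baseline
#'   stored in `background`.
#' @export
subtract_background <- function(spec, window_nm = 5) {
  lam <- spec$wavelength_nm
  dlam <- median(diff(lam))
  k <- max(3, round(window_nm / dlam))
  if (k %% 2 == 0) k <- k + 1
  if (k >= length(lam))
    stop("spectrum shorter than the smoothing window (", window_nm, " nm)")
  base <- runmed(spec$intensity, k, endrule = "median")
  # smooth the piecewise-constant median trace
  ks <- max(3, round(k / 4)); if (ks %% 2 == 0) ks <- ks + 1
  base <- stats::filter(base, rep(1 / ks, ks), sides = 2)
  base <- as.numeric(base)
  na <- is.na(base)
  base[na] <- runmed(spec$intensity, k, endrule = "median")[na]
  dsli_spectrum(lam, spec$intensity - base, background = base)
}

# topographic prominence of local maxima
.prominence <- function(y, idx_max) {
  n <- length(y)
  vapply(idx_max, function(i) {
    h <- y[i]
    # walk left until a higher point; key saddle = min along the way
    lmin <- h
    j <- i - 1
    while (j >= 1 && y[j] <= h) { if (y[j] < lmin) lmin <- y[j]; j <- j - 1 }
    left <- if (j >= 1) lmin else min(y[1:i])
    rmin <- h
    j <- i + 1
    while (j <= n && y[j] <= h) { if (y[j] < rmin) rmin <- y[j]; j <- j + 1 }
    right <- if (j <= n) rmin else min(y[i:n])
    h - max(left, right)
  }, numeric(1))
}

#' Detect WGM peaks in a background-subtracted spectrum
#'
#' Local maxima with topographic prominence above `prominence_threshold` are
#' refined by a local Lorentzian fit (center, width, amplitude, offset) over
#' `fit_window` grid points on each side of the maximum. If a local fit does
#' not converge the raw maximum is kept with `fit_ok = FALSE` and `fwhm_nm`
#' from the half-maximum crossings.
#'
#' @param spec background-subtracted [dsli_spectrum()].
#' @param prominence_threshold minimum prominence in counts; `NULL` (default)
#'   uses 8x the robust noise level (the median absolute successive
#'   difference scaled to a Gaussian sd).
#' @param fit_window half-width of the Lorentzian fit window in grid points
#'   (default 5; peaks are ~3 points wide at Q ~ 7000 and 0.023 nm sampling).
#' @return `peak_list` data.frame: `wavelength_nm`, `sigma_nm` (standard
#'   error of the fitted center), `fwhm_nm`, `prominence`, `amplitude`,
#'   `q_factor`, `fit_ok`.
#' @export
detect_peaks <- function(spec, prominence_threshold = NULL, fit_window = 5) {
  lam <- spec$wavelength_nm
  y <- spec$intensity
  n <- length(y)
  if (is.null(prominence_threshold))
    prominence_threshold <- 8 * stats::mad(diff(y)) / sqrt(2)
  cand <- which(diff(sign(diff(y))) < 0) + 1
  if (length(cand)) {
    prom <- .prominence(y, cand)
    keep <- prom >= prominence_threshold
    cand <- cand[keep]; prom <- prom[keep]
  }
  if (!length(cand)) {
    return(structure(data.frame(wavelength_nm = numeric(0),
                                fwhm_nm = numeric(0), prominence = numeric(0),
                                amplitude = numeric(0), q_factor = numeric(0),
                                fit_ok = logical(0)),
                     class = c("peak_list", "data.frame")))
  }
  dlam <- median(diff(lam))
  fits <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    sel <- max(1, i - fit_window):min(n, i + fit_window)
    xs <- lam[sel]; ys <- y[sel]
    # initialize gamma (HWHM) from half-max crossings
    half <- y[i] / 2
    li <- i; while (li > 1 && y[li] > half) li <- li - 1
    ri <- i; while (ri < n && y[ri] > half) ri <- ri + 1
    g0 <- max((lam[ri] - lam[li]) / 2, dlam / 2)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ys ~ A * g^2 / ((xs - x0)^2 + g^2) + c0,
        start = list(A = y[i], x0 = lam[i], g = g0, c0 = min(ys)),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(wavelength_nm = lam[i], sigma_nm = dlam,
                        fwhm_nm = 2 * g0, prominence = prom[k],
                        amplitude = y[i], fit_ok = FALSE))
    }
    cf <- coef(fit)
    ok <- cf[["g"]] > 0 && abs(cf[["x0"]] - lam[i]) < fit_window * dlam
    if (!ok) {
      return(data.frame(wavelength_nm = lam[i], sigma_nm = dlam,
                        fwhm_nm = 2 * g0, prominence = prom[k],
                        amplitude = y[i], fit_ok = FALSE))
    }
    se <- tryCatch(summary(fit)$coefficients["x0", "Std. Error"],
                   error = function(e) NA_real_)
    data.frame(wavelength_nm = cf[["x0"]], sigma_nm = se,
               fwhm_nm = 2 * cf[["g"]], prominence = prom[k],
               amplitude = cf[["A"]], fit_ok = TRUE)
  })
  out <- do.call(rbind, fits)
  out$q_factor <- out$wavelength_nm / out$fwhm_nm
  out <- out[order(out$wavelength_nm),
             c("wavelength_nm", "sigma_nm", "fwhm_nm", "prominence",
               "amplitude", "q_factor", "fit_ok")]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"))
}

#' Default comb-matching tolerance in 1/lambda
#'
#' Half the spectrometer resolution expressed in 1/lambda at a reference
#' wavelength: propagation matching must tolerate grid quantization.
#'
#' @param resolution_nm spectrometer resolution (default 0.023 nm).
#' @param lambda_nm reference wavelength (default 520 nm).
#' @return tolerance in 1/um.
#' @export
default_match_tolerance <- function(resolution_nm = 0.023, lambda_nm = 520) {
  0.5 * resolution_nm * 1e3 / lambda_nm^2
}

#' Noise-aware comb-matching tolerance
#'
#' Comb matching must tolerate both the wavelength-grid quantization (see
#' [default_match_tolerance()]) and the measured peak-center uncertainty:
#' the difference of two fitted centers has standard deviation
#' `sigma sqrt(2)`. This returns the quadrature sum of the quantization term
#' and `2 sigma sqrt(2)` (a ~2 sigma acceptance for true pairs), in 1/um.
#'
#' @param sigma_nm per-peak center uncertainty (nm): a number or the
#'   `sigma_nm` column of a `peak_list` (the median is used).
#' @param lambda_nm reference wavelength (nm).
#' @param resolution_nm spectrometer resolution (nm).
#' @export
noise_match_tolerance <- function(sigma_nm, lambda_nm = 520,
                                  resolution_nm = 0.023) {
  s <- median(sigma_nm, na.rm = TRUE)
  if (!is.finite(s)) s <- 0
  q <- default_match_tolerance(resolution_nm, lambda_nm)
  sqrt(q^2 + (2 * sqrt(2) * s * 1e3 / lambda_nm^2)^2)
}

# matches of a propagated comb: how many of inv (sorted 1/lambda values, 1/um)
# lie within tolerance of {inv0 + N * fsr}. The candidate FSR comes from a
# single peak pair, so its error propagates linearly with the tooth index N:
# the acceptance window grows as tol * (1 + |N| / 2).
.comb_support <- function(inv, inv0, fsr, tol) {
  r <- (inv - inv0) / fsr
  N <- round(r)
  sum(abs(r - N) * fsr <= tol * (1 + abs(N) / 2))
}

#' Assign a free-spectral-range value to every peak
#'
#' For each peak i, the candidate FSR from every partner j (the 1/lambda
#' separation) is propagated across the spectrum as a comb anchored at peak i
#' and refined by least squares over the teeth it matches; the candidate with
#' the best two-sided overlap -- observed peaks matched, with predicted
#' positions lacking an observed peak voting against at half weight (which
#' rejects subharmonics) -- wins, ties broken toward the smaller FSR. Peaks
#' whose best candidate matches fewer than `min_support` observed peaks are
#' left unassigned.
#'
#' @param peaks `peak_list` or numeric vector of wavelengths (nm).
#' @param match_tolerance comb-matching tolerance in 1/um (default
#'   [default_match_tolerance()]).
#' @param min_support minimum number of matched comb teeth (default 4;
#'   rejects chance alignments at realistic peak densities).
#' @param fsr_range admissible FSR range in 1/um (default c(0.005, 0.05),
#'   i.e. diameters ~4-40 um for polystyrene).
#' @return data.frame: `wavelength_nm`, `fsr_per_um`, `support` (matched
#'   peak count of the winning comb), `partner`. Unassigned peaks have
#'   `fsr_per_um = NA`.
#' @export
assign_fsr <- function(peaks, match_tolerance = default_match_tolerance(),
                       min_support = 4, fsr_range = c(0.005, 0.05)) {
  lam <- .peak_lambdas(peaks)
  n <- length(lam)
  out <- data.frame(wavelength_nm = lam, fsr_per_um = NA_real_,
                    support = NA_integer_, partner = NA_integer_)
  if (n < 3) return(out)
  inv <- 1e3 / lam
  for (i in seq_len(n)) {
    best_s <- 0; best_f <- Inf; best_j <- NA_integer_; best_m <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      fsr0 <- abs(inv[i] - inv[j])
      if (fsr0 < fsr_range[1] || fsr0 > fsr_range[2]) next
      # a single-pair FSR carries the two peaks' position errors, which
      # accumulate linearly along the propagated comb: match first with a
      # window growing in |N|, then refine the FSR by least squares over the
      # matched teeth and count support strictly against the refined comb
      r <- (inv - inv[i]) / fsr0
      N <- round(r)
      m <- abs(r - N) * fsr0 <= match_tolerance * (1 + abs(N) / 2)
      if (sum(m) < 3 || sum(N[m]^2) == 0) next
      # anchored at peak i (N = 0 there), so the refined comb cannot slide
      # onto a different microcavity's comb
      b <- sum((inv[m] - inv[i]) * N[m]) / sum(N[m]^2)
      if (b < fsr_range[1] || b > fsr_range[2]) next
      r2 <- (inv - inv[i]) / b
      hit <- abs(r2 - round(r2)) * b <= match_tolerance
      matched_N <- unique(round(r2[hit]))
      m_cnt <- length(matched_N)
      if (m_cnt < min_support) next
      # two-sided overlap: predicted teeth inside the matched span with no
      # observed peak vote against the candidate at half weight. This
      # rejects subharmonics FSR/k (k-1 empty positions per true tooth)
      # while a genuine comb with a few blended-away teeth survives.
      span_N <- seq(min(matched_N), max(matched_N))
      empty <- length(setdiff(span_N, matched_N))
      score <- m_cnt - empty / 2
      if (score > best_s || (score == best_s && b < best_f)) {
        best_s <- score; best_f <- b; best_j <- j; best_m <- m_cnt
      }
    }
    if (best_m >= min_support && best_s > 0) {
      out$fsr_per_um[i] <- best_f
      out$support[i] <- best_m
      out$partner[i] <- best_j
    }
  }
  out
}

# refine group comb by regressing 1/lambda on integer tooth number
.refine_comb <- function(inv, fsr) {
  N <- round((inv - inv[1]) / fsr)
  if (length(unique(N)) < 2) return(list(fsr = fsr, anchor = inv[1], N = N))
  fit <- lm(inv ~ N)
  list(fsr = unname(coef(fit)[2]), anchor = unname(coef(fit)[1]), N = N)
}

#' Group peaks into per-microcavity combs
#'
#' Peaks whose assigned FSR values agree (within `fsr_tolerance`) and whose
#' propagated combs overlap are grouped transitively. After the groups are
#' formed, every peak consistent with a group's comb is added to it, so a
#' peak may belong to more than one group (combs of different microcavities
#' can share a tooth).
#'
#' @param peaks `peak_list` or wavelengths (nm).
#' @param assignments result of [assign_fsr()] (computed if missing).
#' @param match_tolerance comb-matching tolerance in 1/um.
#' @param fsr_rel_tolerance relative FSR agreement tolerance for linking two
#'   peaks into one comb (default 0.012: the local FSR of one sub-comb drifts
#'   by up to ~1% across the spectrum; radial-order sub-combs differ by ~2%
#'   and must stay separate here -- they are merged later, with solver
#'   validation, by [pair_te_tm()]).
#' @param min_support passed to [assign_fsr()] when `assignments` is missing.
#' @param min_exclusive groups owning fewer than this many peaks exclusively
#'   (not claimed by any other group) are dropped as chance alignments.
#' @return list of `peak_group` objects: each has `id`, `fsr_per_um`,
#'   `anchor_per_um` (comb phase), `members` (indices into `peaks`),
#'   `wavelength_nm`, `polarization` (initially "unassigned"), `filled_in`.
#' @export
group_peaks <- function(peaks, assignments = NULL,
                        match_tolerance = default_match_tolerance(),
                        fsr_rel_tolerance = 0.012, min_support = 4,
                        min_exclusive = 2) {
  lam <- .peak_lambdas(peaks)
  if (is.null(assignments))
    assignments <- assign_fsr(lam, match_tolerance, min_support)
  inv <- 1e3 / lam
  assigned <- which(!is.na(assignments$fsr_per_um))
  if (!length(assigned)) return(list())
  # union-find over assigned peaks: same FSR and overlapping combs
  parent <- seq_along(lam)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(assigned)) {
    i <- assigned[a]
    for (b in seq_len(a - 1L)) {
      j <- assigned[b]
      fi <- assignments$fsr_per_um[i]; fj <- assignments$fsr_per_um[j]
      if (abs(fi - fj) > max(match_tolerance, fsr_rel_tolerance * min(fi, fj)))
        next
      r <- (inv[j] - inv[i]) / fi
      if (abs(r - round(r)) * fi > match_tolerance) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(assigned, find, integer(1))
  groups <- split(assigned, roots)
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    mem <- groups[[k]]
    fsr <- median(assignments$fsr_per_um[mem])
    cb <- .refine_comb(sort(inv[mem]), fsr)
    # non-exclusive membership: adopt every peak consistent with this comb
    r <- (inv - cb$anchor) / cb$fsr
    extra <- which(abs(r - round(r)) * cb$fsr <= match_tolerance)
    mem <- sort(union(mem, extra))
    cb <- .refine_comb(sort(inv[mem]), cb$fsr)
    out[[k]] <- structure(list(id = k, fsr_per_um = cb$fsr,
                               anchor_per_um = cb$anchor,
                               members = mem,
                               wavelength_nm = lam[mem],
                               polarization = rep("unassigned", length(mem)),
                               filled_in = numeric(0),
                               flags = character(0)),
                          class = "peak_group")
  }
  # prune chance alignments by ranked coverage: bigger and more coherent
  # combs are accepted first; a later group must contribute at least
  # min_exclusive peaks that no accepted comb already owns (a spurious group
  # is assembled almost entirely from teeth of genuine combs)
  if (length(out) > 1 && min_exclusive > 0) {
    nsz <- vapply(out, function(g) length(g$members), numeric(1))
    dev <- vapply(out, function(g) {
      inv_g <- 1e3 / g$wavelength_nm
      N <- round((inv_g - g$anchor_per_um) / g$fsr_per_um)
      mean(abs(inv_g - (g$anchor_per_um + N * g$fsr_per_um)))
    }, numeric(1))
    keep <- rep(FALSE, length(out))
    covered <- integer(0)
    for (k in order(-nsz, dev)) {
      fresh <- setdiff(out[[k]]$members, covered)
      if (length(fresh) >= min_exclusive) {
        keep[k] <- TRUE
        covered <- union(covered, out[[k]]$members)
      }
    }
    if (any(keep)) out <- out[keep]
  }
  for (k in seq_along(out)) out[[k]]$id <- k
  out
}

#' @export
print.peak_group <- function(x, ...) {
  cat(sprintf("peak group %s: FSR = %.5f 1/um, %d peaks%s%s\n",
              x$id, x$fsr_per_um, length(x$members),
              if (length(x$filled_in))
                sprintf(", %d filled in", length(x$filled_in)) else "",
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Merge TE/TM comb pairs into per-microcavity groups
#'
#' Both polarization combs of one microcavity share the same FSR but have
#' offset comb phases, so [group_peaks()] returns them as two groups. Groups
#' with equal FSR (within `fsr_tolerance`) are candidate pairs. When
#' `n_internal` is supplied, each candidate merge is validated by fitting the
#' combined peak list to the sphere eigenmode model ([fit_size_index()]); a
#' pair that is not consistent with a single sphere (residual above
#' `merge_residual_nm`) is left unmerged, and the accepted fit labels the
#' sub-combs TE/TM. Without `n_internal` the merge is accepted and sub-labels
#' are arbitrary but consistent ("sub1"/"sub2").
#'
#' @param groups list of `peak_group` from [group_peaks()].
#' @param fsr_rel_tolerance relative FSR agreement tolerance for candidate
#'   pairs (default 0.03; sub-combs of one microcavity share the FSR to
#'   within the radial-order dispersion). Use solver validation
#'   (`n_internal`) whenever distinct microcavities may have close FSRs.
#' @param n_internal optional known internal index enabling solver validation.
#' @param merge_residual_nm maximum mean |peak - mode| mismatch (nm) for an
#'   accepted solver-validated merge.
#' @param ... passed to [fit_size_index()] (e.g. `d_range`, `n_ext_range`).
#' @return list of `peak_group`, merged where appropriate; merged groups carry
#'   `polarization` sub-labels and (if fitted) a `fit` element.
#' @export
pair_te_tm <- function(groups, fsr_rel_tolerance = 0.03,
                       n_internal = NULL, merge_residual_nm = 0.02, ...) {
  if (length(groups) < 2) return(groups)
  used <- rep(FALSE, length(groups))
  out <- list()
  for (i in seq_along(groups)) {
    if (used[i]) next
    gi <- groups[[i]]
    merged <- gi
    for (j in seq_along(groups)) {
      if (j <= i || used[j]) next
      gj <- groups[[j]]
      if (abs(gi$fsr_per_um - gj$fsr_per_um) >
            fsr_rel_tolerance * min(gi$fsr_per_um, gj$fsr_per_um)) next
      # same comb phase would have been one group already; candidate TE/TM
      lam_all <- sort(c(merged$wavelength_nm, gj$wavelength_nm))
      accept <- TRUE
      fit <- NULL
      if (!is.null(n_internal)) {
        fit <- tryCatch(fit_size_index(lam_all, n_internal, ...),
                        error = function(e) NULL)
        # robust acceptance: the bulk of the teeth must sit on one sphere's
        # modes (a few blended teeth may be off)
        accept <- FALSE
        if (!is.null(fit) && fit$status == "ok" &&
            !is.null(fit$matched_modes)) {
          dev <- abs(fit$matched_modes$peak_nm - fit$matched_modes$mode_nm)
          # an index pinned at the search boundary means the "sphere" only
          # exists at the edge of the admissible range: not a credible merge
          rng <- list(...)$n_ext_range
          if (is.null(rng)) rng <- c(1.33, 1.40)
          interior <- fit$n_external > rng[1] + 1e-3 &&
            fit$n_external < rng[2] - 1e-3
          accept <- interior && median(dev) <= merge_residual_nm &&
            mean(dev <= 2 * merge_residual_nm) >= 0.7
        }
      }
      if (accept) {
        sub <- c(rep("sub1", length(merged$members)),
                 rep("sub2", length(gj$members)))
        ordm <- order(c(merged$wavelength_nm, gj$wavelength_nm))
        merged$members <- c(merged$members, gj$members)[ordm]
        merged$wavelength_nm <- sort(c(merged$wavelength_nm,
                                       gj$wavelength_nm))
        merged$polarization <- sub[ordm]
        if (!is.null(fit) && !is.null(fit$matched_modes)) {
          mm <- fit$matched_modes
          merged$polarization <- mm$polarization[
            match(round(merged$wavelength_nm, 6), round(mm$peak_nm, 6))]
          merged$fit <- fit
        }
        merged$fsr_per_um <- (gi$fsr_per_um + gj$fsr_per_um) / 2
        used[j] <- TRUE
      }
    }
    used[i] <- TRUE
    out[[length(out) + 1]] <- merged
  }
  for (k in seq_along(out)) out[[k]]$id <- k
  out
}

#' Predict missing comb teeth
#'
#' Lists the comb positions inside the spectral window where no peak was
#' observed (in 1/lambda arithmetic, per the group's refined FSR and phase).
#'
#' @param group a `peak_group`.
#' @param window wavelength window (nm); default spans the observed members.
#' @param match_tolerance tolerance (1/um) for "observed".
#' @return the group with `filled_in` populated (predicted wavelengths, nm).
#' @export
fill_missing_peaks <- function(group, window = NULL,
                               match_tolerance = default_match_tolerance()) {
  if (length(group$members) < 2) stop("group must have at least 2 members")
  if (is.null(window)) window <- range(group$wavelength_nm)
  inv_obs <- sort(1e3 / group$wavelength_nm)
  fsr <- group$fsr_per_um; anchor <- group$anchor_per_um
  inv_win <- sort(1e3 / window)
  Nr <- c(ceiling((inv_win[1] - anchor) / fsr - 1e-9),
          floor((inv_win[2] - anchor) / fsr + 1e-9))
  comb <- anchor + fsr * seq(Nr[1], Nr[2])
  miss <- vapply(comb, function(v) all(abs(inv_obs - v) > match_tolerance),
                 logical(1))
  group$filled_in <- sort(1e3 / comb[miss], decreasing = FALSE)
  group
}

#' Write peak groups to CSV
#'
#' One row per comb tooth (observed or filled in), with columns `group_id`,
#' `polarization`, `wavelength_nm`, `observed`, `fsr_per_um`.
#' @param groups list of `peak_group`.
#' @param path output CSV.
#' @export
write_groups_csv <- function(groups, path) {
  rows <- lapply(groups, function(g) {
    rbind(
      data.frame(group_id = g$id, polarization = g$polarization,
                 wavelength_nm = g$wavelength_nm, observed = TRUE,
                 fsr_per_um = g$fsr_per_um),
      if (length(g$filled_in))
        data.frame(group_id = g$id, polarization = "predicted",
                   wavelength_nm = g$filled_in, observed = FALSE,
                   fsr_per_um = g$fsr_per_um))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
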