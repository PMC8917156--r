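# Shared fixtures and independent oracles.

# ideal comb: n_teeth positions exactly equally spaced in 1/lambda
ideal_comb <- function(anchor_inv_um, fsr_per_um, n_teeth) {
  sort(1e3 / (anchor_inv_um + fsr_per_um * (seq_len(n_teeth) - 1)))
}

# independent brute-force oracle for the FSR assignment: for each peak i try
# every partner j, explicitly enumerate the propagated comb positions across
# the peak span with the |N|-growing acceptance window, refine the spacing by
# a least-squares line through the matched teeth (lm(), a different code path
# from the package's moment arithmetic), and count support strictly against
# the refined comb.
brute_force_fsr <- function(lambda_nm, tol, fsr_range = c(0.005, 0.05)) {
  inv <- 1e3 / lambda_nm
  n <- length(inv)
  out <- data.frame(fsr = rep(NA_real_, n), support = NA_integer_)
  if (n < 3) return(out)
  span <- range(inv)
  for (i in seq_len(n)) {
    best_s <- 0; best_f <- Inf; best_m <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      f <- abs(inv[i] - inv[j])
      if (f < fsr_range[1] || f > fsr_range[2]) next
      Nlo <- floor((span[1] - inv[i]) / f) - 1
      Nhi <- ceiling((span[2] - inv[i]) / f) + 1
      Ns <- Nlo:Nhi
      comb <- inv[i] + f * Ns
      # initial matches under the growing window
      mN <- rep(NA_integer_, n)
      for (k in seq_len(n)) {
        dev <- abs(comb - inv[k])
        h <- which.min(dev)
        if (dev[h] <= tol * (1 + abs(Ns[h]) / 2)) mN[k] <- Ns[h]
      }
      ok <- !is.na(mN)
      if (sum(ok) < 3 || all(mN[ok] == 0)) next
      fit <- lm(I(inv[ok] - inv[i]) ~ 0 + mN[ok])   # anchored at peak i
      b <- coef(fit)[1]
      if (b < fsr_range[1] || b > fsr_range[2]) next
      Ns2 <- Nlo:Nhi
      comb2 <- inv[i] + b * Ns2
      hitN <- unique(unlist(lapply(inv, function(v) {
        h <- which(abs(comb2 - v) <= tol)
        if (length(h)) Ns2[h[which.min(abs(comb2[h] - v))]] else NULL
      })))
      if (is.null(hitN) || length(hitN) < 4) next
      spanN <- seq(min(hitN), max(hitN))
      score <- length(hitN) - length(setdiff(spanN, hitN)) / 2
      if (score > best_s || (score == best_s && b < best_f)) {
        best_s <- score; best_f <- unname(b); best_m <- length(hitN)
      }
    }
    out$fsr[i] <- best_f; out$support[i] <- best_m
  }
  out
}

# render a Lorentzian comb spectrum on a grid
comb_spectrum <- function(grid_nm, centers_nm, amp = 100, q = 7000,
                          background = 0) {
  y <- rep(background, length(grid_nm))
  for (c0 in centers_nm) {
    g <- c0 / q / 2
    y <- y + amp * g^2 / ((grid_nm - c0)^2 + g^2)
  }
  y
}

# quick single-bead scene cube used by several tests
small_scene_cube <- function(diameters, n_ext, x, y, depth, seed = 1,
                             noise = TRUE, q_range = c(5000, 10000),
                             wavelength_nm = seq(505, 535, 0.023),
                             background_counts = 100, max_radial_order = 2) {
  pop <- data.frame(diameter_um = diameters, n_internal = 1.59,
                    n_external = n_ext,
                    environment = "medium")
  sc <- make_scene(pop, x_um = x, y_um = y, depth_um = depth)
  render_cube(sc, x_um = seq(0, 315, 5), y_um = seq(0, 315, 5),
              wavelength_nm = wavelength_nm, seed = seed, noise = noise,
              q_range = q_range, background_counts = background_counts,
              max_radial_order = max_radial_order)
}

linear_test_calibration <- function() {
  d <- c(50, 150, 250, 350)
  calibration_curve(d, 15 + 0.55 * d)
}

# K ideal combs whose extended comb positions stay well clear of every other
# comb's teeth (> 5x the matching tolerance), so that membership purity is a
# meaningful target; anchors are resampled deterministically until clean
well_separated_combs <- function(K, n_teeth = 9, seed = 1,
                                 tol = default_match_tolerance()) {
  set.seed(seed)
  ds <- 13 + (seq_len(K) - 1) * 0.35
  fs <- 1 / (pi * 1.59 * ds)
  for (attempt in 1:200) {
    anchors <- 1.9 + runif(K, 0, 0.01)
    ok <- TRUE
    for (i in seq_len(K)) {
      ext_i <- anchors[i] + fs[i] * (-40:40)
      for (j in seq_len(K)) {
        if (i == j) next
        teeth_j <- anchors[j] + fs[j] * (seq_len(n_teeth) - 1)
        if (min(abs(outer(ext_i, teeth_j, "-"))) < 5 * tol) ok <- FALSE
      }
    }
    if (ok) break
  }
  out <- lapply(seq_len(K), function(i)
    sort(1e3 / (anchors[i] + fs[i] * (seq_len(n_teeth) - 1))))
  attr(out, "anchors") <- anchors
  attr(out, "fs") <- fs
  out
}
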