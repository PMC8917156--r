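# End-to-end orchestration and downstream interpretation: per-bead records,
# environment classification, same-cell inference, tagging/tracking, and
# functionalized-sensor shift readout.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with its default. Override any
#' subset via `dsli_config(unmix = list(prominence = 30))` or load a YAML
#' file with [read_config()].
#'
#' @param ... named blocks (`wgm`, `unmix`, `hsi`, `pipeline`) whose entries
#'   override the defaults.
#' @export
dsli_config <- function(...) {
  cfg <- list(
    wgm = list(n_internal = 1.59, d_range = c(12, 18),
               n_ext_range = c(1.33, 1.40), max_radial_order = 2,
               merge_residual_nm = 0.02),
    unmix = list(prominence = NULL, window_nm = 5, fit_window = 5,
                 match_tolerance = NULL,   # NULL: noise-aware, from peak fits
                 min_support = 4),
    hsi = list(bandwidth_nm = NULL, min_amplitude = 0.05),
    pipeline = list(min_peaks_record = 6, min_peaks_full_fit = 6,
                    scatter_max_um = 20,
                    class_centers = c(out_of_cell = 1.34, in_cell = 1.37),
                    dead_band = 0.002, tiles = c(1, 1),
                    dedupe_d_nm = 3, dedupe_xy_um = 25))
  utils::modifyList(cfg, list(...))
}

#' Read a YAML configuration file
#'
#' @param path YAML file with any subset of the [dsli_config()] blocks.
#' @export
read_config <- function(path) {
  do.call(dsli_config, yaml::read_yaml(path))
}

#' Classify the environment of a microcavity from its external index
#'
#' Nearest class mean with a dead band: the refractive index inside cells
#' (~1.37) is clearly higher than in growth medium (~1.34), so the midpoint
#' (1.355) separates the classes; indices within `dead_band` of the boundary
#' are "undetermined". Confidence is the distance to the boundary in units
#' of the class spread.
#'
#' @param n_external measured external index (vector OK); `NA` gives
#'   "undetermined".
#' @param class_centers named class means (default out_of_cell = 1.34,
#'   in_cell = 1.37).
#' @param dead_band half-width of the undetermined band around the midpoint.
#' @param class_sd class spread used for the confidence (default 0.004).
#' @return data.frame: `environment` (factor), `confidence`.
#' @export
classify_environment <- function(n_external,
                                 class_centers = c(out_of_cell = 1.34,
                                                   in_cell = 1.37),
                                 dead_band = 0.002, class_sd = 0.004) {
  stopifnot(length(class_centers) == 2)
  boundary <- mean(class_centers)
  env <- rep("undetermined", length(n_external))
  conf <- rep(NA_real_, length(n_external))
  okv <- !is.na(n_external)
  lo <- names(class_centers)[which.min(class_centers)]
  hi <- names(class_centers)[which.max(class_centers)]
  dist <- n_external - boundary
  inband <- okv & abs(dist) <= dead_band
  env[okv & dist < -dead_band] <- lo
  env[okv & dist > dead_band] <- hi
  conf[okv & !inband] <- abs(dist[okv & !inband]) / class_sd
  data.frame(environment = factor(env, levels = c(lo, hi, "undetermined")),
             confidence = conf)
}

#' Probability that two in-cell microcavities share a cell
#'
#' Microcavities inside one cell see the same cytoplasm, so their measured
#' external indices agree to within ~0.003 RIU; two beads in different cells
#' draw independent indices from the within-cell population. The pair is a
#' same-cell candidate when |dn| < `threshold`, and the false-positive
#' probability (two distinct cells this close) is the closed form
#' P(|dn| < t) = 2 Phi(t / (sigma sqrt(2))) - 1.
#'
#' @param n_a,n_b measured external indices (in-cell records).
#' @param threshold same-cell decision threshold (RIU).
#' @param cell_sd sd of the within-cell index population (default 0.012, the
#'   observed drift scale of cytoplasm indices).
#' @return list: `candidate` (logical), `delta_n`,
#'   `p_different_cells` (probability of so small a difference by chance).
#' @export
same_cell_probability <- function(n_a, n_b, threshold = 0.003,
                                  cell_sd = 0.012) {
  if (is.na(n_a) || is.na(n_b))
    return(list(candidate = NA, delta_n = NA_real_,
                p_different_cells = NA_real_))
  dn <- abs(n_a - n_b)
  list(candidate = dn < threshold, delta_n = dn,
       p_different_cells = 2 * pnorm(dn / (cell_sd * sqrt(2))) - 1)
}

#' Link records across frames by diameter tag
#'
#' Each microcavity's diameter is stable to ~0.6 nm over time, so it acts as
#' a tag. Links are the optimal one-to-one assignment minimizing total
#' |diameter difference| (bipartite matching), with pairs differing by more
#' than `tol_nm` forbidden. A link is flagged ambiguous when a competing
#' partner lies within `ambiguity_nm` of the chosen one's mismatch.
#'
#' @param frame_a,frame_b data.frames with `id` and `diameter_um`.
#' @param tol_nm tag tolerance (nm, default 3: the comb-resolvability limit).
#' @param ambiguity_nm margin for the ambiguity flag (nm).
#' @return data.frame of links: `id_a`, `id_b`, `delta_d_nm`, `ambiguous`;
#'   attribute `unmatched` lists ids without a partner.
#' @export
track_records <- function(frame_a, frame_b, tol_nm = 3, ambiguity_nm = 1) {
  na <- nrow(frame_a); nb <- nrow(frame_b)
  dd <- abs(outer(frame_a$diameter_um, frame_b$diameter_um, "-")) * 1e3
  allowed <- which(dd <= tol_nm, arr.ind = TRUE)
  if (!nrow(allowed)) {
    out <- data.frame(id_a = character(0), id_b = character(0),
                      delta_d_nm = numeric(0), ambiguous = logical(0))
    attr(out, "unmatched") <- list(a = frame_a$id, b = frame_b$id)
    return(out)
  }
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(t(cbind(allowed[, 1], na + allowed[, 2]))))
  igraph::E(g)$weight <- (tol_nm + 1) - dd[allowed]  # maximize = min cost
  m <- igraph::max_bipartite_match(g)$matching
  ia <- which(!is.na(m[seq_len(na)]))
  ib <- m[ia] - na
  delta <- dd[cbind(ia, ib)]
  amb <- vapply(seq_along(ia), function(k) {
    alt <- sort(dd[ia[k], dd[ia[k], ] <= tol_nm])
    length(alt) > 1 && (alt[2] - delta[k]) < ambiguity_nm
  }, logical(1))
  out <- data.frame(id_a = frame_a$id[ia], id_b = frame_b$id[ib],
                    delta_d_nm = delta, ambiguous = amb)
  attr(out, "unmatched") <- list(a = setdiff(frame_a$id, out$id_a),
                                 b = setdiff(frame_b$id, out$id_b))
  out
}

#' Linear sensor calibration for functionalized microcavities
#'
#' Maps a WGM peak shift (nm) to a physical quantity through a linear
#' response: `quantity = reference_value + shift_nm / sensitivity_nm`.
#'
#' @param quantity "pH", "temperature" or "raw-shift".
#' @param sensitivity_nm response in nm per unit of the quantity (e.g. a
#'   pH-responsive coating shifting -1.6 nm over 3.8 pH units has
#'   sensitivity -0.421 nm/pH; a thermo-responsive one 0.044 nm/degC).
#' @param reference_value quantity at zero shift.
#' @param range validity range of the quantity.
#' @export
sensor_calibration <- function(quantity = c("raw-shift", "pH", "temperature"),
                               sensitivity_nm = 1, reference_value = 0,
                               range = c(-Inf, Inf)) {
  quantity <- match.arg(quantity)
  if (quantity != "raw-shift" && sensitivity_nm == 0)
    stop("sensitivity must be nonzero")
  structure(list(quantity = quantity, sensitivity_nm = sensitivity_nm,
                 reference_value = reference_value, range = range),
            class = "sensor_calibration")
}

#' Track WGM peak shifts across conditions and read out a sensor
#'
#' Matches the comb teeth of one microcavity across conditions (nearest
#' neighbour within `max_shift_nm`), averages the per-tooth shifts relative
#' to the reference condition, and optionally converts the mean shift to a
#' calibrated quantity. The standard error of the mean shift is propagated.
#'
#' @param peak_series list of numeric vectors: the group's peak wavelengths
#'   (nm) per condition.
#' @param reference index of the reference condition (default 1).
#' @param calibration optional [sensor_calibration()].
#' @param max_shift_nm maximum credible per-tooth shift (teeth farther than
#'   this from any reference tooth cause an error: comb mismatch).
#' @return data.frame: `condition`, `shift_nm`, `se_nm`, `n_teeth`, and
#'   `quantity` when calibrated.
#' @export
peak_shift_series <- function(peak_series, reference = 1, calibration = NULL,
                              max_shift_nm = 2.5) {
  stopifnot(is.list(peak_series), length(peak_series) >= 1)
  ref <- sort(peak_series[[reference]])
  out <- lapply(seq_along(peak_series), function(i) {
    lam <- sort(peak_series[[i]])
    j <- vapply(lam, function(l) which.min(abs(ref - l)), integer(1))
    d <- lam - ref[j]
    if (any(abs(d) > max_shift_nm))
      stop("comb mismatch between condition ", i, " and the reference ",
           "(shift exceeds ", max_shift_nm, " nm)")
    data.frame(condition = i, shift_nm = mean(d),
               se_nm = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0,
               n_teeth = length(d))
  })
  out <- do.call(rbind, out)
  if (!is.null(calibration) && calibration$quantity != "raw-shift") {
    out$quantity <- calibration$reference_value +
      out$shift_nm / calibration$sensitivity_nm
    out$quantity_se <- abs(out$se_nm / calibration$sensitivity_nm)
  }
  out
}

# process one tile: spectral sum -> peaks -> combs -> per-group record
.dsli_tile <- function(cube, cfg, calibration, tile_id) {
  spec <- spectral_sum(cube, subtract = TRUE,
                       window_nm = cfg$unmix$window_nm)
  spec <- dsli_spectrum(spec$wavelength_nm, spec$intensity)
  peaks <- detect_peaks(spec, cfg$unmix$prominence, cfg$unmix$fit_window)
  if (nrow(peaks) < cfg$pipeline$min_peaks_record) return(NULL)
  tol <- cfg$unmix$match_tolerance
  if (is.null(tol))
    tol <- noise_match_tolerance(peaks$sigma_nm,
                                 median(peaks$wavelength_nm))
  groups <- group_peaks(peaks, match_tolerance = tol,
                        min_support = cfg$unmix$min_support)
  if (!length(groups)) return(NULL)
  groups <- pair_te_tm(groups, n_internal = cfg$wgm$n_internal,
                       merge_residual_nm = cfg$wgm$merge_residual_nm,
                       d_range = cfg$wgm$d_range,
                       n_ext_range = cfg$wgm$n_ext_range,
                       max_radial_order = cfg$wgm$max_radial_order,
                       coarse_dn = 2e-3, nm_maxit = 20)
  recs <- lapply(groups, function(g) {
    if (length(g$members) < cfg$pipeline$min_peaks_record) return(NULL)
    loc <- tryCatch(
      localize_microcavity(cube, g, cfg$hsi$bandwidth_nm,
                           cfg$hsi$min_amplitude),
      error = function(e) NULL)
    if (is.null(loc)) return(NULL)
    # a genuine microcavity's comb teeth all localize to the same spot;
    # chance-aligned teeth from different beads do not
    if (!is.na(loc$scatter_um) && loc$scatter_um > cfg$pipeline$scatter_max_um)
      return(NULL)
    depth <- if (!is.null(calibration)) {
      suppressWarnings(depth_from_width(loc$width_um, calibration))
    } else NA_real_
    flags <- character(0)
    if (length(g$members) >= cfg$pipeline$min_peaks_full_fit) {
      fit <- tryCatch(
        fit_size_index(g$wavelength_nm, cfg$wgm$n_internal,
                       d_range = cfg$wgm$d_range,
                       n_ext_range = cfg$wgm$n_ext_range,
                       max_radial_order = cfg$wgm$max_radial_order),
        error = function(e) NULL)
    } else fit <- NULL
    if (is.null(fit) || fit$status != "ok") {
      sz <- tryCatch(size_from_fsr(g$wavelength_nm, cfg$wgm$n_internal),
                     error = function(e) NULL)
      if (is.null(sz)) return(NULL)
      d <- sz$diameter_um; dsd <- sz$sd_um
      ne <- NA_real_; resid <- NA_real_
      flags <- c(flags, "size-only")
    } else {
      d <- fit$diameter_um; dsd <- fit$residual_nm * 1e-3
      ne <- fit$n_external; resid <- fit$residual_nm
    }
    data.frame(tile = tile_id, x_um = loc$x0_um, y_um = loc$y0_um,
               z_um = depth, width_um = loc$width_um,
               diameter_um = d, diameter_sd_um = dsd,
               n_external = ne, residual_nm = resid,
               n_peaks = length(g$members),
               scatter_um = loc$scatter_um,
               peaks_nm = paste(signif(g$wavelength_nm, 10), collapse = ";"),
               flags = paste(flags, collapse = ";"))
  })
  do.call(rbind, recs)
}

#' Run the full localization-and-sensing pipeline on a cube
#'
#' Background subtraction, spectral summing, peak detection, FSR comb
#' unmixing, per-comb spectral localization, depth from footprint width,
#' diameter/index retrieval (full eigenmode fit, falling back to FSR-only
#' sizing), and environment classification. Large fields are processed in
#' tiles (one collection spot each) and duplicate records merged.
#'
#' @param cube a [hsi_cube()].
#' @param config a [dsli_config()].
#' @param calibration optional [calibration_curve()] for depth assignment.
#' @return data.frame of `microcavity_record`s: `id`, `x_um`, `y_um`, `z_um`,
#'   `diameter_um` (+ sd), `n_external`, `environment`, `n_peaks`, `flags`.
#' @export
run_dsli <- function(cube, config = dsli_config(), calibration = NULL) {
  cfg <- config
  tiles <- cfg$pipeline$tiles
  d <- dim(cube$data)
  tile_idx <- function(n, k) {
    if (k <= 1) return(list(seq_len(n)))
    split(seq_len(n), ceiling(seq_len(n) / (n / k)))
  }
  xb <- tile_idx(d[1], tiles[1])
  yb <- tile_idx(d[2], tiles[2])
  recs <- list()
  for (i in seq_along(xb)) {
    for (j in seq_along(yb)) {
      sub <- hsi_cube(cube$data[xb[[i]], yb[[j]], , drop = FALSE],
                      cube$x_um[xb[[i]]], cube$y_um[yb[[j]]],
                      cube$wavelength_nm)
      r <- tryCatch(.dsli_tile(sub, cfg, calibration,
                               tile_id = sprintf("%d_%d", i, j)),
                    error = function(e) NULL)
      if (!is.null(r)) recs[[length(recs) + 1]] <- r
    }
  }
  if (!length(recs)) {
    return(structure(data.frame(), class = c("microcavity_records",
                                             "data.frame")))
  }
  out <- do.call(rbind, recs)
  # dedupe: (i) same diameter tag + nearby position = one bead seen twice
  # (tile overlap); (ii) a colocalized record whose comb is explained by a
  # stronger record's fitted sphere is a leftover sub-comb of that bead
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$n_peaks)
    for (a in seq_len(nrow(out) - 1)) {
      i <- ord[a]
      if (!keep[i]) next
      modes_i <- if (!is.na(out$n_external[i])) {
        tryCatch(find_modes(
          sphere_params(out$diameter_um[i], cfg$wgm$n_internal,
                        out$n_external[i]),
          window = range(cube$wavelength_nm),
          max_radial_order = cfg$wgm$max_radial_order)$wavelength_nm,
          error = function(e) numeric(0))
      } else numeric(0)
      for (b in (a + 1):nrow(out)) {
        j <- ord[b]
        if (!keep[j]) next
        near <- sqrt((out$x_um[i] - out$x_um[j])^2 +
                     (out$y_um[i] - out$y_um[j])^2) <
          cfg$pipeline$dedupe_xy_um
        if (!near) next
        same_d <- abs(out$diameter_um[i] - out$diameter_um[j]) * 1e3 <
          cfg$pipeline$dedupe_d_nm
        explained <- FALSE
        if (length(modes_i)) {
          pk <- as.numeric(strsplit(out$peaks_nm[j], ";")[[1]])
          dmin <- vapply(pk, function(p) min(abs(modes_i - p)), numeric(1))
          explained <- mean(dmin) < 0.05
        }
        if (same_d || explained) keep[j] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  cl <- classify_environment(out$n_external,
                             class_centers = cfg$pipeline$class_centers,
                             dead_band = cfg$pipeline$dead_band)
  out$environment <- cl$environment
  out$confidence <- cl$confidence
  out$id <- sprintf("mc%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out[, c("id", setdiff(names(out), "id"))],
            class = c("microcavity_records", "data.frame"))
}

#' @export
print.microcavity_records <- function(x, ...) {
  cat(sprintf("%d microcavity record(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(
    x[, intersect(c("id", "x_um", "y_um", "z_um", "diameter_um",
                    "n_external", "environment", "n_peaks", "flags"),
                  names(x))], digits = 6, ...)
  invisible(x)
}
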