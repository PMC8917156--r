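# dsli

Deep-tissue localization and sensing with whispering-gallery-mode (WGM)
microcavity probes, in R.

## The problem

Optical imaging at single-cell resolution fails beyond roughly one transport
length `l* = 1/(mu_a + mu_s (1 - g))` inside scattering media such as
biological tissue: photon directions randomize and images blur into diffuse
blobs. Fluorescent polystyrene microspheres (~15 um) act as optical
microcavities: their emission is a comb of narrow whispering-gallery
resonances whose wavelengths are set by the sphere diameter and the
refractive indices inside and outside. Scattering scrambles *where* photons
go, but not *which wavelength* they carry — so the comb survives intact, and
each bead in a polydisperse batch carries a unique spectral fingerprint.

Diffuse Spectral Localization Imaging (DSLI) exploits this: record a
hyperspectral cube (a full spectrum per pixel) through the scattering layer,
unmix the summed spectrum into per-bead combs, image each bead at its own
resonance wavelengths (only that bead contributes), fit the diffuse surface
footprint to localize it laterally, convert the footprint width to depth
through a Monte-Carlo calibration curve, and fit the comb to the exact sphere
eigenmode model to retrieve the diameter (a stable tag for cell tracking, to
better than a nanometre) and the surrounding refractive index (which tells a
bead inside a cell, ~1.37, from one in growth medium, ~1.34).

## What the package implements

* **`wgm`** — exact eigenmode solver for bare and layered dielectric spheres.
  The characteristic equation matches the interior Riccati-Bessel solution
  `psi_l` to the exterior evanescent solution `chi_l`:
  TE: `psi_l(x_i) chi_l'(x_o) = m chi_l(x_o) psi_l'(x_i)`,
  TM: `m psi_l(x_i) chi_l'(x_o) = chi_l(x_o) psi_l'(x_i)`,
  with `x_o = pi d n_out / lambda`, `x_i = pi d n_in / lambda`,
  `m = n_in/n_out`. `find_modes()` enumerates the roots; `fit_size_index()`
  inverts measured combs for `(d, n_out)`; `size_from_fsr()` sizes from the
  comb spacing alone.
* **`unmix`** — peak detection (Lorentzian refinement) and comb grouping by
  free-spectral-range propagation: peaks `i, j` of one cavity satisfy
  `1/lambda = 1/lambda_i + N * FSR_ij` with `FSR_ij = 1/lambda_i -
  1/lambda_j`; the FSR with the most matching teeth wins
  (`assign_fsr()`, `group_peaks()`, `pair_te_tm()`, `fill_missing_peaks()`).
* **`hsi`** — ENVI cube I/O, per-peak intensity maps, 2D Gaussian
  localization, multi-peak averaging, footprint-width measurement and
  monotone depth calibration (`slice_at_peak()`, `localize_microcavity()`,
  `surface_width()`, `depth_from_width()`).
* **`mc`** — photon-packet Monte Carlo (Rcpp) in slab and embedded
  geometries with Henyey-Greenstein or Mie-tabulated scattering and Fresnel
  boundaries; Mie single-particle optics; depth-calibration construction;
  integrating-sphere R/T and inverse optical-property estimation
  (`run_mc()`, `mie_single_particle()`, `build_calibration()`,
  `invert_optical_properties()`).
* **`synth`** — ground-truthed synthetic scenes and hyperspectral cubes
  (`sample_population()`, `render_cube()`), so every stage is testable with
  no experimental data.
* **`pipeline`** — end-to-end orchestration plus environment classification,
  same-cell inference, diameter-tag tracking and functionalized-sensor
  readout (`run_dsli()`, `classify_environment()`, `track_records()`,
  `peak_shift_series()`).

## Worked example

Render a synthetic scene of two beads under a scattering layer and run the
full pipeline:

```r
library(dsli)

pop <- data.frame(diameter_um = c(14.2, 15.1), n_internal = 1.59,
                  n_external = c(1.34, 1.37),
                  environment = c("medium", "cytoplasm"))
scene <- make_scene(pop, x_um = c(100, 220), y_um = c(120, 200),
                    depth_um = c(150, 250))
rc <- render_cube(scene, wavelength_nm = seq(505, 535, by = 0.023), seed = 9)

cal <- calibration_curve(depth_um = c(50, 150, 250, 350),
                         width_um = 15 + 0.55 * c(50, 150, 250, 350))
recs <- run_dsli(rc$cube, dsli_config(), calibration = cal)
print(recs)
#> 2 microcavity record(s)
#>      id     x_um    y_um    z_um diameter_um n_external environment n_peaks
#> 1 mc001 218.6872 199.068 257.241     15.0988    1.37127     in_cell      11
#> 2 mc002  98.4245 118.858 150.901     14.2000    1.34000 out_of_cell      17
```

Both beads are recovered: positions within ~2 um of the ground truth, depths
within ~7 um, diameters to 0.0 and 1.2 nm, external indices to 0.0000 and
0.0013 — and the bead in cytoplasm is classified `in_cell`.

A thin command-line front end over the same functions is installed at
`inst/cli/dsli.R` (subcommands `simulate`, `unmix`, `localize`, `run`,
`mc-calibrate`, `track`).

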