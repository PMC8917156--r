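---
title: "Methods: localization and sensing with WGM microcavity probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localization and sensing with WGM microcavity probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and the known limitations.

## The physical model

A dye-doped polystyrene microsphere (diameter ~15 um, internal index
`n_in = 1.59`) is an optical resonator: light circulating by total internal
reflection interferes constructively at discrete vacuum wavelengths, the
whispering-gallery modes (WGMs). For a homogeneous sphere the eigenvalue
problem separates; with the Riccati-Bessel functions `psi_l(x) = x j_l(x)`
and `chi_l(x) = -x y_l(x)`, and size parameters `x_i = pi d n_in / lambda`,
`x_o = pi d n_out / lambda`, `m = n_in / n_out`, matching the regular
interior solution to the evanescent exterior solution gives the real
characteristic equations

* TE: `psi_l(x_i) chi_l'(x_o) - m chi_l(x_o) psi_l'(x_i) = 0`
* TM: `m psi_l(x_i) chi_l'(x_o) - chi_l(x_o) psi_l'(x_i) = 0`

Using the exterior Neumann (evanescent) solution in place of the outgoing
Hankel function gives real eigenwavelengths accurate to within the resonance
linewidth, entirely adequate at the Q ~ 7000 of these probes: radiative
linewidths are far narrower than the spectrometer resolution. Complex
eigenfrequencies (radiative Q) are deliberately out of scope.

For coated spheres the same radial equation holds per layer; the package
propagates the continuous quantities -- `u = r R(r)` together with `u'` (TE)
or `u'/n^2` (TM) -- through each interface by a 2x2 transfer matrix in the
`(psi, chi)` basis and matches the evanescent exterior at the outermost
radius. Both degenerate limits (coating index equal to the surrounding, or
to the core) reproduce the bare-sphere modes to solver tolerance, which the
tests assert.

### Solver numerics

`j_l` is evaluated by downward recurrence normalized against
`j_0 = sin(x)/x` (stable), `y_l` by upward recurrence (stable), in C++.
Residuals are normalized by the local magnitudes of `(psi, psi')` and
`(chi, chi')`, so they are O(1) and sign changes are well conditioned. Roots
are bracketed on a 0.05 nm wavelength grid -- safe because the free spectral
range is ~3.6 nm -- and polished by Brent's method to 1e-6 nm. Radial orders
are assigned by counting roots downward from each angular order's cutoff
wavelength `lambda_c = pi d n_in / (l + 1/2)`; no confined mode exists above
the cutoff. The default model includes radial orders q <= 2: higher orders
have low Q and are rarely detected.

Scale invariance is exact for wavelength-independent indices:
`modes(s d, n) = s modes(d, n)`. The fitting code exploits this to evaluate
a whole diameter grid from one solved mode set per candidate index. A
constant `n_in = 1.59` is the default convention (the synthetic data use the
same convention, so fits are self-consistent); a Sellmeier polystyrene
dispersion (`polystyrene_index()`) can be supplied instead, at the cost of
the scale-invariance shortcut.

## Comb unmixing

Peaks of one microcavity are equally spaced in `1/lambda` to leading order.
All comb arithmetic therefore lives in `1/lambda` (units 1/um). For every
peak pair `(i, j)` the candidate spacing `FSR_ij = 1/lambda_i - 1/lambda_j`
is propagated as `1/lambda = 1/lambda_i + N FSR_ij` and scored by its
overlap with the observed peak list; the best-overlap candidate wins, ties
broken toward the smaller FSR (a deterministic choice).

Several numerical choices behind this scoring were forced by failure modes
observed on synthetic data and are worth recording:

* **Noise-aware matching tolerance.** The base tolerance is half the
  spectrometer resolution (0.023 nm) in `1/lambda` (grid quantization). With
  measured peaks the difference of two fitted centers scatters by
  `sigma sqrt(2)`, which at sigma ~ 0.01 nm rivals that base value; the
  pipeline therefore widens the tolerance in quadrature using the Lorentzian
  fits' own standard errors (`noise_match_tolerance()`).
* **Anchored least-squares FSR refinement.** A single-pair FSR carries the
  two peaks' position errors, which accumulate linearly along the comb, so
  the initial acceptance window grows with |N|; the FSR is then refined by a
  least-squares line through the matched teeth anchored at peak i (so a
  candidate cannot slide onto a different bead's comb) and support is
  recounted strictly.
* **Two-sided overlap.** Match count alone is degenerate: a subharmonic
  FSR/k matches every true tooth. Predicted comb positions with no observed
  peak vote against a candidate at half weight -- enough to kill
  subharmonics while a genuine comb with a few blended-away teeth survives.
  `min_support = 4` matched teeth rejects chance alignments at realistic
  peak densities (validated by a random-peak fixture).
* **Relative FSR tolerance for grouping (1.2%).** The local FSR of one
  sub-comb drifts by up to ~1% across a 30-nm window (the mode spacing grows
  with angular order); beads 350 nm apart differ by ~2.4% and must not link.
  Radial-order sub-combs (~2% apart) and the two polarization sub-combs
  (same FSR, offset phase) surface as separate groups; `pair_te_tm()` merges
  them, and when `n_internal` is supplied each candidate merge is validated
  by fitting the combined comb to a single sphere (median mismatch
  <= 0.02 nm, at least 70% of teeth within twice that, and the fitted index
  in the interior of the search range -- two different spheres'
  single-polarization combs can mimic one sphere's TE/TM pair, but only
  with the index pinned at the range edge).
* **Pruning chance groups by ranked coverage.** With ~60 peaks in a 30-nm
  window, spurious combs assembled from other beads' teeth reach the
  minimum support. Groups are accepted largest-and-most-coherent first; a
  later group must contribute at least 2 peaks no accepted comb owns. Peaks
  may still legitimately belong to more than one group (combs of different
  beads can share a tooth), so membership is non-exclusive by design.

Sizing from the FSR alone inverts `FSR = 1/(pi n d)` with a second-order
correction for the Airy-term growth of the mode spacing (the leading-order
relation is ~2.3% biased at size parameter ~140) plus a final
solver-consistency rescale; accuracy ~0.1%, an order of magnitude worse than
the full fit, matching its role as a fallback and seed.

## Diameter and index retrieval

`fit_size_index()` minimizes the mean absolute peak-to-mode mismatch under a
greedy one-to-one nearest assignment (ties toward smaller wavelength),
searching a coarse grid (5 nm in d, 5e-4 in n) followed by Nelder-Mead and
a Gauss-Newton polish on the matched residuals. Two numerical hazards shape
the implementation:

* **Comb aliasing.** The landscape in d is multimodal with period
  `~lambda/(pi n_in)` (~0.1 um): shifting the comb by one tooth nearly
  realigns it. The diameter search is therefore seeded by the FSR estimate
  and restricted to +/-0.12 um around it.
* **Near-degenerate basins.** With both radial orders modelled the mode comb
  is dense, and the within-cell quantization error of the coarse grid (a
  coherent comb shift) exceeds the contrast between basins. Each of the best
  grid cells is first polished to its basin floor in d -- exactly, via scale
  invariance, at no solver cost -- and basins are ranked by floor before
  refinement.

On noiseless synthetic combs the round trip recovers d to ~1e-6 nm and n to
~1e-9. With 0.01 nm Gaussian peak noise on a 14-tooth q = 1 comb
(505-535 nm), the Cramer-Rao bound is sd(d) = 0.54 nm and sd(n) = 6.8e-4
with corr(d, n) = -0.99; the fit sits at this bound. The strong d-n
degeneracy means single-shot joint fits cannot determine the index to 1e-4;
but a bead's diameter is a physical constant, so time-series sensing fixes
d and fits the index alone (`fit_index_fixed_d()`), whose conditional bound
is 8e-5 -- the package's sensing mode, and the regime in which sub-1e-4
index repeatability is meaningful.

## Localization through scattering media

A hyperspectral cube (default scale emulating a 200 x 200 x 1600-point scan
at 0.023 nm resolution; tests use smaller cubes, e.g. 64 x 64 x 1300, purely
for runtime) is summed into one spectrum, unmixed, and each comb's teeth are
imaged one at a time: `slice_at_peak()` integrates a 3-sample band (~0.07 nm,
matched to the linewidth at Q ~ 7000) and removes the local fluorescence
background estimated from flanking bands. A rotated 2D Gaussian with offset
is fitted to each map, initialized from moments; fits whose residuals are
structured (well above the pixel noise estimated from second differences)
are flagged poor rather than silently returning the midpoint of two blobs.
Per-peak centers are combined by amplitude-weighted averaging; the scatter
of per-peak centers is the reported uncertainty. Averaging over the comb's
15-20 teeth empirically reduces the localization error severalfold relative
to a single tooth (the test suite logs the measured ratio).

The fluorescence baseline under the combs is removed by a wide running
median (5 nm window: much wider than a peak, much narrower than the
emission envelope) followed by light smoothing; negative residual noise is
kept (not clipped).

### Depth from the footprint width

The diffuse footprint widens monotonically with source depth. Widths are
measured by `surface_width()` along four directions (0/45/90/135 degrees)
through the centroid, each profile averaged over a 5-sample perpendicular
band. Two metrics are provided and must be used consistently between
building and querying a calibration curve:

* `sigma`: a Gaussian fit with offset within 4x the moment width -- suited
  to compact, near-Gaussian footprints;
* `fwhm`: the direct full width at half maximum with interpolated crossings
  and smoothing scaled to the width itself. The transport-simulated
  footprint of a deeply embedded source is strongly non-Gaussian (a
  backscatter halo), and a Gaussian fit's result then depends on how much
  tail the map happens to contain; the direct FWHM does not, which is why
  the footprint-comparison simulations use it. An azimuthal-average variant
  (`method = "radial"`) exists for exactly isotropic simulated maps.

Depth lookup uses Hyman-filtered monotone cubic interpolation of the
calibration knots; out-of-range widths are clamped with a warning. The
calibration constructor rejects non-monotone width sequences outright.

## Photon transport

The Monte Carlo kernel (C++) is a standard photon-packet random walk:
exponential free paths with `mu_t = mu_s + mu_a`, absorption by packet
weight, Henyey-Greenstein scattering with the Mie-derived anisotropy (or
inverse-CDF sampling of the tabulated Mie phase function), unpolarized
Fresnel reflection/refraction at index-mismatched boundaries, and Russian
roulette (threshold 1e-4, survival 0.1). Three geometries: an isotropic
point source beneath a finite slab (transparent host below, index 1.34 --
downward photons are lost), an isotropic point source embedded in a
semi-infinite medium (truncated 8 transport lengths beyond the source,
where returning photons are negligible), and a collimated beam for
integrating-sphere reflectance/transmittance. Default medium: the standard
phantom at 532 nm, `mu_s = 63 mm^-1`, `g = 0.87`, `mu_a = 0.2 mm^-1`,
`n = 1.41`, giving a transport length of ~120 um; the anisotropy comes out
of the Mie series for 0.51-um polystyrene spheres in the silicone host.
Tallies conserve energy to counting error and are reproducible by seed.
Surface maps for width measurements use 5-um bins over a +/-1250-um field:
the field must contain the footprint, since clipping biases any width
measure downward.

The inverse problem (integrating-sphere R and T to `mu_s`, `g`) is a grid
search over forward simulations with `mu_a` fixed; the full residual surface
is returned because the solution is typically a valley, and a best point on
the search boundary is reported as "range too narrow" rather than a result.
R and T are insensitive to `mu_a` over 0-2 mm^-1 at these albedos, which a
test verifies as a sweep.

## The synthetic-data generator

`render_cube()` composes everything the method assumes: per-bead combs from
the eigenmode solver (Lorentzian lines, per-bead Q drawn uniformly from
5000-10000), a smooth Gaussian dye-emission envelope (center 520 nm, sd
18 nm) as shared background, depth-dependent spatial footprints, and Poisson
shot noise. Bead populations default to the manufacturer's statistics (mean
diameter 15 um, CV 14%, Gaussian truncated at zero) with per-environment
external indices: growth medium 1.34 (sd 0.001, the observed stability
scale), cytoplasm 1.37 (sd 0.004, within the observed 0.012 drift range),
interstitial 1.355. Footprints are either full Monte Carlo maps or a fast
Gaussian approximation whose width comes from a calibration curve (or a
stylized linear law, sigma = 15 + 0.55 z um, when none is given); the
default background level and peak scale (100 and 400 counts at the envelope
maximum) put the end-to-end pipeline at the reliability scale of ~5
identifiable beads per collection spot. The manifest records every rendered
mode and amplitude, so no fixture files are needed anywhere in the tests.

What the generator does not emulate: tissue inhomogeneity (the calibration
curve assumes one medium), autofluorescence structure beyond a smooth
envelope, camera artifacts, and spectral overlap of multiple dyes. Passing
tests therefore demonstrate the pipeline's correctness under the method's
own assumptions, not its robustness to every property of real tissue.

## Pipeline decisions

* Records require >= 6 comb teeth and <= 20 um scatter among per-peak
  localizations: a genuine bead's teeth colocalize, chance-aligned teeth do
  not. This implements the "good spectra" gate behind the recovery-rate
  properties, and is what makes the zero-false-positive property hold.
* Sizing falls back from the full fit to FSR-only (flagged "size-only",
  ~6 nm class accuracy) to dropping the record.
* Environment classification is nearest-class-mean with centers 1.34/1.37,
  a midpoint boundary at 1.355 and a +/-0.002 dead band (the medium's
  stability scale) yielding "undetermined".
* Same-cell inference uses only the index difference (threshold 0.003) with
  the chance probability from the closed form
  `P(|dn| < t) = 2 Phi(t / (sigma sqrt(2))) - 1`; spatial proximity is
  logged, not decisive.
* Tracking solves optimal bipartite matching on |diameter difference| with
  links above 3 nm forbidden (greedy matching fails designed collisions);
  links whose best alternative is within 1 nm are flagged ambiguous.
* Tiled processing (one collection spot per tile) de-duplicates by diameter
  tag and position, and absorbs colocalized records whose comb is explained
  by a stronger record's fitted sphere (leftover sub-combs).

## Limitations

* Two beads with diameters within ~3 nm produce blended peaks at detection
  and are unmixed as one comb; the pipeline cannot flag this from the data
  alone (tested as a designed negative control against generator truth).
* The joint (d, n) fit's index precision is bounded by the d-n degeneracy
  (see above); sub-1e-4 index readout requires the fixed-diameter mode.
* Depth assignment inherits any mismatch between the calibration medium and
  the actual sample; multi-layer media are not modelled.
* Air-to-vacuum wavelength conversion is the caller's responsibility: all
  wavelengths in the package are vacuum wavelengths in nm.

## Problem sizes used by the tests

Simulations are sized for a single CPU: rendered cubes 64 x 64 pixels x
~1300 bands, scenes of 1-5 beads, Monte Carlo runs of 1e4-2e5 packets in the
test suite and 1e6 in the acceptance script, Nelder-Mead capped at 60
iterations with a Gauss-Newton polish. These sizes are stated here as the
package's own choices; all tolerances asserted in the tests were chosen
from the analyses above.
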