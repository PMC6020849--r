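---
title: "Models and numerics behind promscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind promscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promscope)
```

promscope simulates and analyses label-free imaging of live-cell adhesion on
a photonic-crystal (PC) biosensor. A subwavelength grating coated with a
high-index TiO2 film acts as a guided-mode-resonance (GMR) reflector: at one
narrow band near 626 nm under water, incident light couples into a leaky
waveguide mode and is reflected with near-unity efficiency. Cell material
attached within the mode's evanescent tail red-shifts the local resonance
(peak wavelength shift, PWS), while micron-scale focal-adhesion (FA) protein
clusters scatter resonantly stored photons out of the mode and reduce the
local peak reflection efficiency (peak intensity shift, PIS). A line-scan
spectrometer records a full reflectance spectrum per ~0.6 um pixel, so both
quantities are imaged simultaneously, frame by frame.

This vignette records the models, the tunable parameters, and the numerical
decisions, in the order data flows through the package.

## 1. Electromagnetic forward model (RCWA)

`simulate_spectrum()` implements rigorous coupled-wave analysis (the Fourier
modal method) for 1-D gratings in planar incidence, with the stable
enhanced-transmittance-matrix recursion and, for TM polarization, the
inverse-rule ("Li") factorization of the permittivity products. The
zeroth-order reflectance at normal incidence is the instrument observable.
Two independent oracles pin the implementation down in the test suite: the
uniform-layer limit must match closed-form transfer-matrix reflectance to
1e-6, and every lossless solve must conserve energy (R + T = 1) to 1e-6.
A third, analytic oracle — the slab-waveguide dispersion relation phase-matched
to the first grating order — was used during development to verify that the
resonance appears where waveguide theory predicts.

**Stack interpretation.** The fabricated device is a replica-molded polymer
grating (period 400 nm, depth 120 nm, duty 41.6%, sidewall 85 deg, n = 1.46)
sputter-coated with 61 nm of TiO2 (n = 2.4, duty 50%, sidewall 82 deg) under
water (n = 1.333) on glass (n = 1.52). The printed numbers leave open where
the conformal TiO2 goes besides the ridge tops. `build_staircase()` models
the sputter coating as: (i) a trapezoidal TiO2 ridge layer on top of the
polymer ridges; (ii) TiO2 filling the lowest 61 nm of the grooves (the
groove-floor deposit); and (iii) lateral TiO2 strips on the upper ridge
sidewalls whose combined width is the excess of the TiO2 duty over the
polymer duty — the TiO2 ridge is wider than the polymer ridge precisely
because the coating wraps the sidewalls. This choice is not free: with
water-only grooves the TM (E-field perpendicular to the grating lines, the
instrument polarization) effective index falls below the glass cutoff and no
guided resonance exists anywhere in 560-900 nm, whereas the conformal
reading places the TM resonance at ~628 nm with a ~2.4 nm linewidth,
consistent with the ~626 nm design target.

**Trapezoids.** Each trapezoid is discretized into `staircase_layers`
(default 8) equal slabs; a slab takes the ridge width at its own mid-height,
so the thickness-weighted mean fill equals the stated duty cycle exactly and
total thicknesses are preserved. The slab straddling the groove-fill level
is split so layer boundaries stay exact.

**Truncation.** The default is 2M+1 = 25 Fourier harmonics. A 21-harmonic
default was tried first but fails the package's own convergence requirement
(PWV must move < 0.1 nm when the truncation is doubled) because the sidewall
strips are ~17 nm features; 25 harmonics passes with margin and costs little.

**Incidence side.** Spectra are computed with light incident from the water
superstrate. The physical instrument illuminates through the substrate, but
the resonance is a pole of the structure: its wavelength does not depend on
the illumination side, and for a lossless single-mode GMR the peak
reflectance reaches unity from either side. Computing on the superstrate
side keeps the near-field reconstruction (below) in the sensing volume.

**Dispersion.** All indices are constant over the 600-650 nm band, matching
the single values given for the materials.

**Near field.** `field_profile()` reconstructs the laterally averaged
intensity enhancement |E|^2/|E_inc|^2 above the TiO2 surface from the
reflected-order amplitudes. Only evanescent orders are included: the
propagating zeroth order forms an ordinary standing wave that exists with or
without the resonance and carries no sensing contrast. On resonance the
profile is dominated by the +/-1 orders, whose analytic amplitude decay
constant is kappa = (2 pi / lambda) sqrt(n_eff^2 - n2^2) with
n_eff = lambda / period; the fitted decay agrees with this closed form to a
fraction of a percent and gives a ~120 nm amplitude decay length (~61 nm for
intensity). The field "depth" quoted for such sensors (~200 nm) depends on
the criterion used (amplitude vs intensity, 1/e vs visual extent); the
package reports the fitted decay constant rather than hard-coding a depth.

## 2. Focal-adhesion perturbation surrogates

The paper-scale FDTD study of a dielectric sphere (n = 1.46, radius
50-500 nm) on the sensor is replaced by two light-weight surrogates that are
required to reproduce its qualitative structure: bulk index changes move
PWV and not PIV; a scatterer moves both, monotonically in radius, with zero
limits at zero radius and zero contrast.

**Resonance shift** (`fa_pws()`): first-order perturbation theory,
d_lambda = lambda0 (n_FA^2 - n2^2) * Int_sphere I(z) dV / (2 V_proxy),
with the sphere integral evaluated by horizontal-disk slicing against the
laterally averaged exponential tail (cross-checked against 3-D Monte-Carlo
integration to 1%). `modal_volume_proxy()` integrates the superstrate-side
mode intensity over height and one unit cell; the inaccessible in-structure
share of the modal energy is deliberately absorbed into the coupled-mode
calibration constant rather than modelled.

**Intensity loss** (`fa_pis()`): temporal coupled-mode theory with an added
scattering channel. The intrinsic linewidth sets the radiative rate
gamma_r = pi FWHM / lambda0^2; the sphere adds
gamma_s = C sigma_sc <I>_sphere / V_proxy, with sigma_sc the full Mie-series
scattering cross-section in water and <I>_sphere the mode intensity averaged
over the sphere volume. The loaded peak reflectance is
R_peak = PIV0 (gamma_r / (gamma_r + gamma_s))^2. The volume-averaged
intensity — rather than the intensity at the sphere center — is a deliberate
choice: the evanescent intensity decays with a ~61 nm length, so a
500-nm-radius sphere's center sits in a vanishing field even though its
lower cap interacts strongly, and a center-sampled rate would (wrongly) make
the intensity loss non-monotonic between 250 and 500 nm radii. The
volume average restores the strict monotonicity the FDTD study shows.
The calibration constant C defaults to 1 in these model units; only trends,
zero limits and the stated algebra (gamma_s = gamma_r giving a loss of
0.75 PIV0) are claimed, not absolute FDTD values.

The Mie series itself follows the Riccati-Bessel formulation; for size
parameters below ~0.3 it approaches the Rayleigh closed form (2.1% at
x = 0.27). Note that a 50 nm sphere at 626 nm in water has x = 0.67, well
outside the Rayleigh regime; the true Mie-Rayleigh gap there is ~13%,
confirmed against an independent implementation and the analytic
second-order expansion.

## 3. Per-pixel resonance extraction

`normalize_spectrum()` divides raw spectra by the peak of a water-background
reference, so background pixels read a normalized peak intensity (PIV) of
1.0 and the worked attachment example reads 0.90 before and 0.80 after
attachment, with the peak wavelength (PWV) moving 626 to 628 nm.

`fit_resonance()` defaults to Lorentzian least squares,
A (G/2)^2 / ((lambda - lambda_c)^2 + (G/2)^2) + b, over a +/-3 nm window
around the discrete argmax (ties break to the lowest wavelength). The GMR
line is near-Lorentzian over its top; a Fano-asymmetric model is out of
scope, and any residual asymmetry is common mode between frame and
background so it largely cancels in the shift images. The fit profiles the
linear parameters (A, b) in closed form each iteration and takes damped
Gauss-Newton steps in (lambda_c, G) with the variable-projection reduced
Hessian; because every pixel shares the wavelength grid, whole frames are
fitted as matrix operations (a 100 x 100 x 126 frame fits in ~2 s). On
non-convergence the estimator falls back to the parabolic vertex through the
top 7 samples (also available directly as `method = "parabolic_vertex"`;
the estimator in use is recorded in the fit object). Peaks on the grid
boundary and flat spectra are flagged invalid — `NA` plus a validity mask in
`fit_cube()`, an error in `locate_resonance()` — and downstream statistics
ignore invalid pixels.

## 4. Shift images

`shift_images()` fixes the sign conventions: PWS = PWV_frame - PWV_background
(positive = red shift = attachment) and PIS = PIV_background - PIV_frame
(positive = reflection-efficiency reduction = scattering outcoupling).
The default background is the first frame of a sequence (the pre-attachment
scan); `cell_free_median` is available when no clean first frame exists.
Exported images stay in physical units (nm, normalized reflectance) as
32-bit floats — never rescaled to display ranges. The "normalized PIS" used
for cross-channel dynamic comparisons is min-max normalization of the
per-frame means over the series; the source figures do not define their
normalization, so this documented choice stands in.

## 5. Cell morphometry

**Segmentation** (PIS channel by default, where the FA ring gives the
strongest contrast): Gaussian smoothing (sigma 1 px), Otsu threshold,
morphological closing (radius 2 px), largest connected component, hole
filling. The FA ring is a bright annulus, so hole filling is what turns it
into the cell footprint.

**Boundary extraction.** The sample contour starts from the raw binary
0.5-level (exact on straight edges, corner-preserving), is resampled to
`n_points` = 360 equal-arclength samples, lightly smoothed, and then
re-anchored by a crossing search along local normals: high-curvature
stretches (tangent turning > 35 deg over a +/-6-sample stencil) anchor on
the bilinear level of the raw mask so corners survive; elsewhere the
Gaussian-smoothed level removes digitization wiggle. Outward normals come
from circularly smoothed tangent angles — unbiased on circles, where the
tangent angle is linear in arclength — and orientation is verified against
the mask rather than assumed from winding order. On analytic shapes this
yields disk perimeters within 1% with normals radial within 2 deg, and
square perimeters within 2% with corners intact.

**Tracking** (`track_boundary()`): each boundary sample casts a ray along
its outward normal (+/-10 um default) and lands on the 0.5-crossing of the
next frame's mask nearest to the previous position (the documented
tie-break); rows of downstream kymographs therefore stay coherent across
time. Samples with no crossing are interpolated circularly from their
neighbours and counted. Tracking a dilation recovers the dilation radius
within half a pixel and is inverse-consistent (A to B to A returns
displacements summing to < 0.5 px).

**Kymographs** (`band_kymograph()`): entry (i, t) averages the image over
the inward-normal segment [offset, offset + width] um at boundary sample i,
by bilinear interpolation, excluding invalid pixels. Band defaults — band 1 =
[0, 3] um inward (FA ring), band 2 = [6, 12] um inward (interior) — are
documented choices; the source figures do not quantify their band extents.

**Edge/center statistics** (`edge_center_stats()`): edge = mask pixels
within 3 um of the boundary, center = farther than 6 um (defaults), using an
exact distance-to-background transform; the regions are disjoint by
construction. With several cells, per-cell rows are reported plus a pooled
row; pooling weights pixels, and any per-cell equal-weight summary can be
built from the per-cell rows.

## 6. The synthetic stated world

`generate_scene()` emulates what the live-cell experiments image, at the
scale the instrument sees, with every parameter either taken from the
stated experiment or fixed once here:

* canonical cell: 30 x 20 um ellipse on a 100 x 100 px frame at 0.6 um
  pitch — the single-stem-cell scale of the line-scan field of view;
* FA ring: 2 um wide at the boundary (mature FA clusters are ~1-10 um^2,
  concentrated along the adhesion perimeter), with a diffuse interior
  component at 25% of the ring density (attached membrane scatters weakly
  everywhere, matching the observed interior intensity reduction);
* interior mass map: plateau in the interior, tapering to zero over 3 um
  at the boundary;
* calibration: mass to red shift is linear and scaled so the canonical
  interior reaches +2 nm; FA density to amplitude reduction is linear and
  scaled so the ring reaches 0.10 — i.e. the worked example's
  626 to 628 nm and 90% to 80% numbers are built in as the canonical truth.
  The real mass-to-shift calibration curve is unknown (only the 2 nm
  example is stated); the linear surrogate is a documented stand-in;
* instrument: Lorentzian line with 4 nm FWHM sampled at 0.2 nm over
  615-640 nm, additive Gaussian reflectance noise (SD 0.01), 10 s frame
  interval; an adhesion series starts with a cell-free frame and grows the
  mask monotonically;
* determinism: every random draw flows from an explicit seed.

What the generator does **not** emulate — so a green end-to-end test does
not establish robustness to it: Fano line asymmetry, shot noise and camera
gain, stage drift and registration error, filopodia-scale substructure,
multi-cell contact, and any fluorescence channel. The rendered line is the
same family the fitter assumes; end-to-end tests therefore validate the
pipeline's bookkeeping and noise propagation, not lineshape mismatch.

## 7. File formats and the command line

Cubes travel as ENVI pairs (text header with the wavelength axis; flat
32-bit little-endian band-sequential floats) or native `.rds`; images as
single-band ENVI rasters; tables as CSV. `write_outputs()` finalizes a
`manifest.json` (checksums, seed, config hash, package version) only after
all artifacts are written. HDF5 and TIFF are not offered because no R
bindings are available in the supported stack. A thin command-line front
end (`inst/cli/promscope.R`) exposes the main verbs (`simulate-spectrum`,
`fa-sweep`, `synth`, `fit`, `stats`, `profile`) over a single JSON
configuration whose unknown keys are rejected.

## 8. Known limitations

* The RCWA model is 1-D and planar-incidence; conical incidence and 2-D
  PC lattices are out of scope.
* The perturbation/coupled-mode surrogates claim trends and limits, not
  FDTD-exact magnitudes; the gamma_s calibration constant is unity by
  convention.
* The boundary tracker assumes frame-to-frame displacements within the
  search range and a single cell; division and cell-cell contact are not
  handled.
* Fitted PWV/PIV uncertainties are not propagated per pixel; the noise
  floor is characterized empirically by the Monte-Carlo tests instead.
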