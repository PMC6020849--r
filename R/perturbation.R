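# Surrogates for the effect of a focal-adhesion (FA) protein cluster on the
# sensor resonance: a first-order perturbation integral for the resonance
# red-shift (PWS) and a temporal coupled-mode model with a Mie scattering
# loss channel for the peak-intensity reduction (PIS).

#' Focal-adhesion cluster model
#'
#' A FA cluster is represented as a homogeneous, lossless dielectric sphere
#' resting on the sensor surface (center height = radius by default), with a
#' protein-like refractive index.
#'
#' @param radius_nm Sphere radius (nm), 0-500 is the studied range.
#' @param index Cluster refractive index; default 1.46 (dense protein).
#' @param center_height_nm Height of the sphere center above the surface;
#'   default equal to the radius (sphere touching the surface).
#' @return An object of class `fa_cluster`.
#' @export
fa_cluster <- function(radius_nm, index = 1.46, center_height_nm = radius_nm) {
  stopifnot(radius_nm >= 0, index >= 1, center_height_nm >= radius_nm - 1e-9)
  structure(list(radius_nm = radius_nm, index = index,
                 center_height_nm = center_height_nm),
            class = "fa_cluster")
}

#' Lumped resonator description of the sensor
#'
#' Parameters of the unperturbed guided-mode resonance used by the
#' coupled-mode and perturbation surrogates: resonance wavelength, intrinsic
#' linewidth (from the solver's spectral FWHM), unperturbed peak reflectance,
#' and a modal-volume proxy.
#'
#' @param resonance_wavelength_nm Resonance wavelength (nm).
#' @param intrinsic_linewidth_nm Spectral FWHM of the unloaded resonance (nm).
#' @param peak_reflectance Unperturbed normalized peak reflectance in (0, 1].
#' @param modal_volume_proxy Mode-energy normalization (nm^3): the integral
#'   of the superstrate permittivity times the intensity-enhancement profile
#'   over one grating unit cell; see [modal_volume_proxy()].
#' @return An object of class `resonator_params`.
#' @export
resonator_params <- function(resonance_wavelength_nm, intrinsic_linewidth_nm,
                             peak_reflectance, modal_volume_proxy) {
  stopifnot(intrinsic_linewidth_nm > 0,
            peak_reflectance > 0, peak_reflectance <= 1,
            modal_volume_proxy > 0)
  structure(list(resonance_wavelength_nm = resonance_wavelength_nm,
                 intrinsic_linewidth_nm = intrinsic_linewidth_nm,
                 peak_reflectance = peak_reflectance,
                 modal_volume_proxy = modal_volume_proxy),
            class = "resonator_params")
}

# Interpolate the intensity-enhancement profile at heights z (nm), with
# exponential tail extrapolation beyond the sampled grid.
field_intensity_at <- function(field, z) {
  stopifnot(inherits(field, "field_profile"))
  zmax <- max(field$z_nm)
  out <- stats::approx(field$z_nm, field$intensity_enhancement, xout = pmin(z, zmax),
                       rule = 2)$y
  beyond <- z > zmax
  if (any(beyond)) {
    dec <- fit_field_decay(field, z_range_nm = c(0.5 * zmax, zmax))
    out[beyond] <- field$intensity_enhancement[length(field$z_nm)] *
      exp(-2 * dec$kappa_per_nm * (z[beyond] - zmax))
  }
  out
}

#' Modal-volume proxy of the resonant mode
#'
#' Energy-normalization constant for the perturbation formulas: the
#' superstrate permittivity times the laterally averaged intensity
#' enhancement, integrated over height (with exponential tail extrapolation)
#' and multiplied by the unit-cell area `period^2`, in nm^3. This is a proxy
#' for the full modal energy integral: the (inaccessible) field energy inside
#' the guiding layers is not included, which is absorbed by the coupled-mode
#' calibration constant.
#'
#' @param field A [field_profile()] evaluated at resonance.
#' @param period_nm Grating period (nm), taken from the profile metadata when
#'   omitted.
#' @param n2 Superstrate index, from the profile metadata when omitted.
#' @return Scalar proxy (nm^3).
#' @export
modal_volume_proxy <- function(field, period_nm = NULL, n2 = NULL) {
  if (is.null(period_nm)) period_nm <- field$metadata$period_nm
  if (is.null(n2)) n2 <- field$metadata$n2
  z <- field$z_nm
  intens <- field$intensity_enhancement
  core <- sum(diff(z) * (utils::head(intens, -1) + utils::tail(intens, -1)) / 2)
  dec <- fit_field_decay(field, z_range_nm = c(0.5 * max(z), max(z)))
  tail_int <- intens[length(z)] / (2 * dec$kappa_per_nm)
  n2^2 * (core + tail_int) * period_nm^2
}

#' Build resonator parameters from the electromagnetic solver
#'
#' Convenience constructor: simulates the resonance spectrum, fits its
#' linewidth, evaluates the near-field profile at the peak, and assembles a
#' [resonator_params()].
#'
#' @param stack A [grating_stack()].
#' @param medium A [medium()].
#' @param polarization,harmonics Passed to the solver.
#' @return A list with `resonator` ([resonator_params()]), `field`
#'   ([field_profile()]), and `fit` (the spectral [fit_resonance()] result).
#' @export
characterize_resonator <- function(stack, medium, polarization = "TM",
                                   harmonics = 12L) {
  pk <- rcwa_peak(stack, medium, polarization = polarization,
                  harmonics = harmonics)
  wl <- seq(pk$pwv_nm - 6, pk$pwv_nm + 6, by = 0.05)
  sp <- simulate_spectrum(stack, medium, wl, polarization, harmonics)
  fit <- fit_resonance(sp)
  fld <- field_profile(stack, medium, pk$pwv_nm,
                       polarization = polarization, harmonics = harmonics)
  res <- resonator_params(pk$pwv_nm, fit$fwhm_nm, min(pk$piv, 1),
                          modal_volume_proxy(fld))
  list(resonator = res, field = fld, fit = fit)
}

# Overlap of the sphere with the mode intensity: integral of I(z) over the
# sphere volume by horizontal-disk slicing (nm^3 of enhancement-weighted
# volume). Errors when the profile cannot cover the sphere top.
sphere_overlap_integral <- function(cluster, field, n_slices = 400L) {
  a <- cluster$radius_nm
  if (a <= 0) return(0)
  c0 <- cluster$center_height_nm
  z_top <- c0 + a
  zmax_ok <- max(field$z_nm) >= min(c0, 50)  # tail extrapolation handles the rest
  if (!zmax_ok) stop("field profile too short for the sphere", call. = FALSE)
  z <- seq(c0 - a, z_top, length.out = n_slices + 1L)
  area <- pi * pmax(a^2 - (z - c0)^2, 0)
  intens <- field_intensity_at(field, z)
  f <- area * intens
  sum(diff(z) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' First-order resonance shift induced by a FA cluster
#'
#' Perturbation-theory surrogate for the red-shift of the resonance when a
#' dielectric sphere sits in the evanescent field: the permittivity contrast
#' of the sphere, weighted by the local mode intensity, relative to twice the
#' modal energy proxy:
#' `d_lambda = lambda_0 * (n_FA^2 - n2^2) * Int_sphere I(z) dV /
#'  (2 * modal_volume_proxy)`.
#' The sphere integral is evaluated by slicing the sphere into horizontal
#' disks against the (laterally averaged) exponential field tail. The shift
#' is nonnegative whenever the cluster index exceeds the medium index and
#' grows monotonically with cluster radius.
#'
#' @param cluster A [fa_cluster()].
#' @param field A [field_profile()] at resonance.
#' @param resonator A [resonator_params()].
#' @param medium A [medium()].
#' @return Peak wavelength shift (nm).
#' @export
fa_pws <- function(cluster, field, resonator, medium) {
  stopifnot(inherits(cluster, "fa_cluster"), inherits(medium, "medium"))
  n2 <- medium$superstrate_index
  dcontrast <- cluster$index^2 - n2^2
  if (cluster$radius_nm <= 0 || dcontrast == 0) return(0)
  ov <- sphere_overlap_integral(cluster, field)
  resonator$resonance_wavelength_nm * dcontrast * ov /
    (2 * resonator$modal_volume_proxy)
}

# ---- Mie scattering --------------------------------------------------------

# spherical Bessel functions of the first/second kind via half-integer
# cylindrical Bessel functions
sph_jn <- function(n, x) sqrt(pi / (2 * x)) * besselJ(x, n + 0.5)
sph_yn <- function(n, x) sqrt(pi / (2 * x)) * besselY(x, n + 0.5)

#' Mie scattering cross-section of a FA cluster
#'
#' Total scattering cross-section of a homogeneous lossless sphere embedded
#' in the background medium, by the full Mie series (Riccati-Bessel form).
#' In the small-particle limit (size parameter below ~0.3) this approaches
#' the Rayleigh closed form
#' `sigma = (8*pi/3) * k^4 * a^6 * ((m^2-1)/(m^2+2))^2`.
#'
#' @param cluster A [fa_cluster()].
#' @param medium A [medium()].
#' @param wavelength_nm Vacuum wavelength (nm).
#' @return Scattering cross-section (nm^2).
#' @export
#' @examples
#' scattering_cross_section(fa_cluster(100), medium(), 626)
scattering_cross_section <- function(cluster, medium, wavelength_nm) {
  stopifnot(inherits(cluster, "fa_cluster"), inherits(medium, "medium"))
  a <- cluster$radius_nm
  if (a <= 0) return(0)
  n_med <- medium$superstrate_index
  m <- cluster$index / n_med
  k <- 2 * pi * n_med / wavelength_nm
  x <- k * a
  mx <- m * x
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  n <- seq_len(nmax)
  psi_x <- x * sph_jn(n, x)
  psi_x_m1 <- x * sph_jn(n - 1, x)
  dpsi_x <- psi_x_m1 - n * psi_x / x
  chi_x <- -x * sph_yn(n, x)
  chi_x_m1 <- -x * sph_yn(n - 1, x)
  dchi_x <- chi_x_m1 - n * chi_x / x
  xi_x <- psi_x - 1i * chi_x
  dxi_x <- dpsi_x - 1i * dchi_x
  psi_mx <- mx * sph_jn(n, mx)
  psi_mx_m1 <- mx * sph_jn(n - 1, mx)
  dpsi_mx <- psi_mx_m1 - n * psi_mx / mx
  an <- (m * psi_mx * dpsi_x - psi_x * dpsi_mx) /
    (m * psi_mx * dxi_x - xi_x * dpsi_mx)
  bn <- (psi_mx * dpsi_x - m * psi_x * dpsi_mx) /
    (psi_mx * dxi_x - m * xi_x * dpsi_mx)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  qsca * pi * a^2
}

#' Peak-intensity reduction from scattering outcoupling
#'
#' Temporal coupled-mode surrogate for the loss of resonant reflection
#' efficiency caused by a scattering cluster. The intrinsic linewidth sets
#' the radiative decay rate `gamma_r = pi * FWHM / lambda_0^2`; the cluster
#' adds a loss rate `gamma_s = calibration * sigma_sc * <I>_sphere /
#' modal_volume_proxy`, where `<I>_sphere` is the mode intensity enhancement
#' averaged over the sphere volume. The loaded peak reflectance is
#' `R_peak = PIV0 * (gamma_r / (gamma_r + gamma_s))^2`, so
#' `PIS = PIV0 - R_peak` is zero without a scatterer, equals `0.75 * PIV0`
#' when `gamma_s = gamma_r`, and increases monotonically with the scattering
#' cross-section.
#'
#' @param cluster A [fa_cluster()].
#' @param field A [field_profile()] at resonance.
#' @param resonator A [resonator_params()].
#' @param medium A [medium()].
#' @param calibration Dimensionless calibration constant of the loss channel
#'   (default 1), absorbing the unmodelled in-structure share of the modal
#'   energy.
#' @return Peak intensity shift `PIS = PIV0 - R_peak` (normalized units,
#'   in `[0, PIV0]`).
#' @export
fa_pis <- function(cluster, field, resonator, medium, calibration = 1.0) {
  stopifnot(inherits(resonator, "resonator_params"))
  if (resonator$intrinsic_linewidth_nm <= 0) {
    stop("resonator linewidth must be positive", call. = FALSE)
  }
  if (cluster$radius_nm <= 0) return(0)
  sig <- scattering_cross_section(cluster, medium,
                                  resonator$resonance_wavelength_nm)
  vol <- (4 / 3) * pi * cluster$radius_nm^3
  imean <- sphere_overlap_integral(cluster, field) / vol
  gamma_r <- pi * resonator$intrinsic_linewidth_nm /
    resonator$resonance_wavelength_nm^2
  gamma_s <- calibration * sig * imean / resonator$modal_volume_proxy
  r_peak <- resonator$peak_reflectance * (gamma_r / (gamma_r + gamma_s))^2
  resonator$peak_reflectance - r_peak
}

#' Sweep FA cluster radii
#'
#' Computes the perturbation-model PWS and coupled-mode PIS for a set of
#' cluster radii against one resonator state.
#'
#' @param radii_nm Cluster radii (nm).
#' @param field,resonator,medium See [fa_pws()] / [fa_pis()].
#' @param index Cluster refractive index.
#' @param calibration Passed to [fa_pis()].
#' @return Data frame with columns `radius_nm`, `pws_nm`, `pis_norm`.
#' @export
fa_sweep <- function(radii_nm, field, resonator, medium, index = 1.46,
                     calibration = 1.0) {
  rows <- lapply(radii_nm, function(a) {
    cl <- fa_cluster(a, index)
    data.frame(radius_nm = a,
               pws_nm = fa_pws(cl, field, resonator, medium),
               pis_norm = fa_pis(cl, field, resonator, medium, calibration))
  })
  do.call(rbind, rows)
}
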