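# Ground-truth scene generation and instrument rendering: a synthetic cell
# (mask, interior attached-mass map, peripheral focal-adhesion ring) is
# mapped through the sensing calibration into per-pixel resonance truth
# (center wavelength, peak amplitude) and rendered into noisy hyperspectral
# cubes with the line-scan instrument model, so the whole pipeline can be
# validated against known truth without any external data.

#' Line-scan instrument model
#'
#' Spectral and temporal parameters of the imaging instrument used to render
#' synthetic cubes: wavelength grid, Lorentzian lineshape width, additive
#' Gaussian reflectance noise, pixel pitch, and frame interval.
#'
#' @param wavelengths_nm Wavelength grid; default 615-640 nm at 0.2 nm
#'   (126 samples).
#' @param fwhm_nm Lorentzian FWHM of the rendered resonance line (default
#'   4 nm).
#' @param noise_sd Additive Gaussian noise SD on reflectance (default 0.01).
#' @param pixel_pitch_um Pixel pitch (default 0.6 um).
#' @param frame_interval_s Time between re-scans (default 10 s, the
#'   instrument's shortest scan interval).
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(wavelengths_nm = seq(615, 640, by = 0.2),
                             fwhm_nm = 4, noise_sd = 0.01,
                             pixel_pitch_um = 0.6, frame_interval_s = 10) {
  stopifnot(fwhm_nm > 0, noise_sd >= 0, pixel_pitch_um > 0,
            frame_interval_s >= 0)
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 fwhm_nm = fwhm_nm, noise_sd = noise_sd,
                 pixel_pitch_um = pixel_pitch_um,
                 frame_interval_s = frame_interval_s),
            class = "instrument_model")
}

#' Generate a synthetic adhesion scene
#'
#' Builds a ground-truth cell scene: an elliptical cell mask, an interior
#' attached-mass map (largest at the cell center, tapering to zero at the
#' boundary over `mass_taper_um`), and a focal-adhesion map concentrated in
#' a peripheral ring of width `ring_width_um`, with a weaker diffuse
#' interior component. With `n_frames > 1` an adhesion time series is
#' produced: the first frame is cell-free (pre-attachment background) and
#' the cell then grows monotonically in area and amplitude.
#'
#' The canonical scene is a 30 x 20 um ellipse on a 100 x 100 px frame at
#' 0.6 um pitch with a 2 um ring, matching the scale of line-scan images of
#' single stem cells.
#'
#' @param shape Frame shape `c(ny, nx)` in pixels.
#' @param pixel_pitch_um Pixel pitch (um).
#' @param center_px Cell center `c(x, y)` (0-based pixels); default frame
#'   center.
#' @param semi_axes_um Ellipse semi-axes `c(a, b)` in micrometres (default
#'   15 x 10, i.e. a 30 x 20 um cell).
#' @param ring_width_um Width of the peripheral FA ring (default 2 um).
#' @param ring_amplitude Peak FA density in the ring (arbitrary units,
#'   default 1).
#' @param interior_fa_fraction Diffuse interior FA density as a fraction of
#'   the ring amplitude (default 0.25).
#' @param mass_amplitude Peak interior mass (arbitrary units, default 1).
#' @param mass_taper_um Distance from the boundary over which the mass map
#'   rises from 0 to its plateau (default 3 um).
#' @param n_frames Number of frames (1 = single static frame; > 1 = adhesion
#'   series starting cell-free).
#' @param growth_range Start/end scale factors of the cell axes over the
#'   series (default `c(0.5, 1)`).
#' @param seed Integer seed stored with the scene (rendering consumes it).
#' @return An object of class `synthetic_scene`: lists `masks`, `mass_maps`,
#'   `fa_maps` (one element per frame), the generation parameters, and
#'   `cell_index` (the 1.35-1.38 averaged refractive index context of live
#'   cells, recorded as metadata).
#' @export
generate_scene <- function(shape = c(100L, 100L), pixel_pitch_um = 0.6,
                           center_px = NULL,
                           semi_axes_um = c(15, 10), ring_width_um = 2,
                           ring_amplitude = 1, interior_fa_fraction = 0.25,
                           mass_amplitude = 1, mass_taper_um = 3,
                           n_frames = 1L, growth_range = c(0.5, 1),
                           seed = 1L) {
  ny <- shape[1]; nx <- shape[2]
  if (is.null(center_px)) center_px <- c((nx - 1) / 2, (ny - 1) / 2)
  if (ring_width_um >= min(semi_axes_um)) {
    stop("FA ring wider than the cell semi-minor axis", call. = FALSE)
  }
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  n_frames <- as.integer(n_frames)
  scales <- if (n_frames == 1L) 1 else
    c(0, seq(growth_range[1], growth_range[2], length.out = n_frames - 1L))
  amp_ramp <- if (n_frames == 1L) 1 else
    c(0, seq(growth_range[1], growth_range[2], length.out = n_frames - 1L))

  masks <- mass_maps <- fa_maps <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sc <- scales[f]
    if (sc <= 0) {
      masks[[f]] <- matrix(FALSE, ny, nx)
      mass_maps[[f]] <- matrix(0, ny, nx)
      fa_maps[[f]] <- matrix(0, ny, nx)
      next
    }
    a_px <- sc * semi_axes_um[1] / pixel_pitch_um
    b_px <- sc * semi_axes_um[2] / pixel_pitch_um
    r2 <- ((xx - center_px[1]) / a_px)^2 + ((yy - center_px[2]) / b_px)^2
    mask <- r2 <= 1
    dist_um <- distance_to_edge(mask) * pixel_pitch_um
    dist_um[!mask] <- 0
    mass <- amp_ramp[f] * mass_amplitude *
      pmin(dist_um / mass_taper_um, 1)
    mass[!mask] <- 0
    ring <- mask & dist_um <= ring_width_um
    fa <- matrix(0, ny, nx)
    fa[mask] <- amp_ramp[f] * ring_amplitude * interior_fa_fraction
    fa[ring] <- amp_ramp[f] * ring_amplitude
    masks[[f]] <- mask
    mass_maps[[f]] <- mass
    fa_maps[[f]] <- fa
  }
  structure(list(masks = masks, mass_maps = mass_maps, fa_maps = fa_maps,
                 shape = c(ny, nx), pixel_pitch_um = pixel_pitch_um,
                 center_px = center_px, semi_axes_um = semi_axes_um,
                 ring_width_um = ring_width_um,
                 ring_amplitude = ring_amplitude,
                 interior_fa_fraction = interior_fa_fraction,
                 mass_amplitude = mass_amplitude,
                 mass_taper_um = mass_taper_um,
                 n_frames = n_frames, cell_index = c(1.35, 1.38),
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px (%.2f um pitch), %d frame(s), ring %.1f um, seed %d\n",
    x$shape[1], x$shape[2], x$pixel_pitch_um, x$n_frames, x$ring_width_um,
    x$seed))
  invisible(x)
}

#' Map a scene to per-pixel resonance truth
#'
#' Applies the sensing calibration: attached mass red-shifts the local
#' resonance linearly from the 626.0 nm water background, scaled so that the
#' canonical cell interior reaches +2 nm (the worked attachment example);
#' FA density reduces the normalized peak amplitude from the 0.90 background
#' value, scaled so the canonical ring reaches a reduction of 0.10
#' (90% -> 80%). Background pixels are exactly (626.0 nm, 0.90). Amplitudes
#' driven below zero are clipped with a warning.
#'
#' @param scene A [generate_scene()] result.
#' @param frame Frame number.
#' @param lambda_bg_nm Background resonance wavelength (626.0 nm).
#' @param piv_bg Background normalized peak intensity (0.90).
#' @param pws_per_mass nm of red shift per unit mass (default chosen so the
#'   canonical interior mass of 1 gives +2 nm).
#' @param pis_per_fa Amplitude reduction per unit FA density (default 0.10).
#' @return List of matrices `lambda_c_nm` and `amplitude`, plus the frame's
#'   truth maps for convenience (`mask`, `mass`, `fa`).
#' @export
scene_to_truth_maps <- function(scene, frame = 1L, lambda_bg_nm = 626.0,
                                piv_bg = 0.90, pws_per_mass = 2.0,
                                pis_per_fa = 0.10) {
  stopifnot(inherits(scene, "synthetic_scene"))
  mass <- scene$mass_maps[[frame]]
  fa <- scene$fa_maps[[frame]]
  lam <- lambda_bg_nm + pws_per_mass * mass
  amp <- piv_bg - pis_per_fa * fa
  if (any(amp < 0)) {
    warning("amplitude driven below 0; clipped", call. = FALSE)
    amp[amp < 0] <- 0
  }
  list(lambda_c_nm = lam, amplitude = amp, mask = scene$masks[[frame]],
       mass = mass, fa = fa)
}

#' Render truth maps into a hyperspectral cube
#'
#' Renders each pixel as a Lorentzian resonance line with the pixel's truth
#' center wavelength and amplitude, adds seeded Gaussian noise, and wraps
#' the result in a [hyperspectral_cube()]. The water-reference cube (for
#' normalization) is rendered with `render_reference_cube()` at unit
#' amplitude and the background wavelength.
#'
#' @param truth A [scene_to_truth_maps()] result (or any list with matrices
#'   `lambda_c_nm` and `amplitude`).
#' @param instrument An [instrument_model()].
#' @param seed Integer seed for the noise generator.
#' @param timestamp_s,frame_index Frame metadata.
#' @return A [hyperspectral_cube()].
#' @export
render_cube <- function(truth, instrument, seed = 1L, timestamp_s = 0,
                        frame_index = 1L) {
  stopifnot(inherits(instrument, "instrument_model"))
  wl <- instrument$wavelengths_nm
  lam <- truth$lambda_c_nm
  amp <- truth$amplitude
  if (min(lam) - 2.5 * instrument$fwhm_nm < min(wl) ||
      max(lam) + 2.5 * instrument$fwhm_nm > max(wl)) {
    stop("wavelength grid too narrow for the rendered resonances", call. = FALSE)
  }
  ny <- nrow(lam); nx <- ncol(lam)
  hw2 <- (instrument$fwhm_nm / 2)^2
  # pixels x wavelengths, then reshaped
  dl <- outer(as.vector(lam), wl, function(l0, l) (l - l0))
  Y <- as.vector(amp) * hw2 / (dl^2 + hw2)
  if (instrument$noise_sd > 0) {
    set.seed(seed)
    Y <- Y + stats::rnorm(length(Y), 0, instrument$noise_sd)
  }
  hyperspectral_cube(array(Y, c(ny, nx, length(wl))), wl,
                     instrument$pixel_pitch_um, timestamp_s, frame_index)
}

#' @rdname render_cube
#' @param shape Frame shape `c(ny, nx)` for the reference cube.
#' @param lambda_bg_nm,amplitude Background resonance parameters of the
#'   water reference (defaults 626.0 nm, amplitude 1).
#' @export
render_reference_cube <- function(shape, instrument, seed = 2L,
                                  lambda_bg_nm = 626.0, amplitude = 1) {
  truth <- list(lambda_c_nm = matrix(lambda_bg_nm, shape[1], shape[2]),
                amplitude = matrix(amplitude, shape[1], shape[2]))
  render_cube(truth, instrument, seed = seed)
}

#' Render a full adhesion series and fit it end to end
#'
#' Convenience driver for the canonical synthetic experiment: renders every
#' frame of a scene (noise seeds derived from the scene seed), fits all
#' cubes against a rendered water reference, and assembles shift images
#' against the first (cell-free) frame.
#'
#' @param scene A [generate_scene()] result.
#' @param instrument An [instrument_model()].
#' @param method Peak-fit method for [fit_cube()].
#' @return List with `maps` (per-frame [resonance_maps()]), `shifts`
#'   (per-frame [shift_images()] vs the first frame), `reference` (the
#'   reference cube), and `truths` (per-frame truth maps).
#' @export
simulate_adhesion_series <- function(scene, instrument = instrument_model(),
                                     method = "lorentzian") {
  nfr <- scene$n_frames
  reference <- render_reference_cube(scene$shape, instrument,
                                     seed = scene$seed * 1000L + 999L)
  maps <- vector("list", nfr)
  truths <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    truths[[f]] <- scene_to_truth_maps(scene, f)
    cube <- render_cube(truths[[f]], instrument,
                        seed = scene$seed * 1000L + f,
                        timestamp_s = (f - 1) * instrument$frame_interval_s,
                        frame_index = f)
    maps[[f]] <- fit_cube(cube, reference, method = method)
  }
  background <- background_from_sequence(maps, "first_frame")
  shifts <- lapply(maps, shift_images, background = background)
  list(maps = maps, shifts = shifts, reference = reference, truths = truths)
}
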