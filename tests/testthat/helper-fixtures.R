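# Shared fixtures. Expensive electromagnetic solves are computed lazily and
# cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

design_stack <- function() grating_stack()
water <- function() medium(1.333)

# resonance of the printed sensor design (coarse-to-fine peak search)
design_peak <- function() {
  cached("design_peak",
         promscope:::rcwa_peak(design_stack(), water(), 600, 650,
                               coarse_step = 0.1))
}

# full resonator characterization (spectrum fit + field profile + proxies)
design_resonator <- function() {
  cached("design_resonator", characterize_resonator(design_stack(), water()))
}

# synthetic Lorentzian spectrum on the instrument grid
lorentz_spectrum <- function(center_nm, fwhm_nm = 4, amplitude = 1,
                             baseline = 0,
                             wavelengths_nm = seq(615, 640, by = 0.2),
                             noise_sd = 0, seed = NULL) {
  y <- amplitude * (fwhm_nm / 2)^2 /
    ((wavelengths_nm - center_nm)^2 + (fwhm_nm / 2)^2) + baseline
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  reflection_spectrum(wavelengths_nm, y)
}

# binary disk mask on an ny x nx frame, 0-based center coordinates
disk_mask <- function(cx, cy, r, ny = 100, nx = 100) {
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

# fabricated exponential near-field profile (analytic stand-in used by unit
# tests that exercise the overlap integrals without an RCWA solve)
analytic_field <- function(i0 = 50, kappa = 1 / 120, z_max = 1500,
                           period_nm = 400, n2 = 1.333) {
  z <- seq(0, z_max, by = 1)
  structure(list(z_nm = z, intensity_enhancement = i0 * exp(-2 * kappa * z),
                 wavelength_nm = 626,
                 metadata = list(period_nm = period_nm, n2 = n2)),
            class = "field_profile")
}

# canonical noisy 10-frame adhesion experiment (shared by morphometry and
# acceptance tests)
canonical_series <- function() {
  cached("canonical_series", {
    scene <- generate_scene(n_frames = 10, seed = 7)
    list(scene = scene, run = simulate_adhesion_series(scene))
  })
}
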