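# Resonance-peak extraction: normalization, Lorentzian and parabolic
# estimators, equivariances, noise behaviour, and cube fitting.

test_that("normalization to the water reference behaves as specified", {
  ref <- lorentz_spectrum(626, amplitude = 0.85)
  expect_equal(max(normalize_spectrum(ref, ref)$reflectance), 1.0)
  raw <- reflection_spectrum(ref$wavelengths_nm, 0.8 * ref$reflectance)
  expect_equal(max(normalize_spectrum(raw, ref)$reflectance), 0.8)
  other <- lorentz_spectrum(626, wavelengths_nm = seq(610, 635, by = 0.2))
  expect_error(normalize_spectrum(raw, other), "grid")
  zero <- reflection_spectrum(ref$wavelengths_nm, rep(0, 126))
  expect_error(normalize_spectrum(raw, zero), "nonpositive")
})

test_that("noiseless Lorentzian lines are recovered essentially exactly", {
  fit <- fit_resonance(lorentz_spectrum(628.00, 4, 0.80))
  expect_equal(fit$pwv_nm, 628.00, tolerance = 1e-3)
  expect_equal(fit$piv, 0.80, tolerance = 1e-3)
  expect_equal(fit$fwhm_nm, 4, tolerance = 1e-3)
  expect_true(fit$valid)
  # off-grid center with a baseline
  fit2 <- fit_resonance(lorentz_spectrum(627.93, 4, 0.9, baseline = 0.05))
  expect_equal(fit2$pwv_nm, 627.93, tolerance = 1e-6)
  expect_equal(fit2$piv, 0.95, tolerance = 1e-6)
})

test_that("an exact parabola is recovered to machine precision", {
  wl <- seq(615, 640, by = 0.2)
  y <- 0.9 - 0.05 * (wl - 628.1)^2
  fit <- fit_resonance(reflection_spectrum(wl, y), method = "parabolic_vertex")
  expect_equal(fit$pwv_nm, 628.1, tolerance = 1e-10)
  expect_equal(fit$piv, 0.9, tolerance = 1e-10)
})

test_that("noisy replicates: mean absolute PWV error below 0.05 nm", {
  set.seed(123)
  errs <- replicate(200, {
    sp <- lorentz_spectrum(628, 4, 0.80, noise_sd = 0.01)
    fit_resonance(sp)$pwv_nm - 628
  })
  expect_lt(mean(abs(errs)), 0.05)
})

test_that("shift and scale equivariance hold", {
  sp <- lorentz_spectrum(627.5, 4, 0.8, baseline = 0.02)
  base <- fit_resonance(sp)
  shifted <- reflection_spectrum(sp$wavelengths_nm + 2.3, sp$reflectance)
  expect_equal(fit_resonance(shifted)$pwv_nm - base$pwv_nm, 2.3,
               tolerance = 1e-6)
  pshift <- fit_resonance(shifted, method = "parabolic_vertex")
  pbase <- fit_resonance(sp, method = "parabolic_vertex")
  expect_equal(pshift$pwv_nm - pbase$pwv_nm, 2.3, tolerance = 1e-12)
  scaled <- reflection_spectrum(sp$wavelengths_nm, 2.5 * sp$reflectance)
  sfit <- fit_resonance(scaled)
  expect_equal(sfit$piv / base$piv, 2.5, tolerance = 1e-9)
  expect_equal(sfit$pwv_nm, base$pwv_nm, tolerance = 1e-9)
})

test_that("PWV noise decreases with fit-window length", {
  set.seed(7)
  sd_for_window <- function(win) {
    # very short windows occasionally trip the parabolic fallback; that is
    # by design and irrelevant to the variance comparison
    suppressWarnings(stats::sd(replicate(150, {
      sp <- lorentz_spectrum(628, 4, 0.8, noise_sd = 0.02)
      fit_resonance(sp, window_nm = win)$pwv_nm
    })))
  }
  expect_gt(sd_for_window(1.2), sd_for_window(4))
})

test_that("fit_cube maps pixels, masks failures, and honours references", {
  wl <- seq(615, 640, by = 0.2)
  y <- 0.8 * 4 / ((wl - 627)^2 + 4)
  arr <- array(rep(y, each = 12), c(3, 4, length(wl)))
  cube <- hyperspectral_cube(arr, wl)
  maps <- fit_cube(cube)
  expect_true(all(abs(maps$pwv_map - 627) < 1e-6))
  expect_true(all(maps$valid_mask))
  # one flat pixel is masked invalid, the others are fitted
  arr2 <- arr
  arr2[2, 2, ] <- 0.3
  maps2 <- fit_cube(hyperspectral_cube(arr2, wl))
  expect_false(maps2$valid_mask[2, 2])
  expect_true(is.na(maps2$pwv_map[2, 2]))
  expect_equal(sum(maps2$valid_mask), 11)
  # per-pixel reference normalization
  ref <- hyperspectral_cube(array(rep(2 * y / 0.8, each = 12),
                                  c(3, 4, length(wl))), wl)
  maps3 <- fit_cube(cube, ref)
  expect_equal(maps3$piv_map[1, 1], 0.8 / 2, tolerance = 1e-6)
})
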