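# Coupled-wave forward model: staircase geometry, oracle equivalences,
# resonance behaviour and the evanescent near field.

test_that("staircase discretization reproduces the trapezoid geometry", {
  # rectangular limit: all slabs share the duty cycle
  rect <- grating_stack(grating_sidewall_deg = 90, tio2_sidewall_deg = 90,
                        staircase_layers = 7L)
  slabs <- build_staircase(rect, medium())
  expect_true(all(abs(slabs$fill[slabs$region != "tio2_ridge"] - 0.416) < 1e-12))
  expect_true(all(abs(slabs$fill[slabs$region == "tio2_ridge"] - 0.5) < 1e-12))

  # stated geometry: fills strictly monotonic through each trapezoid,
  # thickness-weighted mean fill equals the mid-height duty exactly
  st <- grating_stack(staircase_layers = 10L)
  slabs <- build_staircase(st, medium())
  pg <- slabs[slabs$region != "tio2_ridge", ]
  # top narrow -> base wide; the slab straddling the groove TiO2 fill level
  # is split in two, so fills are nondecreasing with 10 distinct values
  expect_true(all(diff(pg$fill) >= 0))
  expect_length(unique(pg$fill), 10L)
  expect_equal(sum(pg$fill * pg$thickness_nm) / sum(pg$thickness_nm),
               0.416, tolerance = 1e-12)
  tg <- slabs[slabs$region == "tio2_ridge", ]
  expect_true(all(diff(tg$fill) > 0))
  expect_equal(sum(tg$fill * tg$thickness_nm) / sum(tg$thickness_nm),
               0.5, tolerance = 1e-12)
  # total thicknesses preserved exactly
  expect_equal(sum(pg$thickness_nm), 120)
  expect_equal(sum(tg$thickness_nm), 61)

  # single slab sits at the mid-height width
  one <- build_staircase(grating_stack(staircase_layers = 1L), medium())
  expect_equal(one$fill[one$region == "tio2_ridge"], 0.5, tolerance = 1e-12)

  # sidewall geometry driving the fill outside (0, 1) is a geometry error
  expect_error(build_staircase(grating_stack(grating_duty = 0.97,
                                             grating_sidewall_deg = 45)),
               "fill fraction")
})

test_that("grating_stack and medium validate their invariants", {
  expect_error(grating_stack(grating_duty = 0), "duty")
  expect_error(grating_stack(tio2_sidewall_deg = 0), "sidewall")
  expect_error(grating_stack(period_nm = -1))
  expect_error(medium(0.9), ">= 1")
})

test_that("uniform-layer limit matches the transfer-matrix oracle to 1e-6", {
  st <- grating_stack(grating_duty = 1 - 1e-9, tio2_duty = 1 - 1e-9,
                      grating_sidewall_deg = 90, tio2_sidewall_deg = 90)
  wl <- seq(600, 650, by = 2.5)
  for (pol in c("TE", "TM")) {
    sp <- simulate_spectrum(st, medium(), wl, polarization = pol,
                            harmonics = 6L)
    oracle <- thin_film_reflectance(wl, c(2.4, 1.46), c(61, 120),
                                    n_in = 1.333, n_out = 1.52)
    expect_lt(max(abs(sp$reflectance - oracle)), 1e-6)
  }
})

test_that("lossless stacks conserve energy to 1e-6 at every wavelength", {
  sp <- simulate_spectrum(design_stack(), water(), seq(604, 648, by = 4),
                          check_energy = TRUE)
  resid <- abs(sp$metadata$R_total + sp$metadata$T_total - 1)
  expect_lt(max(resid), 1e-6)
  spTE <- simulate_spectrum(design_stack(), water(), seq(604, 648, by = 8),
                            polarization = "TE")
  expect_lt(max(abs(spTE$metadata$R_total + spTE$metadata$T_total - 1)), 1e-6)
})

test_that("resonance converges in harmonic truncation (PWV moves < 0.1 nm on doubling)", {
  pk <- design_peak()
  pk2 <- promscope:::rcwa_peak(design_stack(), water(), pk$pwv_nm - 2,
                               pk$pwv_nm + 2, coarse_step = 0.2,
                               harmonics = 24L)
  expect_lt(abs(pk$pwv_nm - pk2$pwv_nm), 0.1)
})

test_that("PWV is nondecreasing in superstrate index over [1.30, 1.40]", {
  tab <- resonance_vs_index(design_stack(), c(1.30, 1.35, 1.40),
                            lower = 615, upper = 650)
  expect_true(all(diff(tab$pwv_nm) > 0))
  # single-element sweep has zero shift by construction
  one <- resonance_vs_index(design_stack(), 1.333, lower = 620, upper = 640)
  expect_identical(one$pws_nm, 0)
})

test_that("locate_resonance returns the fitted peak and rejects flat spectra", {
  sp <- lorentz_spectrum(627.3, fwhm_nm = 2.5, amplitude = 0.95)
  fit <- locate_resonance(sp)
  expect_equal(fit$pwv_nm, 627.3, tolerance = 1e-9)
  flat <- reflection_spectrum(seq(615, 640, 0.2), rep(0.4, 126))
  expect_error(locate_resonance(flat), "boundary|flat")
  # the design spectrum reaches near-unity peak reflectance when lossless
  expect_gte(design_resonator()$fit$piv, 0.9)
})

test_that("near field: resonant enhancement, exponential tail, analytic decay", {
  pk <- design_peak()
  ch <- design_resonator()
  fp <- ch$field
  expect_gte(fp$intensity_enhancement[1], 10)       # >= 10x on resonance
  off <- field_profile(design_stack(), water(), pk$pwv_nm + 20)
  expect_lt(off$intensity_enhancement[1], 3)        # off-resonance limit
  dec <- fit_field_decay(fp)
  kappa_analytic <- (2 * pi / pk$pwv_nm) *
    sqrt((pk$pwv_nm / 400)^2 - 1.333^2)
  expect_lt(abs(dec$kappa_per_nm - kappa_analytic) / kappa_analytic, 0.25)
  expect_gte(dec$r_squared, 0.99)
})
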