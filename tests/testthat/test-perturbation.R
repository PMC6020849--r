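# FA perturbation surrogates: overlap-integral resonance shift, Mie
# scattering, and the coupled-mode intensity-loss model.

test_that("fa_pws has the correct zero limits and radius monotonicity", {
  fld <- analytic_field()
  res <- resonator_params(626, 2.4, 1.0, modal_volume_proxy(fld))
  md <- medium()
  expect_identical(fa_pws(fa_cluster(0), fld, res, md), 0)
  expect_identical(fa_pws(fa_cluster(200, index = 1.333), fld, res, md), 0)
  shifts <- vapply(c(50, 100, 250, 500),
                   function(a) fa_pws(fa_cluster(a), fld, res, md), numeric(1))
  expect_true(all(diff(shifts) > 0))
  expect_true(all(shifts >= 0))
})

test_that("disk-slicing overlap integral matches 3D Monte-Carlo within 1%", {
  fld <- analytic_field()
  set.seed(11)
  for (a in c(80, 250)) {
    cl <- fa_cluster(a)
    n_mc <- 1e6
    pts <- matrix(runif(3 * n_mc, -1, 1), ncol = 3)
    pts <- pts[rowSums(pts^2) <= 1, , drop = FALSE]
    z <- a + a * pts[, 3]
    mc <- mean(promscope:::field_intensity_at(fld, z)) * (4 / 3) * pi * a^3
    disk <- promscope:::sphere_overlap_integral(cl, fld)
    expect_lt(abs(disk - mc) / mc, 0.01)
  }
})

test_that("small-sphere shift follows the a^3-weighted field overlap", {
  # for radii far below the decay length the overlap reduces to
  # V * I(center): check the ratio against the analytic cube law
  fld <- analytic_field(kappa = 1 / 5000)   # nearly uniform field
  res <- resonator_params(626, 2.4, 1.0, modal_volume_proxy(fld))
  md <- medium()
  s10 <- fa_pws(fa_cluster(10), fld, res, md)
  s20 <- fa_pws(fa_cluster(20), fld, res, md)
  expect_equal(s20 / s10, 8, tolerance = 0.02)
})

test_that("Mie cross-section: zero limit, Rayleigh regime, monotone growth", {
  md <- medium()
  expect_identical(scattering_cross_section(fa_cluster(0), md, 626), 0)
  # x <= 0.3: Mie approaches the Rayleigh closed form (within 2.5% at x=0.27)
  a <- 20
  k <- 2 * pi * 1.333 / 626
  m <- 1.46 / 1.333
  ray <- (8 * pi / 3) * k^4 * a^6 * ((m^2 - 1) / (m^2 + 2))^2
  mie <- scattering_cross_section(fa_cluster(a), md, 626)
  expect_lt(abs(mie - ray) / ray, 0.025)
  sig <- vapply(seq(10, 500, by = 10),
                function(a) scattering_cross_section(fa_cluster(a), md, 626),
                numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("coupled-mode intensity loss: limits, algebra, monotonicity, bounds", {
  fld <- analytic_field()
  res <- resonator_params(626, 2.4, 0.98, modal_volume_proxy(fld))
  md <- medium()
  expect_identical(fa_pis(fa_cluster(0), fld, res, md), 0)
  pis <- vapply(c(50, 100, 250, 500),
                function(a) fa_pis(fa_cluster(a), fld, res, md), numeric(1))
  expect_true(all(diff(pis) > 0))
  expect_true(all(pis >= 0 & pis <= res$peak_reflectance))
  # gamma_s = gamma_r gives PIS = 0.75 * PIV0: back out the calibration that
  # equalizes the two rates and check the stated algebra
  cl <- fa_cluster(150)
  pis1 <- fa_pis(cl, fld, res, md, calibration = 1)
  g_ratio <- sqrt(res$peak_reflectance / (res$peak_reflectance - pis1)) - 1
  pis_eq <- fa_pis(cl, fld, res, md, calibration = 1 / g_ratio)
  expect_equal(pis_eq, 0.75 * res$peak_reflectance, tolerance = 1e-9)
  # nonpositive linewidth is a domain error
  expect_error(resonator_params(626, 0, 1, 1), "linewidth")
})

test_that("a superstrate index change alone leaves the intensity loss at zero", {
  fld <- analytic_field()
  for (n2 in c(1.333, 1.373)) {
    res <- resonator_params(626, 2.4, 1.0, modal_volume_proxy(fld, n2 = n2))
    expect_identical(fa_pis(fa_cluster(0), fld, res, medium(n2)), 0)
  }
})
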