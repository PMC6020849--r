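# Scene generation determinism, calibration of the truth maps against the
# worked attachment example, and rendering round trips.

test_that("scene generation is deterministic and respects its contracts", {
  s1 <- generate_scene(n_frames = 3, seed = 5)
  s2 <- generate_scene(n_frames = 3, seed = 5)
  expect_identical(s1, s2)
  # ring amplitude 0 leaves the FA map identically zero
  s0 <- generate_scene(ring_amplitude = 0)
  expect_true(all(s0$fa_maps[[1]] == 0))
  # adhesion series: first frame cell-free, mask area nondecreasing
  sg <- generate_scene(n_frames = 8, seed = 2)
  areas <- vapply(sg$masks, sum, numeric(1))
  expect_identical(areas[1], 0)
  expect_true(all(diff(areas) >= 0))
  expect_error(generate_scene(ring_width_um = 12, semi_axes_um = c(15, 10)),
               "ring")
})

test_that("truth maps encode the worked attachment example", {
  sc <- generate_scene()
  tr <- scene_to_truth_maps(sc)
  bg <- !tr$mask
  expect_true(all(tr$lambda_c_nm[bg] == 626.0))   # water background PWV
  expect_true(all(tr$amplitude[bg] == 0.90))      # 90% normalized PIV
  interior <- tr$mass == max(tr$mass)
  expect_equal(unique(tr$lambda_c_nm[interior]), 628.0)  # +2 nm attached
  ring <- tr$fa == max(tr$fa)
  expect_equal(unique(tr$amplitude[ring]), 0.80)  # 80% normalized PIV
  # over-strong scattering clips at zero with a warning
  expect_warning(scene_to_truth_maps(sc, pis_per_fa = 1.5), "clipped")
})

test_that("rendering is seeded and the grid guard fires", {
  sc <- generate_scene()
  tr <- scene_to_truth_maps(sc)
  inst <- instrument_model()
  c1 <- render_cube(tr, inst, seed = 9)
  c2 <- render_cube(tr, inst, seed = 9)
  expect_identical(c1$data, c2$data)
  c3 <- render_cube(tr, inst, seed = 10)
  expect_false(identical(c1$data, c3$data))
  narrow <- instrument_model(wavelengths_nm = seq(620, 634, by = 0.2))
  expect_error(render_cube(tr, narrow), "too narrow")
})

test_that("noiseless rendering inverts exactly through the fitter", {
  sc <- generate_scene()
  tr <- scene_to_truth_maps(sc)
  inst0 <- instrument_model(noise_sd = 0)
  maps <- fit_cube(render_cube(tr, inst0),
                   render_reference_cube(sc$shape, inst0))
  expect_lt(max(abs(maps$pwv_map - tr$lambda_c_nm)), 1e-3)
  expect_lt(max(abs(maps$piv_map - tr$amplitude)), 1e-3)
})

test_that("round trip at instrument noise meets the propagated error budget", {
  run <- canonical_series()
  sh <- run$run$shifts[[10]]
  tr <- run$run$truths[[10]]
  mask <- tr$mask
  # in-region mean PWS within 3x the propagated per-pixel noise level
  interior <- tr$mass == max(tr$mass)
  pws_err <- mean(sh$pws_image[interior], na.rm = TRUE) - 2.0
  expect_lt(abs(pws_err), 3 * 0.02 / sqrt(sum(interior)) + 0.01)
  ring <- tr$fa == max(tr$fa)
  pis_err <- mean(sh$pis_image[ring], na.rm = TRUE) - 0.10
  expect_lt(abs(pis_err), 0.01)
})
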