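# Shift-image assembly: sign conventions, background strategies, series
# normalization.

mk_maps <- function(pwv, piv, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pwv), ncol(pwv))
  resonance_maps(pwv, piv, valid)
}

test_that("shift images follow the attachment sign conventions", {
  bg <- mk_maps(matrix(626, 2, 2), matrix(0.90, 2, 2))
  fr <- mk_maps(matrix(628, 2, 2), matrix(0.80, 2, 2))
  sh <- shift_images(fr, bg)
  expect_equal(sh$pws_image, matrix(2, 2, 2))    # 626 -> 628 nm: +2 nm red shift
  expect_equal(sh$pis_image, matrix(0.10, 2, 2)) # 0.90 -> 0.80: +0.10 reduction
  zero <- shift_images(bg, bg)
  expect_true(all(zero$pws_image == 0) && all(zero$pis_image == 0))
  expect_error(shift_images(fr, mk_maps(matrix(626, 3, 2), matrix(1, 3, 2))),
               "shape")
})

test_that("swapping frame and background negates both images", {
  set.seed(4)
  a <- mk_maps(matrix(626 + runif(9), 3, 3), matrix(runif(9, 0.5, 1), 3, 3))
  b <- mk_maps(matrix(626 + runif(9), 3, 3), matrix(runif(9, 0.5, 1), 3, 3))
  ab <- shift_images(a, b)
  ba <- shift_images(b, a)
  expect_equal(ab$pws_image, -ba$pws_image)
  expect_equal(ab$pis_image, -ba$pis_image)
})

test_that("validity masks intersect into the shift image", {
  va <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  vb <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  sh <- shift_images(mk_maps(matrix(628, 2, 2), matrix(0.8, 2, 2), va),
                     mk_maps(matrix(626, 2, 2), matrix(0.9, 2, 2), vb))
  expect_equal(sh$valid_mask, va & vb)
  expect_true(all(is.na(sh$pws_image[!(va & vb)])))
})

test_that("background strategies recover the reference maps", {
  one <- mk_maps(matrix(626.5, 2, 2), matrix(0.91, 2, 2))
  expect_identical(background_from_sequence(list(one)), one)
  const <- replicate(5, one, simplify = FALSE)
  med <- background_from_sequence(const, "cell_free_median")
  expect_equal(med$pwv_map, one$pwv_map)
  expect_equal(med$piv_map, one$piv_map)
  expect_error(background_from_sequence(list()), "empty")
})

test_that("cell-free median recovers a drift-free background under a growing cell", {
  set.seed(21)
  nfr <- 8; ny <- nx <- 20
  truth_pwv <- matrix(626, ny, nx)
  maps <- vector("list", nfr)
  cf_masks <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    cell <- disk_mask(10, 10, 1 + f, ny, nx)
    pwv <- truth_pwv + rnorm(ny * nx, 0, 0.005)
    pwv[cell] <- pwv[cell] + 2
    maps[[f]] <- mk_maps(pwv, matrix(0.9, ny, nx))
    cf_masks[[f]] <- !cell
  }
  bg <- background_from_sequence(maps, "cell_free_median", cf_masks)
  covered <- Reduce(`|`, lapply(cf_masks, `!`)) &
    Reduce(`|`, cf_masks)                    # pixels cell-free in some frame
  err <- abs(bg$pwv_map - truth_pwv)[covered]
  expect_lt(max(err, na.rm = TRUE), 0.02)
})

test_that("min-max series normalization and its degenerate cases", {
  expect_equal(normalize_series(c(0, 0.05, 0.10)), c(0, 0.5, 1))
  expect_identical(normalize_series(c(3, 1, 2), "none"), c(3, 1, 2))
  expect_error(normalize_series(c(1, 1, 1)), "degenerate")
  expect_error(normalize_series(0.5), ">= 2")
})
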