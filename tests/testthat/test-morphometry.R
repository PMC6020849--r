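# Segmentation, boundary geometry, normal-direction tracking, kymographs,
# regional statistics and profiles, exercised against analytic shapes.

test_that("segmentation recovers a rendered cell footprint (Jaccard >= 0.9)", {
  run <- canonical_series()
  sh <- run$run$shifts[[10]]
  truth <- run$scene$masks[[10]]
  seg <- segment_cell(sh$pis_image)
  jac <- sum(seg & truth) / sum(seg | truth)
  expect_gte(jac, 0.9)
})

test_that("segmentation degenerate inputs error; morphology is idempotent on full frames", {
  expect_error(segment_cell(matrix(0, 20, 20)), "no cell")
  full <- matrix(TRUE, 15, 15)
  expect_identical(promscope:::fill_holes(promscope:::binary_close(full, 2)),
                   full)
})

test_that("disk boundary: perimeter within 1%, normals radial within 2 degrees", {
  m <- disk_mask(50, 50, 15)
  bd <- extract_boundary(m)
  expect_lt(abs(bd$length_px - 2 * pi * 15) / (2 * pi * 15), 0.01)
  rad <- cbind(bd$xy[, 1] - 50, bd$xy[, 2] - 50)
  rad <- rad / sqrt(rowSums(rad^2))
  ang <- acos(pmin(pmax(rowSums(rad * bd$normals), -1), 1)) * 180 / pi
  expect_lt(max(ang), 2)
})

test_that("square boundary: perimeter within 2%, all four corners present", {
  sq <- matrix(FALSE, 100, 100)
  sq[36:65, 36:65] <- TRUE
  bs <- extract_boundary(sq)
  expect_lt(abs(bs$length_px - 120) / 120, 0.02)
  corners <- list(c(35.5, 35.5), c(65.5, 35.5), c(35.5, 65.5), c(65.5, 65.5))
  dists <- vapply(corners, function(p) {
    min(sqrt((bs$xy[, 1] - p[1])^2 + (bs$xy[, 2] - p[2])^2))
  }, numeric(1))
  expect_true(all(dists < 2))
})

test_that("degenerate masks are rejected", {
  mm <- matrix(FALSE, 50, 50)
  mm[25, 25] <- TRUE
  expect_error(extract_boundary(mm), "degenerate")
})

test_that("boundary tracking: identity, dilation, translation, inverse consistency", {
  m <- disk_mask(50, 50, 15)
  bd <- extract_boundary(m)
  same <- track_boundary(bd, m)
  expect_lt(max(abs(attr(same, "displacement_px"))), 0.25)
  grown <- track_boundary(bd, disk_mask(50, 50, 17))
  d <- attr(grown, "displacement_px")
  expect_true(all(abs(d - 2) < 0.5))
  shifted <- track_boundary(bd, disk_mask(51, 50, 15))
  d2 <- attr(shifted, "displacement_px")
  theta <- atan2(bd$xy[, 2] - 50, bd$xy[, 1] - 50)
  expect_gt(cor(d2, cos(theta)), 0.99)       # sinusoidal in arclength
  expect_equal((max(d2) - min(d2)) / 2, 1, tolerance = 0.1)
  back <- track_boundary(grown, m)
  expect_lt(max(abs(attr(grown, "displacement_px") +
                      attr(back, "displacement_px"))), 0.5)
  expect_error(track_boundary(bd, matrix(FALSE, 100, 100)), "overlap|crossing")
})

test_that("kymographs: uniform images give constant maps; bands separate ring from interior", {
  m <- disk_mask(50, 50, 20)
  bd <- extract_boundary(m)
  uni <- band_kymograph(list(matrix(3.7, 100, 100)), list(bd),
                        offset_um = 0, width_um = 3)
  expect_true(all(abs(uni$values - 3.7) < 1e-9))
  # synthetic FA ring: value 0.1 within 2 um of the boundary, 0.02 inside
  dist_um <- promscope:::distance_to_edge(m) * 0.6
  img <- matrix(0, 100, 100)
  img[m] <- 0.02
  img[m & dist_um <= 2] <- 0.1
  band1 <- band_kymograph(list(img), list(bd), offset_um = 0, width_um = 2)
  band2 <- band_kymograph(list(img), list(bd), offset_um = 6, width_um = 4)
  expect_gt(mean(band1$values), 0.07)          # ring amplitude
  expect_lt(mean(band2$values), 0.03)          # interior value
  # zero-width band is a line profile along the offset curve
  line <- band_kymograph(list(img), list(bd), offset_um = 1, width_um = 0)
  expect_equal(dim(line$values), c(360L, 1L))
})

test_that("edge/center statistics partition the mask and order correctly", {
  m <- disk_mask(50, 50, 20)
  uni <- edge_center_stats(matrix(5, 100, 100), m)
  expect_equal(uni$mean[1], uni$mean[2])
  dist_um <- promscope:::distance_to_edge(m) * 0.6
  edge <- m & dist_um <= 3
  center <- m & dist_um > 6
  expect_false(any(edge & center))             # disjoint subsets of the mask
  expect_true(all((edge | center) <= m))
  expect_error(edge_center_stats(matrix(1, 100, 100), disk_mask(50, 50, 4)),
               "empty")
  # ring-patterned PIS has edge > center; interior-mass PWS the reverse
  run <- canonical_series()
  sh <- run$run$shifts[[10]]
  seg <- segment_cell(sh$pis_image)
  pis <- edge_center_stats(sh$pis_image, seg)
  pws <- edge_center_stats(sh$pws_image, seg)
  expect_gt(pis$mean[pis$region == "edge"], pis$mean[pis$region == "center"])
  expect_gt(pws$mean[pws$region == "center"], pws$mean[pws$region == "edge"])
})

test_that("cross-sections: constant, analytic ramp, ring double peak", {
  expect_true(all(cross_section_profile(matrix(2, 50, 50), c(5, 25),
                                        c(45, 25))$value == 2))
  ramp <- matrix(0:(49), 50, 50, byrow = TRUE) * 1.0
  pr <- cross_section_profile(ramp, c(5, 25), c(45, 25), 41)
  slope <- coef(lm(value ~ position_um, pr))[2]
  expect_equal(unname(slope), 1 / 0.6, tolerance = 1e-9)
  expect_error(cross_section_profile(ramp, c(-3, 0), c(10, 10)), "outside")
  run <- canonical_series()
  sh <- run$run$shifts[[10]]
  prof <- cross_section_profile(sh$pis_image, c(10, 49.5), c(89, 49.5), 160)
  v <- stats::filter(prof$value, rep(1 / 5, 5))
  mid <- which.min(abs(prof$position_um - max(prof$position_um) / 2))
  left_peak <- max(v[seq_len(mid)], na.rm = TRUE)
  right_peak <- max(v[seq(mid, length(v))], na.rm = TRUE)
  interior <- v[mid]
  expect_gt(left_peak, interior + 0.03)        # ring peaks flank the center
  expect_gt(right_peak, interior + 0.03)
})

test_that("temporal curves: static scenes are flat, adhesion ramps are recovered", {
  bgm <- resonance_maps(matrix(626, 10, 10), matrix(0.9, 10, 10),
                        matrix(TRUE, 10, 10))
  sh0 <- shift_images(bgm, bgm)
  flat <- temporal_curves(list(sh0, sh0, sh0))
  expect_true(all(flat$mean == 0))
  # linear amplitude growth: fitted slope of mean PWS within 5% of truth
  slope_true <- 0.2
  shifts <- lapply(1:6, function(f) {
    fr <- resonance_maps(matrix(626 + slope_true * f, 10, 10),
                         matrix(0.9 - 0.01 * f, 10, 10),
                         matrix(TRUE, 10, 10), timestamp_s = (f - 1) * 10,
                         frame_index = f)
    shift_images(fr, bgm)
  })
  tc <- temporal_curves(shifts, normalize_pis = TRUE)
  pws <- tc[tc$channel == "pws", ]
  fit <- coef(lm(mean ~ frame_index, pws))[2]
  expect_equal(unname(fit), slope_true, tolerance = 0.05)
  pn <- tc$mean[tc$channel == "pis_norm"]
  expect_equal(range(pn), c(0, 1))
  one <- temporal_curves(shifts[1])
  expect_equal(nrow(one), 2)                   # one row per channel
})
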