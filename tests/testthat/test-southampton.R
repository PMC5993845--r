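test_that("striatal peaks are found at the true compartment centres", {
  vol <- fixture_phantom_84()
  ph <- attr(vol, "phantom")
  pk <- locate_striatal_peaks(vol)
  expect_lte(max(abs(pk$right_centre_mm - ph$centre_right_mm)), 2)  # 1 voxel
  expect_lte(max(abs(pk$left_centre_mm - ph$centre_left_mm)), 2)
  # mirroring the volume left-right swaps the hemisphere peaks
  mir <- vol
  mir$data <- vol$data[rev(seq_len(dim(vol$data)[1])), , ]
  pk_m <- locate_striatal_peaks(mir)
  expect_equal(pk_m$right_centre_mm[1], -pk$left_centre_mm[1], tolerance = 2)
  expect_equal(pk_m$left_centre_mm[1], -pk$right_centre_mm[1], tolerance = 2)
})

test_that("featureless volumes are rejected by peak localization", {
  zero <- spect_volume(array(0, dim = c(20, 20, 20)), rep(3, 3))
  expect_error(locate_striatal_peaks(zero), "no-signal")
  uni <- rasterize_phantom(build_phantom_spec(1, 1, 5), 2.5)
  expect_error(locate_striatal_peaks(uni), "degenerate-peak|no-signal")
})

test_that("striatal VOIs are fixed-size, intensity-independent and monotone in margin", {
  vol <- fixture_phantom_84()
  pk <- locate_striatal_peaks(vol)
  v10 <- define_striatal_voi(vol, pk$right_centre, 10)
  v20 <- define_striatal_voi(vol, pk$right_centre, 20)
  expect_true(all(v20$mask[v10$mask]))          # strict superset
  expect_gt(v20$n_voxels, v10$n_voxels)
  # size depends only on geometry, not on the image content
  other <- rasterize_phantom(build_phantom_spec(3, 3, 5), 2)
  v20b <- define_striatal_voi(other, pk$right_centre, 20)
  expect_identical(v20$mask, v20b$mask)
  # margin 0 around the nominal box is about the bounding-box volume
  v0 <- define_striatal_voi(vol, pk$right_centre, 0)
  bbox_ml <- prod(2 * c(9.1, 21.1, 14.1)) / 1000
  expect_lt(abs(v0$volume_ml - bbox_ml) / bbox_ml, 0.25)
  expect_error(define_striatal_voi(vol, c(0, 5, 5), 10), "outside the grid")
})

test_that("a 20 mm margin captures >= 99% of 10 mm-blurred striatal counts", {
  vol <- fixture_phantom_84()
  ph <- attr(vol, "phantom")
  # ground-truth striatal-only image, blurred like the data
  str_only <- vol
  str_only$data <- array(0, dim = dim(vol$data))
  str_only$data[ph$right_mask] <- 35
  blurred <- gaussian_blur(str_only, 10)
  pk <- locate_striatal_peaks(gaussian_blur(vol, 10))
  voi <- define_striatal_voi(vol, pk$right_centre, 20)
  expect_gte(sum(blurred$data[voi$mask]) / sum(blurred$data), 0.99)
})

test_that("the reference slab has the prescribed slice count and background mean", {
  vol <- fixture_phantom_84()
  pk <- locate_striatal_peaks(vol)
  vois <- list(define_striatal_voi(vol, pk$right_centre, 20),
               define_striatal_voi(vol, pk$left_centre, 20))
  ref <- define_reference_region(vol, pk$peak_axial, vois)
  expect_equal(ref$n_slices, 22)          # 44 mm at 2 mm voxels
  expect_equal(mean(vol$data[ref$mask]), 5, tolerance = 1e-6)
  # striatal VOIs are excluded
  expect_equal(sum(ref$mask & vois[[1]]$mask), 0)
  # uniform in-head activity: reference mean equals the filling exactly
  uni <- rasterize_phantom(build_phantom_spec(1, 1, 5), 2)
  ref_u <- define_reference_region(uni, dim(uni$data)[3] %/% 2, vois)
  expect_equal(mean(uni$data[ref_u$mask]), 5, tolerance = 1e-9)
})

test_that("the oversized-VOI SBR estimator recovers ratio - 1 on digital phantoms", {
  vol <- fixture_phantom_84()
  m <- quantify(vol)
  expect_equal(m$sbr_right, 7, tolerance = 0.15 / 7)
  expect_equal(m$sbr_left, 3, tolerance = 0.07 / 3)
  expect_equal(m$ai, compute_ai(m$sbr_right, m$sbr_left), tolerance = 1e-12)
  # deterministic on the same volume
  m2 <- quantify(vol)
  expect_identical(m[c("sbr_right", "sbr_left", "ai")],
                   m2[c("sbr_right", "sbr_left", "ai")])
})

test_that("a VOI reading at background level yields SBR 0; scaling leaves SBR fixed", {
  vol <- fixture_phantom_84()
  pk <- locate_striatal_peaks(vol)
  vois <- list(define_striatal_voi(vol, pk$right_centre, 20),
               define_striatal_voi(vol, pk$left_centre, 20))
  ref <- define_reference_region(vol, pk$peak_axial, vois)
  # a pure-background box far from the striata
  bg_centre <- pk$right_centre + c(0, -28, 0)
  bg_voi <- define_striatal_voi(vol, bg_centre, 0, nominal_semi_mm = c(6, 6, 6))
  expect_equal(compute_sbr(vol, bg_voi, ref), 0, tolerance = 1e-12)
  # global count rescaling: exactly invariant
  scaled <- vol
  scaled$data <- vol$data * 37.5
  expect_equal(compute_sbr(scaled, vois[[1]], ref),
               compute_sbr(vol, vois[[1]], ref), tolerance = 1e-12)
})

test_that("adding pure-background voxels to the striatal VOI does not change SBR", {
  vol <- fixture_phantom_84()
  pk <- locate_striatal_peaks(vol)
  ref <- define_reference_region(vol, pk$peak_axial,
                                 list(define_striatal_voi(vol, pk$right_centre, 20),
                                      define_striatal_voi(vol, pk$left_centre, 20)))
  small <- define_striatal_voi(vol, pk$right_centre, 6)
  big <- define_striatal_voi(vol, pk$right_centre, 16)
  expect_equal(compute_sbr(vol, big, ref), compute_sbr(vol, small, ref),
               tolerance = 1e-9)
})

test_that("SBR converges as the VOI margin grows on a blurred phantom", {
  img <- gaussian_blur(fixture_phantom_84(), 10)
  pk <- locate_striatal_peaks(img)
  ref_vois <- list(define_striatal_voi(img, pk$right_centre, 20),
                   define_striatal_voi(img, pk$left_centre, 20))
  ref <- define_reference_region(img, pk$peak_axial, ref_vois)
  # margins up to 20 mm: the largest VOI box still inside the background
  # compartment of the default digital head
  sbrs <- vapply(c(5, 10, 15, 20), function(mg)
    compute_sbr(img, define_striatal_voi(img, pk$right_centre, mg), ref), 0)
  # non-decreasing up to the sub-percent boundary graze of the largest box
  expect_true(all(diff(sbrs) > -0.01))
  expect_lt(abs(sbrs[4] - sbrs[3]), 0.01)      # converged
  expect_equal(sbrs[4], 7, tolerance = 0.05)
})

test_that("vectorized voxel sums agree with a brute-force loop oracle", {
  set.seed(42)
  for (rep in 1:3) {
    d <- c(7, 8, 6)
    data <- array(rexp(prod(d), rate = 0.2), dim = d)
    vol <- spect_volume(data, rep(3, 3))
    str_mask <- array(runif(prod(d)) < 0.2, dim = d)
    ref_mask <- array(runif(prod(d)) < 0.3, dim = d) & !str_mask
    str_voi <- structure(list(mask = str_mask, n_voxels = sum(str_mask),
                              volume_ml = sum(str_mask) * 27 / 1000,
                              role = "striatal"), class = "voi_mask")
    ref_voi <- structure(list(mask = ref_mask, n_voxels = sum(ref_mask),
                              volume_ml = sum(ref_mask) * 27 / 1000,
                              role = "reference"), class = "voi_mask")
    vol_str_vox <- 11.2 * 1000 / 27
    expect_equal(compute_sbr(vol, str_voi, ref_voi),
                 sbr_loop_oracle(data, str_mask, ref_mask, vol_str_vox),
                 tolerance = 1e-10)
  }
})

test_that("the asymmetry index follows its definition and symmetries", {
  expect_equal(compute_ai(5, 5), 0)
  expect_equal(compute_ai(3, 1), 100)
  # hand calculation on the published male right/left means
  expect_equal(compute_ai(8.07, 7.97), 1.247, tolerance = 5e-4)
  expect_equal(compute_ai(2, 6), compute_ai(6, 2))
  expect_equal(compute_ai(3 * 1.7, 1 * 1.7), compute_ai(3, 1), tolerance = 1e-12)
  expect_error(compute_ai(1, -1), "domain error")
  set.seed(1)
  r <- runif(20, 0.5, 10); l <- runif(20, 0.5, 10)
  expect_true(all(compute_ai(r, l) >= 0 & compute_ai(r, l) <= 200))
})

test_that("quantifying the 8:1/4:1 phantom yields the derived asymmetry", {
  m <- quantify(fixture_phantom_84())
  expect_equal(m$ai, 80, tolerance = 0.02 * 80)  # |7-3|/10*200
  expect_false(m$negative_flag)
  expect_equal(m$vol_str_used, 11.2)
})

test_that("a uniform phantom quantified with forced VOIs reads SBR 0", {
  vol <- fixture_phantom_84()
  pk <- locate_striatal_peaks(vol)
  voi_r <- define_striatal_voi(vol, pk$right_centre, 20)
  voi_l <- define_striatal_voi(vol, pk$left_centre, 20)
  ref <- define_reference_region(vol, pk$peak_axial, list(voi_r, voi_l))
  uni <- rasterize_phantom(build_phantom_spec(1, 1, 5), 2)
  m <- quantify(uni, vois = list(right = voi_r, left = voi_l, reference = ref))
  expect_equal(m$sbr_right, 0, tolerance = 1e-9)
  expect_equal(m$sbr_left, 0, tolerance = 1e-9)
})
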