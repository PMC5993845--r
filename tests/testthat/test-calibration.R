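test_that("aliquot concentrations give ratio - 1 as the true SBR", {
  expect_equal(true_sbr_from_aliquots(40, 5), 7)
  expect_equal(true_sbr_from_aliquots(5, 5), 0)
  expect_equal(true_sbr_from_aliquots(20, 6.65), 2.008, tolerance = 5e-4)
  expect_error(true_sbr_from_aliquots(10, 0), "domain error")
})

test_that("calibration fits recover exact lines and reject degenerate input", {
  x <- c(0, 2, 3, 5, 7)
  fit <- fit_calibration(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 5)

  two <- fit_calibration(c(1, 3), c(2.2, 6.0))
  expect_equal(two$slope, 1.9, tolerance = 1e-12)
  expect_equal(two$intercept, 0.3, tolerance = 1e-12)

  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "rank-deficiency")
  expect_error(fit_calibration(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("poor-quality curves are rejected by the gates", {
  x <- c(0, 2, 4, 6)
  expect_error(fit_calibration(x, 0.05 * x + 1), "quality")
  set.seed(5)
  expect_error(fit_calibration(x, 0.5 * x + rnorm(4, sd = 3)), "quality")
  # gates can be disabled
  expect_s3_class(fit_calibration(x, 0.05 * x + 1, min_slope = -Inf, min_r = -Inf),
                  "calibration_curve")
})

test_that("applying a curve inverts the measured-on-true map", {
  ident <- fit_calibration(c(0, 1, 5), c(0, 1, 5))
  expect_equal(apply_calibration(3.3, ident), 3.3)
  curve <- fit_calibration(c(0, 2, 7), c(1, 5, 15))  # y = 2x + 1
  expect_equal(apply_calibration(15, curve), 7, tolerance = 1e-12)
  # order preservation
  ms <- sort(runif(10, 0, 20))
  expect_true(all(diff(apply_calibration(ms, curve)) > 0))
})

test_that("fit-then-apply is the identity on noise-free affine-biased data", {
  truths <- c(7, 5, 3, 2, 0)
  for (bias in list(c(1.445, 2.138), c(0.72, -0.3), c(1.0, 0))) {
    measured <- bias[1] * truths + bias[2]
    curve <- fit_calibration(truths, measured)
    expect_lt(max(abs(apply_calibration(measured, curve) - truths)), 1e-9)
  }
})

test_that("cohort calibration fills calibrated columns and keeps originals", {
  rec <- fixture_exact_cohort(n = 40)
  ident <- fit_calibration(c(0, 3, 7), c(0, 3, 7), scanner = "sim",
                           condition = "NOACNOSC")
  cal <- calibrate_cohort(rec, calibration_table(list(ident)))
  expect_equal(cal$sbr_calibrated_right, rec$sbr_right, tolerance = 1e-12)
  expect_equal(cal$sbr_right, rec$sbr_right)

  rec2 <- rec
  rec2$scanner <- "ghost"
  expect_error(calibrate_cohort(rec2, calibration_table(list(ident))),
               "ghost, NOACNOSC")
})

test_that("calibration shrinks between-scanner differences far below the original", {
  truth <- fixture_exact_cohort(n = 120, seed = 21)
  half <- seq_len(60)
  a <- bias_cohort(truth[half, ], gain = 1.445, offset = 2.138,
                   scanner = "A", condition = "ChangACSC")
  b <- bias_cohort(truth[-half, ], gain = 0.72, offset = -0.3,
                   scanner = "B", condition = "NOACNOSC")
  tab <- calibration_table(list(
    fit_calibration(c(7, 5, 3, 2, 0), 1.445 * c(7, 5, 3, 2, 0) + 2.138,
                    "A", "ChangACSC"),
    fit_calibration(c(7, 5, 3, 2, 0), 0.72 * c(7, 5, 3, 2, 0) - 0.3,
                    "B", "NOACNOSC")))
  cal <- calibrate_cohort(rbind(a, b), tab)
  orig_gap <- abs(mean(average_sbr(a)) - mean(average_sbr(b)))
  cal_gap <- abs(mean(average_sbr(cal, calibrated = TRUE)[half]) -
                   mean(average_sbr(cal, calibrated = TRUE)[-half]))
  expect_lt(cal_gap, 0.25 * orig_gap)
})

test_that("a paired two-condition cohort agrees better after calibration", {
  set.seed(31)
  truth <- average_sbr(generate_cohort(60, seed = 77))
  m1 <- 1.445 * truth + 2.138 + rnorm(60, sd = 0.4)
  m2 <- 0.72 * truth - 0.30 + rnorm(60, sd = 0.4)
  c1 <- fit_calibration(c(7, 5, 3, 2, 0), 1.445 * c(7, 5, 3, 2, 0) + 2.138)
  c2 <- fit_calibration(c(7, 5, 3, 2, 0), 0.72 * c(7, 5, 3, 2, 0) - 0.30)
  icc_orig <- icc_between_conditions(m1, m2)$estimate
  icc_cal <- icc_between_conditions(apply_calibration(m1, c1),
                                    apply_calibration(m2, c2))$estimate
  expect_gt(icc_cal, icc_orig)
  expect_gt(icc_cal, 0.8)
})

test_that("scatter-correction nonlinearity survives affine calibration", {
  # NOSC conditions are exactly affine; the SC condition carries a quadratic
  # term, so after calibration the NOSC pair agrees more closely with each
  # other than either does with SC
  truth <- average_sbr(fixture_exact_cohort(n = 80, seed = 41))
  tr <- c(7, 5, 3, 2, 0)
  cond <- list(nosc1 = c(0.72, -0.3, 0), nosc2 = c(1.0, 0.2, 0),
               sc = c(1.445, 2.138, 0.05))
  cal <- lapply(cond, function(b) {
    curve <- fit_calibration(tr, b[1] * tr + b[2] + b[3] * tr^2)
    apply_calibration(b[1] * truth + b[2] + b[3] * truth^2, curve)
  })
  gap <- function(u, v) mean(abs(u - v))
  expect_lt(gap(cal$nosc1, cal$nosc2), gap(cal$nosc1, cal$sc))
  expect_lt(gap(cal$nosc1, cal$nosc2), gap(cal$nosc2, cal$sc))
})

test_that("calibration tables serialize to JSON and back losslessly", {
  tab <- calibration_table(list(
    fit_calibration(c(0, 3, 7), c(0.1, 4.4, 10.2), "A", "NOACNOSC"),
    fit_calibration(c(0, 3, 7), c(2.0, 6.5, 12.3), "A", "ChangACSC")))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_table(tab, path)
  back <- read_calibration_table(path)
  expect_equal(back[["A|NOACNOSC"]]$slope, tab[["A|NOACNOSC"]]$slope,
               tolerance = 1e-12)
  expect_equal(back[["A|ChangACSC"]]$intercept, tab[["A|ChangACSC"]]$intercept,
               tolerance = 1e-12)
  expect_error(calibration_table(list(tab[[1]], tab[[1]])), "duplicate")
})

test_that("curves fitted from an imaged phantom series match the scanner bias", {
  sc <- scanner_model("sx", 2.0, psf_fwhm = 0,
                      condition_bias = list(NOACNOSC = c(gain = 0.8, offset = 0.5)))
  series <- generate_phantom_series(sc, "NOACNOSC",
                                    ratios = list(c(8, 4), c(1, 1)))
  tab <- fit_calibration_from_series(series)
  curve <- tab[["sx|NOACNOSC"]]
  expect_equal(curve$slope, 0.8, tolerance = 1e-6)
  expect_equal(curve$intercept, 0.5, tolerance = 1e-6)
  expect_equal(curve$n_points, 4)
})
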