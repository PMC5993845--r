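test_that("simple regression matches a normal-equations oracle and exact lines", {
  x <- 1:10
  exact <- fit_simple_regression(x, 2 * x)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  expect_equal(exact$residual_sd, 0, tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:4) {
    xr <- rnorm(20); yr <- 1.5 - 0.4 * xr + rnorm(20)
    fit <- fit_simple_regression(xr, yr)
    beta <- ols_oracle(cbind(1, xr), yr)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-8)
    expect_equal(fit$slope, beta[2], tolerance = 1e-8)
  }
  expect_error(fit_simple_regression(rep(1, 5), rnorm(5)), "rank error")
})

test_that("the pooled age slope is recovered from a large synthetic cohort", {
  rec <- generate_cohort(5000, seed = 2024)
  line <- fit_simple_regression(rec$age, average_sbr(rec))
  se <- line$residual_sd / sqrt(line$ssx)
  expect_lt(abs(line$slope - (-0.063)), 3 * se)
  expect_lt(line$slope, 0)
  expect_lt(line$r, -0.4)
})

test_that("the multiple-regression normative model interpolates noise-free data", {
  rec <- fixture_exact_cohort(n = 300, seed = 15)
  model <- fit_normative_model(rec, "average_sbr")
  expect_equal(unname(model$coefficients),
               unname(default_sbr_coefficients()), tolerance = 1e-9)
  expect_equal(model$residual_sd, 0, tolerance = 1e-7)

  ai_model <- fit_normative_model(rec, "ai")
  expect_equal(ai_model$coefficients[["age"]],
               default_ai_coefficients()[["age"]], tolerance = 1e-9)
})

test_that("all four coefficients are recovered within 3 SE at n = 5000", {
  rec <- generate_cohort(5000, seed = 99)
  model <- fit_normative_model(rec, "average_sbr")
  truth <- default_sbr_coefficients()
  for (nm in names(truth))
    expect_lt(abs(model$coefficients[[nm]] - truth[[nm]]), 3 * model$se[[nm]])
  expect_equal(model$residual_sd, 1.38, tolerance = 0.05)
})

test_that("expected values follow the printed-coefficient arithmetic", {
  model <- fit_normative_model(fixture_exact_cohort(n = 300), "average_sbr")
  # 10.610 - 0.063*57 + 0.263*3.5
  expect_equal(predict_expected(model, 57, "M", 3.5), 7.9395, tolerance = 1e-6)
  expect_equal(predict_expected(model, 57, "F", 3.5) -
                 predict_expected(model, 57, "M", 3.5), 0.461, tolerance = 1e-9)
  expect_equal(predict_expected(model, 67, "M", 3.5) -
                 predict_expected(model, 57, "M", 3.5), 10 * (-0.063),
               tolerance = 1e-9)
})

test_that("prediction intervals contain confidence intervals and behave at limits", {
  set.seed(3)
  x <- runif(80, 30, 83)
  y <- 11.6 - 0.06 * x + rnorm(80, sd = 1.4)
  line <- fit_simple_regression(x, y)
  for (x0 in c(35, 55.5, 80)) {
    ci <- confidence_interval(line, x0)
    pi <- prediction_interval(line, x0)
    expect_lte(pi["lo"], ci["lo"])
    expect_gte(pi["hi"], ci["hi"])
    expect_equal(unname(ci["fit"]), unname(pi["fit"]))
  }
  # degenerate noise-free line
  exact <- fit_simple_regression(x, 2 * x)
  pi0 <- prediction_interval(exact, 40)
  expect_equal(unname(pi0["lo"]), 80, tolerance = 1e-9)
  expect_equal(unname(pi0["hi"]), 80, tolerance = 1e-9)
  expect_error(prediction_interval(line, 40, level = 1.2), "domain error")
})

test_that("the large-n prediction half-width approaches 1.96 residual SDs", {
  rec <- generate_cohort(5000, seed = 12)
  model <- fit_normative_model(rec, "average_sbr")
  pi <- prediction_interval(model, list(age = 56.5, sex = "F",
                                        scan_start_time = 3.5))
  half <- (pi["hi"] - pi["lo"]) / 2
  # residual SD 1.38 implies ~2.70, the decade-table mean-minus-lower-limit gap
  expect_equal(unname(half), 2.70, tolerance = 0.08 / 2.70)
})

test_that("prediction intervals have close to nominal coverage", {
  model <- fit_normative_model(generate_cohort(4000, seed = 5), "average_sbr")
  new <- generate_cohort(4000, seed = 6)
  pis <- vapply(seq_len(nrow(new)), function(i)
    prediction_interval(model, new[i, ])[c("lo", "hi")], c(lo = 0, hi = 0))
  y <- average_sbr(new)
  cover <- mean(y >= pis["lo", ] & y <= pis["hi", ])
  expect_gt(cover, 0.935)
  expect_lt(cover, 0.965)
})

test_that("decade summaries are regression means at midpoints, linear for linear truth", {
  rec <- fixture_exact_cohort(n = 600, seed = 19)
  dec <- decade_summary(rec)
  both <- dec[dec$group == "both" & !is.na(dec$sbr_mean), ]
  # linear generative model => decade means linear in the midpoint
  fit <- lm(sbr_mean ~ midpoint, data = both)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_lt(both$sbr_mean[2] - both$sbr_mean[1], 0)
  expect_true(all(both$sbr_lower_pi < both$sbr_mean))

  # single-decade cohort populates exactly one decade per group
  one <- generate_cohort(80, demographics = list(age_range = c(40, 49)),
                         seed = 3)
  dec1 <- decade_summary(one)
  filled <- dec1[dec1$group == "both" & dec1$n_scans > 0, ]
  expect_equal(nrow(filled), 1)
  expect_equal(filled$decade, "40-49")
  expect_equal(sum(dec1$group == "both" & dec1$n_scans == 0), 5)
})

test_that("the synthetic pooled cohort reproduces the generator's decade decline", {
  rec <- generate_cohort(5000, seed = 31)
  dec <- decade_summary(rec)
  got <- pct_decline_per_decade(dec, "both")
  # oracle from the generator configuration: 0.63 per decade over the
  # predicted mean at the 30-39 midpoint
  cf <- default_sbr_coefficients()
  mean345 <- cf[["intercept"]] + cf[["age"]] * 34.5 + cf[["start_time"]] * 3.5 +
    cf[["sex_female"]] * (140 / 256)
  expect_equal(got, -cf[["age"]] * 10 / mean345 * 100, tolerance = 0.08)
})

test_that("the agreement ICC matches its definition, oracle and symmetries", {
  set.seed(23)
  x <- rnorm(100, 8, 1.5)
  expect_equal(icc_between_conditions(x, x)$estimate, 1, tolerance = 1e-9)
  # systematic offset: near-perfect correlation, much lower agreement
  shifted <- icc_between_conditions(x, x + 3)
  expect_lt(shifted$estimate, 0.4)
  expect_gt(cor(x, x + 3), 0.999)
  # consistency form ignores the offset
  expect_gt(icc_between_conditions(x, x + 3, form = "consistency")$estimate,
            0.999)
  # swap invariance of the absolute-agreement form
  y <- x + rnorm(100, 0, 1)
  expect_equal(icc_between_conditions(x, y)$estimate,
               icc_between_conditions(y, x)$estimate, tolerance = 1e-12)
  # aov-based mean-squares oracle
  expect_equal(icc_between_conditions(x, y)$estimate, icc21_aov_oracle(x, y),
               tolerance = 1e-10)
  # independent pairs: near zero
  a <- rnorm(500); b <- rnorm(500)
  near0 <- icc_between_conditions(a, b)
  expect_lt(abs(near0$estimate), 0.1)
  # CI brackets the estimate
  expect_lte(near0$lo, near0$estimate)
  expect_gte(near0$hi, near0$estimate)
  expect_error(icc_between_conditions(rep(1, 5), rep(2, 5)), "undefined-ICC")
})

test_that("ANOVA effect tests are well calibrated under the null and powered", {
  # null: no age/sex/start-time effects at all
  set.seed(17)
  n_rep <- 400
  rej <- matrix(FALSE, n_rep, 4)
  for (i in seq_len(n_rep)) {
    rec <- generate_cohort(150,
                           coefficients = c(intercept = 8, age = 0,
                                            start_time = 0, sex_female = 0),
                           residual_sd = 1.38, seed = 10000 + i)
    rej[i, ] <- anova_effects(rec)$p < 0.05
  }
  rates <- colMeans(rej)
  for (rate in rates) {
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.09)
  }

  # power: a strong built-in sex-by-age interaction is detected
  hits <- vapply(1:40, function(i) {
    rec <- generate_cohort(300, seed = 555 + i)
    sel <- rec$sex == "F"
    rec$sbr_right[sel] <- rec$sbr_right[sel] - 0.04 * (rec$age[sel] - 56.5)
    rec$sbr_left[sel] <- rec$sbr_left[sel] - 0.04 * (rec$age[sel] - 56.5)
    anova_effects(rec)$p[3] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_true(all(anova_effects(generate_cohort(200, seed = 1))$F >= 0))
})

test_that("z-scoring flags observations below the lower prediction limit", {
  model <- fit_normative_model(generate_cohort(2000, seed = 44), "average_sbr")
  rec <- list(age = 64.5, sex = "M", scan_start_time = 3.5)
  expected <- predict_expected(model, 64.5, "M", 3.5)
  z0 <- zscore_subject(model, rec, observed = expected)
  expect_equal(z0$z, 0, tolerance = 1e-12)
  expect_false(z0$below_lower_pi)

  lower <- prediction_interval(model, rec)[["lo"]]
  just_below <- zscore_subject(model, rec, observed = lower - 1e-6)
  expect_true(just_below$below_lower_pi)
  expect_false(zscore_subject(model, rec, observed = lower + 1e-6)$below_lower_pi)

  # a ~35% reduction from the 60-69 expected value sits at the lower limit
  expect_true(zscore_subject(model, rec, observed = 0.63 * expected)$below_lower_pi)

  exact <- fit_normative_model(fixture_exact_cohort(300), "average_sbr")
  expect_error(zscore_subject(exact, rec, observed = 5), "degenerate-model")
})

test_that("normative models serialize to JSON with intact prediction intervals", {
  model <- fit_normative_model(generate_cohort(500, seed = 61), "average_sbr")
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_model(model, path)
  back <- read_normative_model(path)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  x0 <- list(age = 47, sex = "F", scan_start_time = 3.1)
  expect_equal(prediction_interval(back, x0), prediction_interval(model, x0),
               tolerance = 1e-10)
})

test_that("the right striatum reads higher than the left under the default generator", {
  rec <- generate_cohort(2000, seed = 13)
  res <- paired_lr_test(rec)
  expect_gt(res$mean_diff, 0)
  expect_lt(res$p, 0.001)
})
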