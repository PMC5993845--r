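## summary.lm warns on zero-residual fits; noise-free synthetic cohorts are a
## designed-for input here, so that specific warning is muffled
quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Simple linear regression with confidence and prediction intervals
#'
#' Least-squares fit of `y` on a single covariate `x`, keeping the design
#' summaries (n, mean of x, centred sum of squares, residual SD) needed to
#' evaluate t-based confidence intervals for the mean response and prediction
#' intervals for a new observation at any x.
#'
#' @param x,y numeric vectors of equal length (n >= 3, x not constant).
#' @return an object of class `regression_line`: `slope`, `intercept`, `r`,
#'   `n`, `residual_sd`, `mean_x`, `ssx`, `p_slope`.
#' @export
fit_simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("rank error: x is constant")
  fit <- stats::lm(y ~ x)
  sm <- quiet_summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = if (stats::var(y) == 0) 0 else stats::cor(x, y),
    n = n,
    residual_sd = sm$sigma,
    mean_x = mean(x),
    ssx = sum((x - mean(x))^2),
    p_slope = sm$coefficients[2, 4]
  ), class = "regression_line")
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("<regression_line> Y = %.4gX + %.4g (r = %.3f, n = %d, residual SD %.3g)\n",
              x$slope, x$intercept, x$r, x$n, x$residual_sd))
  invisible(x)
}

line_se <- function(line, x0, new_observation) {
  extra <- if (new_observation) 1 else 0
  line$residual_sd *
    sqrt(extra + 1 / line$n + (x0 - line$mean_x)^2 / line$ssx)
}

#' Confidence and prediction intervals of a fitted line or normative model
#'
#' `confidence_interval()` bounds the mean response at `x0`;
#' `prediction_interval()` bounds a single new observation (always the wider
#' of the two at the same level). Both use the exact t-based formulas; with
#' zero residual SD they degenerate to the fitted value.
#'
#' @param object a `regression_line` or `normative_model`.
#' @param x0 covariate value: a number for a line; for a normative model a
#'   list/data.frame row with `age`, `sex` ("M"/"F" or 0/1 female indicator)
#'   and `scan_start_time`.
#' @param level coverage level in (0, 1).
#' @return named numeric `c(fit =, lo =, hi =)`.
#' @export
prediction_interval <- function(object, x0, level = 0.95)
  UseMethod("prediction_interval")

#' @rdname prediction_interval
#' @export
confidence_interval <- function(object, x0, level = 0.95)
  UseMethod("confidence_interval")

check_level <- function(level) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("domain error: level must lie strictly between 0 and 1")
}

line_interval <- function(line, x0, level, new_observation) {
  check_level(level)
  fit <- line$intercept + line$slope * x0
  tq <- stats::qt(1 - (1 - level) / 2, df = line$n - 2)
  se <- line_se(line, x0, new_observation)
  c(fit = fit, lo = fit - tq * se, hi = fit + tq * se)
}

#' @rdname prediction_interval
#' @export
prediction_interval.regression_line <- function(object, x0, level = 0.95)
  line_interval(object, x0, level, new_observation = TRUE)

#' @rdname prediction_interval
#' @export
confidence_interval.regression_line <- function(object, x0, level = 0.95)
  line_interval(object, x0, level, new_observation = FALSE)

sex_indicator <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    s <- toupper(as.character(sex))
    if (!all(s %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
    as.numeric(s == "F")
  } else as.numeric(sex)
}

outcome_vector <- function(records, outcome, use = "auto") {
  calibrated <- switch(use,
    auto = !all(is.na(records$sbr_calibrated_right)),
    calibrated = TRUE,
    original = FALSE,
    stop("use must be 'auto', 'calibrated' or 'original'"))
  r <- if (calibrated) records$sbr_calibrated_right else records$sbr_right
  l <- if (calibrated) records$sbr_calibrated_left else records$sbr_left
  switch(outcome,
         average_sbr = (r + l) / 2,
         ai = compute_ai_vec(r, l),
         stop("outcome must be 'average_sbr' or 'ai'"))
}

compute_ai_vec <- function(r, l) abs(r - l) / (r + l) * 200

#' Fit the multiple-regression normative model
#'
#' Ordinary least squares of the outcome (average of left and right SBR, or
#' the asymmetry index) on age (years), scan start time (hours) and a female
#' indicator (female = 1, male = 0). Keeps the unscaled coefficient
#' covariance so prediction intervals for new subjects are exact.
#'
#' @param records cohort data.frame (see [generate_cohort()] for columns).
#' @param outcome "average_sbr" or "ai".
#' @param use which SBR columns to model: "auto" (calibrated when present),
#'   "calibrated" or "original".
#' @return an object of class `normative_model`: `outcome`, `coefficients`
#'   (intercept, age, start_time, sex_female), their `se`, `t`, `p`,
#'   `residual_sd`, `n`, `df`, `xtx_inv`.
#' @export
fit_normative_model <- function(records, outcome = "average_sbr", use = "auto") {
  y <- outcome_vector(records, outcome, use)
  female <- sex_indicator(records$sex)
  if (length(unique(female)) < 2)
    stop("need subjects of both sexes to estimate the sex term")
  if (stats::var(records$age) == 0) stop("rank error: age is constant")
  df_fit <- data.frame(y = y, age = records$age,
                       start_time = records$scan_start_time,
                       sex_female = female)
  fit <- stats::lm(y ~ age + start_time + sex_female, data = df_fit)
  if (fit$rank < 4) stop("rank error: collinear design")
  sm <- quiet_summary(fit)
  co <- sm$coefficients
  nm <- c("intercept", "age", "start_time", "sex_female")
  structure(list(
    outcome = outcome,
    coefficients = stats::setNames(co[, 1], nm),
    se = stats::setNames(co[, 2], nm),
    t = stats::setNames(co[, 3], nm),
    p = stats::setNames(co[, 4], nm),
    residual_sd = sm$sigma,
    n = nrow(records),
    df = fit$df.residual,
    xtx_inv = sm$cov.unscaled
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> outcome:", x$outcome, " n =", x$n, "\n")
  for (nm in names(x$coefficients))
    cat(sprintf("  %-11s %9.4f  (t = %.3f, p %s)\n", nm, x$coefficients[nm],
                x$t[nm], format_pvalue(x$p[nm])))
  cat(sprintf("  residual SD %.4f\n", x$residual_sd))
  invisible(x)
}

#' Format a p-value, flooring at machine-representable precision
#' @param p numeric p-value.
#' @return character; values below 1e-15 are reported as "< 1e-15".
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-15, "< 1e-15", paste0("= ", signif(p, 3)))
}

model_design_row <- function(x0) {
  age <- x0$age
  st <- if (!is.null(x0$scan_start_time)) x0$scan_start_time else x0$start_time
  if (is.null(st)) stop("x0 needs a scan_start_time")
  c(1, age, st, sex_indicator(x0$sex))
}

#' Expected outcome for given covariates under a normative model
#'
#' Evaluates the linear predictor: intercept + age x age-slope + start-time x
#' slope + female offset.
#'
#' @param model a `normative_model`.
#' @param age age, years.
#' @param sex "M"/"F" (or female indicator 0/1).
#' @param start_time scan start time, hours post-injection.
#' @return expected outcome (unitless).
#' @export
predict_expected <- function(model, age, sex, start_time) {
  stopifnot(inherits(model, "normative_model"))
  drop(model_design_row(list(age = age, sex = sex, start_time = start_time)) %*%
         model$coefficients)
}

model_interval <- function(model, x0, level, new_observation) {
  check_level(level)
  xr <- model_design_row(as.list(x0))
  fit <- drop(xr %*% model$coefficients)
  se <- model$residual_sd *
    sqrt((if (new_observation) 1 else 0) + drop(t(xr) %*% model$xtx_inv %*% xr))
  tq <- stats::qt(1 - (1 - level) / 2, df = model$df)
  c(fit = fit, lo = fit - tq * se, hi = fit + tq * se)
}

#' @rdname prediction_interval
#' @export
prediction_interval.normative_model <- function(object, x0, level = 0.95)
  model_interval(object, x0, level, new_observation = TRUE)

#' @rdname prediction_interval
#' @export
confidence_interval.normative_model <- function(object, x0, level = 0.95)
  model_interval(object, x0, level, new_observation = FALSE)

#' Standardize a new subject against a normative model
#'
#' Returns the standardized residual `(observed - expected) / residual_sd`
#' and flags the record when the observed value falls below the lower limit
#' of the two-sided prediction interval at `level` - the operating point used
#' to call a scan abnormal against the reference database.
#'
#' @param model a `normative_model` (outcome "average_sbr").
#' @param record one-row data.frame / list with `age`, `sex`,
#'   `scan_start_time` and the observed SBRs (calibrated columns preferred).
#' @param observed optionally, the observed outcome value directly.
#' @param level prediction-interval level.
#' @return list `z`, `observed`, `expected`, `lower_pi`, `below_lower_pi`.
#' @export
zscore_subject <- function(model, record, observed = NULL, level = 0.95) {
  stopifnot(inherits(model, "normative_model"))
  if (model$residual_sd <= 1e-10)
    stop("degenerate-model error: residual SD is zero")
  record <- as.list(record)
  if (is.null(observed)) {
    pair <- if (!is.null(record$sbr_calibrated_right) &&
                !is.na(record$sbr_calibrated_right))
      c(record$sbr_calibrated_right, record$sbr_calibrated_left)
    else c(record$sbr_right, record$sbr_left)
    observed <- switch(model$outcome,
                       average_sbr = mean(pair),
                       ai = compute_ai(pair[1], pair[2]))
  }
  expected <- drop(model_design_row(record) %*% model$coefficients)
  pi <- model_interval(model, record, level, new_observation = TRUE)
  list(z = (observed - expected) / model$residual_sd,
       observed = observed, expected = expected,
       lower_pi = unname(pi["lo"]),
       below_lower_pi = observed < pi["lo"])
}

#' Decade-by-sex normative summary
#'
#' Summarises a cohort in decade bins 30-39 ... 80-89 for each sex group and
#' both sexes pooled. The default reporting mode evaluates each group's
#' age regression at the decade midpoint (34.5, 44.5, ...), with the lower
#' prediction limit for the SBR and the upper prediction limit for the
#' asymmetry index; `mode = "raw"` reports raw within-bin means instead
#' (prediction limits still come from the group regression).
#'
#' @param records cohort data.frame.
#' @param mode "predicted" (regression at decade midpoints) or "raw".
#' @param level prediction-interval level.
#' @param use SBR column choice, see [fit_normative_model()].
#' @return data.frame with columns `group` ("both"/"M"/"F"), `decade`,
#'   `midpoint`, `n_subjects`, `n_scans`, `sbr_mean`, `sbr_lower_pi`,
#'   `ai_mean`, `ai_upper_pi`.
#' @export
decade_summary <- function(records, mode = c("predicted", "raw"),
                           level = 0.95, use = "auto") {
  mode <- match.arg(mode)
  breaks <- seq(30, 90, by = 10)
  decades <- paste(breaks[-7], breaks[-7] + 9, sep = "-")
  midpoints <- breaks[-7] + 4.5
  sbr <- outcome_vector(records, "average_sbr", use)
  ai <- outcome_vector(records, "ai", use)
  groups <- list(both = rep(TRUE, nrow(records)),
                 M = records$sex == "M",
                 F = records$sex == "F")
  out <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    line_sbr <- fit_simple_regression(records$age[sel], sbr[sel])
    line_ai <- fit_simple_regression(records$age[sel], ai[sel])
    bin <- findInterval(records$age[sel], breaks, rightmost.closed = TRUE)
    for (i in seq_along(decades)) {
      in_bin <- bin == i
      n_scans <- sum(in_bin)
      n_subjects <- length(unique(records$subject_id[sel][in_bin]))
      if (n_scans == 0) {
        out[[length(out) + 1]] <- data.frame(
          group = g, decade = decades[i], midpoint = midpoints[i],
          n_subjects = 0L, n_scans = 0L, sbr_mean = NA_real_,
          sbr_lower_pi = NA_real_, ai_mean = NA_real_, ai_upper_pi = NA_real_)
        next
      }
      pi_sbr <- prediction_interval(line_sbr, midpoints[i], level)
      pi_ai <- prediction_interval(line_ai, midpoints[i], level)
      sbr_mean <- if (mode == "predicted") unname(pi_sbr["fit"]) else
        mean(sbr[sel][in_bin])
      ai_mean <- if (mode == "predicted") unname(pi_ai["fit"]) else
        mean(ai[sel][in_bin])
      out[[length(out) + 1]] <- data.frame(
        group = g, decade = decades[i], midpoint = midpoints[i],
        n_subjects = n_subjects, n_scans = n_scans,
        sbr_mean = sbr_mean, sbr_lower_pi = unname(pi_sbr["lo"]),
        ai_mean = ai_mean, ai_upper_pi = unname(pi_ai["hi"]))
    }
  }
  do.call(rbind, out)
}

#' Intraclass correlation between two measurement conditions
#'
#' Agreement between paired measurements of the same subjects under two
#' conditions. The default form is the two-way random-effects,
#' absolute-agreement, single-measure ICC - it penalises systematic offsets
#' and scale differences, which is what harmonization is meant to remove; the
#' consistency form (two-way mixed) is available via `form = "consistency"`.
#' The 95% CI uses the standard F-distribution method.
#'
#' @param x,y paired measurements (n >= 3).
#' @param form "agreement" (default) or "consistency".
#' @param level CI level.
#' @return an object of class `icc_result`: `estimate`, `lo`, `hi`, `n`,
#'   `form`.
#' @export
icc_between_conditions <- function(x, y, form = c("agreement", "consistency"),
                                   level = 0.95) {
  form <- match.arg(form)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("undefined-ICC error: zero variance in both members")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - level
  if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    ## F-based CI for the absolute-agreement single-measure form
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_lo <- stats::qf(1 - alpha / 2, n - 1, v)
    f_hi <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_lo * mse) /
      (f_lo * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_hi * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_hi * msr)
  }
  structure(list(estimate = est, lo = min(lo, est), hi = max(hi, est),
                 n = n, form = form, level = level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> rho = %.3f  %d%% CI [%.3f, %.3f]  (n = %d, %s)\n",
              x$estimate, round(100 * x$level), x$lo, x$hi, x$n, x$form))
  invisible(x)
}

#' Type III ANOVA effect tests for the normative design
#'
#' F-tests of sex, age, the sex-by-age interaction and scan start time on the
#' chosen outcome, from the linear model with age and start time continuous
#' and sex as a sum-coded factor (Type III sums of squares).
#'
#' @param records cohort data.frame.
#' @param outcome "average_sbr" or "ai".
#' @param use SBR column choice, see [fit_normative_model()].
#' @return data.frame with columns `effect`, `df`, `F`, `p`.
#' @export
anova_effects <- function(records, outcome = "average_sbr", use = "auto") {
  y <- outcome_vector(records, outcome, use)
  dat <- data.frame(y = y, age = records$age,
                    start_time = records$scan_start_time,
                    sex = factor(sex_indicator(records$sex), levels = c(0, 1),
                                 labels = c("M", "F")))
  if (length(unique(dat$sex)) < 2 || stats::var(dat$age) == 0)
    stop("rank error: design not estimable")
  fit <- stats::lm(y ~ sex * age + start_time, data = dat,
                   contrasts = list(sex = "contr.sum"))
  tab <- car::Anova(fit, type = 3)
  keep <- c("sex", "age", "sex:age", "start_time")
  idx <- match(keep, rownames(tab))
  data.frame(effect = c("sex", "age", "sex_x_age", "start_time"),
             df = tab$Df[idx],
             F = tab$`F value`[idx],
             p = tab$`Pr(>F)`[idx])
}

#' Paired right-vs-left SBR test
#'
#' Paired t-test of signed per-record right minus left SBR, quantifying
#' hemispheric dominance.
#'
#' @param records cohort data.frame.
#' @param use SBR column choice.
#' @return list `mean_right`, `mean_left`, `mean_diff`, `t`, `p`, `n`.
#' @export
paired_lr_test <- function(records, use = "auto") {
  calibrated <- switch(use, auto = !all(is.na(records$sbr_calibrated_right)),
                       calibrated = TRUE, original = FALSE)
  r <- if (calibrated) records$sbr_calibrated_right else records$sbr_right
  l <- if (calibrated) records$sbr_calibrated_left else records$sbr_left
  tt <- stats::t.test(r, l, paired = TRUE)
  list(mean_right = mean(r), mean_left = mean(l), mean_diff = mean(r - l),
       t = unname(tt$statistic), p = tt$p.value, n = length(r))
}

#' Serialize / read a normative model as JSON
#'
#' Stores coefficients, their standard errors, residual SD, sample size,
#' degrees of freedom and the unscaled coefficient covariance, so prediction
#' intervals can be reconstructed exactly.
#'
#' @param model a `normative_model`.
#' @param path JSON path.
#' @return `path` invisibly / a `normative_model`.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  obj <- list(outcome = model$outcome,
              coefficients = as.list(model$coefficients),
              se = as.list(model$se),
              residual_sd = model$residual_sd,
              n = model$n, df = model$df,
              xtx_inv = unname(lapply(seq_len(nrow(model$xtx_inv)), function(i)
                as.numeric(model$xtx_inv[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("intercept", "age", "start_time", "sex_female")
  xtx <- matrix(unlist(obj$xtx_inv), 4, 4, byrow = TRUE)
  dimnames(xtx) <- list(nm, nm)
  structure(list(outcome = obj$outcome,
                 coefficients = stats::setNames(unlist(obj$coefficients), nm),
                 se = stats::setNames(unlist(obj$se), nm),
                 t = stats::setNames(unlist(obj$coefficients) /
                                       unlist(obj$se), nm),
                 p = stats::setNames(rep(NA_real_, 4), nm),
                 residual_sd = obj$residual_sd,
                 n = obj$n, df = obj$df, xtx_inv = xtx),
            class = "normative_model")
}
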