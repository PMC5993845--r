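#' Default normative model coefficients
#'
#' Published multicenter normative coefficients for the average striatal SBR
#' (intercept, per-year age slope, per-hour scan-start-time slope, female
#' offset) and for the interhemispheric asymmetry index of the SBR. These are
#' the generator defaults, so the synthetic cohort emulates the published
#' healthy-control database.
#'
#' @return named numeric vector `(intercept, age, start_time, sex_female)`.
#' @export
default_sbr_coefficients <- function() {
  c(intercept = 10.610, age = -0.063, start_time = 0.263, sex_female = 0.461)
}

#' @rdname default_sbr_coefficients
#' @export
default_ai_coefficients <- function() {
  c(intercept = 2.885, age = 0.031, start_time = 0, sex_female = -0.546)
}

#' Default demographics configuration for the synthetic cohort
#'
#' Age uniform over 30-83 years, 54.7% female (140/256), scan start time
#' normal with mean 3.5 h and SD 0.5 h (spanning the two serial-scan start
#' times of 3.1 and 3.8 h), truncated to be positive.
#'
#' @return a named list of demographic parameters.
#' @export
default_demographics <- function() {
  list(age_range = c(30, 83), prop_female = 140 / 256,
       start_time_mean = 3.5, start_time_sd = 0.5)
}

linear_predictor <- function(coef, age, female, start_time) {
  coef <- as.numeric(coef[c("intercept", "age", "start_time", "sex_female")])
  coef[1] + coef[2] * age + coef[3] * start_time + coef[4] * female
}

#' Generate a synthetic healthy-control cohort
#'
#' Draws demographics, sets each record's average striatal SBR on the
#' normative plane (linear in age, scan start time and a female indicator)
#' plus Gaussian residual noise, then splits the average into right and left
#' SBRs by drawing a signed interhemispheric asymmetry whose mean follows the
#' asymmetry-index model (positive mean = right dominance) and folding it to
#' the absolute value used by the asymmetry index. With `residual_sd = 0` and
#' `ai_residual_sd = 0` every record lies exactly on both planes.
#'
#' @param n number of scan records (>= 1).
#' @param coefficients named vector `(intercept, age, start_time, sex_female)`
#'   for the average SBR; defaults to [default_sbr_coefficients()].
#' @param residual_sd SD of the additive SBR noise; default 1.38, chosen so
#'   the large-n 95% prediction half-width is about 2.70 SBR units.
#' @param ai_coefficients same structure for the asymmetry index (percent
#'   scale, 0-200); defaults to [default_ai_coefficients()].
#' @param ai_residual_sd SD of the signed asymmetry draw; default 3.5.
#' @param demographics list as returned by [default_demographics()].
#' @param seed integer seed; the draw is reproducible given `(n, seed)`.
#' @param scanner,condition identifiers stamped on every record.
#' @return a data.frame of subject records: `subject_id`, `age`, `sex`
#'   ("M"/"F"), `scan_start_time`, `scanner`, `condition`, `sbr_right`,
#'   `sbr_left`, `sbr_calibrated_right`, `sbr_calibrated_left` (NA until
#'   calibration).
#' @export
generate_cohort <- function(n,
                            coefficients = default_sbr_coefficients(),
                            residual_sd = 1.38,
                            ai_coefficients = default_ai_coefficients(),
                            ai_residual_sd = 3.5,
                            demographics = default_demographics(),
                            seed = 1L,
                            scanner = "sim", condition = "NOACNOSC") {
  if (n < 1) stop("n must be >= 1")
  if (residual_sd < 0 || ai_residual_sd < 0) stop("residual SDs must be >= 0")
  dem <- utils::modifyList(default_demographics(), demographics)
  if (dem$age_range[1] < 30 - 1e-9 || dem$age_range[2] > 83 + 1e-9)
    stop("domain error: demographic age range must lie within [30, 83]")
  set.seed(as.integer(seed))
  age <- stats::runif(n, dem$age_range[1], dem$age_range[2])
  female <- as.numeric(stats::runif(n) < dem$prop_female)
  start_time <- stats::rnorm(n, dem$start_time_mean, dem$start_time_sd)
  start_time <- pmax(start_time, 0.5)   # scan start is strictly post-injection
  avg <- linear_predictor(coefficients, age, female, start_time) +
    stats::rnorm(n, 0, residual_sd)
  ## signed asymmetry (percent, right-dominant on average), folded to |.|
  ai_mean <- linear_predictor(ai_coefficients, age, female, start_time)
  ai_signed <- stats::rnorm(n, ai_mean, ai_residual_sd)
  sbr_right <- avg * (1 + ai_signed / 200)
  sbr_left <- avg * (1 - ai_signed / 200)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age,
    sex = ifelse(female == 1, "F", "M"),
    scan_start_time = start_time,
    scanner = scanner,
    condition = condition,
    sbr_right = sbr_right,
    sbr_left = sbr_left,
    sbr_calibrated_right = NA_real_,
    sbr_calibrated_left = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Average SBR of a cohort record set
#' @param records cohort data.frame.
#' @param calibrated use the calibrated columns instead of the originals.
#' @return numeric vector of per-record (right + left) / 2.
#' @export
average_sbr <- function(records, calibrated = FALSE) {
  if (calibrated) (records$sbr_calibrated_right + records$sbr_calibrated_left) / 2
  else (records$sbr_right + records$sbr_left) / 2
}

#' Apply a scanner/condition measurement bias to true cohort SBRs
#'
#' Turns ground-truth (calibrated-scale) SBRs into scanner-measured ones by
#' the same affine-on-SBR bias model the phantom simulator uses:
#' `measured = gain x true + offset + nonlin x true^2 + noise`. Used to build
#' paired multi-condition cohorts with known harmonization ground truth.
#'
#' @param records cohort data.frame (as from [generate_cohort()]); `sbr_right`
#'   and `sbr_left` are interpreted as true SBRs.
#' @param gain,offset,nonlin bias parameters of the measuring condition.
#' @param noise_sd SD of additive measurement noise per hemisphere.
#' @param scanner,condition identifiers stamped on the output records.
#' @param seed integer seed for the noise stream.
#' @return records with `sbr_right`/`sbr_left` replaced by measured values.
#' @export
bias_cohort <- function(records, gain, offset, nonlin = 0, noise_sd = 0,
                        scanner = records$scanner[1],
                        condition = records$condition[1], seed = 1L) {
  if (gain <= 0) stop("gain must be positive")
  set.seed(as.integer(seed))
  out <- records
  for (col in c("sbr_right", "sbr_left")) {
    t <- records[[col]]
    out[[col]] <- gain * t + offset + nonlin * t^2 +
      stats::rnorm(length(t), 0, noise_sd)
  }
  out$scanner <- scanner
  out$condition <- condition
  out$sbr_calibrated_right <- NA_real_
  out$sbr_calibrated_left <- NA_real_
  out
}

#' Write / read a cohort table as CSV
#'
#' UTF-8, comma separated, header row, "." decimal, sex encoded "M"/"F".
#'
#' @param records cohort data.frame.
#' @param path CSV path.
#' @return `path` invisibly / the cohort data.frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "sex", "scan_start_time", "scanner",
                "condition", "sbr_right", "sbr_left")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort file lacks required columns: ", paste(missing, collapse = ", "))
  known <- c(required, "sbr_calibrated_right", "sbr_calibrated_left")
  extra <- setdiff(names(df), known)
  if (length(extra))
    stop("cohort file has unknown columns: ", paste(extra, collapse = ", "))
  for (col in c("sbr_calibrated_right", "sbr_calibrated_left"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df
}
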