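#' True SBR from aliquot concentrations
#'
#' With a uniform nonspecific background, the ground-truth SBR implied by
#' well-counter aliquot measurements is the striatal-to-background
#' concentration ratio minus one.
#'
#' @param striatal_conc striatal aliquot concentration, kBq/mL.
#' @param background_conc background aliquot concentration, kBq/mL (> 0).
#' @return unitless true SBR.
#' @export
true_sbr_from_aliquots <- function(striatal_conc, background_conc) {
  if (any(background_conc <= 0))
    stop("domain error: background concentration must be positive")
  striatal_conc / background_conc - 1
}

#' Fit a per-(scanner, condition) linear calibration curve
#'
#' Ordinary least squares of measured SBR (Y) on true SBR (X), matching the
#' orientation of the phantom calibration plots; harmonization then applies
#' the inverse map. Curves with slope <= `min_slope` or correlation below
#' `min_r` are rejected: phantom series are near-perfectly linear, so a poor
#' fit signals an acquisition problem rather than a usable calibration.
#'
#' @param true_sbrs,measured_sbrs equal-length numeric vectors (>= 2 distinct
#'   true values).
#' @param scanner,condition identifiers keying the curve.
#' @param min_slope,min_r quality gates (defaults 0.1 and 0.9; set to -Inf to
#'   disable).
#' @return an object of class `calibration_curve`: `scanner`, `condition`,
#'   `slope`, `intercept`, `r`, `n_points`.
#' @export
fit_calibration <- function(true_sbrs, measured_sbrs, scanner = "scanner",
                            condition = "condition",
                            min_slope = 0.1, min_r = 0.9) {
  if (length(true_sbrs) != length(measured_sbrs))
    stop("true and measured SBR vectors must have equal length")
  if (length(unique(true_sbrs)) < 2)
    stop("rank-deficiency error: need >= 2 distinct true SBR values")
  fit <- stats::lm(measured_sbrs ~ true_sbrs)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- if (stats::var(measured_sbrs) == 0) 0 else
    stats::cor(true_sbrs, measured_sbrs)
  if (slope <= min_slope || r < min_r)
    stop(sprintf(
      "calibration quality error for (%s, %s): slope %.3f, r %.3f (need slope > %.2f, r >= %.2f)",
      scanner, condition, slope, r, min_slope, min_r))
  structure(list(scanner = scanner, condition = condition,
                 slope = slope, intercept = intercept, r = r,
                 n_points = length(true_sbrs)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> (%s, %s): measured = %.4f x true + %.4f (r = %.4f, n = %d)\n",
              x$scanner, x$condition, x$slope, x$intercept, x$r, x$n_points))
  invisible(x)
}

#' Harmonize a measured SBR through a calibration curve
#'
#' Inverts the fitted measured-on-true map: `calibrated = (measured -
#' intercept) / slope`. Order preserving for positive slope. The alternative
#' orientation (regress true on measured, apply directly) is available via
#' [fit_calibration()] on swapped arguments; the default matches the
#' measured-vs-true plotting convention.
#'
#' @param measured_sbr numeric measured SBR(s).
#' @param curve a `calibration_curve`.
#' @return calibrated SBR(s).
#' @export
apply_calibration <- function(measured_sbr, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("unusable-curve error: slope must be positive")
  (measured_sbr - curve$intercept) / curve$slope
}

curve_key <- function(scanner, condition) paste(scanner, condition, sep = "|")

#' Collect calibration curves into a table keyed by (scanner, condition)
#'
#' @param curves list of `calibration_curve`s with unique (scanner,
#'   condition) pairs.
#' @return an object of class `calibration_table`.
#' @export
calibration_table <- function(curves) {
  keys <- vapply(curves, function(cu) curve_key(cu$scanner, cu$condition), "")
  if (anyDuplicated(keys))
    stop("duplicate (scanner, condition) keys: ",
         paste(keys[duplicated(keys)], collapse = ", "))
  structure(stats::setNames(curves, keys), class = "calibration_table")
}

#' Fit calibration curves from a quantified phantom series
#'
#' VOIs are localised on the highest-contrast filling of each (scanner,
#' condition) group and reused for the whole group - the phantom does not
#' move between fillings, and the uniform (true SBR 0) configuration has no
#' localisable striatal peak of its own.
#'
#' @param series list as from [generate_phantom_series()] (possibly pooled
#'   over scanners and conditions); both hemispheres of every phantom
#'   contribute a (true, measured) point to the curve of their (scanner,
#'   condition).
#' @param config quantifier configuration passed to [quantify()].
#' @param ... quality gates passed to [fit_calibration()].
#' @return a `calibration_table`.
#' @export
fit_calibration_from_series <- function(series, config = quantify_config(), ...) {
  keys <- vapply(series, function(s) curve_key(s$scanner, s$condition), "")
  pts <- do.call(rbind, lapply(unique(keys), function(key) {
    grp <- series[keys == key]
    hot <- grp[[which.max(vapply(grp, function(s)
      s$true_sbr_right + s$true_sbr_left, 0))]]
    cfg <- utils::modifyList(quantify_config(), config)
    pk <- locate_striatal_peaks(hot$volume, cfg$smoothing_fwhm)
    voi_r <- define_striatal_voi(hot$volume, pk$right_centre, cfg$margin_mm,
                                 cfg$nominal_semi_mm, role = "striatal_right")
    voi_l <- define_striatal_voi(hot$volume, pk$left_centre, cfg$margin_mm,
                                 cfg$nominal_semi_mm, role = "striatal_left")
    ref <- define_reference_region(hot$volume, pk$peak_axial,
                                   list(voi_r, voi_l), cfg$slab_mm,
                                   cfg$brain_threshold_frac, cfg$erode_mm,
                                   cfg$ref_smooth_fwhm)
    do.call(rbind, lapply(grp, function(s) {
      m <- quantify(s$volume, cfg,
                    vois = list(right = voi_r, left = voi_l, reference = ref))
      data.frame(scanner = s$scanner, condition = s$condition,
                 true = c(s$true_sbr_right, s$true_sbr_left),
                 measured = c(m$sbr_right, m$sbr_left))
    }))
  }))
  curves <- lapply(split(pts, curve_key(pts$scanner, pts$condition)),
                   function(g) fit_calibration(g$true, g$measured,
                                               g$scanner[1], g$condition[1], ...))
  calibration_table(unname(curves))
}

#' Calibrate a cohort's measured SBRs
#'
#' Looks up each record's (scanner, condition) curve and fills the
#' `sbr_calibrated_right`/`sbr_calibrated_left` columns; the original
#' measured values are preserved. Both hemispheres use the same curve, since
#' each phantom scan calibrates the whole system.
#'
#' @param records cohort data.frame.
#' @param table a `calibration_table`.
#' @return the cohort with calibrated columns filled.
#' @export
calibrate_cohort <- function(records, table) {
  stopifnot(inherits(table, "calibration_table"))
  keys <- curve_key(records$scanner, records$condition)
  missing <- setdiff(unique(keys), names(table))
  if (length(missing))
    stop("no calibration curve for (scanner, condition) pair(s): ",
         paste(gsub("\\|", ", ", missing), collapse = "; "))
  out <- records
  for (i in seq_len(nrow(records))) {
    cu <- table[[keys[i]]]
    out$sbr_calibrated_right[i] <- apply_calibration(records$sbr_right[i], cu)
    out$sbr_calibrated_left[i] <- apply_calibration(records$sbr_left[i], cu)
  }
  out
}

#' Serialize / read a calibration table as JSON
#'
#' One object per curve with keys `scanner`, `condition`, `slope`,
#' `intercept`, `r`, `n_points` - the package's analogue of a published
#' per-scanner calibration equation list.
#'
#' @param table a `calibration_table`.
#' @param path JSON path.
#' @return `path` invisibly / a `calibration_table`.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  rows <- lapply(unname(table), function(cu)
    cu[c("scanner", "condition", "slope", "intercept", "r", "n_points")])
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) stop("no such calibration file: ", path)
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  calibration_table(lapply(rows, function(r) {
    need <- c("scanner", "condition", "slope", "intercept", "r", "n_points")
    if (!all(need %in% names(r)))
      stop("calibration entry lacks keys: ",
           paste(setdiff(need, names(r)), collapse = ", "))
    structure(r[need], class = "calibration_curve")
  }))
}
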