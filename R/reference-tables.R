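#' Published normative reference summaries
#'
#' Summary tables transcribed from the published multicenter healthy-control
#' FP-CIT SPECT normative database that this package's models and synthetic
#' cohort emulate. `ref_decade_summary()` holds the calibrated decade-by-sex
#' summaries (scan counts, decade SBR means, 95% lower prediction limits,
#' asymmetry-index means and 95% upper prediction limits);
#' `ref_condition_summary()` holds the per-reconstruction-condition grand
#' means, regressions against the uncorrected condition, and intraclass
#' correlation coefficients, before and after phantom calibration. They serve
#' as fixed inputs for internal-consistency checks and as targets the
#' synthetic generator is parameterised from.
#'
#' @return a data.frame (see the column dictionaries in the CSVs under
#'   `inst/extdata/`).
#' @export
ref_decade_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_decade_summary.csv",
                              package = "sbrnorm"), stringsAsFactors = FALSE)
}

#' @rdname ref_decade_summary
#' @export
ref_condition_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_condition_summary.csv",
                              package = "sbrnorm"), stringsAsFactors = FALSE)
}

decade_rows <- function(summary_df, group) {
  rows <- summary_df[summary_df$group == group, ]
  rows[order(rows$decade), ]
}

#' Percent sex difference in a decade's SBR mean
#'
#' `(female mean - male mean) / male mean x 100` for one age decade of a
#' decade summary table (as produced by [decade_summary()] or bundled via
#' [ref_decade_summary()]).
#'
#' @param summary_df decade summary data.frame.
#' @param decade decade label, e.g. `"30-39"`.
#' @return percent difference (positive = women higher).
#' @export
pct_sex_difference <- function(summary_df, decade = "30-39") {
  m <- summary_df$sbr_mean[summary_df$group == "M" & summary_df$decade == decade]
  f <- summary_df$sbr_mean[summary_df$group == "F" & summary_df$decade == decade]
  if (!length(m) || !length(f)) stop("decade not present for both sexes")
  (f - m) / m * 100
}

#' Average percent SBR decline per decade
#'
#' Mean consecutive decade-to-decade decrement of the SBR mean, expressed as
#' a percentage of the youngest decade's mean.
#'
#' @param summary_df decade summary data.frame.
#' @param group `"both"`, `"M"` or `"F"`.
#' @return percent decline per decade.
#' @export
pct_decline_per_decade <- function(summary_df, group = "both") {
  rows <- decade_rows(summary_df, group)
  means <- rows$sbr_mean[!is.na(rows$sbr_mean)]
  if (length(means) < 2) stop("need at least two populated decades")
  mean(-diff(means)) / means[1] * 100
}

#' Scan-count-weighted grand mean SBR of a decade summary
#'
#' Weights each decade's SBR mean by its scan count; applied to the bundled
#' reference decades this recovers the uncorrected-condition calibrated grand
#' mean.
#'
#' @param summary_df decade summary data.frame.
#' @param group `"both"`, `"M"` or `"F"`.
#' @return weighted mean SBR.
#' @export
scan_weighted_mean <- function(summary_df, group = "both") {
  rows <- decade_rows(summary_df, group)
  ok <- !is.na(rows$sbr_mean) & rows$n_scans > 0
  sum(rows$sbr_mean[ok] * rows$n_scans[ok]) / sum(rows$n_scans[ok])
}

#' Percent difference between two reconstruction conditions' grand means
#'
#' `(reference mean - other mean) / reference mean x 100` from a condition
#' summary table, e.g. how much lower the uncorrected condition reads than
#' the scatter-corrected one.
#'
#' @param condition_df condition summary data.frame (see
#'   [ref_condition_summary()]).
#' @param other,reference condition labels.
#' @param calibration `"original"` or `"calibrated"`.
#' @return percent difference (positive = `other` lower than `reference`).
#' @export
pct_condition_difference <- function(condition_df, other = "NOACNOSC",
                                     reference = "ChangACSC",
                                     calibration = "calibrated") {
  sel <- condition_df$calibration == calibration
  mo <- condition_df$mean_sbr[sel & condition_df$condition == other]
  mr <- condition_df$mean_sbr[sel & condition_df$condition == reference]
  if (!length(mo) || !length(mr)) stop("condition not present")
  (mr - mo) / mr * 100
}

#' Percent SBR reduction at the lower prediction limit
#'
#' `(1 - lower PI limit / decade mean) x 100` for one decade - the reduction
#' a new scan must show relative to its decade's expected SBR to fall below
#' the normative prediction band.
#'
#' @param summary_df decade summary data.frame.
#' @param group group label.
#' @param decade decade label.
#' @return percent reduction.
#' @export
pct_pi_reduction <- function(summary_df, group = "both", decade = "60-69") {
  row <- summary_df[summary_df$group == group & summary_df$decade == decade, ]
  if (nrow(row) != 1) stop("decade/group not present")
  (1 - row$sbr_lower_pi / row$sbr_mean) * 100
}
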