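#' Default end-to-end pipeline configuration
#'
#' One nested list driving every stage: emulated scanners and their
#' per-condition biases, phantom fillings, quantifier settings, calibration
#' gates, cohort generation and normative settings. Defaults mirror the
#' study conditions: 44 mm reference slab, 11.2 mL striatal volume, nominal
#' fillings 8:1/4:1 then +33% background (~6:1/~3:1) then uniform, 95%
#' prediction level. Round-trips losslessly through YAML/JSON.
#'
#' @param seed root seed; each stage derives its own stream from it.
#' @param n_cohort number of synthetic scan records.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_cohort = 510L) {
  list(
    seed = as.integer(seed),
    scanners = list(
      list(name = "scannerA", voxel_size = 2.0, psf_fwhm = 9,
           noise_scale = 5e6,
           condition_bias = list(
             NOACNOSC = list(gain = 0.72, offset = -0.30, nonlin = 0),
             ChangACSC = list(gain = 1.445, offset = 2.138, nonlin = 0.02))),
      list(name = "scannerB", voxel_size = 2.4, psf_fwhm = 11,
           noise_scale = 5e6,
           condition_bias = list(
             NOACNOSC = list(gain = 0.60, offset = -0.10, nonlin = 0),
             ChangACSC = list(gain = 1.30, offset = 1.80, nonlin = 0.02)))),
    phantom = list(ratios = list(c(8, 4), c(6.015, 3.008), c(1, 1)),
                   background_conc = 5),
    quantify = list(margin_mm = 20, slab_mm = 44, vol_str_ml = 11.2,
                    smoothing_fwhm = 8, brain_threshold_frac = 0.15),
    calibration = list(min_slope = 0.1, min_r = 0.9),
    cohort = list(n = as.integer(n_cohort), residual_sd = 1.38,
                  ai_residual_sd = 3.5, measurement_noise_sd = 0.25),
    normative = list(level = 0.95, icc_form = "agreement",
                     decade_mode = "predicted")
  )
}

#' Read / write a pipeline configuration (YAML, JSON accepted)
#'
#' @param config a `pipeline_config` list.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly / the configuration list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$phantom$ratios <- lapply(cfg$phantom$ratios, as.numeric)
  cfg
}

#' Hash of a configuration for provenance stamping
#' @param config a configuration list.
#' @return md5 hex string of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

provenance <- function(config) {
  list(config_hash = config_hash(config), seed = config$seed,
       package_version = as.character(utils::packageVersion("sbrnorm")))
}

scanner_from_config <- function(sc) {
  scanner_model(sc$name, sc$voxel_size, sc$psf_fwhm,
                condition_bias = sc$condition_bias,
                noise_scale = sc$noise_scale %||% Inf)
}

#' Run the full simulate-quantify-calibrate-model pipeline
#'
#' Stages: (1) simulate phantom series for every scanner x condition and
#' write the volumes plus a manifest CSV; (2) quantify them and fit the
#' per-(scanner, condition) calibration curves; (3) generate the synthetic
#' cohort on the normative plane, apply each assigned condition's measurement
#' bias, and calibrate; (4) fit the normative models and decade summary.
#' Every artifact directory gets a provenance JSON with the seed, config hash
#' and package version; deterministic stages are bit-identical under the same
#' configuration.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir output directory (created if needed).
#' @param write_volumes write phantom volumes as NIfTI (disable to save time
#'   and space; the manifest then records measurements only).
#' @return invisibly, a list with the manifest, calibration table, cohort and
#'   fitted models.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("sbrnorm_run_"),
                         write_volumes = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  qcfg <- utils::modifyList(quantify_config(), config$quantify)

  ## stage 1+2: phantom series, quantification, calibration fits
  manifest <- list(); series_all <- list()
  stage("simulate-phantoms", {
    si <- 0L
    for (sc in config$scanners) {
      scanner <- scanner_from_config(sc)
      for (cond in names(sc$condition_bias)) {
        si <- si + 1L
        series <- generate_phantom_series(
          scanner, cond, ratios = config$phantom$ratios,
          background_conc = config$phantom$background_conc,
          seed = config$seed + 100L * si)
        series_all <- c(series_all, series)
        for (j in seq_along(series)) {
          s <- series[[j]]
          path <- file.path(out_dir, sprintf("phantom_%s_%s_%d.nii.gz",
                                             s$scanner, s$condition, j))
          if (write_volumes) write_volume(s$volume, path)
          manifest[[length(manifest) + 1L]] <- data.frame(
            scanner = s$scanner, condition = s$condition,
            ratio_right = s$ratio_right, ratio_left = s$ratio_left,
            background_kbq_ml = s$background_conc,
            true_sbr_right = s$true_sbr_right, true_sbr_left = s$true_sbr_left,
            volume_path = if (write_volumes) basename(path) else NA_character_)
        }
      }
    }
    manifest <- do.call(rbind, manifest)
  })
  utils::write.csv(manifest, file.path(out_dir, "phantom_manifest.csv"),
                   row.names = FALSE)

  curves <- stage("fit-calibration",
    fit_calibration_from_series(series_all, qcfg,
                                min_slope = config$calibration$min_slope,
                                min_r = config$calibration$min_r))
  write_calibration_table(curves, file.path(out_dir, "calibration_curves.json"))

  ## stage 3: synthetic cohort, measurement bias per assigned condition,
  ## calibration back to the harmonized scale
  cohort <- stage("simulate-cohort", {
    truth <- generate_cohort(config$cohort$n,
                             residual_sd = config$cohort$residual_sd,
                             ai_residual_sd = config$cohort$ai_residual_sd,
                             seed = config$seed + 7L)
    pairs <- do.call(rbind, lapply(config$scanners, function(sc)
      data.frame(scanner = sc$name, condition = names(sc$condition_bias))))
    assign_idx <- rep_len(seq_len(nrow(pairs)), nrow(truth))
    parts <- lapply(seq_len(nrow(pairs)), function(i) {
      sub <- truth[assign_idx == i, , drop = FALSE]
      sc <- config$scanners[[which(vapply(config$scanners, `[[`, "", "name") ==
                                     pairs$scanner[i])[1]]]
      b <- sc$condition_bias[[pairs$condition[i]]]
      bias_cohort(sub, gain = b$gain, offset = b$offset,
                  nonlin = b$nonlin %||% 0,
                  noise_sd = config$cohort$measurement_noise_sd,
                  scanner = pairs$scanner[i], condition = pairs$condition[i],
                  seed = config$seed + 31L + i)
    })
    calibrate_cohort(do.call(rbind, parts), curves)
  })
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  ## stage 4: normative layer
  models <- stage("normative-fit", {
    list(sbr = fit_normative_model(cohort, "average_sbr"),
         ai = fit_normative_model(cohort, "ai"))
  })
  write_normative_model(models$sbr, file.path(out_dir, "normative_sbr.json"))
  write_normative_model(models$ai, file.path(out_dir, "normative_ai.json"))
  decades <- stage("decade-summary",
    decade_summary(cohort, mode = config$normative$decade_mode,
                   level = config$normative$level))
  utils::write.csv(decades, file.path(out_dir, "decade_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(provenance(config), file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, curves = curves, cohort = cohort,
                 models = models, decades = decades, out_dir = out_dir))
}
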