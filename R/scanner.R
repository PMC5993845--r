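#' Emulated SPECT scanner / reconstruction model
#'
#' Abstracts an imaging system as (i) a Gaussian point-spread function, (ii)
#' a per-reconstruction-condition affine bias acting on the ideal
#' specific-binding-ratio relation (measured = gain x true + offset, with an
#' optional quadratic term emulating the residual scatter-correction excess),
#' and (iii) Poisson counting noise at a given expected total count. Physical
#' projection/reconstruction (attenuation, scatter windows, filtering) is not
#' simulated; only its net affine effect on the measured-vs-true SBR relation
#' is, which is what phantom cross-calibration observes and corrects.
#'
#' @param name scanner identifier (e.g. "scannerA").
#' @param voxel_size acquisition voxel size, mm; must lie in [1.7, 3.4].
#' @param psf_fwhm point-spread-function full width at half maximum, mm.
#' @param condition_bias named list: condition -> numeric vector with
#'   elements `gain` (> 0), `offset`, and optionally `nonlin` (coefficient of
#'   true SBR squared, default 0).
#' @param noise_scale expected total counts over the volume driving Poisson
#'   statistics; `Inf` (default) disables noise.
#' @return an object of class `scanner_model`.
#' @export
scanner_model <- function(name, voxel_size, psf_fwhm,
                          condition_bias = list(NOACNOSC = c(gain = 1, offset = 0)),
                          noise_scale = Inf) {
  if (voxel_size < 1.7 || voxel_size > 3.4)
    stop("voxel_size must lie in [1.7, 3.4] mm")
  if (psf_fwhm < 0) stop("psf_fwhm must be non-negative")
  if (is.null(names(condition_bias)) || any(names(condition_bias) == ""))
    stop("condition_bias must be a named list keyed by condition")
  condition_bias <- lapply(condition_bias, function(b) {
    b <- as.list(b)
    if (is.null(b$gain) || b$gain <= 0) stop("each condition needs gain > 0")
    if (is.null(b$offset)) stop("each condition needs an offset")
    if (is.null(b$nonlin)) b$nonlin <- 0
    b[c("gain", "offset", "nonlin")]
  })
  structure(list(name = name, voxel_size = voxel_size, psf_fwhm = psf_fwhm,
                 condition_bias = condition_bias, noise_scale = noise_scale),
            class = "scanner_model")
}

condition_bias_of <- function(scanner, condition) {
  b <- scanner$condition_bias[[condition]]
  if (is.null(b))
    stop("configuration error: condition '", condition,
         "' unknown to scanner '", scanner$name, "'")
  b
}

#' Image a phantom volume through an emulated scanner
#'
#' Applies, in order: the condition's affine bias on the ideal SBR relation
#' (striatal compartment excess counts are set so that a perfect oversized-VOI
#' measurement would read `gain x true_sbr + offset + nonlin x true_sbr^2`),
#' Gaussian PSF blurring, and Poisson counting noise scaled to the scanner's
#' expected total counts. Deterministic given `seed`; with `psf_fwhm = 0`,
#' identity bias and noise disabled it is the identity.
#'
#' @param volume a [spect_volume()] produced by [rasterize_phantom()] (its
#'   `phantom` attribute supplies the compartment ground truth the bias is
#'   defined on).
#' @param scanner a [scanner_model()].
#' @param condition reconstruction condition key (e.g. "NOACNOSC").
#' @param seed integer seed for the Poisson noise stream.
#' @return a [spect_volume()]; the `phantom` attribute is carried through
#'   with the applied bias recorded.
#' @export
apply_scanner <- function(volume, scanner, condition, seed = 1L) {
  stopifnot(inherits(volume, "spect_volume"), inherits(scanner, "scanner_model"))
  b <- condition_bias_of(scanner, condition)
  ph <- attr(volume, "phantom")
  out <- volume
  identity_bias <- b$gain == 1 && b$offset == 0 && b$nonlin == 0
  if (!identity_bias) {
    if (is.null(ph))
      stop("condition bias needs a phantom volume with ground-truth masks")
    bg <- ph$spec$background_conc
    vstr_vox <- ph$spec$striatal_volume_ml * 1000 / prod(volume$spacing)
    for (side in c("right", "left")) {
      mask <- ph[[paste0(side, "_mask")]]
      t_true <- ph$true_sbr[[side]]
      t_meas <- b$gain * t_true + b$offset + b$nonlin * t_true^2
      ## uniform striatal value making the ideal oversized-VOI SBR = t_meas
      out$data[mask] <- bg + t_meas * bg * vstr_vox / sum(mask)
    }
  }
  out <- gaussian_blur(out, scanner$psf_fwhm)
  if (is.finite(scanner$noise_scale)) {
    if (scanner$noise_scale <= 0) stop("noise_scale must be positive")
    s <- scanner$noise_scale / sum(out$data)
    noisy <- local({
      set.seed(as.integer(seed))
      stats::rpois(length(out$data), lambda = s * out$data)
    })
    out$data <- array(noisy / s, dim = dim(out$data))
  }
  if (!is.null(ph)) {
    ph$applied_bias <- b
    ph$condition <- condition
    ph$scanner <- scanner$name
    attr(out, "phantom") <- ph
  }
  out
}

#' Generate a phantom calibration series for one scanner and condition
#'
#' Emulates the physical filling sequence: for each ratio configuration a
#' phantom is specified, rasterized at the scanner's voxel size and imaged
#' through the scanner. The true SBRs are recorded from the specification,
#' playing the role of the well-counter aliquot measurements.
#'
#' @param scanner a [scanner_model()].
#' @param condition reconstruction condition key.
#' @param ratios list of length-2 numeric vectors `c(right, left)` of nominal
#'   striatum:background ratios. The default reproduces the study fillings:
#'   8:1/4:1, then the +33% background giving ~6:1/~3:1, then uniform.
#' @param background_conc initial background concentration, kBq/mL.
#' @param seed integer root seed; one derived stream per volume.
#' @return a list with one element per configuration, each holding `volume`,
#'   `true_sbr_right`, `true_sbr_left`, `ratio_right`, `ratio_left`,
#'   `background_conc`, `scanner`, `condition`.
#' @export
generate_phantom_series <- function(scanner, condition,
                                    ratios = list(c(8, 4), c(6.015, 3.008), c(1, 1)),
                                    background_conc = 5, seed = 1L) {
  stopifnot(inherits(scanner, "scanner_model"))
  if (length(ratios) == 0) stop("ratios must be non-empty")
  lapply(seq_along(ratios), function(i) {
    r <- ratios[[i]]
    spec <- build_phantom_spec(r[1], r[2], background_conc)
    vol <- rasterize_phantom(spec, scanner$voxel_size)
    ts <- true_sbr(spec)
    img <- apply_scanner(vol, scanner, condition, seed = seed + i - 1L)
    list(volume = img,
         true_sbr_right = unname(ts["right"]),
         true_sbr_left = unname(ts["left"]),
         ratio_right = r[1], ratio_left = r[2],
         background_conc = background_conc,
         scanner = scanner$name, condition = condition)
  })
}
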