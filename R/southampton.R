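#' Locate the striatal activity peaks
#'
#' Smooths the volume with a Gaussian (default FWHM 8 mm, stabilising the
#' argmax under counting noise), splits it at the midline - the sagittal
#' plane through the volume's centre of mass - and takes the peak of each
#' half. The axial coordinate of the global smoothed maximum defines the
#' centre of the background reference slab.
#'
#' @param volume a [spect_volume()] with positive counts.
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm before peak finding.
#' @param min_contrast minimum ratio of a half's peak to the upper quartile
#'   of its positive smoothed values (roughly the background level) for the
#'   peak to count as striatal signal; guards against featureless volumes.
#' @return list with `right_centre`, `left_centre` (1-based voxel indices),
#'   `right_centre_mm`, `left_centre_mm`, and `peak_axial` (axial voxel index
#'   of the highest smoothed activity).
#' @export
locate_striatal_peaks <- function(volume, smoothing_fwhm = 8,
                                  min_contrast = 1.05) {
  stopifnot(inherits(volume, "spect_volume"))
  d <- dim(volume$data)
  if (d[3] < 3) stop("volume must have at least 3 axial slices")
  if (all(volume$data <= 0)) stop("no-signal error: volume has no counts")
  sm <- gaussian_blur(volume, smoothing_fwhm)$data
  ## midline: sagittal plane through the centre of mass
  xw <- apply(sm, 1, sum)
  com_x <- sum(seq_len(d[1]) * xw) / sum(xw)
  centres <- list()
  for (side in c("left", "right")) {
    idx <- if (side == "left") seq_len(floor(com_x)) else
      seq.int(ceiling(com_x), d[1])
    half <- sm[idx, , , drop = FALSE]
    nz <- half[half > 0]
    if (!length(nz) ||
        max(half) < min_contrast * stats::quantile(nz, 0.75, names = FALSE))
      stop(if (max(half) <= 0) "lateralization error: no striatal signal on the "
           else "degenerate-peak error: no distinct striatal peak on the ",
           side, " side")
    w <- which(half == max(half), arr.ind = TRUE)[1, ]
    w[1] <- idx[w[1]]
    centres[[side]] <- unname(w)
  }
  gmax <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  list(right_centre = centres$right, left_centre = centres$left,
       right_centre_mm = voxel_to_mm(volume, centres$right),
       left_centre_mm = voxel_to_mm(volume, centres$left),
       peak_axial = unname(gmax[3]))
}

voi_mask <- function(indices_logical, volume, role) {
  structure(list(mask = indices_logical,
                 n_voxels = sum(indices_logical),
                 volume_ml = sum(indices_logical) * voxel_volume_ml(volume),
                 role = role),
            class = "voi_mask")
}

#' Define an oversized striatal VOI around a peak
#'
#' A fixed-physical-size axis-aligned box: the nominal striatal bounding box
#' (semi-extents `nominal_semi_mm`) dilated by `margin` on every side, clipped
#' to the grid. The size is independent of image intensities - the defining
#' property that makes the oversized-VOI SBR estimator insensitive to VOI
#' shape and system resolution. Clipping by more than 5% of the nominal box
#' volume is recorded in the mask's provenance.
#'
#' @param volume a [spect_volume()].
#' @param centre 1-based voxel index of the VOI centre.
#' @param margin dilation margin in mm (>= 0).
#' @param nominal_semi_mm semi-extents of the nominal striatum box, mm.
#' @param role mask role label.
#' @return a `voi_mask`.
#' @export
define_striatal_voi <- function(volume, centre, margin = 20,
                                nominal_semi_mm = c(9.1, 21.1, 14.1),
                                role = "striatal") {
  stopifnot(inherits(volume, "spect_volume"), margin >= 0)
  d <- dim(volume$data)
  if (any(centre < 1) || any(centre > d)) stop("centre outside the grid")
  half_vox <- (nominal_semi_mm + margin) / volume$spacing
  lo <- pmax(1, ceiling(centre - half_vox))
  hi <- pmin(d, floor(centre + half_vox))
  nominal_n <- prod(floor(centre + half_vox) - ceiling(centre - half_vox) + 1)
  mask <- array(FALSE, dim = d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m <- voi_mask(mask, volume, role)
  m$clipped_fraction <- 1 - sum(mask) / nominal_n
  m$clipped_warning <- m$clipped_fraction > 0.05
  m
}

## box erosion of a logical array: half-width r voxels per axis
erode_mask <- function(mask, r_vox) {
  out <- mask
  d <- dim(mask)
  for (axis in 1:3) {
    r <- r_vox[axis]
    if (r < 1) next
    base <- out
    n <- d[axis]
    for (s in seq_len(r)) {
      fwd <- array(FALSE, dim = d); bwd <- array(FALSE, dim = d)
      src_hi <- (s + 1):n; src_lo <- 1:(n - s)
      if (axis == 1) {
        fwd[src_lo, , ] <- base[src_hi, , ]; bwd[src_hi, , ] <- base[src_lo, , ]
      } else if (axis == 2) {
        fwd[, src_lo, ] <- base[, src_hi, ]; bwd[, src_hi, ] <- base[, src_lo, ]
      } else {
        fwd[, , src_lo] <- base[, , src_hi]; bwd[, , src_hi] <- base[, , src_lo]
      }
      out <- out & fwd & bwd
    }
  }
  out
}

#' Define the background reference region
#'
#' Brain voxels within an axial slab (default 44 mm thick) centred on the
#' highest striatal activity, minus both striatal VOIs. The brain mask is
#' built on a lightly smoothed copy of the volume (stable under counting
#' noise) as voxels above a fraction (default 0.15) of the slab's
#' 99th-percentile intensity, then eroded by `erode_mm` so that
#' partial-volume voxels at the compartment boundary - whose counts sit
#' below the true background level after PSF blurring - are excluded. The
#' background mean multiplies the full striatal VOI voxel count in the SBR
#' formula, so even sub-percent background bias is strongly amplified;
#' erosion by roughly 3 standard deviations of the worst-case system PSF
#' keeps the estimate essentially exact. Reference counts are always taken
#' from the original (unsmoothed) volume.
#'
#' @param volume a [spect_volume()].
#' @param peak_axial axial voxel index of the slab centre.
#' @param striatal_vois list of striatal `voi_mask`s to exclude.
#' @param slab_thickness slab thickness in mm; the slab uses
#'   `round(slab_thickness / voxel size)` axial slices.
#' @param brain_threshold_frac brain-mask threshold as a fraction of the
#'   slab's 99th-percentile smoothed intensity.
#' @param erode_mm brain-mask erosion depth, mm.
#' @param smooth_fwhm FWHM of the mask-building smoothing, mm.
#' @return a `voi_mask` with role "reference".
#' @export
define_reference_region <- function(volume, peak_axial, striatal_vois,
                                    slab_thickness = 44,
                                    brain_threshold_frac = 0.15,
                                    erode_mm = 20, smooth_fwhm = 6) {
  stopifnot(inherits(volume, "spect_volume"))
  d <- dim(volume$data)
  n_slices <- max(1, round(slab_thickness / volume$spacing[3]))
  z_lo <- peak_axial - floor((n_slices - 1) / 2)
  z_hi <- peak_axial + ceiling((n_slices - 1) / 2)
  zr <- max(1, z_lo):min(d[3], z_hi)
  if (!length(zr)) stop("slab does not intersect the grid")
  sm <- gaussian_blur(volume, smooth_fwhm)$data
  slab <- array(FALSE, dim = d)
  slab[, , zr] <- TRUE
  thr <- brain_threshold_frac * stats::quantile(sm[slab], 0.99, names = FALSE)
  brain <- sm > thr
  brain <- erode_mask(brain, floor(erode_mm / volume$spacing))
  mask <- brain & slab
  for (v in striatal_vois) mask <- mask & !v$mask
  if (!any(mask)) stop("reference error: empty reference region after exclusion")
  m <- voi_mask(mask, volume, "reference")
  m$n_slices <- length(zr)
  m
}

#' Specific binding ratio from an oversized VOI and a reference region
#'
#' The oversized-VOI estimator: with `Cbg` the mean reference count per voxel,
#' `Cstr` the total count in the striatal VOI of `N` voxels, and the striatal
#' volume fixed to `vol_str_ml` (expressed in voxel units of the grid),
#' `SBR = (Cstr - Cbg * N) / (Cbg * vol_str_vox)`. Because only the excess
#' over background counts, the estimate is invariant to adding further pure
#' background voxels to the VOI, hence insensitive to VOI size and system
#' resolution. Negative values (cold striata) are returned as-is.
#'
#' @param volume a [spect_volume()].
#' @param striatal_voi,reference_voi `voi_mask`s.
#' @param vol_str_ml assumed physical striatal volume per hemisphere, mL
#'   (fixed to 11.2 mL in the standard method).
#' @return unitless SBR (scalar).
#' @export
compute_sbr <- function(volume, striatal_voi, reference_voi, vol_str_ml = 11.2) {
  stopifnot(inherits(volume, "spect_volume"), vol_str_ml > 0)
  if (reference_voi$n_voxels == 0) stop("reference VOI is empty")
  c_bg <- sum(volume$data[reference_voi$mask]) / reference_voi$n_voxels
  if (c_bg == 0) stop("division error: zero mean reference count")
  c_str <- sum(volume$data[striatal_voi$mask])
  n_str <- striatal_voi$n_voxels
  vol_str_vox <- vol_str_ml * 1000 / prod(volume$spacing)
  (c_str - c_bg * n_str) / (c_bg * vol_str_vox)
}

#' Interhemispheric asymmetry index
#'
#' `AI = |R - L| / (R + L) * 200`, in percent-like units on [0, 200] for
#' nonnegative inputs; symmetric in its arguments and scale invariant.
#'
#' @param sbr_right,sbr_left right and left striatal SBR.
#' @return unitless AI.
#' @export
compute_ai <- function(sbr_right, sbr_left) {
  s <- sbr_right + sbr_left
  if (any(s <= 0)) stop("domain error: sbr_right + sbr_left must be positive")
  abs(sbr_right - sbr_left) / s * 200
}

#' Default quantification settings
#' @return named list of quantifier parameters (mm units; `vol_str_ml` in mL).
#' @export
quantify_config <- function(margin_mm = 20, slab_mm = 44, vol_str_ml = 11.2,
                            smoothing_fwhm = 8, brain_threshold_frac = 0.15,
                            erode_mm = 20, ref_smooth_fwhm = 6,
                            nominal_semi_mm = c(9.1, 21.1, 14.1)) {
  list(margin_mm = margin_mm, slab_mm = slab_mm, vol_str_ml = vol_str_ml,
       smoothing_fwhm = smoothing_fwhm,
       brain_threshold_frac = brain_threshold_frac,
       erode_mm = erode_mm, ref_smooth_fwhm = ref_smooth_fwhm,
       nominal_semi_mm = nominal_semi_mm)
}

#' Quantify a SPECT volume: left/right SBR and asymmetry index
#'
#' Composes peak localisation, oversized striatal VOIs, the background
#' reference slab and the fixed-volume SBR estimator. Deterministic given the
#' volume and configuration. Precomputed VOIs can be forced via `vois`, e.g.
#' to quantify a uniformly filled phantom (which has no localisable peaks)
#' with the VOIs found on a hot filling of the same, unmoved phantom.
#'
#' The asymmetry index is defined only when the two SBRs sum to a positive
#' value; otherwise it is reported as `NA` (and the negative flag is set).
#'
#' @param volume a [spect_volume()].
#' @param config list as from [quantify_config()].
#' @param vois optional forced VOIs: a list with elements `right`, `left`
#'   and `reference` (`voi_mask`s on the same grid).
#' @return an object of class `striatal_measurement`: `sbr_right`, `sbr_left`,
#'   `ai`, `vol_str_used`, per-VOI voxel/count bookkeeping and flags.
#' @export
quantify <- function(volume, config = quantify_config(), vois = NULL) {
  config <- utils::modifyList(quantify_config(), config)
  if (is.null(vois)) {
    peaks <- locate_striatal_peaks(volume, config$smoothing_fwhm)
    voi_r <- define_striatal_voi(volume, peaks$right_centre, config$margin_mm,
                                 config$nominal_semi_mm, role = "striatal_right")
    voi_l <- define_striatal_voi(volume, peaks$left_centre, config$margin_mm,
                                 config$nominal_semi_mm, role = "striatal_left")
    ref <- define_reference_region(volume, peaks$peak_axial, list(voi_r, voi_l),
                                   config$slab_mm, config$brain_threshold_frac,
                                   config$erode_mm, config$ref_smooth_fwhm)
  } else {
    peaks <- NULL
    voi_r <- vois$right; voi_l <- vois$left; ref <- vois$reference
  }
  sbr_r <- compute_sbr(volume, voi_r, ref, config$vol_str_ml)
  sbr_l <- compute_sbr(volume, voi_l, ref, config$vol_str_ml)
  voi_summary <- function(v) list(
    n_voxels = v$n_voxels, volume_ml = v$volume_ml,
    total_counts = sum(volume$data[v$mask]),
    clipped_fraction = v$clipped_fraction %||% 0)
  structure(list(
    sbr_right = sbr_r, sbr_left = sbr_l,
    ai = if (sbr_r + sbr_l > 0) compute_ai(sbr_r, sbr_l) else NA_real_,
    vol_str_used = config$vol_str_ml,
    negative_flag = sbr_r < 0 || sbr_l < 0,
    peaks = peaks,
    striatal_voi_right = voi_summary(voi_r),
    striatal_voi_left = voi_summary(voi_l),
    reference_voi = voi_summary(ref),
    config = config
  ), class = "striatal_measurement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.striatal_measurement <- function(x, ...) {
  cat(sprintf("<striatal_measurement> SBR right %.3f, left %.3f, AI %.2f%s\n",
              x$sbr_right, x$sbr_left, x$ai,
              if (x$negative_flag) "  [negative SBR flagged]" else ""))
  invisible(x)
}

#' Quantify several volumes into a measurement table
#'
#' @param volumes list of [spect_volume()]s (optionally named).
#' @param config quantifier configuration.
#' @return data.frame, one row per volume: `sbr_right`, `sbr_left`, `ai`,
#'   VOI voxel counts, negative flag.
#' @export
quantify_batch <- function(volumes, config = quantify_config()) {
  rows <- lapply(volumes, function(v) {
    m <- quantify(v, config)
    data.frame(sbr_right = m$sbr_right, sbr_left = m$sbr_left, ai = m$ai,
               vol_str_used = m$vol_str_used,
               striatal_voxels_right = m$striatal_voi_right$n_voxels,
               striatal_voxels_left = m$striatal_voi_left$n_voxels,
               reference_voxels = m$reference_voi$n_voxels,
               negative_flag = m$negative_flag)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(volumes))) out <- cbind(id = names(volumes), out)
  rownames(out) <- NULL
  out
}
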