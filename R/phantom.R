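#' Digital striatal phantom specification
#'
#' Describes a fillable anthropomorphic striatal phantom: an ellipsoidal
#' background ("head") compartment containing two mirrored ellipsoidal
#' striatal compartments of fixed physical volume, each filled with a known
#' activity concentration. With a uniform nonspecific background, the
#' ground-truth specific binding ratio of a hemisphere is exactly
#' `striatal_conc / background_conc - 1`.
#'
#' The default geometry places each striatal ellipsoid 25 mm lateral to the
#' midline with semi-axes chosen so the hemisphere volume is exactly
#' `striatal_volume_ml` (11.2 mL by default, the fixed striatal volume used
#' by the Southampton quantifier). The exact shape is deliberately generic:
#' the oversized-VOI estimator is designed to be insensitive to it.
#'
#' @param striatal_conc_right,striatal_conc_left activity concentration of
#'   the right/left striatal compartment, kBq/mL.
#' @param background_conc background compartment concentration, kBq/mL.
#' @param striatal_volume_ml physical volume of each striatal compartment, mL.
#' @param head_semiaxes_mm ellipsoid semi-axes of the head compartment
#'   (x = left-right, y = posterior-anterior, z = inferior-superior), mm.
#' @param striatal_semiaxes_mm base semi-axes of each striatal ellipsoid, mm;
#'   rescaled isotropically to enclose exactly `striatal_volume_ml`.
#' @param striatal_offset_mm centre of the right striatum, mm (the left is
#'   the x-mirror image).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(striatal_conc_right,
                         striatal_conc_left,
                         background_conc,
                         striatal_volume_ml = 11.2,
                         head_semiaxes_mm = c(80, 95, 70),
                         striatal_semiaxes_mm = c(9, 21, 14),
                         striatal_offset_mm = c(25, 8, 0)) {
  concs <- c(striatal_conc_right, striatal_conc_left, background_conc)
  if (any(!is.finite(concs)) || any(concs <= 0))
    stop("all activity concentrations must be positive")
  if (striatal_conc_right < background_conc ||
      striatal_conc_left < background_conc)
    stop("striatal concentrations must be >= the background concentration")
  if (striatal_volume_ml <= 0) stop("striatal_volume_ml must be positive")
  ## isotropic rescale so the ellipsoid volume is exactly striatal_volume_ml
  base_vol_mm3 <- 4 / 3 * pi * prod(striatal_semiaxes_mm)
  scale <- (striatal_volume_ml * 1000 / base_vol_mm3)^(1 / 3)
  semi <- striatal_semiaxes_mm * scale
  centre_r <- striatal_offset_mm
  centre_l <- striatal_offset_mm * c(-1, 1, 1)
  ## compartments must be disjoint and inside the head
  if (centre_r[1] - semi[1] <= 0)
    stop("striatal compartments overlap the midline")
  if (any(abs(centre_r) + semi >= head_semiaxes_mm))
    stop("striatal compartment extends outside the head compartment")
  structure(list(
    striatal_conc_right = striatal_conc_right,
    striatal_conc_left = striatal_conc_left,
    background_conc = background_conc,
    striatal_volume_ml = striatal_volume_ml,
    head_semiaxes_mm = head_semiaxes_mm,
    striatal_semiaxes_mm = semi,
    centre_right_mm = centre_r,
    centre_left_mm = centre_l
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> R ", x$striatal_conc_right, " / L ",
      x$striatal_conc_left, " / BG ", x$background_conc,
      " kBq/mL  (true SBR R ", signif(true_sbr(x)["right"], 4),
      ", L ", signif(true_sbr(x)["left"], 4), ")\n", sep = "")
  invisible(x)
}

#' Ground-truth SBR of a phantom specification
#'
#' With uniform nonspecific background, SBR per hemisphere is the
#' concentration ratio minus one.
#'
#' @param spec a [phantom_spec()].
#' @return named numeric `c(right =, left =)`.
#' @export
true_sbr <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  c(right = spec$striatal_conc_right / spec$background_conc - 1,
    left = spec$striatal_conc_left / spec$background_conc - 1)
}

#' Build a phantom specification from nominal striatum:background ratios
#'
#' The striatal compartments are filled at `ratio x background_conc`, so the
#' ground-truth SBR is `ratio - 1` per hemisphere. The study conditions use
#' nominal ratios 8:1, 6:1, 4:1 and 3:1 plus a uniform (1:1) filling.
#'
#' @param target_ratio_right,target_ratio_left nominal striatum:background
#'   concentration ratios (>= 1; 1 gives a uniform phantom).
#' @param background_conc background concentration, kBq/mL.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
build_phantom_spec <- function(target_ratio_right, target_ratio_left,
                               background_conc, ...) {
  if (target_ratio_right < 1 || target_ratio_left < 1)
    stop("invalid ratio: nominal striatum:background ratios must be >= 1")
  if (background_conc <= 0) stop("background_conc must be positive")
  phantom_spec(striatal_conc_right = target_ratio_right * background_conc,
               striatal_conc_left = target_ratio_left * background_conc,
               background_conc = background_conc, ...)
}

#' Increase the background concentration, leaving the striata untouched
#'
#' Mirrors the physical filling sequence in which, after the 8:1/4:1 filling,
#' raising the background concentration by 33% yields nominal ratios of
#' approximately 6:1 and 3:1 without refilling the striatal compartments.
#'
#' @param spec a [phantom_spec()].
#' @param fraction fractional increase of the background concentration
#'   (0.33 reproduces the study's second filling).
#' @return a new [phantom_spec()].
#' @export
raise_background <- function(spec, fraction = 0.33) {
  stopifnot(inherits(spec, "phantom_spec"), fraction > -1)
  phantom_spec(spec$striatal_conc_right, spec$striatal_conc_left,
               spec$background_conc * (1 + fraction),
               striatal_volume_ml = spec$striatal_volume_ml,
               head_semiaxes_mm = spec$head_semiaxes_mm)
}

in_ellipsoid <- function(x, y, z, centre, semi) {
  ((x - centre[1]) / semi[1])^2 + ((y - centre[2]) / semi[2])^2 +
    ((z - centre[3]) / semi[3])^2 <= 1
}

#' Rasterize a phantom specification to a digital volume
#'
#' Produces a noiseless count-concentration volume on an isotropic grid
#' centred on the phantom, with enough padding that a dilated striatal VOI
#' stays inside the grid. Head voxels take the background concentration;
#' striatal compartments are rasterized volume-matched: voxels are ranked by
#' the ellipsoid quadratic form and the compartment takes the voxel count
#' whose total volume is nearest the specified physical volume, so the
#' digital hemisphere volume is within half a voxel of `striatal_volume_ml`
#' at any spacing in range (far inside the 2% contract). The rasterization is
#' rejected if the residual volume error still exceeds `volume_tol_frac`.
#'
#' Compartment masks, true centres and concentrations are carried in the
#' `phantom` attribute so simulator stages (and tests) can use exact ground
#' truth.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_size isotropic voxel size, mm (1 to 4).
#' @param pad_mm grid padding beyond the head ellipsoid, mm.
#' @param volume_tol_frac maximum tolerated relative error of the digital
#'   striatal volume (default 0.02).
#' @return a [spect_volume()] with attribute `phantom`.
#' @export
rasterize_phantom <- function(spec, voxel_size, pad_mm = 14,
                              volume_tol_frac = 0.02) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (voxel_size < 1 || voxel_size > 4)
    stop("voxel_size must be between 1 and 4 mm")
  half <- spec$head_semiaxes_mm + pad_mm
  n <- 2 * floor(half / voxel_size) + 1   # odd counts: a voxel centred at 0
  coords <- lapply(1:3, function(a)
    (seq_len(n[a]) - (n[a] + 1) / 2) * voxel_size)
  x <- coords[[1]]; y <- coords[[2]]; z <- coords[[3]]
  X <- array(rep(x, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(z, each = n[1] * n[2]), dim = n)
  head_mask <- in_ellipsoid(X, Y, Z, c(0, 0, 0), spec$head_semiaxes_mm)
  vox_ml <- voxel_size^3 / 1000
  ## volume-matched striatal rasterization: take the k voxels with the
  ## smallest ellipsoid quadratic form, k = nearest count to the physical
  ## volume (digital volume then within vox_ml/2 of the specification)
  striatal_mask <- function(centre) {
    q <- ((X - centre[1]) / spec$striatal_semiaxes_mm[1])^2 +
      ((Y - centre[2]) / spec$striatal_semiaxes_mm[2])^2 +
      ((Z - centre[3]) / spec$striatal_semiaxes_mm[3])^2
    k <- max(1L, round(spec$striatal_volume_ml / vox_ml))
    cand <- which(q <= 1.3)
    if (length(cand) < k)
      stop("rasterization error: striatal compartment not representable at ",
           voxel_size, " mm voxels")
    mask <- array(FALSE, dim = n)
    mask[cand[order(q[cand])[seq_len(k)]]] <- TRUE
    mask
  }
  right_mask <- striatal_mask(spec$centre_right_mm)
  left_mask <- striatal_mask(spec$centre_left_mm)
  for (m in list(right_mask, left_mask)) {
    dig_vol <- sum(m) * vox_ml
    if (abs(dig_vol - spec$striatal_volume_ml) >
        volume_tol_frac * spec$striatal_volume_ml)
      stop("rasterization error: digital striatal volume ",
           signif(dig_vol, 4), " mL deviates from the specified ",
           spec$striatal_volume_ml, " mL by more than ",
           100 * volume_tol_frac, "%")
  }
  data <- array(0, dim = n)
  data[head_mask] <- spec$background_conc
  data[right_mask] <- spec$striatal_conc_right
  data[left_mask] <- spec$striatal_conc_left
  vol <- spect_volume(data, spacing = rep(voxel_size, 3))
  attr(vol, "phantom") <- list(
    spec = spec,
    head_mask = head_mask,
    right_mask = right_mask,
    left_mask = left_mask,
    centre_right_mm = spec$centre_right_mm,
    centre_left_mm = spec$centre_left_mm,
    true_sbr = true_sbr(spec)
  )
  vol
}
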