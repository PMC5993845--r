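#' SPECT count volume
#'
#' Minimal container for a 3-D SPECT count volume: a numeric array of voxel
#' count concentrations plus voxel spacing (mm) and the world coordinate of
#' the first voxel centre. Axes follow RAS+ order: the first axis runs
#' left-to-right, the second posterior-to-anterior, the third
#' inferior-to-superior.
#'
#' @param data 3-D numeric array of voxel values (count concentration).
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @param origin numeric length-3, world (mm) coordinate of voxel (1,1,1)
#'   centre. Defaults to centring the grid on the world origin.
#' @return an object of class `spect_volume`.
#' @export
spect_volume <- function(data, spacing, origin = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  cat("<spect_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, total counts ", signif(sum(x$data), 6), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spect_volume <- function(x) dim(x$data)

## world mm <-> (fractional) 1-based voxel index
mm_to_voxel <- function(vol, xyz) (xyz - vol$origin) / vol$spacing + 1
voxel_to_mm <- function(vol, ijk) vol$origin + (ijk - 1) * vol$spacing

## mm coordinates of every voxel centre along one axis
axis_coords <- function(vol, axis)
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]

voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' Read a SPECT volume from a NIfTI-1 file
#'
#' The image is reoriented to RAS+ so that the left/right axis convention of
#' all downstream quantification holds regardless of how the file was stored.
#'
#' @param path path to a 3-D NIfTI-1 file.
#' @return a [spect_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(img)), "-D data in ", path)
  RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  spect_volume(array(as.numeric(img), dim = dim(img)), sp, origin)
}

#' Write a SPECT volume to a NIfTI-1 file
#'
#' Data are stored as float32 in RAS+ orientation; `write_volume()` followed
#' by [read_volume()] is lossless for float32 values.
#'
#' @param volume a [spect_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "spect_volume"))
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  arr <- array(volume$data, dim = dim(volume$data))
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Separable Gaussian blur of a volume
#'
#' Count-conserving (column-normalised truncated kernel) separable Gaussian
#' filter, parameterised by full width at half maximum in mm.
#'
#' @param volume a [spect_volume()].
#' @param fwhm_mm full width at half maximum of the Gaussian point-spread
#'   function, in mm (scalar, isotropic). 0 returns the input unchanged.
#' @return blurred [spect_volume()].
#' @export
gaussian_blur <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "spect_volume"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  out <- volume$data
  for (axis in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / volume$spacing[axis]
    out <- blur_along_axis(out, axis, sigma_vox)
  }
  vol2 <- volume
  vol2$data <- out
  vol2
}

## Dense kernel-matrix product along one axis; columns normalised so each
## input voxel distributes unit weight (total counts conserved away from the
## grid boundary truncation).
blur_along_axis <- function(arr, axis, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  n <- dim(arr)[axis]
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma_vox^2)))
  K[abs(row(K) - col(K)) > ceiling(4 * sigma_vox)] <- 0
  K <- sweep(K, 2, colSums(K), "/")
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- K %*% matrix(a, nrow = n)
  aperm(array(m, dim = d), order(perm))
}
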