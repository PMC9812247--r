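#' Construct a brain volume
#'
#' A minimal volumetric container: a 3D numeric array with voxel size in mm
#' and an origin mapping voxel indices to spatial coordinates (mm of voxel
#' center `i` = `origin + (i - 0.5) * voxel_size`). Zero is the background
#' sentinel throughout the package: maps where 0 is a legitimate value must
#' be offset upstream.
#'
#' @param values 3D numeric array.
#' @param voxel_size positive mm triple (scalar recycled).
#' @param origin mm triple.
#' @return object of class `brain_volume`.
#' @export
brain_volume <- function(values, voxel_size = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_imtx("volume payload must be a 3D array, got %s dimension(s)",
              paste(dim(values) %||% length(values), collapse = "x"))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop_imtx("voxel_size must be positive")
  structure(list(values = values,
                 voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "brain_volume")
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [brain_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_imtx("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_imtx("format error reading '%s': %s", path,
                              conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop_imtx("expected a 3D volume, got %dD payload (%s)",
              length(d), paste(d, collapse = "x"))
  vs <- RNifti::pixdim(img)[seq_len(3)]
  brain_volume(array(as.numeric(img), dim = d), voxel_size = vs)
}

#' Write a brain volume as NIfTI-1
#'
#' @param vol a [brain_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# apply a renormalized truncated kernel along one axis of a 3D array
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  n <- dim(arr)[axis]
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  out <- M %*% matrix(a, nrow = n)
  dim(out) <- d
  aperm(out, order(perm))
}

#' Smooth a volume with a Gaussian kernel
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis in mm, converted to voxels via the voxel size. Kernels are truncated
#' at 4 sigma and renormalized at the array boundary, so a constant volume
#' stays constant everywhere. `fwhm = 0` is the identity.
#'
#' @param vol a [brain_volume()].
#' @param fwhm_mm full width at half maximum in mm, scalar or triple.
#' @return a smoothed [brain_volume()].
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "brain_volume"))
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm < 0)) stop_imtx("fwhm must be nonnegative")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size
  out <- vol$values
  for (axis in 1:3) {
    out <- conv_axis(out, gauss_kernel_1d(sigma_vox[axis]), axis)
  }
  brain_volume(out, voxel_size = vol$voxel_size, origin = vol$origin)
}
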