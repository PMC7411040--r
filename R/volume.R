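#' PET volume and VOI mask containers
#'
#' A `pet_volume` holds a 3D grid of SUV values (body-weight standardized
#' uptake, dimensionless) together with the physical voxel spacing in mm and
#' optional patient metadata (sex, weight in kg, height in cm) needed for
#' lean-body-mass features. A `voi_mask` is a logical array of the same shape
#' marking the lesion volume of interest.
#'
#' @param voxels 3D numeric array of SUV values (all finite, `>= 0`).
#' @param spacing numeric length-3, voxel edge lengths in mm (`> 0`).
#' @param patient_meta optional list with `sex` (`"M"`/`"F"`), `weight_kg`,
#'   `height_cm`.
#' @return `pet_volume()` an object of class `pet_volume`; `voi_mask()` an
#'   object of class `voi_mask`.
#' @examples
#' v <- pet_volume(array(1, c(4, 4, 4)), spacing = c(4.3, 4.3, 3.9))
#' m <- voi_mask(array(TRUE, c(4, 4, 4)), spacing = c(4.3, 4.3, 3.9))
#' @export
pet_volume <- function(voxels, spacing, patient_meta = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L) {
    abort("`voxels` must be a non-empty 3D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  if (any(!is.finite(voxels))) abort("`voxels` must be finite.")
  if (any(voxels < 0)) abort("SUV voxel values must be >= 0.")
  structure(
    list(voxels = voxels, spacing = spacing, patient_meta = patient_meta),
    class = "pet_volume"
  )
}

#' @rdname pet_volume
#' @param mask logical 3D array.
#' @export
voi_mask <- function(mask, spacing) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3D logical array.")
  }
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) abort("VOI mask must contain at least one voxel.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  structure(list(mask = mask, spacing = spacing), class = "voi_mask")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = " x "), " mm\n",
      "  SUV range: ", signif(min(x$voxels), 4), " - ",
      signif(max(x$voxels), 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", sum(x$mask), " voxels, ",
      signif(mtv(x), 4), " cm^3\n", sep = "")
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$mask))) {
    abort("Volume and mask grids have different shapes.")
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9) {
    abort("Volume and mask voxel spacings differ.")
  }
  invisible(TRUE)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti that carry voxel spacing through the NIfTI
#' pixdim header field. Masks are stored as 0/1 integer volumes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param patient_meta optional metadata list attached to the returned volume.
#' @return `read_pet_volume()` a [pet_volume()]; `read_voi_mask()` a
#'   [voi_mask()]; writers return `path` invisibly.
#' @export
read_pet_volume <- function(path, patient_meta = NULL) {
  img <- RNifti::readNifti(path)
  pet_volume(array(as.numeric(img), dim(img)[1:3]),
             spacing = RNifti::pixdim(img)[1:3],
             patient_meta = patient_meta)
}

#' @rdname read_pet_volume
#' @param volume a [pet_volume()].
#' @export
write_pet_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_pet_volume
#' @export
read_voi_mask <- function(path) {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_pet_volume
#' @param mask a [voi_mask()].
#' @export
write_voi_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
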