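#' Quantize in-mask SUVs to discrete gray levels
#'
#' Uniform binning of the in-mask intensity range `[min, max]` into `levels`
#' bins (the fixed-bin-number convention); the top edge is
#' inclusive so the maximum maps to level `levels`. A constant VOI
#' (degenerate range) maps every voxel to level 1.
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()] aligned to `volume`.
#' @param levels number of gray levels (`>= 2`), default 64.
#' @return object of class `quantized_voi`: list with `levels_arr` (integer
#'   array, `NA` outside the mask), `n_levels`, `mask`, `spacing`.
#' @export
quantize_voi <- function(volume, mask, levels = 64L) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"))
  check_aligned(volume, mask)
  levels <- as.integer(levels)
  if (levels < 2L) abort("`levels` must be >= 2.")
  vals <- volume$voxels[mask$mask]
  if (length(vals) == 0L) abort("empty mask")
  rng <- range(vals)
  q <- array(NA_integer_, dim(volume$voxels))
  if (rng[2] - rng[1] <= 0) {
    q[mask$mask] <- 1L
  } else {
    lev <- pmin(levels,
                1L + floor((volume$voxels[mask$mask] - rng[1]) /
                             (rng[2] - rng[1]) * levels))
    q[mask$mask] <- as.integer(lev)
  }
  structure(list(levels_arr = q, n_levels = levels, mask = mask$mask,
                 spacing = mask$spacing),
            class = "quantized_voi")
}
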