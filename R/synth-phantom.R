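#' Specify a synthetic lesion
#'
#' Parameters of an ellipsoidal FDG-avid lesion used by
#' [make_lesion_phantom()]. Intensities are SUV; geometry is in mm.
#' `heterogeneity_sd` is the amplitude of a smoothed Gaussian random field
#' (white noise convolved with a Gaussian kernel of correlation length
#' `heterogeneity_corr_mm`) added inside the lesion to emulate intratumoral
#' texture; `edge_blur_sigma` softens the lesion boundary; `noise_sd` is
#' additive Gaussian noise over the whole grid.
#'
#' @param center mm coordinates of the ellipsoid center (length 3).
#' @param radii mm semi-axes (length 3, `> 0`).
#' @param peak_suv,background_suv SUV levels; `peak_suv > background_suv >= 0`.
#' @param heterogeneity_sd,edge_blur_sigma,noise_sd non-negative SD/scale
#'   parameters (SUV, mm, SUV).
#' @param heterogeneity_corr_mm correlation length of the texture field, mm.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radii, peak_suv = 12, background_suv = 1,
                        heterogeneity_sd = 0, edge_blur_sigma = 0,
                        noise_sd = 0, heterogeneity_corr_mm = 8) {
  center <- as.numeric(center); radii <- as.numeric(radii)
  if (length(center) != 3L || length(radii) != 3L) {
    abort("`center` and `radii` must have length 3.")
  }
  if (any(radii <= 0)) abort("`radii` must be positive.")
  if (!(peak_suv > background_suv) || background_suv < 0) {
    abort("Require peak_suv > background_suv >= 0.")
  }
  if (heterogeneity_sd < 0 || edge_blur_sigma < 0 || noise_sd < 0 ||
      heterogeneity_corr_mm <= 0) {
    abort("SD and correlation-length parameters must be non-negative.")
  }
  structure(list(center = center, radii = radii, peak_suv = peak_suv,
                 background_suv = background_suv,
                 heterogeneity_sd = heterogeneity_sd,
                 edge_blur_sigma = edge_blur_sigma, noise_sd = noise_sd,
                 heterogeneity_corr_mm = heterogeneity_corr_mm),
            class = "lesion_spec")
}

#' Generate a phantom PET volume with ground-truth mask
#'
#' Builds an ellipsoidal lesion on a background grid: the sharp indicator of
#' the ellipsoid (voxel centers inside) is optionally blurred with a Gaussian
#' of `edge_blur_sigma` mm, scaled between `background_suv` and `peak_suv`,
#' textured inside the lesion by a smoothed Gaussian random field, and
#' overlaid with additive Gaussian noise. Negative values are clipped at 0
#' (SUV is non-negative). The returned mask is the exact ground truth
#' (centers inside the ellipsoid), so the true metabolic tumor volume equals
#' voxel count times voxel volume.
#'
#' Deterministic for a fixed `seed`.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param spacing mm per axis; default 3.9 x 3.9 x 3.3 mm (a common
#'   whole-body PET reconstruction grid).
#' @param spec a [lesion_spec()].
#' @param seed integer RNG seed.
#' @return list with `volume` ([pet_volume()]) and `mask` ([voi_mask()]).
#' @examples
#' ph <- make_lesion_phantom(
#'   c(32, 32, 32), c(3, 3, 3),
#'   lesion_spec(center = c(46, 46, 46), radii = c(20, 20, 20)), seed = 1
#' )
#' mtv(ph$mask)
#' @export
make_lesion_phantom <- function(grid_shape, spacing = c(3.9, 3.9, 3.3),
                                spec, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, length(spacing) == 3L)
  extent <- grid_shape * spacing
  pad <- spec$radii + 3 * spec$edge_blur_sigma
  for (ax in 1:3) {
    if (spec$center[ax] - pad[ax] < 0 || spec$center[ax] + pad[ax] > extent[ax]) {
      abort(sprintf(
        "Ellipsoid (plus 3 blur sigmas) overflows the grid on axis %s.",
        c("x", "y", "z")[ax]))
    }
  }

  cx <- (seq_len(grid_shape[1]) - 1) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 1) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 1) * spacing[3]
  dx2 <- ((cx - spec$center[1]) / spec$radii[1])^2
  dy2 <- ((cy - spec$center[2]) / spec$radii[2])^2
  dz2 <- ((cz - spec$center[3]) / spec$radii[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  truth <- r2 <= 1

  indicator <- array(as.numeric(truth), grid_shape)
  if (spec$edge_blur_sigma > 0) {
    indicator <- gauss_smooth3d(indicator, spec$edge_blur_sigma / spacing)
  }
  vox <- spec$background_suv + (spec$peak_suv - spec$background_suv) * indicator

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (spec$heterogeneity_sd > 0) {
    field <- array(rnorm(prod(grid_shape)), grid_shape)
    field <- gauss_smooth3d(field, spec$heterogeneity_corr_mm / spacing)
    fsd <- sd(field)
    if (fsd > 0) field <- field / fsd * spec$heterogeneity_sd
    vox <- vox + field * as.numeric(truth)
  }
  if (spec$noise_sd > 0) {
    vox <- vox + array(rnorm(prod(grid_shape), sd = spec$noise_sd), grid_shape)
  }
  vox[vox < 0] <- 0

  list(volume = pet_volume(vox, spacing),
       mask = voi_mask(truth, spacing))
}

# Save/restore the global RNG state so generators are self-seeding without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
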