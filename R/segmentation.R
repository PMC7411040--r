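#' Gradient-based tumor segmentation from a seed point
#'
#' Emulates interactive six-axis gradient delineation: the volume is smoothed
#' with a Gaussian (sigma = 1 voxel per axis); rays are cast from the seed
#' along +/-x, +/-y, +/-z; each axis is stopped at the sample with the
#' most-negative directional derivative within `search_limit` mm (the
#' steepest intensity drop, i.e. the metabolic edge). The edge threshold is
#' the mean smoothed SUV at the six edge points, and the VOI is the
#' 26-connected component containing the seed of voxels at or above that
#' threshold, clipped to the axis-aligned ellipsoid spanned by the detected
#' axis lengths dilated by two voxels.
#'
#' @param volume a [pet_volume()].
#' @param seed_voxel integer voxel index triple (1-based) inside the grid.
#' @param search_limit maximal axis length searched, mm.
#' @return a [voi_mask()] containing the seed.
#' @examples
#' ph <- make_lesion_phantom(
#'   c(32, 32, 32), c(3, 3, 3),
#'   lesion_spec(center = c(46, 46, 46), radii = c(18, 18, 18)), seed = 1
#' )
#' m <- gradient_segment(ph$volume, seed_voxel = c(16, 16, 16) + 1)
#' mtv(m)
#' @export
gradient_segment <- function(volume, seed_voxel, search_limit = 60) {
  stopifnot(inherits(volume, "pet_volume"))
  dm <- dim(volume$voxels)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > dm)) {
    abort("`seed_voxel` must be a voxel index triple inside the grid.")
  }
  if (volume$voxels[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <= 0) {
    abort("invalid seed: zero-intensity voxel")
  }
  sm <- gauss_smooth3d(volume$voxels, c(1, 1, 1))
  spacing <- volume$spacing

  # per signed direction: index of the steepest negative step
  axis_len_vox <- matrix(NA_integer_, nrow = 3L, ncol = 2L,
                         dimnames = list(c("x", "y", "z"), c("neg", "pos")))
  edge_vals <- numeric(0)
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nmax <- floor(search_limit / spacing[ax])
      steps <- seq_len(nmax)
      pos <- seed_voxel[ax] + sgn * c(0L, steps)
      pos <- pos[pos >= 1L & pos <= dm[ax]]
      idx <- matrix(rep(seed_voxel, each = length(pos)), ncol = 3L)
      idx[, ax] <- pos
      prof <- sm[idx]
      if (length(prof) < 2L) abort("no edge detected")
      d <- diff(prof)
      if (min(d) >= 0) abort("no edge detected")
      i_edge <- which.min(d) + 1L  # sample after the steepest drop
      axis_len_vox[ax, if (sgn < 0) "neg" else "pos"] <- i_edge - 1L
      # edge intensity at the gradient maximum, midway between the two
      # samples bracketing the steepest drop (half-maximum for a smoothed
      # sharp boundary)
      edge_vals <- c(edge_vals, (prof[i_edge - 1L] + prof[i_edge]) / 2)
    }
  }
  thr <- mean(edge_vals)

  region <- sm >= thr
  # clip to the detected axis-aligned extents, dilated by 2 voxels
  ix <- slice.index(region, 1L) - seed_voxel[1]
  iy <- slice.index(region, 2L) - seed_voxel[2]
  iz <- slice.index(region, 3L) - seed_voxel[3]
  rad <- axis_len_vox + 2L
  rx <- ifelse(ix < 0, rad["x", "neg"], rad["x", "pos"])
  ry <- ifelse(iy < 0, rad["y", "neg"], rad["y", "pos"])
  rz <- ifelse(iz < 0, rad["z", "neg"], rad["z", "pos"])
  inside <- (ix / rx)^2 + (iy / ry)^2 + (iz / rz)^2 <= 1
  region <- region & inside

  lab <- label_components26(region)$labels
  seed_lab <- lab[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  if (seed_lab == 0L) {
    # seed sits marginally below the mean-edge threshold; keep the nearest
    # above-threshold component by including the seed itself
    region[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
    lab <- label_components26(region)$labels
    seed_lab <- lab[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  }
  voi_mask(lab == seed_lab, spacing)
}

#' Metabolic tumor volume of a VOI
#'
#' @param mask a [voi_mask()].
#' @return MTV in cm^3 (voxel count times voxel volume).
#' @examples
#' mtv(voi_mask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1)))
#' @export
mtv <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  n <- sum(mask$mask)
  if (n == 0L) abort("empty mask")
  n * prod(mask$spacing) / 1000
}

#' Apply the minimum-volume cohort filter
#'
#' Lesions below the minimum metabolic tumor volume are excluded from
#' texture analysis (texture features are unstable on small volumes); the
#' default cutoff of 10 cm^3 retains lesions with `MTV >= 10`.
#'
#' @param lesions data frame with columns `id` and `mtv_cm3` (`>= 0`).
#' @param min_mtv cutoff in cm^3.
#' @return the input as a tibble with a logical `retained` column.
#' @examples
#' volume_filter(data.frame(id = c("a", "b"), mtv_cm3 = c(9.9, 10)))
#' @export
volume_filter <- function(lesions, min_mtv = 10) {
  lesions <- tibble::as_tibble(lesions)
  if (nrow(lesions) == 0L) {
    return(tibble::tibble(id = character(), mtv_cm3 = numeric(),
                          retained = logical()))
  }
  stopifnot(all(c("id", "mtv_cm3") %in% names(lesions)))
  if (any(lesions$mtv_cm3 < 0)) abort("negative MTV")
  dplyr::mutate(lesions, retained = .data$mtv_cm3 >= min_mtv)
}
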