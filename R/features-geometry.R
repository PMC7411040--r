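# MTV-independent shape features (4). Surface area is estimated with the
# coarea identity: for a smoothed indicator u of the mask,
# integral |grad u| dV equals the average area of its level surfaces, which
# converges to the true boundary area for resolved shapes. The indicator is
# smoothed with an isotropic Gaussian (sigma = 0.8 x min spacing, in mm) and
# the gradient taken by central differences on the physical grid. Very small
# masks (< 27 voxels) leave no room for smoothing and fall back to exact
# voxel-face counting.
#
#   sphericity  = pi^(1/3) (6 V)^(2/3) / A        (1 for a ball)
#   irregularity = 1 / sphericity                 (>= 1, larger = rougher)
#   eccentricity = sqrt(1 - l3 / l1)              (principal-axis ratio of
#                                                  the voxel-center scatter)

surface_area_mm2 <- function(mask) {
  m <- mask$mask
  spacing <- mask$spacing
  if (sum(m) < 27L) {
    # exposed-face count, exact for voxel unions
    area <- 0
    face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
              spacing[1] * spacing[2])
    num <- array(as.numeric(m), dim(m))
    for (ax in 1:3) {
      for (sgn in c(-1L, 1L)) {
        off <- c(0L, 0L, 0L); off[ax] <- sgn
        exposed <- m & !(shift_arr(num, off, fill = 0) > 0.5)
        area <- area + sum(exposed) * face[ax]
      }
    }
    return(area)
  }
  sig_mm <- 0.8 * min(spacing)
  # pad so the smoothed indicator decays inside the grid
  pad <- ceiling(3 * sig_mm / spacing) + 1L
  dmp <- dim(m) + 2L * pad
  big <- array(0, dmp)
  big[pad[1] + seq_len(dim(m)[1]), pad[2] + seq_len(dim(m)[2]),
      pad[3] + seq_len(dim(m)[3])] <- as.numeric(m)
  u <- gauss_smooth3d(big, sig_mm / spacing)
  g2 <- array(0, dmp)
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    d <- (shift_arr(u, -off, fill = 0) - shift_arr(u, off, fill = 0)) /
      (2 * spacing[ax])
    g2 <- g2 + d^2
  }
  sum(sqrt(g2)) * prod(spacing)
}

geometry_features <- function(mask) {
  A <- surface_area_mm2(mask)
  V <- sum(mask$mask) * prod(mask$spacing)  # mm^3
  spher <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  co <- arrayInd(which(mask$mask), dim(mask$mask))
  ecc <- 0
  if (nrow(co) > 3L) {
    xyz <- voxel_centers_mm(co, mask$spacing)
    ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] > 0) ecc <- sqrt(max(0, 1 - ev[3] / ev[1]))
  }
  c(
    geom_surface_area = A / 100,  # cm^2
    geom_sphericity = spher,
    geom_irregularity = 1 / spher,
    geom_eccentricity = ecc
  )
}
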