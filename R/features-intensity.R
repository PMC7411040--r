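# SUV / intensity-histogram features (25) computed on the raw in-mask SUVs.
# SUL features use the James sex-specific lean-body-mass formula:
#   LBM(male)   = 1.10 W - 128 (W/H)^2
#   LBM(female) = 1.07 W - 148 (W/H)^2   (W kg, H cm)
# and SUL = SUV * LBM / W. Entropy and uniformity use the 64-bin in-mask
# histogram; entropy is in bits.

james_lbm <- function(sex, weight_kg, height_cm) {
  if (is.null(sex) || is.null(weight_kg) || is.null(height_cm) ||
      is.na(sex) || is.na(weight_kg) || is.na(height_cm)) {
    return(NA_real_)
  }
  r <- weight_kg / height_cm
  if (toupper(substr(sex, 1, 1)) == "M") 1.10 * weight_kg - 128 * r^2
  else 1.07 * weight_kg - 148 * r^2
}

# Mean SUV in the 1 cm^3 sphere (radius 6.2 mm) positioned at the in-mask
# voxel center maximizing that mean; the sphere may extend beyond the mask
# but is truncated at the grid.
suv_peak <- function(volume, mask) {
  spacing <- volume$spacing
  r_mm <- 6.2
  rv <- pmax(0L, floor(r_mm / spacing))
  offs <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2],
                                dz = -rv[3]:rv[3]))
  dist2 <- (offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
    (offs[, 3] * spacing[3])^2
  offs <- offs[dist2 <= r_mm^2, , drop = FALSE]
  acc <- array(0, dim(volume$voxels))
  cnt <- array(0, dim(volume$voxels))
  ones <- array(1, dim(volume$voxels))
  for (i in seq_len(nrow(offs))) {
    acc <- acc + shift_arr(volume$voxels, -offs[i, ], fill = 0)
    cnt <- cnt + shift_arr(ones, -offs[i, ], fill = 0)
  }
  max((acc / cnt)[mask$mask])
}

# SD over in-mask voxels having at least one out-of-mask 6-neighbor.
surface_suv_sd <- function(volume, mask) {
  m <- mask$mask
  interior <- m
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- sgn
      interior <- interior & shift_arr(array(as.numeric(m), dim(m)), off,
                                       fill = 0) > 0.5
    }
  }
  surf <- m & !interior
  if (!any(surf)) surf <- m  # mask with no interior: all voxels are surface
  v <- volume$voxels[surf]
  if (length(v) < 2L) 0 else sd(v)
}

intensity_features <- function(volume, mask, levels = 64L) {
  check_aligned(volume, mask)
  x <- volume$voxels[mask$mask]
  n <- length(x)
  mtv_cm3 <- mtv(mask)
  mu <- mean(x)
  s <- if (n > 1L) sd(x) else 0
  # 64-bin histogram over in-mask range
  rng <- range(x)
  if (rng[2] > rng[1]) {
    b <- pmin(levels, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * levels))
  } else {
    b <- rep(1L, n)
  }
  p <- tabulate(b, nbins = levels) / n
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  unif <- sum(p^2)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 - 3 else 0
  meta <- volume$patient_meta
  lbm <- james_lbm(meta$sex, meta$weight_kg, meta$height_cm)
  sul_scale <- if (is.na(lbm) || is.null(meta$weight_kg)) NA_real_
  else lbm / meta$weight_kg
  pk <- suv_peak(volume, mask)
  qs <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  c(
    suv_max = max(x),
    suv_mean = mu,
    suv_min = min(x),
    suv_sd = s,
    suv_peak = pk,
    sul_max = max(x) * sul_scale,
    sul_mean = mu * sul_scale,
    sul_peak = pk * sul_scale,
    surface_suv_sd = surface_suv_sd(volume, mask),
    mtv = mtv_cm3,
    tlg = mu * mtv_cm3,
    suv_skewness = skew,
    suv_kurtosis = kurt,
    hist_entropy = ent,
    hist_uniformity = unif,
    suv_cov = if (mu > 0) s / mu else 0,
    suv_median = qs[3],
    suv_p10 = qs[1],
    suv_p25 = qs[2],
    suv_p75 = qs[4],
    suv_p90 = qs[5],
    suv_iqr = qs[4] - qs[2],
    suv_range = max(x) - min(x),
    suv_mad = mean(abs(x - mu)),
    suv_rms = sqrt(mean(x^2))
  )
}
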