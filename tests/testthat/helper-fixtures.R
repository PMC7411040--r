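# Shared fixtures built in code at test time.

# Digital ball mask on an isotropic grid.
make_ball_mask <- function(r_vox, spacing = c(1, 1, 1), margin = 4L) {
  n <- 2L * ceiling(r_vox) + 2L * margin + 1L
  c0 <- (n - 1) / 2
  d2 <- outer(outer((seq_len(n) - 1 - c0)^2, (seq_len(n) - 1 - c0)^2, "+"),
              (seq_len(n) - 1 - c0)^2, "+")
  voi_mask(d2 <= r_vox^2, spacing)
}

# Uniform-intensity volume over a given mask shape.
constant_volume <- function(mask, value = 5, background = 0,
                            patient_meta = NULL) {
  v <- array(background, dim(mask$mask))
  v[mask$mask] <- value
  pet_volume(v, mask$spacing, patient_meta = patient_meta)
}

# Sharp noise-free sphere phantom used by the segmentation tests.
sphere_phantom <- function(radius_mm = 20, spacing = c(2, 2, 2),
                           peak = 10, background = 0, n = 36) {
  ctr <- (n - 1) / 2 * spacing
  make_lesion_phantom(
    rep(n, 3), spacing,
    lesion_spec(center = ctr, radii = rep(radius_mm, 3), peak_suv = peak,
                background_suv = background),
    seed = 1)
}

# Quantized VOI built directly from an integer array (NA outside mask).
qvoi_from_array <- function(qarr, levels) {
  structure(list(levels_arr = qarr, n_levels = as.integer(levels),
                 mask = !is.na(qarr), spacing = c(1, 1, 1)),
            class = "quantized_voi")
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
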