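# Texture feature coding (TFC). Each in-mask voxel is assigned a discrete
# code summarizing the local gray-level gradient pattern on the quantized
# VOI. For each of the 13 symmetric lattice axes with both opposite
# neighbors in the mask, the pair of level differences
#   g1 = q(v + d) - q(v),  g2 = q(v - d) - q(v)
# is classified (zero tolerance) into
#   1 "flat"     g1 = 0 and g2 = 0
#   2 "slope"    g1 * g2 < 0        (monotone ramp through the voxel)
#   3 "extremum" g1 * g2 > 0        (local ridge or valley)
#   4 "step"     exactly one of g1, g2 is 0
# The voxel code is the sum of its axis classes, with axes lacking an
# in-mask opposite pair counted as flat, so codes range over 13..52 and a
# constant VOI maps every voxel to code 13. Codes depend only on the
# ordering of quantized levels, hence are invariant to order-preserving
# intensity rescaling.
#
# TFC features are first-order statistics of the code image; the two
# texture-spectrum features summarize the pooled axis-class histogram; the
# TFCCM features are co-occurrence statistics of rank-indexed codes between
# 26-neighbors (13 symmetric axes, distance 1).

tfc_code_image <- function(q) {
  a <- q$levels_arr
  dirs <- directions13()
  code <- array(0L, dim(a))
  class_counts <- c(flat = 0, slope = 0, extremum = 0, step = 0)
  n_axes <- nrow(dirs)
  for (d in seq_len(n_axes)) {
    fw <- shift_arr(a, dirs[d, ], fill = NA_integer_)
    bw <- shift_arr(a, -dirs[d, ], fill = NA_integer_)
    g1 <- fw - a
    g2 <- bw - a
    valid <- !is.na(a) & !is.na(g1) & !is.na(g2)
    cls <- array(1L, dim(a))  # default flat (also for invalid axes)
    prod_ <- g1 * g2
    cls[valid & prod_ < 0] <- 2L
    cls[valid & prod_ > 0] <- 3L
    cls[valid & prod_ == 0 & (g1 != 0 | g2 != 0)] <- 4L
    cls[is.na(a)] <- NA_integer_
    code <- code + ifelse(is.na(a), NA_integer_, cls)
    tabv <- tabulate(cls[valid], nbins = 4L)
    class_counts <- class_counts + tabv
  }
  list(code = code, class_counts = class_counts, n_axes = n_axes)
}

tfc_features <- function(q) {
  ci <- tfc_code_image(q)
  codes <- ci$code[!is.na(ci$code)]
  n <- length(codes)
  n_axes <- ci$n_axes
  # normalized mean deviation of codes from the all-flat floor
  conv <- mean(codes - n_axes) / (3 * n_axes)
  f <- table(codes) / n
  c(
    tfc_mean_convergence = conv,
    tfc_variance = mean((codes - mean(codes))^2),
    tfc_code_entropy = -sum(f * log2(f))
  )
}

texture_spectrum_features <- function(q) {
  ci <- tfc_code_image(q)
  cc <- ci$class_counts
  tot <- sum(cc)
  p <- if (tot > 0) cc / tot else c(1, 0, 0, 0)
  c(
    ts_peak_fraction = max(p),
    ts_uniformity = sum(p^2)
  )
}

tfccm_features <- function(q) {
  ci <- tfc_code_image(q)
  code <- ci$code
  # rank-index the observed codes to 1..C so distances are in code-rank units
  obs <- sort(unique(code[!is.na(code)]))
  r <- array(NA_integer_, dim(code))
  r[!is.na(code)] <- match(code[!is.na(code)], obs)
  C <- length(obs)
  dirs <- directions13()
  P <- matrix(0, C, C)
  for (d in seq_len(nrow(dirs))) {
    b <- shift_arr(r, dirs[d, ], fill = NA_integer_)
    ok <- !is.na(r) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(r[ok], levels = 1:C), factor(b[ok], levels = 1:C))
    P <- P + unclass(tab)
  }
  if (sum(P) == 0) abort("no voxel pairs")
  P <- P + t(P)
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  nz <- P > 0
  c(
    tfccm_sam = sum(P^2),
    tfccm_contrast = sum((i - j)^2 * P),
    tfccm_entropy = -sum(P[nz] * log2(P[nz])),
    tfccm_idm = sum(P / (1 + (i - j)^2)),
    tfccm_code_similarity = sum(P / (1 + abs(i - j)))
  )
}
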