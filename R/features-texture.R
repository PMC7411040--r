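# Gray-level texture-matrix features. All matrix families use the 13 unique
# distance-1 directions of the 3D lattice; co-occurrences are made symmetric
# by counting each ordered pair both ways. Direction-dependent families
# (GLCM, GLRM) compute features per direction and average them; GLSZM and
# NGLD are direction-free (26-connectivity / 26-neighborhood).

# --- GLCM ------------------------------------------------------------------

# Symmetric co-occurrence probability matrix for one direction.
glcm_matrix <- function(q, dir) {
  a <- q$levels_arr
  b <- shift_arr(a, dir, fill = NA_integer_)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  L <- q$n_levels
  tab <- matrix(0, L, L)
  counts <- table(factor(a[ok], levels = 1:L), factor(b[ok], levels = 1:L))
  tab <- unclass(counts)
  tab <- tab + t(tab)  # symmetric
  tab / sum(tab)
}

glcm_features_one <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  contrast <- sum((i - j)^2 * P)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  # sum / difference distributions
  s_idx <- 2:(2 * L)
  ps <- vapply(s_idx, function(k) sum(P[(i + j) == k]), numeric(1))
  d_idx <- 0:(L - 1)
  pd <- vapply(d_idx, function(k) sum(P[abs(i - j) == k]), numeric(1))
  sum_mean <- sum(s_idx * ps)
  diff_mean <- sum(d_idx * pd)
  nzs <- ps > 0; nzd <- pd > 0
  c(
    glcm_energy = sum(P^2),
    glcm_contrast = contrast,
    glcm_norm_contrast = if (L > 1) contrast / (L - 1)^2 else 0,
    glcm_entropy = entropy,
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_correlation = corr,
    glcm_variance = sig2,
    glcm_sum_mean = sum_mean,
    glcm_sum_variance = sum((s_idx - sum_mean)^2 * ps),
    glcm_sum_entropy = -sum(ps[nzs] * log2(ps[nzs])),
    glcm_diff_mean = diff_mean,
    glcm_diff_variance = sum((d_idx - diff_mean)^2 * pd),
    glcm_diff_entropy = -sum(pd[nzd] * log2(pd[nzd])),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P)
  )
}

glcm_features <- function(q) {
  dirs <- directions13()
  feats <- NULL
  k <- 0L
  for (d in seq_len(nrow(dirs))) {
    P <- glcm_matrix(q, dirs[d, ])
    if (is.null(P)) next
    f <- glcm_features_one(P)
    feats <- if (is.null(feats)) f else feats + f
    k <- k + 1L
  }
  if (k == 0L) abort("no voxel pairs")
  feats / k
}

# --- GLRM ------------------------------------------------------------------

# Run-length matrix (levels x run length) for one direction.
glrm_matrix <- function(q, dir) {
  a <- q$levels_arr
  idx <- which(!is.na(a))
  if (length(idx) == 0L) return(NULL)
  co <- arrayInd(idx, dim(a))
  lev <- a[idx]
  # parameterize each lattice line x = p + t*dir by t along the first
  # nonzero direction axis; the line key is the position minus t*dir
  ax <- which(dir != 0)[1]
  t <- co[, ax] * dir[ax]  # dir entries are +/-1 on nonzero axes
  key <- co - outer(t, dir)
  keystr <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  n_vox <- length(idx)
  Lmax <- max(dim(a))
  R <- matrix(0, q$n_levels, Lmax)
  for (ln in split(seq_along(t), keystr)) {
    o <- ln[order(t[ln])]
    tt <- t[ln][order(t[ln])]
    lv <- lev[o]
    brk <- c(TRUE, diff(tt) != 1L | diff(lv) != 0L)
    run_id <- cumsum(brk)
    rl <- tabulate(run_id)
    rg <- lv[brk]
    for (r in seq_along(rl)) R[rg[r], rl[r]] <- R[rg[r], rl[r]] + 1
  }
  list(R = R, n_vox = n_vox)
}

glrm_features_one <- function(R, n_vox) {
  nr <- sum(R)
  g <- row(R); l <- col(R)
  rg <- rowSums(R); rl <- colSums(R)
  c(
    glrm_sre = sum(R / l^2) / nr,
    glrm_lre = sum(R * l^2) / nr,
    glrm_lgre = sum(R / g^2) / nr,
    glrm_hgre = sum(R * g^2) / nr,
    glrm_srlge = sum(R / (g^2 * l^2)) / nr,
    glrm_srhge = sum(R * g^2 / l^2) / nr,
    glrm_lrlge = sum(R * l^2 / g^2) / nr,
    glrm_lrhge = sum(R * g^2 * l^2) / nr,
    glrm_glnu = sum(rg^2) / nr,
    glrm_rlnu = sum(rl^2) / nr,
    glrm_rp = nr / n_vox
  )
}

glrm_features <- function(q) {
  dirs <- directions13()
  feats <- NULL
  k <- 0L
  for (d in seq_len(nrow(dirs))) {
    rm <- glrm_matrix(q, dirs[d, ])
    if (is.null(rm)) next
    f <- glrm_features_one(rm$R, rm$n_vox)
    feats <- if (is.null(feats)) f else feats + f
    k <- k + 1L
  }
  if (k == 0L) abort("no voxel pairs")
  feats / k
}

# --- GLSZM -----------------------------------------------------------------

# Size-zone matrix: zones are 26-connected components of equal gray level.
glszm_matrix <- function(q) {
  a <- q$levels_arr
  n_vox <- sum(!is.na(a))
  zones <- list()
  for (g in sort(unique(a[!is.na(a)]))) {
    m <- !is.na(a) & a == g
    cc <- label_components26(m)
    if (cc$n > 0L) {
      sizes <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n)
      zones[[length(zones) + 1L]] <- cbind(g, sizes)
    }
  }
  zs <- do.call(rbind, zones)
  Z <- matrix(0, q$n_levels, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) {
    Z[zs[r, 1], zs[r, 2]] <- Z[zs[r, 1], zs[r, 2]] + 1
  }
  list(Z = Z, n_vox = n_vox)
}

glszm_features <- function(q) {
  zm <- glszm_matrix(q)
  Z <- zm$Z
  nz <- sum(Z)
  g <- row(Z); s <- col(Z)
  zg <- rowSums(Z); zs <- colSums(Z)
  c(
    glszm_sze = sum(Z / s^2) / nz,
    glszm_lze = sum(Z * s^2) / nz,
    glszm_lgze = sum(Z / g^2) / nz,
    glszm_hgze = sum(Z * g^2) / nz,
    glszm_szlge = sum(Z / (g^2 * s^2)) / nz,
    glszm_szhge = sum(Z * g^2 / s^2) / nz,
    glszm_lzlge = sum(Z * s^2 / g^2) / nz,
    glszm_lzhge = sum(Z * g^2 * s^2) / nz,
    glszm_glnu = sum(zg^2) / nz,
    glszm_zsnu = sum(zs^2) / nz,
    glszm_zp = nz / zm$n_vox
  )
}

# --- NGLD ------------------------------------------------------------------

# Dependence count per in-mask voxel: number of its in-mask 26-neighbors
# with the same gray level (tolerance a = 0). Matrix Q over
# (gray level, dependence count 0..26).
ngld_matrix <- function(q) {
  a <- q$levels_arr
  dep <- array(0L, dim(a))
  offs <- offsets26()
  for (i in seq_len(nrow(offs))) {
    nb <- shift_arr(a, offs[i, ], fill = NA_integer_)
    same <- !is.na(a) & !is.na(nb) & a == nb
    dep <- dep + as.integer(same)
  }
  ok <- !is.na(a)
  Q <- matrix(0, q$n_levels, 27L)  # dependence 0..26 -> columns 1..27
  tab <- table(factor(a[ok], levels = 1:q$n_levels),
               factor(dep[ok], levels = 0:26))
  Q[] <- unclass(tab)
  Q
}

ngld_features <- function(q) {
  Q <- ngld_matrix(q)
  n <- sum(Q)
  g <- row(Q)
  d <- col(Q) - 1L  # dependence count
  qg <- rowSums(Q); qd <- colSums(Q)
  p <- Q / n
  nzp <- p > 0
  c(
    ngld_sne = sum(Q / (d + 1)^2) / n,
    ngld_lne = sum(Q * (d + 1)^2) / n,
    ngld_nnu = sum(qd^2) / n,
    ngld_second_moment = sum(Q^2) / n^2,
    ngld_entropy = -sum(p[nzp] * log2(p[nzp])),
    ngld_dcp = sum(Q[, -1L]) / n,
    ngld_glnu = sum(qg^2) / n,
    ngld_lgce = sum(Q / g^2) / n,
    ngld_hgce = sum(Q * g^2) / n
  )
}
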