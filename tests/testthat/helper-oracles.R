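# Independent brute-force oracles for the texture-matrix families and the
# BH procedure. These deliberately use naive per-voxel loops (no array
# shifting, no shared helpers) so they exercise a different code path than
# the package implementation.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

in_grid <- function(v, dm) all(v >= 1) && all(v <= dm)

# Symmetric GLCM probabilities for one direction by exhaustive pair counting.
oracle_glcm_matrix <- function(qarr, L, dir) {
  dm <- dim(qarr)
  M <- matrix(0, L, L)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- qarr[x, y, z]
    if (is.na(a)) next
    v2 <- c(x, y, z) + dir
    if (!in_grid(v2, dm)) next
    b <- qarr[v2[1], v2[2], v2[3]]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracle_glcm_feature <- function(qarr, L, what) {
  vals <- c()
  for (d in seq_len(nrow(oracle_dirs))) {
    P <- oracle_glcm_matrix(qarr, L, oracle_dirs[d, ])
    if (is.null(P)) next
    i <- row(P); j <- col(P)
    v <- switch(what,
      contrast = sum((i - j)^2 * P),
      energy = sum(P^2),
      entropy = { nz <- P > 0; -sum(P[nz] * log2(P[nz])) },
      idm = sum(P / (1 + (i - j)^2)),
      dissimilarity = sum(abs(i - j) * P),
      homogeneity = sum(P / (1 + abs(i - j))))
    vals <- c(vals, v)
  }
  mean(vals)
}

# All maximal runs (gray level, length) for one direction by explicit
# line-walking from run starts.
oracle_runs <- function(qarr, dir) {
  dm <- dim(qarr)
  runs <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- qarr[x, y, z]
    if (is.na(a)) next
    prev <- c(x, y, z) - dir
    prev_val <- if (in_grid(prev, dm)) qarr[prev[1], prev[2], prev[3]] else NA
    is_start <- is.na(prev_val) || prev_val != a
    if (!is_start) next
    len <- 1
    cur <- c(x, y, z) + dir
    while (in_grid(cur, dm) && !is.na(qarr[cur[1], cur[2], cur[3]]) &&
           qarr[cur[1], cur[2], cur[3]] == a) {
      len <- len + 1
      cur <- cur + dir
    }
    runs[[length(runs) + 1]] <- c(level = a, len = len)
  }
  do.call(rbind, runs)
}

oracle_glrm_feature <- function(qarr, what) {
  n_vox <- sum(!is.na(qarr))
  vals <- c()
  for (d in seq_len(nrow(oracle_dirs))) {
    r <- oracle_runs(qarr, oracle_dirs[d, ])
    nr <- nrow(r)
    g <- r[, "level"]; l <- r[, "len"]
    v <- switch(what,
      sre = sum(1 / l^2) / nr,
      lre = sum(l^2) / nr,
      glnu = { tg <- table(g); sum(tg^2) / nr },
      rp = nr / n_vox,
      hgre = sum(g^2) / nr)
    vals <- c(vals, v)
  }
  mean(vals)
}

# Zones by depth-first flood fill with an explicit stack (26-connectivity).
oracle_zones <- function(qarr) {
  dm <- dim(qarr)
  seen <- array(FALSE, dm)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (is.na(qarr[x, y, z]) || seen[x, y, z]) next
    g <- qarr[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (!in_grid(w, dm)) next
        if (seen[w[1], w[2], w[3]]) next
        val <- qarr[w[1], w[2], w[3]]
        if (is.na(val) || val != g) next
        seen[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(level = g, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm_feature <- function(qarr, what) {
  zs <- oracle_zones(qarr)
  nz <- nrow(zs)
  g <- zs[, "level"]; s <- zs[, "size"]
  switch(what,
    sze = sum(1 / s^2) / nz,
    lze = sum(s^2) / nz,
    zp = nz / sum(!is.na(qarr)),
    glnu = { tg <- table(g); sum(tg^2) / nz })
}

# Dependence counts by explicit neighbor loops.
oracle_ngld_counts <- function(qarr) {
  dm <- dim(qarr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- qarr[x, y, z]
    if (is.na(a)) next
    dep <- 0
    for (o in seq_len(nrow(offs))) {
      w <- c(x, y, z) + offs[o, ]
      if (!in_grid(w, dm)) next
      b <- qarr[w[1], w[2], w[3]]
      if (!is.na(b) && b == a) dep <- dep + 1
    }
    out[[length(out) + 1]] <- c(level = a, dep = dep)
  }
  do.call(rbind, out)
}

oracle_ngld_feature <- function(qarr, what) {
  cd <- oracle_ngld_counts(qarr)
  n <- nrow(cd)
  d <- cd[, "dep"]; g <- cd[, "level"]
  switch(what,
    sne = sum(1 / (d + 1)^2) / n,
    lne = sum((d + 1)^2) / n,
    dcp = mean(d >= 1),
    hgce = sum(g^2) / n)
}

# Per-voxel TFC codes by explicit axis loops (flat=1, slope=2, extremum=3,
# step=4; missing opposite pairs count as flat).
oracle_tfc_codes <- function(qarr) {
  dm <- dim(qarr)
  codes <- c()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- qarr[x, y, z]
    if (is.na(a)) next
    code <- 0
    for (d in seq_len(nrow(oracle_dirs))) {
      v1 <- c(x, y, z) + oracle_dirs[d, ]
      v2 <- c(x, y, z) - oracle_dirs[d, ]
      g1 <- if (in_grid(v1, dm)) qarr[v1[1], v1[2], v1[3]] - a else NA
      g2 <- if (in_grid(v2, dm)) qarr[v2[1], v2[2], v2[3]] - a else NA
      cls <- if (is.na(g1) || is.na(g2)) 1
      else if (g1 == 0 && g2 == 0) 1
      else if (g1 * g2 < 0) 2
      else if (g1 * g2 > 0) 3
      else 4
      code <- code + cls
    }
    codes <- c(codes, code)
  }
  codes
}

# Step-up BH by direct minimization over the tail.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random quantized VOI on a small grid: random mask (kept non-degenerate)
# with random levels.
random_qvoi <- function(seed, dim_max = 6L, levels = 4L) {
  set.seed(seed)
  dm <- sample(3:dim_max, 3, replace = TRUE)
  repeat {
    mask <- array(runif(prod(dm)) < 0.7, dm)
    if (sum(mask) >= 8) break
  }
  qarr <- array(NA_integer_, dm)
  qarr[mask] <- sample.int(levels, sum(mask), replace = TRUE)
  # ensure the full level range is present so quantized conventions agree
  idx <- which(mask)
  qarr[idx[1]] <- 1L
  qarr[idx[length(idx)]] <- levels
  structure(list(levels_arr = qarr, n_levels = levels, mask = mask,
                 spacing = c(1, 1, 1)),
            class = "quantized_voi")
}
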