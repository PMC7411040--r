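# Low-level 3D array helpers shared by the phantom generator, the segmenter
# and the texture-matrix builders. All arrays are plain base-R 3D arrays
# indexed [x, y, z], 1-based; physical positions are voxel centers.

# The 13 unique distance-1 direction vectors of the 3D lattice (one per
# +/- pair of the 26-neighborhood).
directions13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(d, 1L, function(v) {
    nz <- v[v != 0]
    nz[1L] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# All 26 neighbor offsets.
offsets26 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(d[rowSums(abs(d)) > 0, , drop = FALSE])
}

# Shift a 3D array by one offset triple, padding with `fill`.
shift_arr <- function(a, off, fill = NA_real_) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(dm[ax] - o)
      dst[[ax]] <- src[[ax]] + o
    } else {
      src[[ax]] <- seq(1L - o, dm[ax])
      dst[[ax]] <- src[[ax]] + o
    }
    if (abs(o) >= dm[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian smoothing; sigma given per axis in voxel units.
# Edge handling: renormalize the kernel over in-grid support (replicate-free,
# mass-preserving at borders).
gauss_smooth3d <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  out <- a
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    acc <- array(0, dim(out))
    wsum <- array(0, dim(out))
    off <- c(0L, 0L, 0L)
    ones <- array(1, dim(out))
    for (i in seq_along(k)) {
      off[ax] <- i - r - 1L
      acc <- acc + k[i] * shift_arr(out, off, fill = 0)
      wsum <- wsum + k[i] * shift_arr(ones, off, fill = 0)
    }
    out <- acc / wsum
  }
  out
}

# Label 26-connected components of a logical 3D array. Returns an integer
# array (0 outside) plus the number of components. Frontier-expansion BFS on
# voxel coordinates; fine for VOI-sized inputs.
label_components26 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0L) return(list(labels = lab, n = 0L))
  coord <- arrayInd(idx, dm)
  key <- function(co) (co[, 3L] - 1L) * dm[1L] * dm[2L] + (co[, 2L] - 1L) * dm[1L] + co[, 1L]
  inmask <- logical(prod(dm))
  inmask[idx] <- TRUE
  visited <- logical(prod(dm))
  offs <- offsets26()
  ncomp <- 0L
  for (start in idx) {
    if (visited[start]) next
    ncomp <- ncomp + 1L
    frontier <- matrix(arrayInd(start, dm), ncol = 3L)
    visited[start] <- TRUE
    lab[start] <- ncomp
    while (nrow(frontier) > 0L) {
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
        sweep(frontier, 2L, offs[i, ], "+")
      }))
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0L) break
      li <- key(nb)
      fresh <- inmask[li] & !visited[li]
      nb <- nb[fresh, , drop = FALSE]
      li <- li[fresh]
      dup <- !duplicated(li)
      nb <- nb[dup, , drop = FALSE]
      li <- li[dup]
      if (length(li) == 0L) break
      visited[li] <- TRUE
      lab[li] <- ncomp
      frontier <- nb
    }
  }
  list(labels = lab, n = ncomp)
}

# Voxel-center physical coordinates (mm) for index triples.
voxel_centers_mm <- function(coord, spacing) {
  sweep(coord - 1, 2L, spacing, "*")
}
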