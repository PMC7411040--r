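# Every matrix family must reproduce a naive pair/run/zone/dependence/code
# enumeration on random small VOIs, plus its analytic degenerate limits.

test_that("GLCM features match exhaustive pair counting", {
  # constant VOI limits
  qc <- qvoi_from_array(array(1L, c(3, 3, 3)), 4)
  fc <- petromics:::glcm_features(qc)
  expect_equal(unname(fc["glcm_contrast"]), 0)
  expect_equal(unname(fc["glcm_idm"]), 1)
  expect_equal(unname(fc["glcm_entropy"]), 0)
  # 4x4x1 alternating two-level grid
  alt <- array(NA_integer_, c(4, 4, 1))
  alt[, , 1] <- (outer(1:4, 1:4, "+") %% 2) + 1L
  qa <- qvoi_from_array(alt, 2)
  fa <- petromics:::glcm_features(qa)
  for (w in c("contrast", "energy", "entropy", "idm", "dissimilarity",
              "homogeneity")) {
    expect_equal(unname(fa[paste0("glcm_", w)]),
                 oracle_glcm_feature(alt, 2, w), tolerance = 1e-10)
  }
  # random VOIs
  for (s in 1:12) {
    q <- random_qvoi(s)
    f <- petromics:::glcm_features(q)
    for (w in c("contrast", "energy", "entropy", "idm")) {
      expect_equal(unname(f[paste0("glcm_", w)]),
                   oracle_glcm_feature(q$levels_arr, q$n_levels, w),
                   tolerance = 1e-10)
    }
  }
  # single voxel: no pairs
  single <- array(NA_integer_, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_error(petromics:::glcm_features(qvoi_from_array(single, 2)),
               "no voxel pairs")
})

test_that("GLRM features match explicit run enumeration", {
  # strictly alternating line: all runs length 1 in every direction
  alt <- array(NA_integer_, c(8, 1, 1))
  alt[, 1, 1] <- rep(c(1L, 2L), 4)
  expect_equal(unname(petromics:::glrm_features(
    qvoi_from_array(alt, 2))["glrm_sre"]), 1)
  # constant 1xN line along one direction: single run of length N
  line <- array(NA_integer_, c(6, 1, 1)); line[, 1, 1] <- 1L
  rm_x <- petromics:::glrm_matrix(qvoi_from_array(line, 1), c(1, 0, 0))
  expect_equal(sum(rm_x$R), 1)
  expect_equal(petromics:::glrm_features_one(rm_x$R, 6)["glrm_sre"],
               c(glrm_sre = 1 / 36))
  # random VOIs against the oracle
  for (s in 13:24) {
    q <- random_qvoi(s)
    f <- petromics:::glrm_features(q)
    for (w in c("sre", "lre", "glnu", "rp", "hgre")) {
      expect_equal(unname(f[paste0("glrm_", w)]),
                   oracle_glrm_feature(q$levels_arr, w), tolerance = 1e-10)
    }
  }
})

test_that("GLSZM features match flood-fill zone enumeration", {
  # constant VOI: one zone covering everything
  qc <- qvoi_from_array(array(1L, c(4, 4, 2)), 2)
  zm <- petromics:::glszm_matrix(qc)
  expect_equal(sum(zm$Z), 1)
  expect_equal(unname(petromics:::glszm_features(qc)["glszm_lze"]), 32^2)
  # 3D checkerboard on >= 2 levels still has single-voxel zones only in 2D;
  # with 26-connectivity diagonal same-level voxels join, so use a strict
  # 4-level pattern that isolates every voxel
  iso <- array(NA_integer_, c(4, 4, 1))
  iso[, , 1] <- matrix(rep(c(1L, 2L, 3L, 4L), 4), 4, byrow = TRUE) +
    0L  # rows repeat 1234; columns differ everywhere incl. diagonals
  iso[, , 1] <- (outer(0:3, 0:3, function(i, j) (i + 2 * j) %% 4)) + 1L
  qi <- qvoi_from_array(iso, 4)
  fi <- petromics:::glszm_features(qi)
  expect_equal(unname(fi["glszm_zp"]), 1)  # every zone is one voxel
  expect_equal(unname(fi["glszm_sze"]), 1)
  # random VOIs
  for (s in 25:36) {
    q <- random_qvoi(s)
    f <- petromics:::glszm_features(q)
    for (w in c("sze", "lze", "zp", "glnu")) {
      expect_equal(unname(f[paste0("glszm_", w)]),
                   oracle_glszm_feature(q$levels_arr, w), tolerance = 1e-10)
    }
  }
})

test_that("NGLD features match explicit neighbor counting", {
  # constant VOI: interior voxel has dependence 26
  qc <- qvoi_from_array(array(1L, c(5, 5, 5)), 2)
  cd <- oracle_ngld_counts(qc$levels_arr)
  expect_equal(max(cd[, "dep"]), 26)
  Q <- petromics:::ngld_matrix(qc)
  expect_equal(sum(Q[, 27]), 27)  # 3x3x3 interior voxels at dependence 26
  # all-different neighborhoods maximize small number emphasis
  iso <- array(NA_integer_, c(4, 4, 1))
  iso[, , 1] <- (outer(0:3, 0:3, function(i, j) (i + 2 * j) %% 4)) + 1L
  expect_equal(unname(petromics:::ngld_features(
    qvoi_from_array(iso, 4))["ngld_sne"]), 1)
  # random VOIs
  for (s in 37:48) {
    q <- random_qvoi(s)
    f <- petromics:::ngld_features(q)
    for (w in c("sne", "lne", "dcp", "hgce")) {
      expect_equal(unname(f[paste0("ngld_", w)]),
                   oracle_ngld_feature(q$levels_arr, w), tolerance = 1e-10)
    }
  }
})

test_that("TFC codes match explicit per-axis classification", {
  # constant VOI: single all-flat code, degenerate statistics
  qc <- qvoi_from_array(array(1L, c(4, 4, 4)), 2)
  ci <- petromics:::tfc_code_image(qc)
  expect_true(all(ci$code[!is.na(ci$code)] == 13))
  ftf <- petromics:::tfc_features(qc)
  expect_equal(unname(ftf["tfc_mean_convergence"]), 0)
  expect_equal(unname(ftf["tfc_code_entropy"]), 0)
  fcm <- petromics:::tfccm_features(qc)
  expect_equal(unname(fcm["tfccm_idm"]), 1)
  expect_equal(unname(fcm["tfccm_contrast"]), 0)
  # codes depend only on level ordering (rank-based): affine rescale of the
  # underlying SUVs yields identical quantized levels hence identical codes
  set.seed(9)
  dm <- c(5, 5, 5)
  base <- array(runif(prod(dm), 1, 9), dm)
  mask <- voi_mask(array(TRUE, dm), c(1, 1, 1))
  q1 <- quantize_voi(pet_volume(base, c(1, 1, 1)), mask)
  q2 <- quantize_voi(pet_volume(base * 3 + 2, c(1, 1, 1)), mask)
  expect_identical(petromics:::tfc_code_image(q1)$code,
                   petromics:::tfc_code_image(q2)$code)
  # random VOIs against the oracle code enumeration
  for (s in 49:60) {
    q <- random_qvoi(s, dim_max = 4L)
    ci <- petromics:::tfc_code_image(q)
    expect_equal(sort(as.numeric(ci$code[!is.na(ci$code)])),
                 sort(as.numeric(oracle_tfc_codes(q$levels_arr))))
  }
})
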