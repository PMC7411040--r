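test_that("quantization follows the fixed-bin-number convention", {
  m <- voi_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
  const <- pet_volume(array(3, c(2, 2, 2)), c(1, 1, 1))
  q <- quantize_voi(const, m)
  expect_true(all(q$levels_arr[m$mask] == 1L))

  two <- pet_volume(array(c(1, 2, 1, 2, 1, 2, 1, 2), c(2, 2, 2)), c(1, 1, 1))
  q2 <- quantize_voi(two, m, levels = 64)
  expect_setequal(unique(as.vector(q2$levels_arr[m$mask])), c(1L, 64L))

  # linear ramp quantizes to a uniform level histogram (+/- 1 count)
  n <- 4
  ramp <- pet_volume(array(seq_len(n^3), rep(n, 3)), c(1, 1, 1))
  mr <- voi_mask(array(TRUE, rep(n, 3)), c(1, 1, 1))
  qr <- quantize_voi(ramp, mr, levels = 8)
  counts <- tabulate(qr$levels_arr[mr$mask], 8)
  expect_lte(diff(range(counts)), 1)
  expect_error(quantize_voi(ramp, mr, levels = 1), "levels")
})

test_that("intensity features behave on a constant VOI", {
  # ball large enough to contain the 6.2 mm SUVpeak sphere at its center
  mask <- make_ball_mask(8)
  vol <- constant_volume(mask, value = 6)
  f <- petromics:::intensity_features(vol, mask)
  expect_equal(unname(f["suv_max"]), 6)
  expect_equal(unname(f["suv_mean"]), 6)
  expect_equal(unname(f["suv_peak"]), 6)
  expect_equal(unname(f["suv_sd"]), 0)
  expect_equal(unname(f["hist_entropy"]), 0)
  expect_equal(unname(f["surface_suv_sd"]), 0)
})

test_that("SUVpeak never exceeds SUVmax", {
  for (s in 1:5) {
    ph <- make_lesion_phantom(
      rep(28, 3), c(3, 3, 3),
      lesion_spec(center = rep(40, 3), radii = rep(16, 3),
                  heterogeneity_sd = 2, noise_sd = 0.5), seed = s)
    f <- petromics:::intensity_features(ph$volume, ph$mask)
    expect_lte(f["suv_peak"], f["suv_max"])
  }
})

test_that("hand-computed cube example: SUVmean, MTV, TLG", {
  # 3x3x3 all-in-mask cube with values 1..27 at 10 mm spacing
  vol <- pet_volume(array(1:27, c(3, 3, 3)), c(10, 10, 10))
  mask <- voi_mask(array(TRUE, c(3, 3, 3)), c(10, 10, 10))
  f <- petromics:::intensity_features(vol, mask)
  expect_equal(unname(f["suv_mean"]), 14)
  expect_equal(unname(f["mtv"]), 27)
  expect_equal(unname(f["tlg"]), 378)
})

test_that("SUL features require body metrics and scale by lean body mass", {
  mask <- make_ball_mask(3)
  vol_nometa <- constant_volume(mask, value = 4)
  f <- petromics:::intensity_features(vol_nometa, mask)
  expect_true(is.na(f["sul_max"]))
  expect_false(anyNA(f[setdiff(names(f), c("sul_max", "sul_mean",
                                           "sul_peak"))]))
  vol <- constant_volume(mask, value = 4,
                         patient_meta = list(sex = "M", weight_kg = 80,
                                             height_cm = 175))
  f2 <- petromics:::intensity_features(vol, mask)
  lbm <- 1.10 * 80 - 128 * (80 / 175)^2
  expect_equal(unname(f2["sul_max"]), 4 * lbm / 80)
})

test_that("the catalog has the canonical structure", {
  cat_tbl <- feature_catalog()
  expect_equal(nrow(cat_tbl), 86)
  expect_equal(sum(cat_tbl$class == "texture"), 55)
  expect_equal(sum(cat_tbl$class == "non-texture"), 31)
  expect_equal(sum(cat_tbl$family == "intensity"), 25)
  expect_equal(sum(cat_tbl$family == "texture_spectrum"), 2)
  expect_equal(sum(cat_tbl$family == "geometry"), 4)
  expect_equal(length(robust_features()), 27)
  expect_true(all(robust_features() %in% cat_tbl$name))
  expect_equal(sum(cat_tbl$robust), 27)
})

test_that("extract_features returns the full finite catalog", {
  ph <- make_lesion_phantom(
    rep(26, 3), c(3, 3, 3),
    lesion_spec(center = rep(37.5, 3), radii = c(15, 13, 12),
                heterogeneity_sd = 2, noise_sd = 0.3), seed = 2)
  ph$volume$patient_meta <- list(sex = "F", weight_kg = 62, height_cm = 160)
  fv <- extract_features(ph$volume, ph$mask, patient_id = "p1")
  vals <- unlist(fv[, feature_catalog()$name])
  expect_equal(length(vals), 86)
  expect_true(all(is.finite(vals)))
  expect_equal(length(attr(fv, "robust")), 27)
})

test_that("tiny VOIs are rejected for texture analysis", {
  m <- array(FALSE, c(5, 5, 5)); m[2:3, 2, 2] <- TRUE
  mask <- voi_mask(m, c(1, 1, 1))
  vol <- constant_volume(mask, 5)
  expect_error(extract_features(vol, mask), "too small")
})

test_that("texture features ignore constant intensity offsets", {
  set.seed(42)
  dm <- c(6, 6, 6)
  mask <- voi_mask(array(TRUE, dm), c(1, 1, 1))
  base <- array(runif(prod(dm), 1, 9), dm)
  v1 <- pet_volume(base, c(1, 1, 1))
  v2 <- pet_volume(base + 5, c(1, 1, 1))
  f1 <- extract_features(v1, mask)
  f2 <- extract_features(v2, mask)
  tex <- feature_catalog()$name[feature_catalog()$class == "texture"]
  expect_equal(as.numeric(f1[, tex]), as.numeric(f2[, tex]),
               tolerance = 1e-12)
  # intensity features shift accordingly
  expect_equal(f2$suv_mean, f1$suv_mean + 5)
  expect_equal(f2$suv_sd, f1$suv_sd)
})

test_that("direction-averaged texture features are rotation invariant", {
  set.seed(7)
  dm <- c(5, 5, 5)
  q1 <- qvoi_from_array(array(sample.int(4, prod(dm), TRUE), dm), 4)
  rot <- aperm(q1$levels_arr, c(2, 1, 3))[dim(q1$levels_arr)[2]:1, , ]
  q2 <- qvoi_from_array(array(rot, dm), 4)
  for (fam in list(petromics:::glcm_features, petromics:::glrm_features,
                   petromics:::glszm_features, petromics:::ngld_features,
                   petromics:::tfc_features)) {
    expect_equal(fam(q1), fam(q2), tolerance = 1e-10)
  }
})
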