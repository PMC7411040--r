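test_that("phantom truth mask matches ellipsoid geometry", {
  # sphere radius 20 mm: voxelized volume within a one-voxel-shell of
  # 4/3 * pi * 2^3 cm^3
  ph <- sphere_phantom(radius_mm = 20, spacing = c(2, 2, 2))
  v_true <- 4 / 3 * pi * 2^3
  shell <- 4 * pi * 2^2 * 0.2  # one voxel (2 mm) shell in cm^3
  expect_lt(abs(mtv(ph$mask) - v_true), shell)
  # ground-truth MTV is exactly voxel count x voxel volume
  expect_equal(mtv(ph$mask), sum(ph$mask$mask) * 8 / 1000)
})

test_that("noise-free unblurred phantom is flat at peak inside the mask", {
  ph <- sphere_phantom(radius_mm = 15, peak = 7.5, background = 1)
  expect_true(all(ph$volume$voxels[ph$mask$mask] == 7.5))
  expect_true(all(ph$volume$voxels[!ph$mask$mask] == 1))
})

test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- lesion_spec(center = c(35, 35, 35), radii = c(15, 12, 10),
                      heterogeneity_sd = 1, noise_sd = 0.5)
  a <- make_lesion_phantom(c(36, 36, 36), c(2, 2, 2), spec, seed = 11)
  b <- make_lesion_phantom(c(36, 36, 36), c(2, 2, 2), spec, seed = 11)
  c <- make_lesion_phantom(c(36, 36, 36), c(2, 2, 2), spec, seed = 12)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("overflowing ellipsoid errors naming the axis", {
  expect_error(
    make_lesion_phantom(c(20, 40, 40), c(2, 2, 2),
                        lesion_spec(center = c(20, 40, 40),
                                    radii = c(25, 10, 10))),
    "axis x")
  expect_error(
    make_lesion_phantom(c(40, 40, 12), c(2, 2, 2),
                        lesion_spec(center = c(40, 40, 12),
                                    radii = c(10, 10, 20))),
    "axis z")
})

test_that("lesion_spec validates its invariants", {
  expect_error(lesion_spec(c(0, 0, 0), c(-1, 5, 5)), "radii")
  expect_error(lesion_spec(c(0, 0, 0), c(5, 5, 5), peak_suv = 1,
                           background_suv = 2), "peak_suv")
  expect_error(lesion_spec(c(0, 0, 0), c(5, 5, 5), noise_sd = -1))
})

test_that("null planted effects leave no standardized mean difference", {
  co <- make_cohort(
    n_per_histology = c(ADC = 100), n_genes = 5,
    background_alteration_rate = 0.3,
    planted_effects = data.frame(gene = "G001", feature = "suv_max",
                                 cohen_d = 0),
    batch_shift = list(scannerA = list(offset = 0, scale = 1),
                       scannerB = list(offset = 0, scale = 1)),
    seed = 21)
  w <- petromics:::alteration_wide(co$alterations)
  carrier <- w[co$features$patient_id, "G001"] == 1
  x <- co$features$suv_max
  d_hat <- (mean(x[carrier]) - mean(x[!carrier])) /
    sqrt(((sum(carrier) - 1) * var(x[carrier]) +
            (sum(!carrier) - 1) * var(x[!carrier])) / (length(x) - 2))
  expect_lt(abs(d_hat), 0.3)
})

test_that("planted effect of d = 1.5 is detectable at the oracle power", {
  # noncentral-t power for d = 1.5 with n = 20 vs 40 is > 0.999
  pow <- power.t.test(delta = 1.5, sd = 1, n = 26.7, sig.level = 0.05)$power
  expect_gt(pow, 0.99)
  rej <- vapply(1:20, function(s) {
    co <- make_cohort(
      n_per_histology = c(ADC = 60), n_genes = 3,
      background_alteration_rate = 0.1,
      planted_effects = data.frame(gene = "G001", feature = "suv_max",
                                   cohen_d = 1.5, n_carriers = 20),
      n_clusters = 1, cluster_separation = 0,
      batch_shift = list(scannerA = list(offset = 0, scale = 1),
                         scannerB = list(offset = 0, scale = 1)),
      seed = 100 + s)
    w <- petromics:::alteration_wide(co$alterations)
    carrier <- w[co$features$patient_id, "G001"] == 1
    t.test(co$features$suv_max[carrier],
           co$features$suv_max[!carrier])$p.value < 0.05
  }, logical(1))
  expect_true(all(rej))
})

test_that("planted batch offset appears at construction scale", {
  co <- make_cohort(
    n_per_histology = c(ADC = 120), n_genes = 3,
    batches = c(scannerA = 0.5, scannerB = 0.5),
    batch_shift = list(scannerA = list(offset = 0, scale = 1),
                       scannerB = list(offset = 2, scale = 1)),
    n_clusters = 1, cluster_separation = 0, seed = 5)
  gap <- mean(co$features$suv_max[co$features$batch == "scannerB"]) -
    mean(co$features$suv_max[co$features$batch == "scannerA"])
  expect_lt(abs(gap - 2), 0.5)
})

test_that("cohort generation is reproducible and patient-stable", {
  a <- make_cohort(n_per_histology = c(ADC = 20), n_genes = 8, seed = 3)
  b <- make_cohort(n_per_histology = c(ADC = 20), n_genes = 8, seed = 3)
  expect_identical(a$features, b$features)
  expect_identical(a$alterations$gene, b$alterations$gene)
  # enlarging the cohort preserves earlier patients' draws
  big <- make_cohort(n_per_histology = c(ADC = 30), n_genes = 8, seed = 3)
  expect_equal(as.data.frame(big$features[1:20, ]),
               as.data.frame(a$features))
})

test_that("non-planted alteration frequency matches the background rate", {
  co <- make_cohort(n_per_histology = c(ADC = 150), n_genes = 40,
                    background_alteration_rate = 0.1, seed = 8)
  w <- petromics:::alteration_wide(co$alterations)
  freq <- mean(colMeans(w))
  # binomial CI on 150 x 40 draws at p = 0.1
  se <- sqrt(0.1 * 0.9 / (150 * 40))
  expect_lt(abs(freq - 0.1), 4 * se)
})

test_that("untestable planted genes are rejected", {
  expect_error(
    make_cohort(n_per_histology = c(ADC = 20), n_genes = 5,
                background_alteration_rate = 0.01,
                planted_effects = data.frame(gene = "G001",
                                             feature = "suv_max",
                                             cohen_d = 1)),
    "carrier count")
})
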