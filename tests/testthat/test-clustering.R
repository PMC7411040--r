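blob_cohort <- function(n = 60, k = 3, sep = 10, seed = 1) {
  make_cohort(n_per_histology = c(ADC = n), n_genes = 4,
              n_clusters = k, cluster_separation = sep,
              batch_shift = list(scannerA = list(offset = 0, scale = 1),
                                 scannerB = list(offset = 0, scale = 1)),
              seed = seed)
}

test_that("pac counts ambiguous off-diagonal entries", {
  cm01 <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3)
  expect_equal(pac(cm01), 0)
  half <- matrix(0.5, 4, 4); diag(half) <- 1
  expect_equal(pac(half), 1)
  cm <- diag(4)
  cm[lower.tri(cm)] <- c(0.05, 0.5, 0.95, 0.5, 0.5, 0.05)
  cm <- cm + t(cm) - diag(diag(cm))
  expect_equal(pac(cm), 0.5)  # 3 of 6 unique pairs ambiguous
  # ideal block-diagonal consensus has PAC exactly 0
  ideal <- kronecker(diag(3), matrix(1, 5, 5))
  expect_equal(pac(ideal), 0)
})

test_that("consensus matrices are well-formed and deterministic", {
  co <- blob_cohort(n = 30, seed = 2)
  cr1 <- consensus_cluster(co$features, k_range = 2:4, resamples = 60,
                           seed = 5)
  cr2 <- consensus_cluster(co$features, k_range = 2:4, resamples = 60,
                           seed = 5)
  expect_identical(cr1$consensus, cr2$consensus)
  expect_identical(cr1$chosen_labels, cr2$chosen_labels)
  for (cm in cr1$consensus) {
    expect_true(all(cm >= 0 & cm <= 1))
    expect_equal(diag(cm), setNames(rep(1, nrow(cm)), rownames(cm)))
    expect_equal(cm, t(cm))
  }
})

test_that("three well-separated blobs are recovered at K = 3", {
  co <- blob_cohort(n = 60, k = 3, sep = 10, seed = 4)
  cr <- consensus_cluster(co$features, k_range = 2:5, resamples = 200,
                          seed = 6)
  expect_equal(cr$k_opt, 3)
  truth <- co$truth$true_clusters$cluster
  expect_gt(ari(cr$chosen_labels, truth), 0.95)
})

test_that("consensus stabilizes as resamples grow", {
  co <- blob_cohort(n = 40, k = 2, sep = 6, seed = 9)
  cr500 <- consensus_cluster(co$features, k_range = 2:3, resamples = 500,
                             seed = 1)
  cr1000 <- consensus_cluster(co$features, k_range = 2:3, resamples = 1000,
                              seed = 1)
  dmax <- max(abs(cr500$consensus[["2"]] - cr1000$consensus[["2"]]))
  expect_lt(dmax, 0.05)
})

test_that("too-few resamples to co-sample every pair is an error", {
  co <- blob_cohort(n = 30, seed = 3)
  expect_error(
    consensus_cluster(co$features, k_range = 2:3, resamples = 2,
                      subsample = 0.5, seed = 1),
    "co-sampled")
})

test_that("representative features demand omnibus and pairwise significance", {
  set.seed(21)
  n <- 48
  labels <- rep(1:4, each = n / 4)
  fm <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:n),
    strong = rnorm(n) + 5 * labels,          # separated in every pair
    null_feat = rnorm(n),                    # no signal
    partial = rnorm(n, sd = 0.2) + c(0, 0, 1.5, 3)[labels])  # clusters 1,2 tie
  rf0 <- representative_features(fm, labels)
  expect_true(rf0$selected[rf0$feature == "strong"])
  expect_false(rf0$selected[rf0$feature == "null_feat"])
  expect_false(rf0$selected[rf0$feature == "partial"])
  expect_equal(unique(rf0$n_pairwise), choose(4, 2))
  # the five-of-six fallback admits a feature failing exactly one pair
  rf1 <- representative_features(fm, labels, fallback_misses = 1)
  expect_true(rf1$selected[rf1$feature == "partial"])
  # identical-across-cluster features are never selected
  fm$constant <- 3
  rfc <- representative_features(fm, labels)
  expect_false(rfc$selected[rfc$feature == "constant"])
  expect_error(representative_features(fm, c(1, rep(2, n - 1))), "size 1")
})

test_that("representative feature selection ignores feature order", {
  set.seed(22)
  labels <- rep(1:3, each = 10)
  fm <- tibble::tibble(a = rnorm(30) + labels * 3, b = rnorm(30),
                       c = rnorm(30) + (labels == 2) * 4)
  r1 <- representative_features(fm, labels)
  r2 <- representative_features(fm[, c("c", "a", "b")], labels)
  expect_equal(r1[order(r1$feature), ], r2[order(r2$feature), ])
})

test_that("cluster-pathway exact test behaves at the limits", {
  labels <- rep(1:3, each = 20)
  # pathway altered only in cluster 1
  pf <- tibble::tibble(patient_id = sprintf("p%02d", 1:60),
                       pathway = "P1",
                       MUT = 0L, LoF = 0L, CNV = 0L, FUSION = 0L,
                       any = as.integer(labels == 1))
  res <- cluster_pathway_test(labels, pf)
  expect_lt(res$p_value, 0.001)
  # oracle check on the same table
  expect_equal(res$p_value,
               fisher.test(table(labels, labels == 1))$p.value)
  # degenerate: all altered
  pf$any <- 1L
  res_deg <- cluster_pathway_test(labels, pf)
  expect_equal(res_deg$p_value, 1)
  expect_true(res_deg$degenerate)
})

test_that("cluster-pathway p-values are uniform under independence", {
  set.seed(31)
  labels <- rep(1:3, each = 20)
  ps <- vapply(1:300, function(i) {
    pf <- tibble::tibble(patient_id = sprintf("p%02d", 1:60),
                         pathway = "P1", MUT = 0L, LoF = 0L, CNV = 0L,
                         FUSION = 0L,
                         any = rbinom(60, 1, 0.4))
    cluster_pathway_test(labels, pf)$p_value
  }, numeric(1))
  # exact-test p-values are discrete and conservative; check super-uniformity
  expect_gt(mean(ps < 0.05), 0)
  expect_lte(mean(ps <= 0.05), 0.07)
})

test_that("reclassification groups clusters by dendrogram proximity", {
  # K = 2: reclassification is the identity up to relabeling
  co <- blob_cohort(n = 40, k = 2, sep = 8, seed = 10)
  cr <- consensus_cluster(co$features, k_range = 2:3, resamples = 100,
                          seed = 2)
  rc <- reclassify(cr, groups = 2, labels = cr$labels[["2"]],
                   cm = cr$consensus[["2"]])
  expect_equal(length(unique(paste(rc$cluster, rc$group))), 2)
  # structural 9-cluster case: clusters 1 and 9 share a high branch
  set.seed(12)
  k <- 9; per <- 4; n <- k * per
  labels <- rep(1:k, each = per)
  # clusters 2..8 moderately similar to each other (0.3), clusters 1 and 9
  # strongly co-clustering (0.85) and distant from the rest (0.05)
  cm <- matrix(0.05, n, n)
  rest <- !(labels %in% c(1, 9))
  cm[rest, rest] <- 0.3
  pair <- labels %in% c(1, 9)
  cm[pair, pair] <- 0.85
  for (g in 1:k) cm[labels == g, labels == g] <- 1
  diag(cm) <- 1
  rc9 <- reclassify(structure(list(), class = "not_used"),
                    groups = 2, labels = setNames(labels,
                                                  sprintf("p%02d", 1:n)),
                    cm = cm)
  grp_of <- tapply(rc9$group, rc9$cluster, unique)
  expect_equal(unname(grp_of["1"]), unname(grp_of["9"]))
  expect_true(all(grp_of[as.character(2:8)] != grp_of["1"]))
  # degenerate single cluster
  expect_error(reclassify(structure(list(), class = "x"), groups = 2,
                          labels = rep(1, 10), cm = diag(10)),
               ">= 2 clusters")
})

test_that("tidiers expose labels and model-selection summary", {
  co <- blob_cohort(n = 30, seed = 14)
  cr <- consensus_cluster(co$features, k_range = 2:4, resamples = 80,
                          seed = 3)
  td <- tidy(cr)
  expect_equal(nrow(td), 30)
  gl <- glance(cr)
  expect_equal(gl$k_opt, cr$k_opt)
  p <- autoplot(cr)
  expect_s3_class(p, "ggplot")
})
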