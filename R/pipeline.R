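#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: cohort
#' composition, thresholds (minimum MTV 10 cm^3, FDR 0.05, major-gene
#' carriers > 3), clustering hyperparameters and seeds. Every randomized
#' stage draws from `seed`; the full configuration is echoed into the run
#' manifest.
#'
#' @param seed master seed.
#' @param n_per_histology cohort composition for the synthetic stage.
#' @param n_genes,background_alteration_rate,planted_effects,n_clusters,cluster_separation
#'   passed to [make_cohort()].
#' @param min_mtv_cm3,fdr_cutoff,min_major_carriers pipeline thresholds.
#' @param k_range,resamples,subsample consensus-clustering hyperparameters.
#' @param n_phantoms phantoms generated for the imaging stage demo
#'   (segment -> extract -> volume filter); 0 disables the stage.
#' @param pathway_map pathway membership table; `NULL` = synthetic map.
#' @param reclassify_groups super-groups for survival stratification.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_histology = c(ADC = 61, SQCC = 31, SCLC = 45),
                            n_genes = 60,
                            background_alteration_rate = 0.08,
                            planted_effects = NULL,
                            n_clusters = 3,
                            cluster_separation = 3,
                            min_mtv_cm3 = 10,
                            fdr_cutoff = 0.05,
                            min_major_carriers = 4L,
                            k_range = 2:5,
                            resamples = 200L,
                            subsample = 0.8,
                            n_phantoms = 0L,
                            pathway_map = NULL,
                            reclassify_groups = 2L) {
  cfg <- as.list(environment())
  if (cfg$min_mtv_cm3 <= 0 || cfg$fdr_cutoff <= 0 || cfg$min_major_carriers <= 0) {
    abort("thresholds must be positive")
  }
  if (max(cfg$k_range) + 1 > min(cfg$n_per_histology)) {
    abort("k_range exceeds what the smallest histology can support")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full radiogenomic pipeline on a synthetic cohort
#'
#' Executes, per histology: cohort synthesis (or user-supplied tables),
#' batch harmonization, the feature-by-gene association screen, consensus
#' clustering with PAC model selection, representative-feature selection,
#' cluster-vs-pathway testing, dendrogram reclassification into
#' super-groups, and Kaplan-Meier/log-rank survival comparison. When
#' `n_phantoms > 0` an imaging stage demonstrates segmentation, feature
#' extraction and the minimum-volume filter on generated phantoms.
#'
#' Deterministic: rerunning with the same configuration reproduces every
#' table. If `out_dir` is given, all stage tables are written as TSV plus a
#' JSON manifest of parameters and seeds.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional precomputed cohort (as returned by
#'   [make_cohort()]); default generates one from the config.
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result`: `cohort`, `harmonized`,
#'   `associations`, `clustering`, `representative`, `pathway_tests`,
#'   `reclassified`, `survival_tests`, `imaging` (or `NULL`), `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(
#'   seed = 7, n_per_histology = c(ADC = 24), n_genes = 12,
#'   k_range = 2:3, resamples = 50))
#' res$clustering$ADC$k_opt
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- make_cohort(
      n_per_histology = config$n_per_histology,
      n_genes = config$n_genes,
      background_alteration_rate = config$background_alteration_rate,
      planted_effects = config$planted_effects,
      n_clusters = config$n_clusters,
      cluster_separation = config$cluster_separation,
      pathway_map = config$pathway_map,
      seed = config$seed)
  }
  pm <- cohort$truth$pathway_map
  if (is.null(pm)) abort("config validation: pathway map required")

  harmonized <- harmonize_features(cohort$features)
  pf <- pathway_flags(cohort$alterations, pm)

  hists <- unique(harmonized$histology)
  associations <- list(); clustering <- list(); representative <- list()
  pathway_tests <- list(); reclassified <- list(); survival_tests <- list()
  for (h in hists) {
    sub <- harmonized[harmonized$histology == h, ]
    associations[[h]] <- association_screen(
      harmonized, cohort$alterations, histology = h,
      fdr_cutoff = config$fdr_cutoff)
    cr <- consensus_cluster(
      sub, k_range = config$k_range, resamples = config$resamples,
      subsample = config$subsample, seed = config$seed + match(h, hists))
    clustering[[h]] <- cr
    representative[[h]] <- representative_features(sub, cr$chosen_labels)
    pf_h <- pf[pf$patient_id %in% sub$patient_id, ]
    pf_h <- pf_h[order(match(pf_h$patient_id, sub$patient_id)), ]
    pathway_tests[[h]] <- cluster_pathway_test(
      cr$chosen_labels, pf_h, seed = config$seed)
    rc <- reclassify(cr, groups = min(config$reclassify_groups, cr$k_opt))
    reclassified[[h]] <- rc
    sv <- dplyr::inner_join(cohort$survival, rc, by = "patient_id")
    survival_tests[[h]] <- if (length(unique(sv$group)) >= 2L) {
      logrank_test(sv, by = "group")
    } else {
      tibble::tibble(chi2 = NA_real_, df = 0L, p_value = NA_real_)
    }
  }

  imaging <- NULL
  if (config$n_phantoms > 0L) {
    imaging <- run_imaging_demo(config)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("petromics")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "planted_effects")],
    histologies = hists,
    timestamp = NULL)  # kept NULL so reruns are byte-identical

  res <- structure(list(
    cohort = cohort, harmonized = harmonized, associations = associations,
    clustering = clustering, representative = representative,
    pathway_tests = pathway_tests, reclassified = reclassified,
    survival_tests = survival_tests, imaging = imaging,
    manifest = manifest), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

# Segment -> extract -> volume-filter demonstration on generated phantoms.
run_imaging_demo <- function(config) {
  radii <- seq(14, 26, length.out = config$n_phantoms)
  rows <- list(); feats <- list()
  for (i in seq_len(config$n_phantoms)) {
    sp <- c(3, 3, 3)
    grid <- c(36, 36, 36)
    ctr <- grid / 2 * sp
    ph <- make_lesion_phantom(
      grid, sp,
      lesion_spec(center = ctr, radii = rep(radii[i], 3), peak_suv = 10,
                  background_suv = 0.5, heterogeneity_sd = 1.5,
                  edge_blur_sigma = 2, noise_sd = 0.2),
      seed = config$seed + i)
    seg <- gradient_segment(ph$volume, seed_voxel = round(grid / 2))
    rows[[i]] <- tibble::tibble(
      id = sprintf("phantom%02d", i), mtv_cm3 = mtv(seg),
      truth_mtv_cm3 = mtv(ph$mask),
      dice = dice_overlap(seg, ph$mask))
    feats[[i]] <- extract_features(ph$volume, seg,
                                   lesion_id = sprintf("phantom%02d", i))
  }
  lesions <- dplyr::bind_rows(rows)
  list(lesions = volume_filter(lesions, min_mtv = config$min_mtv_cm3),
       features = dplyr::bind_rows(feats))
}

#' Dice overlap of two masks
#'
#' @param a,b [voi_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a$mask), dim(b$mask)))
  2 * sum(a$mask & b$mask) / (sum(a$mask) + sum(b$mask))
}

# Write every stage table as TSV plus a JSON manifest.
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(res$harmonized, "features_harmonized")
  wt(res$cohort$features, "features_raw")
  wt(res$cohort$alterations, "alterations")
  wt(res$cohort$survival, "survival")
  for (h in names(res$associations)) {
    wt(res$associations[[h]], paste0("associations_", h))
    wt(res$clustering[[h]]$pac, paste0("pac_", h))
    wt(tibble::tibble(patient_id = res$clustering[[h]]$patients,
                      cluster = res$clustering[[h]]$chosen_labels),
       paste0("clusters_", h))
    wt(res$representative[[h]], paste0("representative_features_", h))
    wt(res$pathway_tests[[h]], paste0("pathway_tests_", h))
    wt(res$reclassified[[h]], paste0("reclassified_", h))
  }
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  histologies:",
      paste(names(x$associations), collapse = ", "), "\n")
  for (h in names(x$associations)) {
    cat(sprintf(
      "  %s: %d association rows (%d significant), K = %d, log-rank p = %s\n",
      h, nrow(x$associations[[h]]), sum(x$associations[[h]]$significant),
      x$clustering[[h]]$k_opt,
      format.pval(x$survival_tests[[h]]$p_value, digits = 3)))
  }
  invisible(x)
}
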