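#' Generate a synthetic radiogenomic cohort with known ground truth
#'
#' Emulates the statistical structure the downstream stages assume: patient
#' feature vectors are built as cluster mean + planted gene effects + batch
#' shift + unit Gaussian noise, gene alterations are i.i.d. Bernoulli except
#' planted genes, and survival is exponential with cluster-dependent
#' hazards.
#'
#' Construction per patient, in feature SD units (noise SD = 1):
#' * patients within each histology are assigned round-robin to `n_clusters`
#'   true clusters; cluster `j` adds `cluster_separation` to its own block
#'   of features (blocks partition the feature list, so cluster mean
#'   profiles are mutually orthogonal);
#' * carriers of a planted `(gene, feature, cohen_d)` effect get `cohen_d`
#'   added to that feature (Cohen's d equals the shift since noise is unit);
#' * batch `b` transforms each feature `x` to `scale_b * x + offset_b`;
#' * survival time is exponential with the hazard (events/month) of the
#'   patient's true cluster, censored administratively at a uniform
#'   follow-up draw on `(0, followup_months)`.
#'
#' A single RNG seed drives the run; each patient consumes a sub-stream
#' derived from `seed` and the patient index, so enlarging the cohort does
#' not perturb earlier patients.
#'
#' @param n_per_histology named integer vector of patients per histology;
#'   default the 61/31/45 ADC/SQCC/SCLC composition of a typical
#'   mixed lung-cancer series.
#' @param features character feature names to simulate (default the robust
#'   27-name subset).
#' @param n_genes number of panel genes (named `G001`...).
#' @param background_alteration_rate Bernoulli alteration probability for
#'   unplanted patient-gene pairs.
#' @param planted_effects data frame with columns `gene`, `feature`,
#'   `cohen_d` and optionally `n_carriers` (exact carrier count; otherwise
#'   carriers are Bernoulli at the background rate). Expected carrier count
#'   below 2 is an error (the association is untestable).
#' @param n_clusters true clusters per histology.
#' @param cluster_separation cluster block shift in SD units.
#' @param batches named numeric vector of batch assignment probabilities.
#' @param batch_shift named list per batch: `list(offset =, scale =)`,
#'   scalars or per-feature named vectors. Default: second scanner shifted
#'   by +0.4 SD and scaled by 1.15 (a realistic inter-scanner effect).
#' @param pathway_map data frame `pathway`, `gene`; default
#'   [synthetic_pathway_map()] over the panel.
#' @param survival_spec list with `hazard_by_group` (events/month per true
#'   cluster, recycled) and `followup_months`.
#' @param seed integer seed.
#' @return list with `features` (tibble: patient_id, histology, batch, then
#'   feature columns), `alterations` (condensed call tibble as from
#'   [condense_calls()]), `survival` (tibble: patient_id, time_months,
#'   event), and `truth` (planted effects, batch shifts, true cluster
#'   labels, hazards).
#' @examples
#' co <- make_cohort(n_per_histology = c(ADC = 20), n_genes = 10, seed = 1)
#' dplyr::glimpse(co$features[, 1:5])
#' @export
make_cohort <- function(n_per_histology = c(ADC = 61, SQCC = 31, SCLC = 45),
                        features = robust_features(),
                        n_genes = 100,
                        background_alteration_rate = 0.05,
                        planted_effects = NULL,
                        n_clusters = 3,
                        cluster_separation = 3,
                        batches = c(scannerA = 0.3, scannerB = 0.7),
                        batch_shift = list(
                          scannerA = list(offset = 0, scale = 1),
                          scannerB = list(offset = 0.4, scale = 1.15)),
                        pathway_map = NULL,
                        survival_spec = list(hazard_by_group = c(0.02, 0.04, 0.08),
                                             followup_months = 72),
                        seed = 1L) {
  stopifnot(length(n_per_histology) >= 1L, !is.null(names(n_per_histology)))
  if (background_alteration_rate < 0 || background_alteration_rate > 1) {
    abort("`background_alteration_rate` must be in [0, 1].")
  }
  genes <- sprintf("G%03d", seq_len(n_genes))
  n_total <- sum(n_per_histology)
  if (!is.null(planted_effects)) {
    planted_effects <- tibble::as_tibble(planted_effects)
    stopifnot(all(c("gene", "feature", "cohen_d") %in% names(planted_effects)))
    bad <- setdiff(planted_effects$feature, features)
    if (length(bad)) abort(paste("Planted features not in catalog:",
                                 paste(bad, collapse = ", ")))
    bad <- setdiff(planted_effects$gene, genes)
    if (length(bad)) abort(paste("Planted genes not in panel:",
                                 paste(bad, collapse = ", ")))
    if (any(!is.finite(planted_effects$cohen_d))) {
      abort("`cohen_d` must be finite.")
    }
    exp_carriers <- if ("n_carriers" %in% names(planted_effects)) {
      planted_effects$n_carriers
    } else {
      rep(n_total * background_alteration_rate, nrow(planted_effects))
    }
    if (any(exp_carriers < 2)) {
      abort("planted gene with expected carrier count < 2: association untestable")
    }
  }
  if (abs(sum(batches) - 1) > 1e-8 || any(batches < 0)) {
    abort("`batches` must be assignment probabilities summing to 1.")
  }
  stopifnot(all(names(batches) %in% names(batch_shift)))
  if (is.null(pathway_map)) pathway_map <- synthetic_pathway_map(genes, seed = seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  p <- length(features)
  histology <- rep(names(n_per_histology), n_per_histology)
  patient_id <- sprintf("P%04d", seq_len(n_total))
  # deterministic round-robin cluster assignment within histology
  cluster <- unlist(lapply(n_per_histology, function(n) {
    rep_len(seq_len(n_clusters), n)
  }), use.names = FALSE)
  # orthogonal cluster mean profiles: block j of the feature list elevated
  block <- rep_len(seq_len(n_clusters), p)
  cluster_means <- vapply(seq_len(n_clusters), function(j) {
    ifelse(block == j, cluster_separation, 0)
  }, numeric(p))  # p x k

  # exact-carrier planted genes: sampled once from a dedicated sub-stream
  carrier_sets <- list()
  if (!is.null(planted_effects) && "n_carriers" %in% names(planted_effects)) {
    set.seed(as.integer(seed) + 424243L)
    for (g in unique(planted_effects$gene[!is.na(planted_effects$n_carriers)])) {
      nc <- planted_effects$n_carriers[match(g, planted_effects$gene)]
      carrier_sets[[g]] <- sample(n_total, nc)
    }
  }

  expand_shift <- function(x, default) {
    if (is.null(x)) return(setNames(rep(default, p), features))
    if (length(x) == 1L && is.null(names(x))) {
      return(setNames(rep(x, p), features))
    }
    out <- setNames(rep(default, p), features)
    out[intersect(names(x), features)] <- x[intersect(names(x), features)]
    out
  }
  shift_tbl <- lapply(batch_shift, function(b) {
    list(offset = expand_shift(b$offset, 0), scale = expand_shift(b$scale, 1))
  })

  categories <- c("MUT", "LoF", "CNV", "FUSION")
  cat_probs <- c(0.6, 0.2, 0.15, 0.05)
  hz <- rep_len(survival_spec$hazard_by_group, n_clusters)
  if (any(hz <= 0)) abort("hazards must be positive")

  feat_mat <- matrix(NA_real_, n_total, p, dimnames = list(NULL, features))
  batch_lab <- character(n_total)
  alt_rows <- vector("list", n_total)
  surv_time <- numeric(n_total)
  surv_event <- integer(n_total)

  for (i in seq_len(n_total)) {
    set.seed((as.integer(seed) + 7919L * i) %% .Machine$integer.max)
    b <- sample(names(batches), 1L, prob = batches)
    batch_lab[i] <- b
    base <- cluster_means[, cluster[i]] + rnorm(p)
    # gene alterations
    alt <- runif(n_genes) < background_alteration_rate
    names(alt) <- genes
    for (g in names(carrier_sets)) alt[g] <- i %in% carrier_sets[[g]]
    if (!is.null(planted_effects)) {
      for (r in seq_len(nrow(planted_effects))) {
        g <- planted_effects$gene[r]
        if (alt[[g]]) {
          fi <- match(planted_effects$feature[r], features)
          base[fi] <- base[fi] + planted_effects$cohen_d[r]
        }
      }
    }
    feat_mat[i, ] <- shift_tbl[[b]]$scale * base + shift_tbl[[b]]$offset
    altered <- names(alt)[alt]
    if (length(altered)) {
      is_planted <- altered %in% if (is.null(planted_effects)) character() else
        planted_effects$gene
      alt_rows[[i]] <- tibble::tibble(
        patient_id = patient_id[i],
        gene = altered,
        category = ifelse(is_planted, "MUT",
                          sample(categories, length(altered), replace = TRUE,
                                 prob = cat_probs)))
    }
    tte <- rexp(1, rate = hz[cluster[i]])
    cens <- runif(1, 0, survival_spec$followup_months)
    surv_event[i] <- as.integer(tte <= cens)
    surv_time[i] <- min(tte, cens)
  }

  calls <- dplyr::bind_rows(alt_rows)
  if (nrow(calls) == 0L) {
    calls <- tibble::tibble(patient_id = character(), gene = character(),
                            category = character())
  }
  am <- condense_calls(calls, patients = patient_id, genes = genes)

  list(
    features = dplyr::bind_cols(
      tibble::tibble(patient_id = patient_id, histology = histology,
                     batch = batch_lab),
      tibble::as_tibble(feat_mat)),
    alterations = am,
    survival = tibble::tibble(patient_id = patient_id,
                              time_months = surv_time, event = surv_event),
    truth = list(
      planted_effects = planted_effects,
      batch_shift = shift_tbl,
      true_clusters = tibble::tibble(patient_id = patient_id,
                                     histology = histology,
                                     cluster = cluster),
      hazard_by_group = hz,
      pathway_map = pathway_map
    )
  )
}

#' Canonical oncogenic signaling pathway names
#'
#' The ten canonical pathways used to aggregate gene-level alterations.
#'
#' @return character vector of 10 names.
#' @export
pathway_names <- function() {
  c("cell cycle", "Hippo", "Myc", "Notch", "Nrf2", "PI-3-Kinase/Akt",
    "RTK-RAS", "TGFβ", "p53", "β-catenin/Wnt")
}

#' Synthetic pathway membership map
#'
#' Assigns panel genes to the ten canonical pathways for testing: each gene
#' joins one pathway round-robin, and a fraction joins a second pathway
#' (genes may belong to multiple pathways). Real analyses should supply the
#' curated membership table instead.
#'
#' @param genes character gene names.
#' @param second_membership fraction of genes given a second pathway.
#' @param seed integer seed.
#' @return tibble with columns `pathway`, `gene`.
#' @export
synthetic_pathway_map <- function(genes, second_membership = 0.1, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) + 90001L)
  pw <- pathway_names()
  primary <- tibble::tibble(
    pathway = rep_len(pw, length(genes)), gene = genes)
  n2 <- round(second_membership * length(genes))
  if (n2 > 0) {
    g2 <- sample(genes, n2)
    secondary <- tibble::tibble(
      pathway = sample(pw, n2, replace = TRUE), gene = g2)
    primary <- dplyr::distinct(dplyr::bind_rows(primary, secondary))
  }
  dplyr::arrange(primary, .data$pathway, .data$gene)
}
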