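# Consensus clustering of patients on PET feature signatures, PAC-based
# selection of the cluster number, representative-feature selection,
# cluster-vs-pathway testing and dendrogram-based reclassification.

#' Consensus clustering with hierarchical base learner
#'
#' Repeatedly subsamples patients, clusters each subsample hierarchically
#' with Pearson-correlation distance (`1 - cor` between patient feature
#' profiles) and the chosen linkage, and aggregates co-clusterings into a
#' consensus matrix per candidate K (co-cluster count / co-sample count).
#' Features are z-scored before clustering; constant features are dropped
#' with a warning. Final labels per K come from hierarchical clustering of
#' `1 - consensus`; the optimal K minimizes the proportion of ambiguous
#' clustering ([pac()]).
#'
#' @param fm feature tibble (`patient_id` plus feature columns; extra label
#'   columns are ignored).
#' @param features feature columns to use (default: all numeric non-label
#'   columns).
#' @param k_range candidate cluster numbers.
#' @param resamples number of subsamples per K.
#' @param subsample fraction of patients drawn per resample.
#' @param feature_subsample fraction of features drawn per resample.
#'   Feature subsampling keeps the base learner's view of the data changing
#'   between resamples; without it, a merge of truly equidistant clusters is
#'   decided once by the realized noise and the consensus matrix cannot
#'   expose the ambiguity.
#' @param linkage hierarchical linkage: `"average"`, `"complete"` or
#'   `"ward.D2"`.
#' @param seed integer RNG seed (fixed seed gives an identical result).
#' @return object of class `consensus_result`: list with `consensus`
#'   (matrices per K), `labels` (per K), `pac` (tibble K, pac), `k_opt`,
#'   `chosen_labels`, `patients`, `tree` (hclust of `1 - consensus` at
#'   `k_opt`), `params`.
#' @examples
#' co <- make_cohort(n_per_histology = c(ADC = 24), n_genes = 4,
#'                   n_clusters = 2, cluster_separation = 6, seed = 4)
#' cr <- consensus_cluster(co$features, k_range = 2:3, resamples = 50,
#'                         seed = 9)
#' cr$k_opt
#' @export
consensus_cluster <- function(fm, features = NULL, k_range = 2:6,
                              resamples = 1000L, subsample = 0.8,
                              feature_subsample = 0.8,
                              linkage = c("average", "complete", "ward.D2"),
                              seed = 1L) {
  linkage <- match.arg(linkage)
  fm <- tibble::as_tibble(fm)
  label_cols <- intersect(c("patient_id", "histology", "batch"), names(fm))
  if (is.null(features)) {
    features <- setdiff(names(fm)[vapply(fm, is.numeric, logical(1))],
                        label_cols)
  }
  patients <- if ("patient_id" %in% names(fm)) fm$patient_id
  else sprintf("P%04d", seq_len(nrow(fm)))
  x <- as.matrix(fm[, features])
  rownames(x) <- patients
  n <- nrow(x)
  if (n < max(k_range) + 1L) abort("need at least Kmax + 1 patients")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant feature(s): %s", sum(sds == 0),
                 paste(head(colnames(x)[sds == 0], 5), collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  x <- scale(x)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  m <- max(2L, round(subsample * n))
  p_use <- ncol(x)
  mf <- max(2L, round(feature_subsample * p_use))
  draws <- lapply(seq_len(resamples), function(i) sort(sample(n, m)))
  fdraws <- lapply(seq_len(resamples), function(i) sort(sample(p_use, mf)))
  cosample <- matrix(0, n, n)
  for (s in draws) cosample[s, s] <- cosample[s, s] + 1
  if (any(cosample[upper.tri(cosample)] == 0)) {
    abort("some patient pairs were never co-sampled; increase `resamples`")
  }

  consensus <- list()
  labels <- list()
  pac_vals <- numeric(length(k_range))
  # distance per subsample is reused across K
  dists <- lapply(seq_len(resamples), function(b) {
    as.dist(1 - cor(t(x[draws[[b]], fdraws[[b]], drop = FALSE])))
  })
  trees <- lapply(dists, hclust, method = linkage)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    cocluster <- matrix(0, n, n)
    for (b in seq_len(resamples)) {
      s <- draws[[b]]
      cl <- cutree(trees[[b]], k = k)
      for (g in unique(cl)) {
        mem <- s[cl == g]
        cocluster[mem, mem] <- cocluster[mem, mem] + 1
      }
    }
    cm <- cocluster / cosample
    diag(cm) <- 1
    dimnames(cm) <- list(patients, patients)
    consensus[[as.character(k)]] <- cm
    tr <- hclust(as.dist(1 - cm), method = linkage)
    labels[[as.character(k)]] <- setNames(cutree(tr, k = k), patients)
    pac_vals[ki] <- pac(cm)
  }
  k_opt <- k_range[which.min(pac_vals)]
  structure(list(
    consensus = consensus,
    labels = labels,
    pac = tibble::tibble(k = k_range, pac = pac_vals),
    k_opt = k_opt,
    chosen_labels = labels[[as.character(k_opt)]],
    patients = patients,
    tree = hclust(as.dist(1 - consensus[[as.character(k_opt)]]),
                  method = linkage),
    params = list(k_range = k_range, resamples = resamples,
                  subsample = subsample,
                  feature_subsample = feature_subsample,
                  linkage = linkage, seed = seed,
                  features = colnames(x))
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", length(x$patients), " patients, K in {",
      paste(x$pac$k, collapse = ", "), "}, chosen K = ", x$k_opt, "\n",
      sep = "")
  print(x$pac)
  invisible(x)
}

#' Proportion of ambiguous clustering
#'
#' Fraction of off-diagonal consensus entries strictly inside the
#' `(lower, upper)` window: entries near 0 or 1 are unambiguous, values in
#' between mark unstable pair assignments. Lower PAC = more stable K.
#'
#' @param cm consensus matrix (symmetric, unit diagonal).
#' @param lower,upper window bounds (default 0.1 and 0.9).
#' @return scalar in `[0, 1]`.
#' @examples
#' cm <- diag(3); cm[1, 2] <- cm[2, 1] <- 0.5
#' pac(cm)  # 1/3 of off-diagonal entries ambiguous
#' @export
pac <- function(cm, lower = 0.1, upper = 0.9) {
  off <- cm[row(cm) != col(cm)]
  mean(off > lower & off < upper)
}

#' Select representative features distinguishing the clusters
#'
#' Stage 1: per feature an omnibus test across clusters, routed by
#' Shapiro-Wilk normality per cluster and Levene variance homogeneity (both
#' at alpha 0.05): ANOVA if normal and homoscedastic, Welch's ANOVA if
#' normal only, Kruskal-Wallis otherwise. Stage 2: all pairwise two-sample
#' t-tests between clusters. A feature is representative when its omnibus
#' test is significant and it misses at most `fallback_misses` of the
#' pairwise tests (0 = significant in all).
#'
#' @param fm feature tibble (rows aligned with `labels`).
#' @param labels cluster labels (>= 2 clusters, each of size >= 2).
#' @param features feature columns to assess (default: numeric non-label
#'   columns).
#' @param alpha significance level for every test.
#' @param fallback_misses allowed pairwise-test misses (e.g. 1 to accept
#'   features significant in five of six tests).
#' @return tibble: feature, omnibus_test, omnibus_p, n_pairwise,
#'   n_significant, selected.
#' @export
representative_features <- function(fm, labels, features = NULL,
                                    alpha = 0.05, fallback_misses = 0L) {
  fm <- tibble::as_tibble(fm)
  label_cols <- intersect(c("patient_id", "histology", "batch"), names(fm))
  if (is.null(features)) {
    features <- setdiff(names(fm)[vapply(fm, is.numeric, logical(1))],
                        label_cols)
  }
  g <- factor(labels)
  stopifnot(length(g) == nrow(fm))
  if (nlevels(g) < 2L) abort("need >= 2 clusters")
  if (any(table(g) < 2L)) abort("cluster of size 1")
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  out <- lapply(features, function(f) {
    v <- fm[[f]]
    normal <- groups_normal(v, g, alpha)
    homosc <- tryCatch(
      car::leveneTest(v ~ g)[1, "Pr(>F)"] >= alpha,
      error = function(e) FALSE)
    if (normal && homosc) {
      test <- "anova"
      p <- oneway.test(v ~ g, var.equal = TRUE)$p.value
    } else if (normal) {
      test <- "welch"
      p <- oneway.test(v ~ g, var.equal = FALSE)$p.value
    } else {
      test <- "kruskal"
      p <- kruskal.test(v, g)$p.value
    }
    pw <- vapply(pairs, function(pr) {
      a <- v[g == pr[1]]; b <- v[g == pr[2]]
      if (sd(a) == 0 && sd(b) == 0) {
        return(if (mean(a) == mean(b)) 1 else 0)
      }
      tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    }, numeric(1))
    if (is.na(p)) p <- 1
    tibble::tibble(
      feature = f, omnibus_test = test, omnibus_p = p,
      n_pairwise = length(pw), n_significant = sum(pw < alpha),
      selected = p < alpha &
        (length(pw) - sum(pw < alpha)) <= fallback_misses)
  })
  dplyr::bind_rows(out)
}

#' Test pathway alteration incidence across clusters
#'
#' For each pathway, tests independence of the K x 2 table of cluster by
#' pathway-alteration flag with Fisher's exact test (Monte Carlo p-value
#' with `mc_draws` seeded draws when exact enumeration is infeasible).
#' Pathways altered in none or all patients are degenerate and reported
#' with p = 1.
#'
#' @param labels cluster labels, named by or aligned with patients.
#' @param pf pathway flag tibble from [pathway_flags()] (rows for the same
#'   patients); the `any` column is tested unless `category` says otherwise.
#' @param category which flag column to test (`"any"`, `"MUT"`, ...).
#' @param mc_draws Monte Carlo draws for large tables.
#' @param seed seed for the Monte Carlo p-value.
#' @return tibble: pathway, n_altered, p_value, degenerate.
#' @export
cluster_pathway_test <- function(labels, pf, category = "any",
                                 mc_draws = 1e5, seed = 1L) {
  pf <- tibble::as_tibble(pf)
  stopifnot(category %in% names(pf), "pathway" %in% names(pf))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  out <- lapply(unique(pf$pathway), function(pw) {
    sub <- pf[pf$pathway == pw, ]
    stopifnot(nrow(sub) == length(labels))
    flag <- sub[[category]]
    if (all(flag == 0) || all(flag == 1)) {
      return(tibble::tibble(pathway = pw, n_altered = sum(flag),
                            p_value = 1, degenerate = TRUE))
    }
    tab <- table(labels, factor(flag, levels = 0:1))
    p <- tryCatch(
      fisher.test(tab, workspace = 2e7)$p.value,
      error = function(e) {
        set.seed(as.integer(seed))
        fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value
      })
    tibble::tibble(pathway = pw, n_altered = sum(flag), p_value = p,
                   degenerate = FALSE)
  })
  dplyr::bind_rows(out)
}

#' Reclassify clusters into super-groups from the dendrogram
#'
#' Builds the between-cluster dendrogram (average linkage on
#' `1 - mean consensus` between cluster members) and cuts it into `groups`
#' super-clusters; each patient inherits its cluster's super-label
#' (`"A"`, `"B"`, ...). Clusters that split off together from the higher
#' branches end up in the same super-group.
#'
#' @param cr a `consensus_result` (or a consensus matrix via `cm` plus
#'   `labels`).
#' @param groups number of super-groups (default 2).
#' @param labels optional cluster labels (default `cr$chosen_labels`).
#' @param cm optional consensus matrix (default the chosen-K matrix).
#' @return tibble: patient_id, cluster, group.
#' @export
reclassify <- function(cr, groups = 2L, labels = NULL, cm = NULL) {
  if (inherits(cr, "consensus_result")) {
    if (is.null(labels)) labels <- cr$chosen_labels
    if (is.null(cm)) cm <- cr$consensus[[as.character(cr$k_opt)]]
    patients <- cr$patients
  } else {
    stopifnot(!is.null(labels), !is.null(cm))
    patients <- if (!is.null(names(labels))) names(labels)
    else sprintf("P%04d", seq_along(labels))
  }
  ks <- sort(unique(labels))
  if (length(ks) < 2L) abort("need >= 2 clusters to reclassify")
  if (groups > length(ks)) abort("`groups` exceeds the number of clusters")
  S <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  for (a in seq_along(ks)) {
    for (b in seq_along(ks)) {
      S[a, b] <- mean(cm[labels == ks[a], labels == ks[b], drop = FALSE])
    }
  }
  tr <- hclust(as.dist(1 - S), method = "average")
  super <- cutree(tr, k = groups)
  tibble::tibble(
    patient_id = patients,
    cluster = unname(labels),
    group = LETTERS[super[match(labels, ks)]])
}
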