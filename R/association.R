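# Feature-by-gene association screening: normality-routed two-sample tests,
# rescaled log2 fold changes, and Benjamini-Hochberg FDR within each
# histology screen.

#' Rescale feature values into (0, 1]
#'
#' Order-preserving map `((x / max(x)) * (N - 1) + 0.5) / N` used before a
#' log fold change whenever a group mean is zero (so the ratio is defined).
#' `N` is the cohort subject count and `max(x)` the cohort-level maximum:
#' both groups are rescaled jointly on the same scale.
#'
#' @param x numeric feature values (`max(x) > 0`).
#' @param n subject count `N >= 1` (default `length(x)`).
#' @return numeric vector in `(0, 1]`.
#' @examples
#' rescale_unit(c(0, 5, 10))  # 1/6, 1/2, 5/6
#' @export
rescale_unit <- function(x, n = length(x)) {
  mx <- max(x)
  if (mx <= 0) abort("all-zero values: rescaling undefined (max(x) = 0)")
  if (n < 1) abort("`n` must be >= 1")
  ((x / mx) * (n - 1) + 0.5) / n
}

#' Log2 fold change of group means
#'
#' `log2(mean(carriers) / mean(non-carriers))`. If either group mean is
#' zero, both groups are first rescaled jointly with [rescale_unit()] using
#' the pooled subject count, making the ratio finite.
#'
#' @param carrier,noncarrier numeric feature values of the two groups
#'   (both non-empty).
#' @return scalar log2 fold change.
#' @export
log_fold_change <- function(carrier, noncarrier) {
  if (length(carrier) == 0L || length(noncarrier) == 0L) {
    abort("empty group")
  }
  m1 <- mean(carrier); m0 <- mean(noncarrier)
  if (m1 == 0 || m0 == 0) {
    n <- length(carrier) + length(noncarrier)
    all_r <- rescale_unit(c(carrier, noncarrier), n)
    m1 <- mean(all_r[seq_along(carrier)])
    m0 <- mean(all_r[-seq_along(carrier)])
  }
  log2(m1 / m0)
}

# Shapiro-Wilk normality per group at alpha; groups too small (or constant)
# for the test are treated as non-normal.
groups_normal <- function(x, g, alpha = 0.05) {
  all(vapply(split(x, g), function(v) {
    if (length(v) < 3L || length(v) > 5000L) return(FALSE)
    p <- tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
    p >= alpha
  }, logical(1)))
}

#' Normality-routed two-sample test
#'
#' Shapiro-Wilk normality is checked per group at `alpha = 0.05`. Normal
#' values take a two-sided Welch t-test. Non-normal values are
#' log-transformed (shifted above zero first when needed) and re-checked:
#' if normal after the transform a t-test is used on the transformed
#' values, otherwise the Wilcoxon rank-sum test on the original values.
#'
#' @param values numeric feature values.
#' @param carrier logical/0-1 group indicator (both groups non-empty).
#' @param alpha normality alpha.
#' @return list: `p_value`, `test_used` (`"t"`/`"wilcoxon"`), `transformed`.
#' @export
two_sample_test <- function(values, carrier, alpha = 0.05) {
  carrier <- as.logical(carrier)
  if (!any(carrier) || all(carrier)) abort("a group of size 0")
  g <- factor(carrier, levels = c(FALSE, TRUE))
  if (groups_normal(values, g, alpha)) {
    p <- t.test(values[carrier], values[!carrier])$p.value
    return(list(p_value = p, test_used = "t", transformed = FALSE))
  }
  shifted <- values
  if (any(shifted <= 0)) shifted <- shifted - min(shifted) + 1e-6
  lg <- log(shifted)
  if (groups_normal(lg, g, alpha)) {
    p <- t.test(lg[carrier], lg[!carrier])$p.value
    return(list(p_value = p, test_used = "t", transformed = TRUE))
  }
  p <- suppressWarnings(
    wilcox.test(values[carrier], values[!carrier], exact = FALSE)$p.value)
  if (is.nan(p)) p <- 1  # fully tied degenerate case
  list(p_value = p, test_used = "wilcoxon", transformed = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1); a thin named wrapper over
#' `stats::p.adjust(method = "BH")` so the screening code reads as the
#' procedure it implements.
#'
#' @param p numeric p-values.
#' @return adjusted values, same length.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Screen all feature-by-gene associations within a histology
#'
#' For every (gene, feature) pair, patients carrying any alteration of the
#' gene are compared to non-carriers with [two_sample_test()]; the log2
#' fold change of group means is computed with zero-mean rescaling; and the
#' Benjamini-Hochberg FDR is taken over all tested pairs of the screen (one
#' histology is one FDR family). Genes with fewer than `min_carriers`
#' carriers (or fewer than 2 non-carriers) are skipped and listed in the
#' `skipped` attribute.
#'
#' @param fm feature tibble (`patient_id`, `histology`, feature columns).
#' @param am an `alteration_matrix` from [condense_calls()].
#' @param histology histology label to screen (`NULL` = use all rows).
#' @param features feature names to test (default: intersect of
#'   [robust_features()] and the columns of `fm`).
#' @param min_carriers minimum carriers to test a gene (default 2).
#' @param fdr_cutoff significance threshold on the adjusted values.
#' @return tibble: histology, gene, feature, n_carriers, n_noncarriers,
#'   test_used, transformed, p_value, log_fold_change, fdr, significant;
#'   attribute `skipped` lists untested genes.
#' @examples
#' co <- make_cohort(
#'   n_per_histology = c(ADC = 40), n_genes = 6,
#'   background_alteration_rate = 0.25,
#'   planted_effects = data.frame(gene = "G001", feature = "suv_max",
#'                                cohen_d = 2),
#'   seed = 3
#' )
#' scr <- association_screen(co$features, co$alterations, "ADC")
#' head(dplyr::arrange(scr, fdr), 3)
#' @export
association_screen <- function(fm, am, histology = NULL,
                               features = NULL, min_carriers = 2L,
                               fdr_cutoff = 0.05) {
  fm <- tibble::as_tibble(fm)
  if (!is.null(histology)) {
    stopifnot("histology" %in% names(fm))
    fm <- fm[fm$histology == histology, ]
  }
  if (is.null(features)) {
    features <- intersect(robust_features(), names(fm))
  }
  stopifnot(all(features %in% names(fm)), "patient_id" %in% names(fm))
  w <- alteration_wide(am)
  common <- intersect(fm$patient_id, rownames(w))
  fm <- fm[match(common, fm$patient_id), ]
  w <- w[common, , drop = FALSE]
  genes <- colnames(w)
  empty <- tibble::tibble(
    histology = character(), gene = character(), feature = character(),
    n_carriers = integer(), n_noncarriers = integer(),
    test_used = character(), transformed = logical(), p_value = numeric(),
    log_fold_change = numeric(), fdr = numeric(), significant = logical())
  if (length(genes) == 0L || nrow(fm) == 0L) {
    attr(empty, "skipped") <- character()
    return(empty)
  }
  carriers_n <- colSums(w)
  testable <- carriers_n >= min_carriers & (nrow(w) - carriers_n) >= 2L
  skipped <- genes[!testable]
  rows <- list()
  hist_lab <- if (is.null(histology)) "all" else histology
  for (g in genes[testable]) {
    cf <- w[, g] == 1L
    for (f in features) {
      v <- fm[[f]]
      tst <- two_sample_test(v, cf)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        histology = hist_lab, gene = g, feature = f,
        n_carriers = sum(cf), n_noncarriers = sum(!cf),
        test_used = tst$test_used, transformed = tst$transformed,
        p_value = tst$p_value,
        log_fold_change = suppressWarnings(log_fold_change(v[cf], v[!cf])))
    }
  }
  if (length(rows) == 0L) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < fdr_cutoff
  attr(out, "skipped") <- skipped
  out
}
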