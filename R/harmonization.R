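#' Remove scanner/batch effects with parametric empirical-Bayes ComBat
#'
#' Per feature the values are standardized, batch location and scale are
#' estimated and shrunk toward parametric empirical-Bayes priors (normal for
#' location, inverse-gamma for scale), and the batch effects are removed
#' before back-transforming. Delegates the numerics to `sva::ComBat`.
#'
#' Behavior at the edges: with a single batch there is nothing to correct
#' and the input is returned unchanged; features with zero overall variance
#' cannot be standardized and are passed through unchanged with a warning;
#' a batch with fewer than 2 patients is an error naming the batch.
#'
#' By default no biological covariate is protected during harmonization; set
#' `protect_histology = TRUE` to preserve histology group means through the
#' ComBat design matrix.
#'
#' @param fm feature tibble with a `batch` column (and `histology` if
#'   protected); feature columns are all numeric columns except
#'   `patient_id`, `histology`, `batch`.
#' @param protect_histology protect histology means via the model matrix.
#' @return tibble of the same shape with harmonized feature values.
#' @examples
#' co <- make_cohort(n_per_histology = c(ADC = 30), n_genes = 5, seed = 2)
#' harm <- harmonize_features(co$features)
#' @export
harmonize_features <- function(fm, protect_histology = FALSE) {
  fm <- tibble::as_tibble(fm)
  stopifnot("batch" %in% names(fm))
  id_cols <- intersect(c("patient_id", "histology", "batch"), names(fm))
  feat_cols <- setdiff(names(fm)[vapply(fm, is.numeric, logical(1))], id_cols)
  if (length(feat_cols) == 0L) abort("No feature columns found.")
  x <- t(as.matrix(fm[, feat_cols]))  # features x patients
  if (any(!is.finite(x))) abort("non-finite feature values")
  batch <- as.character(fm$batch)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    abort(sprintf("batch '%s' has fewer than 2 patients",
                  names(sizes)[sizes < 2][1]))
  }
  if (length(sizes) < 2L) return(fm)

  v <- apply(x, 1L, var)
  flat <- v <= .Machine$double.eps * 100
  if (any(flat)) {
    warn(sprintf("%d zero-variance feature(s) passed through unchanged: %s",
                 sum(flat), paste(head(feat_cols[flat], 5), collapse = ", ")))
  }
  mod <- NULL
  if (protect_histology) {
    stopifnot("histology" %in% names(fm))
    mod <- stats::model.matrix(~ factor(fm$histology))
  }
  if (sum(!flat) == 1L) {
    # a single feature gives the EB priors nothing to pool over: use the
    # direct location/scale batch adjustment for that feature
    x[!flat, ] <- ls_adjust_one(x[!flat, ], batch)
  } else if (any(!flat)) {
    corrected <- suppressMessages(
      sva::ComBat(dat = x[!flat, , drop = FALSE], batch = batch, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE))
    x[!flat, ] <- corrected
  }
  fm[, feat_cols] <- tibble::as_tibble(t(x))
  fm
}

# Location/scale batch adjustment for one feature (no pooling across
# features): remove each batch's mean and scale in standardized space, then
# restore the grand mean and pooled scale.
ls_adjust_one <- function(v, batch) {
  alpha <- mean(v)
  s <- sd(v)
  z <- (v - alpha) / s
  for (b in unique(batch)) {
    sel <- batch == b
    zb_sd <- sd(z[sel])
    if (zb_sd > 0) z[sel] <- (z[sel] - mean(z[sel])) / zb_sd
    else z[sel] <- z[sel] - mean(z[sel])
  }
  z * s + alpha
}
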