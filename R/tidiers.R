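# broom-style accessors for the package's result objects.

#' Tidy a consensus clustering result
#'
#' @param x a `consensus_result`.
#' @param ... unused.
#' @return tibble with one row per patient: patient_id, cluster (at the
#'   chosen K).
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble::tibble(patient_id = x$patients,
                 cluster = unname(x$chosen_labels))
}

#' @rdname tidy.consensus_result
#' @return `glance()`: one-row tibble with k_opt, pac_min, n_patients,
#'   resamples.
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(
    k_opt = x$k_opt,
    pac_min = min(x$pac$pac),
    n_patients = length(x$patients),
    resamples = x$params$resamples)
}

#' Tidy a pipeline result
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return tibble with one row per histology summarizing the run.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$associations), function(h) {
    tibble::tibble(
      histology = h,
      n_association_rows = nrow(x$associations[[h]]),
      n_significant = sum(x$associations[[h]]$significant),
      k_opt = x$clustering[[h]]$k_opt,
      n_representative = sum(x$representative[[h]]$selected),
      min_pathway_p = suppressWarnings(
        min(x$pathway_tests[[h]]$p_value[!x$pathway_tests[[h]]$degenerate],
            na.rm = TRUE)),
      logrank_p = x$survival_tests[[h]]$p_value)
  }))
}
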