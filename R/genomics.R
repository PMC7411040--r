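# Gene-level alteration handling: condensation of variant calls into binary
# patient x gene x category flags, pathway aggregation, and the cohort
# bookkeeping filters.

alteration_categories <- c("MUT", "LoF", "CNV", "FUSION")

# Map free-text variant descriptions to the four categories when calls
# arrive unclassified.
classify_detail <- function(detail) {
  d <- tolower(detail)
  dplyr::case_when(
    grepl("missense|miss-sense", d) ~ "MUT",
    grepl("frame|stop[- _]?gain|nonsense|loss[- _]?of[- _]?function", d) ~ "LoF",
    grepl("cnv|copy|amplif|delet", d) ~ "CNV",
    grepl("fusion", d) ~ "FUSION",
    TRUE ~ NA_character_
  )
}

#' Condense variant calls to binary gene-level alteration flags
#'
#' Multiple calls of one category in the same gene and patient collapse to a
#' single flag. Calls may arrive pre-classified (`category` column with
#' values MUT, LoF, CNV, FUSION) or with a free-text `detail` column
#' (e.g. "missense", "stop-gain", "fusion") that is mapped to the four
#' categories.
#'
#' @param calls data frame with `patient_id`, `gene` and `category` (or
#'   `detail`).
#' @param patients,genes optional full universes (patients with no calls,
#'   genes never altered) carried as attributes for downstream matrices.
#' @return tibble of class `alteration_matrix`: unique
#'   (`patient_id`, `gene`, `category`) rows with attributes `patients` and
#'   `genes`.
#' @examples
#' condense_calls(data.frame(
#'   patient_id = c("p1", "p1", "p2"), gene = c("TP53", "TP53", "EGFR"),
#'   detail = c("missense", "missense", "stop-gain")
#' ))
#' @export
condense_calls <- function(calls, patients = NULL, genes = NULL) {
  calls <- tibble::as_tibble(calls)
  if (!all(c("patient_id", "gene") %in% names(calls))) {
    abort("`calls` needs `patient_id` and `gene` columns.")
  }
  if (!"category" %in% names(calls)) {
    if (!"detail" %in% names(calls)) {
      abort("`calls` needs a `category` or `detail` column.")
    }
    calls$category <- classify_detail(calls$detail)
    if (anyNA(calls$category)) {
      abort(paste("Unrecognized variant detail; valid categories are:",
                  paste(alteration_categories, collapse = ", ")))
    }
  }
  bad <- setdiff(unique(calls$category), alteration_categories)
  if (length(bad)) {
    abort(sprintf("Unknown category '%s'; valid categories are: %s",
                  bad[1], paste(alteration_categories, collapse = ", ")))
  }
  out <- dplyr::distinct(calls[, c("patient_id", "gene", "category")])
  out <- dplyr::arrange(out, .data$patient_id, .data$gene, .data$category)
  attr(out, "patients") <- sort(unique(c(patients, out$patient_id)))
  attr(out, "genes") <- sort(unique(c(genes, out$gene)))
  class(out) <- c("alteration_matrix", class(out))
  out
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat("<alteration_matrix> ", nrow(x), " flags, ",
      length(attr(x, "patients")), " patients x ",
      length(attr(x, "genes")), " genes\n", sep = "")
  NextMethod()
}

# Wide 0/1 patient x gene matrix (any category OR) from a condensed table.
alteration_wide <- function(am, category = NULL) {
  patients <- attr(am, "patients")
  genes <- attr(am, "genes")
  m <- matrix(0L, length(patients), length(genes),
              dimnames = list(patients, genes))
  rows <- if (is.null(category)) am else am[am$category == category, ]
  if (nrow(rows)) {
    m[cbind(match(rows$patient_id, patients), match(rows$gene, genes))] <- 1L
  }
  m
}

#' Aggregate gene alterations to pathway flags
#'
#' A patient carries a pathway alteration if any member gene of the pathway
#' is altered (per category, and overall).
#'
#' @param am an `alteration_matrix` from [condense_calls()].
#' @param pm pathway map: data frame `pathway`, `gene`. Pathway genes absent
#'   from the panel raise a warning and are ignored.
#' @return tibble: `patient_id`, `pathway`, columns `MUT`, `LoF`, `CNV`,
#'   `FUSION`, `any` (0/1).
#' @export
pathway_flags <- function(am, pm) {
  pm <- tibble::as_tibble(pm)
  stopifnot(all(c("pathway", "gene") %in% names(pm)))
  genes <- attr(am, "genes")
  missing_genes <- setdiff(pm$gene, genes)
  if (length(missing_genes)) {
    warn(sprintf("%d pathway gene(s) absent from the panel ignored: %s",
                 length(missing_genes),
                 paste(head(missing_genes, 5), collapse = ", ")))
    pm <- pm[pm$gene %in% genes, ]
  }
  patients <- attr(am, "patients")
  pws <- unique(pm$pathway)
  per_cat <- lapply(alteration_categories, function(cc) alteration_wide(am, cc))
  names(per_cat) <- alteration_categories
  out <- lapply(pws, function(pw) {
    members <- pm$gene[pm$pathway == pw]
    flags <- vapply(alteration_categories, function(cc) {
      as.integer(rowSums(per_cat[[cc]][, members, drop = FALSE]) > 0)
    }, integer(length(patients)))
    if (is.null(dim(flags))) {
      flags <- matrix(flags, nrow = 1L,
                      dimnames = list(NULL, alteration_categories))
    }
    tibble::tibble(patient_id = patients, pathway = pw,
                   MUT = flags[, "MUT"], LoF = flags[, "LoF"],
                   CNV = flags[, "CNV"], FUSION = flags[, "FUSION"],
                   any = as.integer(rowSums(flags) > 0))
  })
  dplyr::bind_rows(out)
}

#' Filter genes by carrier count
#'
#' Retains major genes: those altered (any category) in more than
#' `min_carriers - 1` patients, i.e. at least `min_carriers`.
#'
#' @param am an `alteration_matrix`.
#' @param min_carriers minimum carrier count to retain (default 4, the
#'   "mutated in more than 3 patients" rule).
#' @return character vector of retained gene names.
#' @export
major_gene_filter <- function(am, min_carriers = 4L) {
  w <- alteration_wide(am)
  colnames(w)[colSums(w) >= min_carriers]
}

#' Sequential cohort exclusion accounting
#'
#' Applies an exclusion ledger to a candidate count, reporting the running
#' remainder after each stage. Totals are conserved at every stage
#' (remaining + cumulative excluded = candidates). If `expected_final` is
#' supplied and disagrees with the computed remainder, the discrepancy is
#' reported in the `note` attribute and flagged, not silently forced.
#'
#' @param n_candidates integer, patients entering the funnel.
#' @param exclusions data frame with `stage` (label) and `n_excluded`.
#' @param expected_final optional externally-stated final cohort size.
#' @return tibble: `stage`, `excluded`, `remaining`, with attributes
#'   `consistent` (logical) and `note`.
#' @examples
#' cohort_filter(417, data.frame(
#'   stage = c("post-therapy or late biopsy", "QC fail", "cell line",
#'             "assay cancelled", "other histology"),
#'   n_excluded = c(28, 95, 20, 55, 11)
#' ))
#' @export
cohort_filter <- function(n_candidates, exclusions, expected_final = NULL) {
  exclusions <- tibble::as_tibble(exclusions)
  if (nrow(exclusions) > 0) {
    stopifnot(all(c("stage", "n_excluded") %in% names(exclusions)))
    if (any(exclusions$n_excluded < 0)) abort("negative exclusion count")
  }
  remaining <- n_candidates - c(0, cumsum(exclusions$n_excluded))
  out <- tibble::tibble(
    stage = c("candidates", exclusions$stage),
    excluded = c(0L, as.integer(exclusions$n_excluded)),
    remaining = as.integer(remaining))
  if (any(out$remaining < 0)) abort("exclusions exceed candidates")
  final <- out$remaining[nrow(out)]
  consistent <- TRUE
  note <- ""
  if (!is.null(expected_final) && expected_final != final) {
    consistent <- FALSE
    note <- sprintf(
      "declared final cohort (%d) does not match computed remainder (%d)",
      expected_final, final)
    warn(note)
  }
  attr(out, "consistent") <- consistent
  attr(out, "note") <- note
  out
}
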