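#' The canonical 86-feature catalog
#'
#' One row per feature with its family, texture/non-texture class, units and
#' robust-subset flag: 55 texture features (GLCM 16, GLRM 11, GLSZM 11,
#' NGLD 9, TFC 3, TFCCM 5) and 31 non-texture features (SUV/intensity
#' histogram 25, texture spectrum 2, geometry 4). The default robust subset
#' flags 27 features that remain usable across segmentation methods; its
#' membership is configuration, not a property of the math, and can be
#' overridden in [extract_features()].
#'
#' @return tibble with columns `name`, `family`, `class`
#'   (`"texture"`/`"non-texture"`), `units`, `robust`.
#' @examples
#' dplyr::count(feature_catalog(), class)
#' @export
feature_catalog <- function() {
  intensity <- c("suv_max", "suv_mean", "suv_min", "suv_sd", "suv_peak",
                 "sul_max", "sul_mean", "sul_peak", "surface_suv_sd",
                 "mtv", "tlg", "suv_skewness", "suv_kurtosis",
                 "hist_entropy", "hist_uniformity", "suv_cov", "suv_median",
                 "suv_p10", "suv_p25", "suv_p75", "suv_p90", "suv_iqr",
                 "suv_range", "suv_mad", "suv_rms")
  glcm <- c("glcm_energy", "glcm_contrast", "glcm_norm_contrast",
            "glcm_entropy", "glcm_homogeneity", "glcm_dissimilarity",
            "glcm_idm", "glcm_correlation", "glcm_variance",
            "glcm_sum_mean", "glcm_sum_variance", "glcm_sum_entropy",
            "glcm_diff_mean", "glcm_diff_variance", "glcm_diff_entropy",
            "glcm_cluster_shade")
  glrm <- c("glrm_sre", "glrm_lre", "glrm_lgre", "glrm_hgre", "glrm_srlge",
            "glrm_srhge", "glrm_lrlge", "glrm_lrhge", "glrm_glnu",
            "glrm_rlnu", "glrm_rp")
  glszm <- c("glszm_sze", "glszm_lze", "glszm_lgze", "glszm_hgze",
             "glszm_szlge", "glszm_szhge", "glszm_lzlge", "glszm_lzhge",
             "glszm_glnu", "glszm_zsnu", "glszm_zp")
  ngld <- c("ngld_sne", "ngld_lne", "ngld_nnu", "ngld_second_moment",
            "ngld_entropy", "ngld_dcp", "ngld_glnu", "ngld_lgce",
            "ngld_hgce")
  tfc <- c("tfc_mean_convergence", "tfc_variance", "tfc_code_entropy")
  tfccm <- c("tfccm_sam", "tfccm_contrast", "tfccm_entropy", "tfccm_idm",
             "tfccm_code_similarity")
  ts <- c("ts_peak_fraction", "ts_uniformity")
  geom <- c("geom_surface_area", "geom_sphericity", "geom_irregularity",
            "geom_eccentricity")

  units <- c(
    setNames(rep("SUV", 25), intensity), mtv = "cm^3", tlg = "SUV*cm^3",
    geom_surface_area = "cm^2"
  )
  dimless <- c("suv_skewness", "suv_kurtosis", "hist_entropy",
               "hist_uniformity", "suv_cov")

  cat_tbl <- tibble::tibble(
    name = c(intensity, ts, geom, glcm, glrm, glszm, ngld, tfc, tfccm),
    family = c(rep("intensity", length(intensity)),
               rep("texture_spectrum", length(ts)),
               rep("geometry", length(geom)),
               rep("glcm", length(glcm)), rep("glrm", length(glrm)),
               rep("glszm", length(glszm)), rep("ngld", length(ngld)),
               rep("tfc", length(tfc)), rep("tfccm", length(tfccm))),
    class = c(rep("non-texture", length(intensity) + length(ts) + length(geom)),
              rep("texture", length(glcm) + length(glrm) + length(glszm) +
                    length(ngld) + length(tfc) + length(tfccm)))
  )
  cat_tbl$units <- ifelse(cat_tbl$name %in% names(units),
                          units[cat_tbl$name],
                          ifelse(cat_tbl$name %in% dimless, "-", "-"))
  cat_tbl$units[cat_tbl$name %in% setdiff(intensity, c("mtv", "tlg")) &
                  !(cat_tbl$name %in% dimless)] <- "SUV"
  cat_tbl$units[cat_tbl$name == "mtv"] <- "cm^3"
  cat_tbl$units[cat_tbl$name == "tlg"] <- "SUV*cm^3"
  cat_tbl$units[cat_tbl$name == "geom_surface_area"] <- "cm^2"
  cat_tbl$robust <- cat_tbl$name %in% robust_features()
  cat_tbl
}

#' Default robust feature subset (27 names)
#'
#' Features retained for downstream association and clustering because they
#' are comparatively stable across delineation methods. The set includes
#' every feature reported in the published association and cluster-signature
#' tables (SUVmax, SUVpeak, SULpeak, histogram entropy, SUV SD, surface SUV
#' SD, GLCM contrast/normalized contrast/IDM, GLRM short-run emphasis,
#' TFCCM IDM, TFC mean convergence, NGLD small-number emphasis) padded with
#' documented common choices to 27 names.
#'
#' @return character vector of 27 feature names.
#' @export
robust_features <- function() {
  c("suv_max", "suv_peak", "sul_peak", "suv_mean", "suv_sd",
    "surface_suv_sd", "hist_entropy", "suv_cov", "suv_skewness",
    "mtv", "tlg",
    "glcm_contrast", "glcm_norm_contrast", "glcm_idm", "glcm_entropy",
    "glcm_energy", "glcm_correlation",
    "glrm_sre", "glrm_lre", "glrm_rp",
    "glszm_sze", "glszm_zp",
    "ngld_sne", "ngld_lne",
    "tfc_mean_convergence", "tfccm_idm", "tfccm_entropy")
}

#' Extract the full 86-feature vector from a VOI
#'
#' Quantizes the VOI to 64 gray levels (fixed bin number over the in-mask
#' range) and computes every feature in [feature_catalog()]. SUL features
#' require `patient_meta` (sex, weight, height) on the volume and are `NA`
#' when absent; all other features are always computed.
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()] with at least 8 voxels.
#' @param levels gray levels for quantization (default 64).
#' @param robust feature names flagged as the robust subset (default
#'   [robust_features()]).
#' @return one-row tibble: `patient_id`, `lesion_id` (both `NA` unless set
#'   via `patient_id=`/`lesion_id=`), then the 86 features in catalog order,
#'   plus attribute `"robust"`.
#' @param patient_id,lesion_id optional identifiers carried into the row.
#' @examples
#' ph <- make_lesion_phantom(
#'   c(24, 24, 24), c(3, 3, 3),
#'   lesion_spec(center = c(34, 34, 34), radii = c(14, 14, 14),
#'               heterogeneity_sd = 2), seed = 7
#' )
#' fv <- extract_features(ph$volume, ph$mask)
#' fv$suv_max
#' @export
extract_features <- function(volume, mask, levels = 64L,
                             robust = robust_features(),
                             patient_id = NA_character_,
                             lesion_id = NA_character_) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"))
  check_aligned(volume, mask)
  if (sum(mask$mask) < 8L) abort("VOI too small for texture analysis")
  q <- quantize_voi(volume, mask, levels)
  vals <- c(
    intensity_features(volume, mask, levels),
    texture_spectrum_features(q),
    geometry_features(mask),
    glcm_features(q),
    glrm_features(q),
    glszm_features(q),
    ngld_features(q),
    tfc_features(q),
    tfccm_features(q)
  )
  catalog <- feature_catalog()
  stopifnot(setequal(names(vals), catalog$name))
  vals <- vals[catalog$name]
  out <- tibble::as_tibble(as.list(vals))
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id, lesion_id = lesion_id), out
  )
  attr(out, "robust") <- intersect(robust, catalog$name)
  out
}
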