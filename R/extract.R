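#' Extract one dosimetric feature group for one region
#'
#' Feature names are prefixed `region__family__feature` so that a flat
#' feature table keeps its (region, group) provenance.
#'
#' @param volume An analysis-ready [dose_volume()] (already session-summed
#'   and outlier-clipped).
#' @param region Region name.
#' @param group `"mean_dose"` (1 value), `"dose_volume"` (24),
#'   `"firstorder"` (18), `"dosiomics_full"` (the 93 dosiomics: first-order
#'   plus GLCM/GLRLM/GLSZM/NGTDM/GLDM textures), or `"all"` (the union,
#'   118 values).
#' @param bin_width Discretization bin width in Gy.
#' @return Named numeric vector.
#' @export
extract_region_features <- function(volume, region,
                                    group = c("mean_dose", "dose_volume",
                                              "firstorder", "dosiomics_full",
                                              "all"),
                                    bin_width = 0.5) {
  group <- match.arg(group)
  pre <- function(fam, v) setNames(v, paste0(region, "__", fam, "__",
                                             names(v)))
  m <- region_mask(volume, region)
  doses <- volume$values[m]
  sorted <- sort(doses)
  out <- numeric(0)
  if (group %in% c("mean_dose", "all"))
    out <- c(out, setNames(sum(doses) / length(doses),
                           paste0(region, "__meandose")))
  if (group %in% c("dose_volume", "all"))
    out <- c(out, pre("dv", dv_from_sorted(sorted)))
  if (group %in% c("firstorder", "dosiomics_full", "all")) {
    disc <- discretize(volume, region, bin_width)
    counts <- tabulate(disc$levels[!is.na(disc$levels)],
                       nbins = disc$n_levels)
    out <- c(out, pre("firstorder",
                      firstorder_from_sorted(sorted, counts,
                                             prod(volume$spacing))))
    if (group != "firstorder") {
      out <- c(out, pre("glcm", glcm_features(disc)))
      out <- c(out, pre("glrlm", texture_matrix_features(disc, "GLRLM")))
      out <- c(out, pre("glszm", texture_matrix_features(disc, "GLSZM")))
      out <- c(out, pre("ngtdm", texture_matrix_features(disc, "NGTDM")))
      out <- c(out, pre("gldm", texture_matrix_features(disc, "GLDM")))
    }
  }
  out
}

scale_regions <- function(scale = c("whole_heart", "subparts")) {
  scale <- match.arg(scale)
  if (scale == "whole_heart") "whole_heart" else
    setdiff(heart_regions(), "whole_heart")
}

#' Build a patient-by-feature table
#'
#' Concatenates the clinical and chemotherapy columns of `records` with one
#' dosimetric feature group extracted over the chosen spatial scale. Each
#' patient's course is session-summed within the six-month window and
#' outlier-clipped at the whole-heart D2 before extraction.
#'
#' @param records Patient tibble from [generate_cohort()] (or with the same
#'   clinical columns).
#' @param courses Named list of [rt_course()] objects, one per `patient_id`.
#' @param group Dosimetric feature group, see [extract_region_features()].
#' @param scale `"whole_heart"` or `"subparts"`.
#' @param window_days,clip_quantile,bin_width Preprocessing parameters.
#' @return A tibble: `patient_id`, clinical columns, dosimetric columns.
#' @export
extract_feature_table <- function(records, courses,
                                  group = "mean_dose",
                                  scale = c("whole_heart", "subparts"),
                                  window_days = 183, clip_quantile = 0.98,
                                  bin_width = 0.5) {
  regions <- scale_regions(scale)
  dosim <- purrr::map(records$patient_id, function(pid) {
    course <- courses[[as.character(pid)]]
    if (is.null(course))
      stop("no course for patient ", pid, call. = FALSE)
    vol <- clip_outliers(aggregate_sessions(course, window_days),
                         quantile = clip_quantile)
    unlist(lapply(regions, function(r)
      extract_region_features(vol, r, group, bin_width)))
  })
  dosim <- tibble::as_tibble(do.call(rbind, dosim))
  dplyr::bind_cols(clinical_columns(records), dosim)
}

#' Clinical and chemotherapy predictor columns of a patient table
#'
#' Expands the age category into dummy indicators (reference 0-5 years) and
#' keeps sex, the diagnosis-group indicators and the two chemotherapy flags.
#'
#' @param records Patient tibble.
#' @return Tibble with `patient_id` and the clinical predictors.
#' @export
clinical_columns <- function(records) {
  out <- tibble::tibble(
    patient_id = records$patient_id,
    sex = as.numeric(records$sex),
    age_6_10 = as.numeric(records$age_category == "6-10"),
    age_11_15 = as.numeric(records$age_category == "11-15"),
    age_gt15 = as.numeric(records$age_category == ">15"))
  dx <- dplyr::select(records, dplyr::starts_with("dx_"))
  dplyr::bind_cols(out, dx,
                   tibble::tibble(
                     anthracyclines = as.numeric(records$anthracyclines),
                     alkylating_agents =
                       as.numeric(records$alkylating_agents)))
}

#' Metadata for feature-table columns
#'
#' Parses `region__family__feature` column names back into (region, family,
#' feature) tags; clinical columns are tagged `clinical`.
#'
#' @param table A feature table (tibble).
#' @return Tibble with columns `column`, `region`, `family`, `feature`.
#' @export
feature_metadata <- function(table) {
  nm <- setdiff(names(table), "patient_id")
  parts <- strsplit(nm, "__", fixed = TRUE)
  purrr::map2_dfr(nm, parts, function(n, p) {
    if (length(p) == 1L)
      tibble::tibble(column = n, region = NA_character_,
                     family = "clinical", feature = n)
    else if (length(p) == 2L)
      tibble::tibble(column = n, region = p[1], family = "meandose",
                     feature = "meandose")
    else
      tibble::tibble(column = n, region = p[1], family = p[2],
                     feature = p[3])
  })
}

# Columns of the "all"-groups table belonging to one (group, scale) spec.
feature_group_columns <- function(all_names, group, scale) {
  regions <- scale_regions(scale)
  fams <- switch(group,
    mean_dose = "meandose",
    dose_volume = "dv",
    firstorder = "firstorder",
    dosiomics_full = c("firstorder", "glcm", "glrlm", "glszm", "ngtdm",
                       "gldm"),
    stop("unknown feature group: ", group, call. = FALSE))
  keep <- unlist(lapply(regions, function(r) {
    if (identical(fams, "meandose")) paste0(r, "__meandose") else
      unlist(lapply(fams, function(f)
        grep(paste0("^", r, "__", f, "__"), all_names, value = TRUE)))
  }))
  intersect(all_names, keep)
}
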