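FEATURE_NAMES <- c("wb_norm_4h", "wb_norm_24h", "wb_norm_48h",
                   "blood_4h", "blood_24h", "blood_48h",
                   "age_y", "weight_kg")
FEATURE_TIMES_H <- c(4, 24, 48)

#' Abbreviated-protocol feature vector for one patient
#'
#' Builds the eight predictor inputs from the first three study days only:
#' whole-body retained fractions (standard-ratio normalized, baseline = 4 h)
#' and blood fraction-per-mL at 4, 24 and 48 h, plus age and weight. Later
#' time points in the record are ignored, so a full five-point record yields
#' the same features as its 4/24/48 h truncation. Column order is fixed:
#' `wb_norm_4h, wb_norm_24h, wb_norm_48h, blood_4h, blood_24h, blood_48h,
#' age_y, weight_kg`.
#'
#' @param record a [patient_record()] containing whole-body scans (with
#'   source standard) and blood samples at 4, 24 and 48 h.
#' @param constants see [dosimetry_constants()].
#' @return A one-row tibble with `patient_id` plus the eight feature columns.
#' @export
build_features <- function(record, constants = dosimetry_constants()) {
  stopifnot(inherits(record, "patient_record"))
  fracs <- retained_fractions(record$scans, constants = constants)
  wb <- dplyr::filter(fracs, .data$region == "whole_body",
                      .data$time_h %in% FEATURE_TIMES_H)
  bl <- dplyr::filter(
    blood_fractions(record$blood, record$patient$administered_activity_MBq,
                    constants),
    .data$time_h %in% FEATURE_TIMES_H
  )
  missing_bits <- c(
    sprintf("whole-body scan at %d h", setdiff(FEATURE_TIMES_H, wb$time_h)),
    sprintf("blood sample at %d h", setdiff(FEATURE_TIMES_H, bl$time_h))
  )
  if (length(missing_bits)) {
    stop("cannot build features: missing ", paste(missing_bits, collapse = ", "),
         call. = FALSE)
  }
  wb <- dplyr::arrange(wb, .data$time_h)
  bl <- dplyr::arrange(bl, .data$time_h)
  out <- tibble::tibble(
    patient_id = record$patient$patient_id,
    wb_norm_4h = wb$retained_fraction[1],
    wb_norm_24h = wb$retained_fraction[2],
    wb_norm_48h = wb$retained_fraction[3],
    blood_4h = bl$fraction_per_mL[1],
    blood_24h = bl$fraction_per_mL[2],
    blood_48h = bl$fraction_per_mL[3],
    age_y = record$patient$age_y,
    weight_kg = record$patient$weight_kg
  )
  if (any(!is.finite(unlist(out[FEATURE_NAMES])))) {
    stop("non-finite feature value", call. = FALSE)
  }
  out
}

#' Feature table for a whole cohort
#'
#' Applies [build_features()] to every patient in cohort-level tables.
#'
#' @param patients,scans,blood cohort tibbles keyed by `patient_id`.
#' @param constants see [dosimetry_constants()].
#' @return A tibble with one feature row per patient.
#' @export
cohort_features <- function(patients, scans, blood,
                            constants = dosimetry_constants()) {
  recs <- split_records(patients, scans, blood)
  dplyr::bind_rows(lapply(recs, build_features, constants = constants))
}
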