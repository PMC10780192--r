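#' Blood absorbed dose per unit administered activity
#'
#' Standard Benua/EANM blood-dosimetry form: the beta self-dose of activity in
#' the blood plus the photon contribution from activity anywhere in the body,
#'
#' `D/A0 [Gy/GBq] = 108 * tau_mL + 0.0188 * weight_kg^(-2/3) * tau_wb`
#'
#' where `tau_mL` is the time-integrated blood activity concentration per
#' administered activity (h/mL) and `tau_wb` the whole-body time-integrated
#' activity coefficient (h), both on *effective* retention (physical decay
#' included).
#'
#' @param tau_blood_per_mL time-integrated blood concentration, h/mL.
#' @param tau_whole_body whole-body time-integrated activity coefficient, h.
#' @param weight_kg patient weight in kg.
#' @param constants see [dosimetry_constants()].
#' @return Blood absorbed dose per administered activity, Gy/GBq.
#' @examples
#' blood_dose_per_unit_activity(3.5e-3, 30, 70) # ~0.411 Gy/GBq
#' @export
blood_dose_per_unit_activity <- function(tau_blood_per_mL, tau_whole_body,
                                         weight_kg,
                                         constants = dosimetry_constants()) {
  if (any(weight_kg <= 0)) stop("weight_kg must be > 0", call. = FALSE)
  if (any(tau_blood_per_mL < 0) || any(tau_whole_body < 0)) {
    stop("time-integrated coefficients must be >= 0", call. = FALSE)
  }
  constants$beta_self_Gy_mL_per_GBq_h * tau_blood_per_mL +
    constants$photon_wb_coef * weight_kg^(-2 / 3) * tau_whole_body
}

#' Maximum permissible activity under the 2 Gy blood-dose limit
#'
#' Inverts the blood-dose coefficient at the 2 Gy threshold and converts to
#' mCi (1 mCi = 0.037 GBq).
#'
#' @param dose_per_A0 blood dose coefficient, Gy/GBq (> 0).
#' @param constants see [dosimetry_constants()].
#' @return Activity in mCi.
#' @examples
#' mpa_blood_limit(2) # exactly 1 GBq = 27.03 mCi
#' @export
mpa_blood_limit <- function(dose_per_A0, constants = dosimetry_constants()) {
  if (any(!is.finite(dose_per_A0)) || any(dose_per_A0 <= 0)) {
    stop("dose coefficient must be finite and > 0", call. = FALSE)
  }
  gbq_to_mci(constants$blood_dose_limit_Gy / dose_per_A0)
}

#' Retention-capped administered activity
#'
#' The 48 h retention safety caps: whole-body retention may not exceed
#' 120 mCi (4.4 GBq); activity in the lungs may not exceed 80 mCi (3 GBq);
#' and for patients with iodine-avid diffuse lung metastases the 80 mCi cap
#' is applied to whole-body retention. Each cap divides its activity limit by
#' the corresponding retained fraction at 48 h; the binding (smallest)
#' candidate is returned with its label.
#'
#' @param wb_fraction_48h whole-body retained fraction of administered
#'   activity at 48 h (effective, i.e. physical decay included), in (0, 1].
#' @param lung_fraction_48h lung retained fraction at 48 h from the chest
#'   ROI, or `NA` when no chest ROI is available.
#' @param diffuse_lung_mets logical flag.
#' @param constants see [dosimetry_constants()].
#' @return One-row tibble with `activity_mCi` and `constraint`
#'   (`"wb_48h_120mCi"` or `"lung_48h_80mCi"`).
#' @examples
#' retention_limited_activity(0.25)                            # 480 mCi
#' retention_limited_activity(0.25, diffuse_lung_mets = TRUE)  # 320 mCi
#' @export
retention_limited_activity <- function(wb_fraction_48h, lung_fraction_48h = NA,
                                       diffuse_lung_mets = FALSE,
                                       constants = dosimetry_constants()) {
  if (!is.finite(wb_fraction_48h) || wb_fraction_48h <= 0 || wb_fraction_48h > 1) {
    stop("wb_fraction_48h must be in (0, 1]", call. = FALSE)
  }
  caps <- constants$wb_retention_cap_mCi / wb_fraction_48h
  labels <- "wb_48h_120mCi"
  if (isTRUE(diffuse_lung_mets)) {
    caps <- c(constants$lung_retention_cap_mCi / wb_fraction_48h, caps)
    labels <- c("lung_48h_80mCi", labels)
  }
  if (!is.na(lung_fraction_48h)) {
    if (lung_fraction_48h <= 0 || lung_fraction_48h > 1) {
      stop("lung_fraction_48h must be in (0, 1]", call. = FALSE)
    }
    caps <- c(caps, constants$lung_retention_cap_mCi / lung_fraction_48h)
    labels <- c(labels, "lung_48h_80mCi")
  }
  i <- which.min(caps)
  tibble::tibble(activity_mCi = caps[i], constraint = labels[i])
}

#' Maximum permissible activity for one patient
#'
#' Runs the full blood-dose-limited pipeline on a patient record: reduces
#' counts to retained fractions and blood concentrations, converts them to
#' effective retention, fits clearance curves, integrates them to
#' time-integrated activity coefficients, evaluates the blood-dose formula
#' and the 48 h retention caps, and returns the binding constraint. The
#' computation is deterministic given a record.
#'
#' @param record a [patient_record()] with at least two whole-body scans
#'   (plus matching source-standard scans, including the 4 h baseline) and at
#'   least two blood samples.
#' @param method integration method, `"analytic"` (default; unbiased when the
#'   exponential model holds, which sparse protocol sampling otherwise turns
#'   into a several-percent trapezoid bias) or `"trapezoid_tail"`.
#' @param constants see [dosimetry_constants()].
#' @return One-row tibble: `patient_id`, `mpa_blood_mCi`,
#'   `mpa_wb_retention_mCi`, `mpa_lung_retention_mCi` (`NA` without a chest
#'   ROI), `mpa_final_mCi`, `limiting_constraint`, plus intermediates
#'   `wb_fraction_48h`, `lung_fraction_48h`, `tau_wb_h`,
#'   `tau_blood_h_per_mL`, `blood_dose_Gy_per_GBq`.
#' @export
compute_mpa <- function(record, method = c("analytic", "trapezoid_tail"),
                        constants = dosimetry_constants()) {
  stopifnot(inherits(record, "patient_record"))
  method <- match.arg(method)
  p <- record$patient

  fracs <- retained_fractions(record$scans, constants = constants)
  wb <- dplyr::arrange(dplyr::filter(fracs, .data$region == "whole_body"), .data$time_h)
  lung <- dplyr::filter(fracs, .data$region == "chest")
  blood_pts <- dplyr::arrange(
    blood_fractions(record$blood, p$administered_activity_MBq, constants),
    .data$time_h
  )

  missing_bits <- c(
    if (nrow(wb) < 2) sprintf("whole-body scans (%d found, >= 2 needed)", nrow(wb)),
    if (nrow(blood_pts) < 2) sprintf("blood samples (%d found, >= 2 needed)", nrow(blood_pts))
  )
  if (length(missing_bits)) {
    stop("insufficient data for MPA: missing ", paste(missing_bits, collapse = "; "),
         call. = FALSE)
  }

  # integrate effective retention: physical decay restored onto the
  # decay-corrected (biological) fractions
  eff_wb <- effective_retention(wb[c("time_h", "retained_fraction")], constants)
  eff_blood <- effective_retention(blood_pts, constants)
  fit_wb <- fit_clearance(eff_wb)
  fit_blood <- fit_clearance(eff_blood)
  tau_wb <- time_integrated_coefficient(fit_wb, eff_wb, method)
  tau_mL <- time_integrated_coefficient(fit_blood, eff_blood, method)

  # 48 h effective retained fractions: measured when available, else modelled
  f48 <- eff_wb$retained_fraction[eff_wb$time_h == 48]
  if (length(f48) != 1L) f48 <- unname(predict(fit_wb, 48))
  f48 <- min(f48, 1)
  lung48 <- NA_real_
  if (nrow(lung) > 0 && any(lung$time_h == 48)) {
    lung48 <- lung$retained_fraction[lung$time_h == 48][1] /
      decay_correction_factor(48, constants$i131_half_life_h)
  }

  dose_coef <- blood_dose_per_unit_activity(tau_mL, tau_wb, p$weight_kg, constants)
  mpa_blood <- mpa_blood_limit(dose_coef, constants)
  ret <- retention_limited_activity(f48, lung48, isTRUE(p$diffuse_lung_mets), constants)

  wb_cap_limit <- if (isTRUE(p$diffuse_lung_mets)) {
    constants$lung_retention_cap_mCi
  } else {
    constants$wb_retention_cap_mCi
  }
  mpa_wb_ret <- wb_cap_limit / f48
  mpa_lung_ret <- if (is.na(lung48)) NA_real_ else constants$lung_retention_cap_mCi / lung48

  candidates <- c(blood_2Gy = mpa_blood, stats::setNames(ret$activity_mCi, ret$constraint))
  i <- which.min(candidates)

  tibble::tibble(
    patient_id = p$patient_id,
    mpa_blood_mCi = mpa_blood,
    mpa_wb_retention_mCi = mpa_wb_ret,
    mpa_lung_retention_mCi = mpa_lung_ret,
    mpa_final_mCi = unname(candidates[i]),
    limiting_constraint = names(candidates)[i],
    wb_fraction_48h = f48,
    lung_fraction_48h = lung48,
    tau_wb_h = tau_wb,
    tau_blood_h_per_mL = tau_mL,
    blood_dose_Gy_per_GBq = dose_coef
  )
}

#' Maximum permissible activity for a whole cohort
#'
#' Applies [compute_mpa()] to every patient in cohort-level tables.
#'
#' @param patients,scans,blood cohort tibbles keyed by `patient_id` (the
#'   layout produced by [generate_cohort()] / [read_cohort()]).
#' @inheritParams compute_mpa
#' @return A tibble with one [compute_mpa()] row per patient.
#' @export
dose_cohort <- function(patients, scans, blood,
                        method = c("analytic", "trapezoid_tail"),
                        constants = dosimetry_constants()) {
  method <- match.arg(method)
  recs <- split_records(patients, scans, blood)
  dplyr::bind_rows(lapply(recs, compute_mpa, method = method, constants = constants))
}
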