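PROTOCOL_TIMES_H <- c(4, 24, 48, 72, 96)

#' Assemble and validate a patient dosimetry record
#'
#' Bundles one patient's demographics, conjugate-view scan table and blood
#' sample table into a validated record consumed by [compute_mpa()] and
#' [build_features()].
#'
#' @param patient one-row data frame with `patient_id`, `age_y`, `weight_kg`,
#'   `diffuse_lung_mets` (logical) and `administered_activity_MBq`.
#' @param scans data frame of conjugate-view measurements: `time_h`, `region`
#'   (`whole_body`/`chest`/`standard`), `anterior_counts`, `posterior_counts`,
#'   `duration_s`. Scan times must be a subset of the 4/24/48/72/96 h
#'   protocol grid.
#' @param blood data frame of well-counter measurements: `time_h`,
#'   `gross_cpm`, `volume_mL`, `background_cpm`, `capsule_cpm`,
#'   `capsule_activity_MBq`.
#' @return An object of class `patient_record` (a list with elements
#'   `patient`, `scans`, `blood`).
#' @export
patient_record <- function(patient, scans, blood) {
  patient <- tibble::as_tibble(patient)
  scans <- tibble::as_tibble(scans)
  blood <- tibble::as_tibble(blood)
  stopifnot(nrow(patient) == 1L)
  if (patient$weight_kg <= 0) stop("weight_kg must be > 0", call. = FALSE)
  if (patient$age_y < 18) stop("age_y must be >= 18 (adult cohort)", call. = FALSE)
  if (patient$administered_activity_MBq <= 0) {
    stop("administered_activity_MBq must be > 0", call. = FALSE)
  }
  if (!all(scans$time_h %in% PROTOCOL_TIMES_H)) {
    stop("scan time points must be a subset of {4, 24, 48, 72, 96} h",
         call. = FALSE)
  }
  if (any(scans$anterior_counts < 0) || any(scans$posterior_counts < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (any(scans$duration_s <= 0)) stop("duration_s must be > 0", call. = FALSE)
  if (nrow(blood) > 0) {
    if (any(blood$volume_mL <= 0)) stop("volume_mL must be > 0", call. = FALSE)
    if (any(blood$capsule_cpm <= blood$background_cpm)) {
      stop("capsule_cpm must exceed background_cpm", call. = FALSE)
    }
  }
  structure(list(patient = patient, scans = scans, blood = blood),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  p <- x$patient
  cat(sprintf(
    "<patient_record> %s: %g y, %.1f kg, %s, %.1f MBq tracer\n",
    p$patient_id, p$age_y, p$weight_kg,
    if (isTRUE(p$diffuse_lung_mets)) "diffuse lung mets" else "no diffuse mets",
    p$administered_activity_MBq
  ))
  cat(sprintf("  scans: %d rows at %s h; blood: %d samples at %s h\n",
              nrow(x$scans), paste(sort(unique(x$scans$time_h)), collapse = "/"),
              nrow(x$blood), paste(sort(unique(x$blood$time_h)), collapse = "/")))
  invisible(x)
}

#' Restrict a record to a subset of protocol time points
#'
#' Returns a copy of the record keeping only scans and blood samples whose
#' times fall in `keep_times` (intersection semantics: times absent from the
#' record are silently ignored). Used to emulate the abbreviated 4/24/48 h
#' protocol from a full five-point study.
#'
#' @param record a [patient_record()].
#' @param keep_times hours to retain, a subset of `c(4, 24, 48, 72, 96)`.
#' @return A new `patient_record`; the input is unchanged.
#' @export
truncate_record <- function(record, keep_times) {
  stopifnot(inherits(record, "patient_record"))
  if (length(keep_times) == 0L) stop("keep_times must be non-empty", call. = FALSE)
  if (!all(keep_times %in% PROTOCOL_TIMES_H)) {
    stop("keep_times must be a subset of {4, 24, 48, 72, 96} h", call. = FALSE)
  }
  patient_record(
    record$patient,
    dplyr::filter(record$scans, .data$time_h %in% keep_times),
    dplyr::filter(record$blood, .data$time_h %in% keep_times)
  )
}

#' Split cohort tables into per-patient records
#'
#' @param patients,scans,blood cohort-level tibbles keyed by `patient_id`
#'   (the layout produced by [generate_cohort()] / [read_cohort()]).
#' @return A named list of [patient_record()] objects.
#' @export
split_records <- function(patients, scans, blood) {
  ids <- patients$patient_id
  recs <- lapply(ids, function(id) {
    patient_record(
      patients[patients$patient_id == id, , drop = FALSE],
      dplyr::select(dplyr::filter(scans, .data$patient_id == id), -"patient_id"),
      dplyr::select(dplyr::filter(blood, .data$patient_id == id), -"patient_id")
    )
  })
  stats::setNames(recs, ids)
}

#' Read / write a cohort as protocol CSV files
#'
#' The on-disk layout mirrors the clinical protocol: `scans.csv`
#' (`patient_id, time_h, region, anterior_counts, posterior_counts,
#' duration_s`), `blood.csv` (`patient_id, time_h, gross_cpm, volume_mL,
#' background_cpm, capsule_cpm, capsule_activity_MBq`) and `patients.csv`
#' (`patient_id, age_y, weight, weight_unit, diffuse_lung_mets,
#' administered_activity_mCi`). Weights may be given in `lbs` or `kg`; they
#' are stored internally in kg and activities in MBq.
#'
#' @param dir directory containing (or to receive) the CSV files.
#' @return `read_cohort()`: a list with tibbles `patients`, `scans`, `blood`
#'   (and `truth` if `truth.csv` is present). `write_cohort()`: `dir`,
#'   invisibly.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("patients.csv", "scans.csv", "blood.csv"))
  absent <- need[!file.exists(need)]
  if (length(absent)) {
    stop("missing cohort file(s): ", paste(basename(absent), collapse = ", "),
         call. = FALSE)
  }
  patients_raw <- readr::read_csv(need[1], show_col_types = FALSE)
  scans <- readr::read_csv(need[2], show_col_types = FALSE)
  blood <- readr::read_csv(need[3], show_col_types = FALSE)

  check_columns(patients_raw, c("patient_id", "age_y", "weight", "weight_unit",
                                "diffuse_lung_mets", "administered_activity_mCi"),
                "patients.csv")
  check_columns(scans, c("patient_id", "time_h", "region", "anterior_counts",
                         "posterior_counts", "duration_s"), "scans.csv")
  check_columns(blood, c("patient_id", "time_h", "gross_cpm", "volume_mL",
                         "background_cpm", "capsule_cpm", "capsule_activity_MBq"),
                "blood.csv")
  bad_unit <- setdiff(unique(patients_raw$weight_unit), c("kg", "lbs"))
  if (length(bad_unit)) {
    stop("unknown weight_unit: ", paste(bad_unit, collapse = ", "), call. = FALSE)
  }
  patients <- dplyr::transmute(
    patients_raw,
    patient_id = as.character(.data$patient_id),
    age_y = .data$age_y,
    weight_kg = ifelse(.data$weight_unit == "lbs",
                       lbs_to_kg(.data$weight), .data$weight),
    diffuse_lung_mets = as.logical(.data$diffuse_lung_mets),
    administered_activity_MBq = mci_to_mbq(.data$administered_activity_mCi)
  )
  out <- list(patients = patients,
              scans = dplyr::mutate(scans, patient_id = as.character(.data$patient_id)),
              blood = dplyr::mutate(blood, patient_id = as.character(.data$patient_id)))
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_csv(truth_path, show_col_types = FALSE)
    out$truth$patient_id <- as.character(out$truth$patient_id)
  }
  out
}

#' @rdname read_cohort
#' @param cohort a cohort list as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  patients_out <- dplyr::transmute(
    cohort$patients,
    patient_id = .data$patient_id,
    age_y = .data$age_y,
    weight = .data$weight_kg,
    weight_unit = "kg",
    diffuse_lung_mets = .data$diffuse_lung_mets,
    administered_activity_mCi = mbq_to_mci(.data$administered_activity_MBq)
  )
  readr::write_csv(patients_out, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$scans, file.path(dir, "scans.csv"))
  readr::write_csv(cohort$blood, file.path(dir, "blood.csv"))
  if (!is.null(cohort$truth)) {
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

check_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
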