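#' Physical and dosimetric constants
#'
#' Constants used throughout the blood-dose-limited dosimetry pipeline.
#' `dosimetry_constants()` returns the default set; individual values can be
#' overridden, which is how an institution-specific calibration would be
#' injected without touching code.
#'
#' @details
#' * `i131_half_life_h` — physical half-life of I-131, 8.0252 d = 192.6 h.
#' * `blood_dose_limit_Gy` — 2 Gy blood absorbed-dose threshold protecting
#'   bone marrow (blood as marrow surrogate).
#' * `wb_retention_cap_mCi` — 120 mCi whole-body retention allowed at 48 h
#'   (lung-dose surrogate, 4.4 GBq).
#' * `lung_retention_cap_mCi` — 80 mCi cap (3 GBq) applied to lung activity
#'   at 48 h, and to whole-body retention for patients with iodine-avid
#'   diffuse lung metastases.
#' * `beta_self_Gy_mL_per_GBq_h` — 108, beta self-dose coefficient of the
#'   standard Benua/EANM blood-dose formula (external-standard value).
#' * `photon_wb_coef` — 0.0188, photon whole-body contribution coefficient
#'   multiplying `weight_kg^(-2/3)` (external-standard value).
#' * `remnant_dose_Gy` / `metastasis_dose_Gy` — 300 / 80 Gy lesion targets;
#'   recorded for reference, they drive no computation here.
#'
#' @param ... named overrides of the defaults, e.g.
#'   `dosimetry_constants(i131_half_life_h = 192.5)`.
#' @return A named list of constants.
#' @examples
#' dosimetry_constants()$i131_half_life_h
#' @export
dosimetry_constants <- function(...) {
  defaults <- list(
    i131_half_life_h        = 192.6,
    blood_dose_limit_Gy     = 2,
    wb_retention_cap_mCi    = 120,
    lung_retention_cap_mCi  = 80,
    beta_self_Gy_mL_per_GBq_h = 108,
    photon_wb_coef          = 0.0188,
    remnant_dose_Gy         = 300,
    metastasis_dose_Gy      = 80
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  defaults
}

# unit conversions; 1 mCi = 37 MBq = 0.037 GBq exactly
MBQ_PER_MCI <- 37
LB_PER_KG <- 1 / 0.45359237

#' Activity and weight unit conversions
#'
#' Exact conversions between the paper-facing units (mCi, lbs) and SI
#' (MBq/GBq, kg). 1 mCi = 37 MBq; 1 lb = 0.45359237 kg.
#'
#' @param x numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' mci_to_gbq(27.027027)  # ~1 GBq
#' lbs_to_kg(161.1)
#' @export
mci_to_mbq <- function(x) x * MBQ_PER_MCI

#' @rdname mci_to_mbq
#' @export
mbq_to_mci <- function(x) x / MBQ_PER_MCI

#' @rdname mci_to_mbq
#' @export
mci_to_gbq <- function(x) x * MBQ_PER_MCI / 1000

#' @rdname mci_to_mbq
#' @export
gbq_to_mci <- function(x) x * 1000 / MBQ_PER_MCI

#' @rdname mci_to_mbq
#' @export
lbs_to_kg <- function(x) x / LB_PER_KG

#' @rdname mci_to_mbq
#' @export
kg_to_lbs <- function(x) x * LB_PER_KG
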