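#' Geometric mean of conjugate-view counts
#'
#' Combines simultaneous anterior/posterior gamma-camera counts into the
#' conjugate-view geometric mean, `sqrt(anterior * posterior)`, which reduces
#' the depth dependence of planar counting.
#'
#' @param anterior,posterior non-negative counts (vectorized).
#' @return `sqrt(anterior * posterior)`, same length as the inputs.
#' @examples
#' geometric_mean_counts(10000, 40000) # 20000
#' @export
geometric_mean_counts <- function(anterior, posterior) {
  if (any(!is.finite(anterior)) || any(!is.finite(posterior)) ||
      any(anterior < 0) || any(posterior < 0)) {
    stop("invalid measurement: conjugate-view counts must be finite and >= 0",
         call. = FALSE)
  }
  sqrt(as.numeric(anterior) * as.numeric(posterior))
}

#' Physical decay correction factor for I-131
#'
#' Factor that refers counts measured at `time_h` hours post-administration
#' back to administration time: `2^(time_h / T_phys)` with
#' `T_phys = 192.6` h (8.0252 d). Multiplying measured counts by this factor
#' removes physical decay, leaving biological clearance.
#'
#' @param time_h hours post-administration (vectorized, >= 0).
#' @param half_life_h physical half-life in hours; defaults to the I-131
#'   value in [dosimetry_constants()].
#' @return Numeric vector of correction factors (>= 1).
#' @examples
#' decay_correction_factor(0)      # 1
#' decay_correction_factor(192.6)  # 2
#' @export
decay_correction_factor <- function(time_h,
                                    half_life_h = dosimetry_constants()$i131_half_life_h) {
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("time_h must be finite and >= 0", call. = FALSE)
  }
  2^(time_h / half_life_h)
}

#' Retained fractions from conjugate-view scan tables
#'
#' Reduces one patient's conjugate-view count table to retained fractions of
#' administered activity. For each time point the geometric-mean count rate of
#' a region is divided by that of the source standard imaged in the same
#' session (cancelling day-to-day camera sensitivity), both decay-corrected to
#' administration time, and the result is normalized so the whole-body value
#' at the baseline time point (4 h, taken as pre-void 100% retention) equals 1.
#' Because the source standard itself decays physically, the standard-ratio
#' fraction tracks biological retention.
#'
#' @param scans data frame with columns `time_h`, `region` (one of
#'   `"whole_body"`, `"chest"`, `"standard"`), `anterior_counts`,
#'   `posterior_counts`, `duration_s` for a single patient.
#' @param baseline_time baseline scan time in hours (default 4).
#' @param constants see [dosimetry_constants()].
#' @return A tibble with columns `time_h`, `region`, `retained_fraction`
#'   for the non-standard regions. The whole-body fraction at
#'   `baseline_time` is exactly 1.
#' @export
retained_fractions <- function(scans, baseline_time = 4,
                               constants = dosimetry_constants()) {
  required <- c("time_h", "region", "anterior_counts", "posterior_counts", "duration_s")
  missing_cols <- setdiff(required, names(scans))
  if (length(missing_cols)) {
    stop("scans is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(scans$duration_s <= 0)) stop("duration_s must be > 0", call. = FALSE)

  scans <- dplyr::mutate(
    scans,
    gm_rate = geometric_mean_counts(.data$anterior_counts, .data$posterior_counts) /
      .data$duration_s *
      decay_correction_factor(.data$time_h, constants$i131_half_life_h)
  )
  std <- dplyr::filter(scans, .data$region == "standard")
  body <- dplyr::filter(scans, .data$region != "standard")
  if (nrow(body) == 0L) stop("no non-standard scans to reduce", call. = FALSE)

  joined <- dplyr::left_join(
    body,
    dplyr::select(std, "time_h", std_rate = "gm_rate"),
    by = "time_h"
  )
  if (any(is.na(joined$std_rate))) {
    bad <- unique(joined$time_h[is.na(joined$std_rate)])
    stop("no source-standard scan at time(s): ", paste(bad, collapse = ", "),
         " h", call. = FALSE)
  }
  if (any(joined$std_rate <= 0)) {
    stop("source-standard counts are zero; cannot normalize", call. = FALSE)
  }
  joined$ratio <- joined$gm_rate / joined$std_rate

  base <- joined$ratio[joined$region == "whole_body" & joined$time_h == baseline_time]
  if (length(base) != 1L) {
    stop("need exactly one whole-body scan at the baseline time (",
         baseline_time, " h)", call. = FALSE)
  }
  if (base <= 0) stop("baseline whole-body counts are zero", call. = FALSE)

  tibble::tibble(
    time_h = joined$time_h,
    region = joined$region,
    retained_fraction = joined$ratio / base
  )
}

#' Blood activity concentration from well-counter measurements
#'
#' Converts well-counter blood-sample counts to the fraction of administered
#' activity per mL of blood. Background (0.5 mL water sample) is subtracted
#' from both the sample and the I-131 calibration capsule; the net ratio times
#' the known capsule activity gives the aliquot activity, which is divided by
#' the aliquot volume, decay-corrected to administration time, and expressed
#' as a fraction of the administered activity.
#'
#' @param blood data frame with columns `time_h`, `gross_cpm`, `volume_mL`,
#'   `background_cpm`, `capsule_cpm`, `capsule_activity_MBq` for one patient.
#' @param administered_activity_MBq administered tracer activity in MBq.
#' @param constants see [dosimetry_constants()].
#' @return A tibble with columns `time_h`, `fraction_per_mL`. Net counts
#'   below background are clamped to zero with a warning.
#' @export
blood_fractions <- function(blood, administered_activity_MBq,
                            constants = dosimetry_constants()) {
  required <- c("time_h", "gross_cpm", "volume_mL", "background_cpm",
                "capsule_cpm", "capsule_activity_MBq")
  missing_cols <- setdiff(required, names(blood))
  if (length(missing_cols)) {
    stop("blood is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(blood$volume_mL <= 0)) stop("volume_mL must be > 0", call. = FALSE)
  if (administered_activity_MBq <= 0) {
    stop("administered_activity_MBq must be > 0", call. = FALSE)
  }
  cal_net <- blood$capsule_cpm - blood$background_cpm
  if (any(cal_net <= 0)) {
    stop("calibration capsule counts do not exceed background", call. = FALSE)
  }
  net <- blood$gross_cpm - blood$background_cpm
  if (any(net < 0)) {
    warning("net blood counts below background clamped to 0", call. = FALSE)
    net <- pmax(net, 0)
  }
  activity_MBq <- net / cal_net * blood$capsule_activity_MBq *
    decay_correction_factor(blood$time_h, constants$i131_half_life_h)
  tibble::tibble(
    time_h = blood$time_h,
    fraction_per_mL = activity_MBq / blood$volume_mL / administered_activity_MBq
  )
}

#' Convert biological retention to effective retention
#'
#' Decay-corrected (biological) retention values are re-multiplied by
#' `2^(-t / T_phys)` so that the integrand of the absorbed-dose calculation is
#' the activity actually present (effective retention: biological clearance
#' plus physical decay).
#'
#' @param points tibble with `time_h` and a value column (`retained_fraction`
#'   or `fraction_per_mL`).
#' @param constants see [dosimetry_constants()].
#' @return The input tibble with the value column multiplied by the physical
#'   decay factor.
#' @export
effective_retention <- function(points, constants = dosimetry_constants()) {
  vcol <- clearance_value_col(points)
  points[[vcol]] <- points[[vcol]] /
    decay_correction_factor(points$time_h, constants$i131_half_life_h)
  points
}

# pick the value column of a retention table: the first known name, else the
# first numeric non-time column
clearance_value_col <- function(points) {
  known <- intersect(c("retained_fraction", "fraction_per_mL", "value"),
                     names(points))
  if (length(known)) return(known[[1L]])
  cand <- setdiff(names(points)[vapply(points, is.numeric, logical(1))], "time_h")
  if (!length(cand)) stop("no value column found in points", call. = FALSE)
  cand[[1L]]
}

#' Fit a mono- or bi-exponential clearance model
#'
#' Least-squares fit of `f(t) = sum_i a_i * exp(-lambda_i * t)` to a
#' time-retention table. The bi-exponential fit is initialized by curve
#' peeling (slow component from the last two points, fast component from the
#' early residual) and refined by Levenberg-Marquardt with positivity bounds;
#' if it fails to converge it falls back to the mono-exponential model with a
#' warning.
#'
#' @param points tibble with `time_h` (strictly increasing) and a value
#'   column (`retained_fraction` or `fraction_per_mL`).
#' @param model `"auto"` (bi when >= 4 points, else mono), `"mono"` or
#'   `"bi"`.
#' @param check_total if `TRUE`, warn when the amplitude sum is outside
#'   `[0.8, 1.2]` (sanity check for whole-body fits, whose extrapolated
#'   value at t = 0 should be near 1).
#' @return An object of class `clearance_fit`: a list with `model`,
#'   `amplitudes`, `decay_rates` (per hour, fast first for `bi`), `rss`,
#'   `n_points` and the data. Supports [generics::tidy()],
#'   [generics::glance()], `predict()` and [ggplot2::autoplot()].
#' @examples
#' pts <- tibble::tibble(time_h = c(0, 24, 48), retained_fraction = c(1, .5, .25))
#' fit <- fit_clearance(pts, "mono")
#' fit$decay_rates # log(2)/24
#' @export
fit_clearance <- function(points, model = c("auto", "mono", "bi"),
                          check_total = FALSE) {
  model <- match.arg(model)
  vcol <- clearance_value_col(points)
  t <- points$time_h
  y <- points[[vcol]]
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(y < 0)) {
    stop("retention points must be finite with non-negative values", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  if (model == "auto") model <- if (length(t) >= 4L) "bi" else "mono"
  if (model == "mono" && length(t) < 2L) {
    stop("mono-exponential fit needs >= 2 points", call. = FALSE)
  }
  if (model == "bi" && length(t) < 4L) {
    stop("bi-exponential fit needs >= 4 points", call. = FALSE)
  }

  scale <- max(y)
  if (scale <= 0) stop("all retention values are zero; nothing to fit", call. = FALSE)
  ys <- y / scale

  fit <- if (model == "mono") {
    fit_mono(t, ys)
  } else {
    tryCatch(fit_bi(t, ys), error = function(e) {
      warning("bi-exponential fit failed (", conditionMessage(e),
              "); falling back to mono-exponential", call. = FALSE)
      fit_mono(t, ys)
    })
  }

  a <- fit$a * scale
  lam <- fit$lambda
  ord <- order(lam, decreasing = TRUE) # fast component first
  a <- a[ord]
  lam <- lam[ord]
  resid <- y - colSums(a * exp(-outer(lam, t)))
  out <- structure(
    list(
      model = if (length(a) == 2L) "bi" else "mono",
      amplitudes = unname(a),
      decay_rates = unname(lam),
      rss = sum(resid^2),
      n_points = length(t),
      data = tibble::tibble(time_h = t, value = y)
    ),
    class = "clearance_fit"
  )
  if (check_total) {
    tot <- sum(out$amplitudes)
    if (tot < 0.8 || tot > 1.2) {
      warning(sprintf("amplitude sum %.3f outside [0.8, 1.2]", tot), call. = FALSE)
    }
  }
  out
}

fit_mono <- function(t, y) {
  pos <- y > 0
  if (sum(pos) < 2L) stop("too few positive values for mono fit", call. = FALSE)
  lm0 <- stats::lm(log(y[pos]) ~ t[pos])
  a0 <- exp(unname(stats::coef(lm0)[1]))
  l0 <- max(-unname(stats::coef(lm0)[2]), 1e-9)
  df <- data.frame(t = t, y = y)
  nl <- minpack.lm::nlsLM(
    y ~ a * exp(-l * t), data = df,
    start = list(a = a0, l = l0),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  cf <- stats::coef(nl)
  list(a = cf[["a"]], lambda = cf[["l"]])
}

fit_bi <- function(t, y) {
  n <- length(t)
  # curve peeling: slow component from the two latest positive points
  i2 <- n - 1L
  if (y[n] <= 0 || y[i2] <= 0) stop("terminal values non-positive", call. = FALSE)
  ls0 <- log(y[i2] / y[n]) / (t[n] - t[i2])
  ls0 <- min(max(ls0, 1e-6), 1)
  as0 <- y[n] * exp(ls0 * t[n])
  res <- y - as0 * exp(-ls0 * t)
  early <- which(res > 0 & seq_along(t) <= ceiling(n / 2))
  if (length(early) >= 2L) {
    lmf <- stats::lm(log(res[early]) ~ t[early])
    af0 <- exp(unname(stats::coef(lmf)[1]))
    lf0 <- max(-unname(stats::coef(lmf)[2]), ls0 * 3)
  } else {
    af0 <- max(y[1] - as0, 0.1)
    lf0 <- max(ls0 * 10, 0.05)
  }
  df <- data.frame(t = t, y = y)
  nl <- minpack.lm::nlsLM(
    y ~ a1 * exp(-l1 * t) + a2 * exp(-l2 * t), data = df,
    start = list(a1 = af0, l1 = lf0, a2 = as0, l2 = ls0),
    lower = rep(1e-12, 4),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15)
  )
  cf <- stats::coef(nl)
  if (!all(is.finite(cf))) stop("non-finite coefficients", call. = FALSE)
  list(a = c(cf[["a1"]], cf[["a2"]]), lambda = c(cf[["l1"]], cf[["l2"]]))
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("<clearance_fit> %s-exponential, %d points, rss = %.3g\n",
              x$model, x$n_points, x$rss))
  comps <- tibble::tibble(
    component = if (x$model == "bi") c("fast", "slow") else "mono",
    amplitude = x$amplitudes,
    rate_per_h = x$decay_rates,
    half_life_h = log(2) / x$decay_rates
  )
  print(comps)
  invisible(x)
}

#' @export
predict.clearance_fit <- function(object, times = object$data$time_h, ...) {
  colSums(object$amplitudes * exp(-outer(object$decay_rates, times)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.clearance_fit <- function(x, ...) {
  comp <- if (x$model == "bi") c("fast", "slow") else "mono"
  tibble::tibble(
    term = c(paste0("amplitude_", comp), paste0("rate_", comp)),
    estimate = c(x$amplitudes, x$decay_rates)
  )
}

#' @export
glance.clearance_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_points = x$n_points,
    rss = x$rss,
    tau_h = time_integrated_coefficient(x)
  )
}

#' Time-integrated activity coefficient (residence time)
#'
#' Integrates a fitted clearance curve from time zero to infinity, yielding
#' the time-integrated activity coefficient tau in hours (hours of
#' administered-activity fraction; per mL for blood fits).
#'
#' @param fit a [fit_clearance()] object on *effective* retention (physical
#'   decay included) when the result feeds the absorbed-dose formula.
#' @param points observed points (tibble with `time_h` and a value column);
#'   required for `method = "trapezoid_tail"`.
#' @param method `"analytic"`: `sum(a_i / lambda_i)`. `"trapezoid_tail"`:
#'   trapezoid rule over the observed points with the model value at t = 0
#'   prepended, plus the analytic tail of the slowest fitted component
#'   beyond the last observation.
#' @return tau in hours.
#' @examples
#' pts <- tibble::tibble(time_h = c(0, 24, 48), retained_fraction = c(1, .5, .25))
#' time_integrated_coefficient(fit_clearance(pts, "mono")) # 24/log(2)
#' @export
time_integrated_coefficient <- function(fit, points = NULL,
                                        method = c("analytic", "trapezoid_tail")) {
  method <- match.arg(method)
  if (any(fit$decay_rates <= 0)) {
    stop("non-positive decay rate: integral diverges", call. = FALSE)
  }
  if (method == "analytic") {
    return(sum(fit$amplitudes / fit$decay_rates))
  }
  if (is.null(points) || nrow(points) == 0L) {
    stop("trapezoid_tail integration needs observed points", call. = FALSE)
  }
  vcol <- clearance_value_col(points)
  ord <- order(points$time_h)
  t <- points$time_h[ord]
  y <- points[[vcol]][ord]
  if (t[1] > 0) {
    t <- c(0, t)
    y <- c(sum(fit$amplitudes), y)
  }
  trap <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  slow <- which.min(fit$decay_rates)
  tail_int <- fit$amplitudes[slow] *
    exp(-fit$decay_rates[slow] * t[length(t)]) / fit$decay_rates[slow]
  trap + tail_int
}
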