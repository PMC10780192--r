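test_that("conjugate-view geometric mean matches closed form and rejects bad input", {
  expect_equal(geometric_mean_counts(10000, 40000), 20000)
  expect_equal(geometric_mean_counts(5000, 5000), 5000)
  expect_equal(geometric_mean_counts(0, 5000), 0)
  expect_equal(geometric_mean_counts(3, 12), geometric_mean_counts(12, 3))
  expect_error(geometric_mean_counts(-1, 10), "invalid measurement")
  expect_error(geometric_mean_counts(10, NA), "invalid measurement")
})

test_that("geometric mean never exceeds arithmetic mean, equality iff equal", {
  set.seed(1)
  a <- runif(200, 0, 1e6)
  p <- runif(200, 0, 1e6)
  gm <- geometric_mean_counts(a, p)
  am <- (a + p) / 2
  expect_true(all(gm <= am + 1e-9))
  expect_equal(geometric_mean_counts(a, a), a)
  expect_true(all(gm[abs(a - p) > 1e-6] < am[abs(a - p) > 1e-6]))
})

test_that("decay correction factor is the I-131 closed form and multiplicative", {
  expect_equal(decay_correction_factor(0), 1)
  expect_equal(decay_correction_factor(192.6), 2)
  expect_equal(decay_correction_factor(96), 2^(96 / 192.6))
  expect_error(decay_correction_factor(-1), ">= 0")
  set.seed(2)
  t1 <- runif(50, 0, 200)
  t2 <- runif(50, 0, 200)
  expect_equal(decay_correction_factor(t1 + t2),
               decay_correction_factor(t1) * decay_correction_factor(t2))
})

test_that("retained fractions normalize to the 4 h baseline via the standard ratio", {
  fr <- retained_fractions(toy_scans())
  expect_equal(fr$retained_fraction[fr$time_h == 4], 1)
  expect_equal(fr$retained_fraction[fr$time_h == 24], 0.5)
  expect_equal(fr$retained_fraction[fr$time_h == 48], 0.25)
})

test_that("retained fractions fail without a usable source standard", {
  scans <- toy_scans()
  expect_error(retained_fractions(scans[scans$region != "standard", ]),
               "source-standard")
  zeroed <- scans
  zeroed$anterior_counts[zeroed$region == "standard"] <- 0
  expect_error(retained_fractions(zeroed), "zero")
  expect_error(retained_fractions(scans[scans$time_h != 4 | scans$region != "whole_body", ]),
               "baseline")
})

test_that("zero-noise simulation reproduces biological retention in closed form", {
  # mono-like kinetics: both components share one biological half-life, so the
  # standard-ratio fraction must equal 2^(-(t-4)/T_bio) exactly
  cfg <- cohort_config(n_patients = 1, seed = 3, noise = 0)
  set.seed(3)
  params <- sample_kinetics(cfg, 1)
  t_bio <- 24
  params$wb_fast_halflife_h <- t_bio
  params$wb_slow_halflife_h <- t_bio
  rec <- generate_record(params, cfg)
  fr <- retained_fractions(rec$scans)
  wb <- fr[fr$region == "whole_body", ]
  expect_equal(wb$retained_fraction[wb$time_h == 48], 2^(-44 / t_bio),
               tolerance = 1e-9)
  expect_equal(wb$retained_fraction, 2^(-(wb$time_h - 4) / t_bio),
               tolerance = 1e-9)
})

test_that("blood fractions follow the well-counter calibration arithmetic", {
  blood <- tibble::tibble(
    time_h = 0, gross_cpm = 2030, volume_mL = 4, background_cpm = 30,
    capsule_cpm = 100030, capsule_activity_MBq = 1
  )
  out <- blood_fractions(blood, administered_activity_MBq = 74)
  expect_equal(out$fraction_per_mL, (2000 / 100000) * 1 / 4 / 74)

  # calibration identity: net equals capsule net, 1 mL, capsule = administered
  ident <- tibble::tibble(
    time_h = 0, gross_cpm = 100030, volume_mL = 1, background_cpm = 30,
    capsule_cpm = 100030, capsule_activity_MBq = 74
  )
  expect_equal(blood_fractions(ident, 74)$fraction_per_mL, 1)

  # pure background -> zero
  bg <- tibble::tibble(
    time_h = 24, gross_cpm = 30, volume_mL = 3.5, background_cpm = 30,
    capsule_cpm = 100030, capsule_activity_MBq = 1
  )
  expect_equal(blood_fractions(bg, 74)$fraction_per_mL, 0)

  below <- bg
  below$gross_cpm <- 10
  expect_warning(res <- blood_fractions(below, 74), "clamped")
  expect_equal(res$fraction_per_mL, 0)
  bad <- bg
  bad$volume_mL <- 0
  expect_error(blood_fractions(bad, 74), "volume")
  nocal <- bg
  nocal$capsule_cpm <- 20
  expect_error(blood_fractions(nocal, 74), "capsule")
})

test_that("mono-exponential fit recovers exact halving data", {
  pts <- tibble::tibble(time_h = c(0, 24, 48), retained_fraction = c(1, 0.5, 0.25))
  fit <- fit_clearance(pts, "mono")
  expect_equal(fit$amplitudes, 1, tolerance = 1e-9)
  expect_equal(fit$decay_rates, log(2) / 24, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-18)
  expect_error(fit_clearance(pts[1, ], "mono"), ">= 2")
})

test_that("bi-exponential fit recovers generating parameters on noiseless data", {
  t <- c(4, 24, 48, 72, 96)
  y <- 0.6 * exp(-0.1 * t) + 0.4 * exp(-0.01 * t)
  fit <- fit_clearance(tibble::tibble(time_h = t, retained_fraction = y), "bi")
  expect_equal(fit$amplitudes, c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(fit$decay_rates, c(0.1, 0.01), tolerance = 1e-6)
  expect_true(fit$decay_rates[1] > fit$decay_rates[2])
  expect_error(fit_clearance(tibble::tibble(time_h = t[1:3],
                                            retained_fraction = y[1:3]), "bi"),
               ">= 4")
})

test_that("time-integrated coefficient: closed forms and quadrature convergence", {
  pts <- tibble::tibble(time_h = c(0, 24, 48), retained_fraction = c(1, 0.5, 0.25))
  mono <- fit_clearance(pts, "mono")
  expect_equal(time_integrated_coefficient(mono), 24 / log(2), tolerance = 1e-8)

  t <- c(4, 24, 48, 72, 96)
  y <- 0.6 * exp(-0.1 * t) + 0.4 * exp(-0.01 * t)
  bi <- fit_clearance(tibble::tibble(time_h = t, retained_fraction = y), "bi")
  expect_equal(time_integrated_coefficient(bi), 0.6 / 0.1 + 0.4 / 0.01,
               tolerance = 1e-6)

  # dense trapezoid-with-tail converges to the analytic integral
  dense <- tibble::tibble(time_h = seq(0.1, 96, by = 0.1))
  dense$retained_fraction <- predict(mono, dense$time_h)
  trap <- time_integrated_coefficient(mono, dense, "trapezoid_tail")
  expect_lt(abs(trap / (24 / log(2)) - 1), 1e-3)

  # error decreases monotonically with sampling density on noiseless data
  errs <- vapply(c(8, 4, 2, 1, 0.5), function(dt) {
    grid <- tibble::tibble(time_h = seq(dt, 96, by = dt))
    grid$retained_fraction <- predict(mono, grid$time_h)
    abs(time_integrated_coefficient(mono, grid, "trapezoid_tail") - 24 / log(2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  degenerate <- mono
  degenerate$decay_rates <- -0.01
  expect_error(time_integrated_coefficient(degenerate), "diverges")
})

test_that("noiseless simulate -> fit -> integrate round trip recovers tau", {
  cfg <- cohort_config(n_patients = 5, seed = 21, noise = 0)
  set.seed(21)
  params <- sample_kinetics(cfg, 5)
  lam_p <- log(2) / dosimetry_constants()$i131_half_life_h
  for (i in seq_len(5)) {
    p <- params[i, ]
    rec <- generate_record(p, cfg)
    wb <- dplyr::filter(retained_fractions(rec$scans), region == "whole_body")
    eff <- effective_retention(wb[c("time_h", "retained_fraction")])
    fit <- fit_clearance(eff, "bi")
    r4 <- raidose:::wb_retention_bio(p, 4)
    tau_true <- (p$wb_fast_fraction / r4) / (log(2) / p$wb_fast_halflife_h + lam_p) +
      ((1 - p$wb_fast_fraction) / r4) / (log(2) / p$wb_slow_halflife_h + lam_p)
    expect_equal(time_integrated_coefficient(fit), tau_true, tolerance = 1e-6)
  }
})

test_that("records truncate by time intersection without mutating the input", {
  rec <- toy_record()
  kept <- truncate_record(rec, c(4, 24, 48))
  expect_equal(sort(unique(kept$scans$time_h)), c(4, 24, 48))
  expect_equal(nrow(kept$scans[kept$scans$region == "whole_body", ]), 3)
  expect_equal(nrow(kept$scans[kept$scans$region == "standard", ]), 3)
  expect_equal(nrow(kept$scans[kept$scans$region == "chest", ]), 1)
  expect_equal(nrow(kept$blood), 3)
  expect_equal(nrow(rec$blood), 5) # original unchanged

  all5 <- truncate_record(rec, c(4, 24, 48, 72, 96))
  expect_identical(all5$scans, rec$scans)

  short <- truncate_record(rec, c(4, 24, 48))
  expect_equal(sort(unique(truncate_record(short, c(4, 24, 48, 72, 96))$blood$time_h)),
               c(4, 24, 48))
  expect_error(truncate_record(rec, numeric(0)), "non-empty")
  expect_error(truncate_record(rec, c(4, 12)), "subset")
})
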