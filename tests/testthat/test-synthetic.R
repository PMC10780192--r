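test_that("kinetic draws are deterministic under a seed and respect bounds", {
  cfg <- cohort_config(n_patients = 50, seed = 5)
  set.seed(5); a <- sample_kinetics(cfg, 50)
  set.seed(5); b <- sample_kinetics(cfg, 50)
  expect_identical(a, b)
  set.seed(6); c <- sample_kinetics(cfg, 50)
  expect_false(identical(a, c))

  set.seed(7)
  big <- sample_kinetics(cfg, 10000)
  expect_true(all(big$wb_fast_fraction > 0 & big$wb_fast_fraction < 1))
  expect_true(all(big$blood_fast_fraction > 0 & big$blood_fast_fraction < 1))
  expect_true(all(big$wb_fast_halflife_h > 0))
  expect_true(all(big$wb_fast_halflife_h < big$wb_slow_halflife_h))
  expect_true(all(big$blood_fast_halflife_h < big$blood_slow_halflife_h))
  expect_true(all(big$weight_kg > 0))
  expect_true(all(big$age_y >= 18))
})

test_that("early and late retention are positively correlated across patients", {
  cfg <- cohort_config()
  set.seed(8)
  params <- sample_kinetics(cfg, 2000)
  r48 <- raidose:::wb_retention_bio(params, 48) / raidose:::wb_retention_bio(params, 4)
  r96 <- raidose:::wb_retention_bio(params, 96) / raidose:::wb_retention_bio(params, 4)
  expect_gt(cor(r48, r96), 0.8)
})

test_that("records carry the full five-point protocol layout", {
  rec <- toy_record()
  counts <- table(rec$scans$region)
  expect_equal(unname(counts[["whole_body"]]), 5)
  expect_equal(unname(counts[["standard"]]), 5)
  expect_equal(unname(counts[["chest"]]), 1)
  expect_equal(rec$scans$time_h[rec$scans$region == "chest"], 48)
  expect_equal(nrow(rec$blood), 5)
  expect_equal(sort(unique(rec$blood$time_h)), c(4, 24, 48, 72, 96))
})

test_that("zero-noise measurements invert to the generating kinetics exactly", {
  cfg <- cohort_config(n_patients = 1, seed = 31, noise = 0)
  set.seed(31)
  params <- sample_kinetics(cfg, 1)
  rec <- generate_record(params, cfg)
  fr <- retained_fractions(rec$scans)
  wb <- fr[fr$region == "whole_body", ]
  expected <- raidose:::wb_retention_bio(params, wb$time_h) /
    raidose:::wb_retention_bio(params, 4)
  expect_equal(wb$retained_fraction, expected, tolerance = 1e-9)

  bl <- blood_fractions(rec$blood, params$administered_activity_MBq)
  expect_equal(bl$fraction_per_mL,
               raidose:::blood_conc_bio(params, bl$time_h), tolerance = 1e-9)
})

test_that("Poisson counting noise is centered on the noiseless expectation", {
  cfg <- cohort_config(n_patients = 1, seed = 32)
  set.seed(32)
  params <- sample_kinetics(cfg, 1)
  noiseless <- generate_record(params, cfg, noise = 0)
  exact <- noiseless$scans
  gm0 <- geometric_mean_counts(
    exact$anterior_counts[exact$region == "whole_body" & exact$time_h == 48],
    exact$posterior_counts[exact$region == "whole_body" & exact$time_h == 48]
  )
  set.seed(33)
  gms <- replicate(1000, {
    r <- generate_record(params, cfg, noise = 1)
    s <- r$scans[r$scans$region == "whole_body" & r$scans$time_h == 48, ]
    geometric_mean_counts(s$anterior_counts, s$posterior_counts)
  })
  expect_lt(abs(mean(gms) / gm0 - 1), 0.01)
})

test_that("cohort generation is deterministic and seed-disjoint", {
  a <- suppressWarnings(generate_cohort(cohort_config(n_patients = 15, seed = 34)))
  b <- suppressWarnings(generate_cohort(cohort_config(n_patients = 15, seed = 34)))
  expect_identical(a$scans, b$scans)
  expect_identical(a$blood, b$blood)
  expect_identical(a$truth, b$truth)
  d <- suppressWarnings(generate_cohort(cohort_config(n_patients = 15, seed = 35)))
  expect_false(identical(a$scans, d$scans))
  expect_true(all(a$truth$reference_mpa_mCi > 0))
  expect_true(all(is.finite(a$truth$reference_mpa_mCi)))
})

test_that("cohort CSV round trip preserves the tables", {
  co <- suppressWarnings(generate_cohort(cohort_config(n_patients = 5, seed = 36)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("patients.csv", "scans.csv",
                                               "blood.csv", "truth.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$patients$weight_kg, co$patients$weight_kg, tolerance = 1e-12)
  expect_equal(back$patients$administered_activity_MBq,
               co$patients$administered_activity_MBq, tolerance = 1e-12)
  expect_equal(back$scans$anterior_counts, co$scans$anterior_counts)
  expect_equal(back$blood$gross_cpm, co$blood$gross_cpm)
  # re-writing the same cohort is byte-identical
  dir2 <- withr::local_tempdir()
  write_cohort(co, dir2)
  expect_identical(readLines(file.path(dir, "scans.csv")),
                   readLines(file.path(dir2, "scans.csv")))
})

test_that("reading a corrupt cohort names the missing column", {
  co <- suppressWarnings(generate_cohort(cohort_config(n_patients = 3, seed = 37)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  blood <- readr::read_csv(file.path(dir, "blood.csv"), show_col_types = FALSE)
  readr::write_csv(blood[names(blood) != "capsule_cpm"], file.path(dir, "blood.csv"))
  expect_error(read_cohort(dir), "capsule_cpm")
})

test_that("calibrated cohort reproduces the clinical MPA distribution", {
  co <- noiseless_cohort_500()
  mpas <- co$truth$reference_mpa_mCi
  expect_lt(abs(mean(mpas) - 456), 60)
  q <- quantile(mpas, c(0.05, 0.95))
  expect_gt(q[[1]], 117)
  expect_lt(q[[2]], 1080)
})
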