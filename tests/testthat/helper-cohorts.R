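# Shared fixtures, built once per test run. The two large cohorts are cached
# because several files assert different properties of the same experiment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# noiseless cohort: exact measurements, used for oracle round trips,
# calibration checks and the noiseless learning experiment
noiseless_cohort_500 <- function() {
  cached("c500", suppressWarnings(
    generate_cohort(cohort_config(n_patients = 500, seed = 11, noise = 0))
  ))
}

# default-noise cohort at the abbreviation-fidelity experiment scale
noisy_cohort_600 <- function() {
  cached("c600", suppressWarnings(
    generate_cohort(cohort_config(n_patients = 600, seed = 101))
  ))
}

# model trained on 400 noiseless patients, evaluated on the held-out 100
noiseless_experiment <- function() {
  cached("exp500", {
    co <- noiseless_cohort_500()
    feats <- cohort_features(co$patients, co$scans, co$blood)
    ref <- stats::setNames(co$truth$reference_mpa_mCi, co$truth$patient_id)
    set.seed(12)
    ids <- sample(co$patients$patient_id)
    train_ids <- ids[1:400]
    test_ids <- ids[401:500]
    fi <- function(id) feats[match(id, feats$patient_id), ]
    model <- train_mpa_model(fi(train_ids), ref[train_ids], seed = 13)
    list(cohort = co, features = feats, ref = ref, model = model,
         train_ids = train_ids, test_ids = test_ids, fi = fi)
  })
}

# abbreviation-fidelity experiment: train 500 / test 100 at default noise,
# reference = full five-point pipeline on the measured (noisy) records
fidelity_experiment <- function() {
  cached("exp600", {
    co <- noisy_cohort_600()
    mpa <- suppressWarnings(dose_cohort(co$patients, co$scans, co$blood))
    feats <- suppressWarnings(cohort_features(co$patients, co$scans, co$blood))
    ref <- stats::setNames(mpa$mpa_final_mCi, mpa$patient_id)
    set.seed(102)
    ids <- sample(co$patients$patient_id)
    train_ids <- ids[1:500]
    test_ids <- ids[501:600]
    fi <- function(id) feats[match(id, feats$patient_id), ]
    model <- train_mpa_model(fi(train_ids), ref[train_ids], seed = 103)
    predictions <- predict(model, fi(test_ids))
    list(cohort = co, mpa = mpa, ref = ref, model = model,
         train_ids = train_ids, test_ids = test_ids,
         predictions = predictions, fi = fi)
  })
}

# two identically-configured end-to-end runs at the clinical 83/70 scale,
# kept for the whole session so structure and reproducibility checks share them
pipeline_runs <- function() {
  cached("pipe83", {
    cfg <- function(dir) pipeline_config(n_patients = 83, n_train = 70,
                                         seed = 61, out_dir = dir)
    dir1 <- tempfile("pipe1-"); dir2 <- tempfile("pipe2-")
    res1 <- suppressWarnings(run_pipeline(cfg(dir1)))
    res2 <- suppressWarnings(run_pipeline(cfg(dir2)))
    list(res1 = res1, res2 = res2, dir1 = dir1, dir2 = dir2)
  })
}

# a single small patient table with exactly known count ratios
toy_scans <- function() {
  # standard 10000/10000 everywhere; whole-body ratio halves at each later time
  tibble::tibble(
    time_h = c(4, 24, 48, 4, 24, 48),
    region = c(rep("whole_body", 3), rep("standard", 3)),
    anterior_counts = c(40000, 20000, 10000, 10000, 10000, 10000) /
      decay_correction_factor(c(4, 24, 48, 4, 24, 48)),
    posterior_counts = c(40000, 20000, 10000, 10000, 10000, 10000) /
      decay_correction_factor(c(4, 24, 48, 4, 24, 48)),
    duration_s = 300
  )
}

toy_record <- function() {
  cfg <- cohort_config(n_patients = 1, seed = 400, noise = 0)
  set.seed(400)
  params <- sample_kinetics(cfg, 1)
  generate_record(params, cfg)
}
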