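test_that("the 13-pair validation fixture matches the published table", {
  s <- table2_fixture()
  expect_equal(nrow(s), 13)
  d <- s$predicted_mCi - s$reference_mCi
  expect_equal(d[4], -35)   # P4
  expect_equal(d[10], -61)  # P10
  # recomputation from the value rows, not the printed difference row
  expect_equal(d[2], -13)   # P2 (printed difference row says -14)
  expect_equal(d[3], -11)   # P3 (printed difference row says -10)
})

test_that("paired t-test agrees with the library reference to 1e-10", {
  s <- table2_fixture()
  mine <- paired_t_test(s)
  ref <- t.test(s$predicted_mCi, s$reference_mCi, paired = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
  expect_equal(mine$df, 12)
  expect_true(mine$ci_low < mine$mean_diff && mine$mean_diff < mine$ci_high)
})

test_that("paired t-test matches hand arithmetic on three pairs", {
  # d = (1, 2, 3): mean 2, sd 1, se 1/sqrt(3), t = 2*sqrt(3), df 2
  s <- paired_series(1:3, c(100, 200, 300), c(101, 202, 303))
  out <- paired_t_test(s)
  expect_equal(out$mean_diff, 2)
  expect_equal(out$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$ci_low, 2 - qt(0.975, 2) / sqrt(3), tolerance = 1e-12)
  expect_equal(out$ci_high, 2 + qt(0.975, 2) / sqrt(3), tolerance = 1e-12)
})

test_that("paired t-test handles degenerate difference patterns", {
  z <- paired_t_test(paired_series(1:4, c(10, 10, 10, 10), c(11, 9, 11, 9)))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  same <- paired_t_test(paired_series(1:3, c(5, 6, 7), c(5, 6, 7)))
  expect_equal(same$p_value, 1)
  expect_warning(
    shifted <- paired_t_test(paired_series(1:3, c(5, 6, 7), c(6, 7, 8))),
    "zero-variance"
  )
  expect_equal(shifted$p_value, 0)
})

test_that("paired t-test is antisymmetric and shift invariant", {
  set.seed(51)
  ref <- runif(12, 100, 900)
  pred <- ref + rnorm(12, 5, 20)
  s <- paired_series(1:12, ref, pred)
  swapped <- paired_series(1:12, pred, ref)
  a <- paired_t_test(s)
  b <- paired_t_test(swapped)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  shifted <- paired_series(1:12, ref + 100, pred + 100)
  expect_equal(paired_t_test(shifted), a)
  w <- wilcoxon_signed_rank(s)
  expect_equal(wilcoxon_signed_rank(shifted), w)
})

test_that("exact signed-rank p equals brute-force enumeration for n <= 10", {
  set.seed(52)
  for (case in 1:25) {
    n <- sample(5:10, 1)
    d <- sample(c(-6:-1, 1:6), n, replace = TRUE) # ties likely
    ref <- rep(100, n)
    out <- wilcoxon_signed_rank(paired_series(seq_len(n), ref, ref + d))
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% r
    p_enum <- min(1, 2 * min(mean(ws <= w_obs + 1e-12),
                             mean(ws >= w_obs - 1e-12)))
    expect_equal(out$p_value, p_enum, tolerance = 1e-10)
    expect_equal(out$statistic, w_obs)
  }
})

test_that("signed-rank agrees with the library exact p when there are no ties", {
  set.seed(53)
  for (case in 1:10) {
    n <- sample(6:15, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE) # distinct |d| -> no ties
    ref <- runif(n, 100, 900)
    s <- paired_series(seq_len(n), ref, ref + d)
    mine <- wilcoxon_signed_rank(s)
    ref_test <- wilcox.test(s$predicted_mCi, s$reference_mCi,
                            paired = TRUE, exact = TRUE)
    expect_equal(mine$p_value, ref_test$p.value, tolerance = 1e-10)
    expect_equal(mine$statistic, unname(ref_test$statistic))
  }
})

test_that("signed-rank degenerate and symmetric cases", {
  allzero <- wilcoxon_signed_rank(paired_series(1:4, c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(allzero$p_value, 1)
  expect_equal(allzero$n_used, 0)
  # +/- k symmetric differences put W at the null center n(n+1)/4
  sym <- paired_series(1:4, c(100, 100, 100, 100), c(103, 97, 105, 95))
  out <- wilcoxon_signed_rank(sym)
  expect_equal(out$statistic, 4 * 5 / 4)
  # large-n branch stays close to the library approximation
  set.seed(54)
  n <- 40
  d <- rnorm(n, 2, 10)
  ref <- runif(n, 100, 900)
  s <- paired_series(seq_len(n), ref, ref + d)
  mine <- wilcoxon_signed_rank(s)
  expect_match(mine$method, "normal approximation")
  libp <- wilcox.test(s$predicted_mCi, s$reference_mCi, paired = TRUE,
                      exact = FALSE, correct = TRUE)$p.value
  expect_equal(mine$p_value, libp, tolerance = 1e-10)
})

test_that("percent differences reproduce the published worked examples", {
  expect_equal(round(percent_difference(798, 804)), 1)
  expect_equal(round(percent_difference(219, 230)), 5)
  expect_equal(percent_difference(798, 804), 100 * 6 / 804)
  expect_equal(percent_difference(450, 450), 0)
  expect_error(percent_difference(100, 0), "> 0")
})

test_that("agreement report bundles pairs, tests and summaries coherently", {
  rep <- agreement_report(table2_fixture())
  expect_equal(nrow(rep$pairs), 13)
  s <- rep$summary
  expect_equal(s$n, 13)
  expect_true(s$ci95_low_mCi < s$mean_diff_mCi && s$mean_diff_mCi < s$ci95_high_mCi)
  expect_equal(s$median_abs_pct_diff, median(rep$pairs$percent_difference))
  expect_equal(s$max_abs_pct_diff, max(rep$pairs$percent_difference))
  # published claim check: max exceeds 10% (P4: 35/310), median well under
  expect_gt(s$max_abs_pct_diff, 10)
  expect_lt(s$median_abs_pct_diff, 10)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_identical(tidy(rep), rep$pairs)
  expect_identical(glance(rep), rep$summary)
})
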