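test_that("RMS relative error matches hand-computed values", {
  expect_equal(rms_relative_error(110, 100), 10)
  expect_equal(rms_relative_error(c(110, 90), c(100, 100)), 10)
  expect_equal(rms_relative_error(c(100, 200), c(100, 200)), 0)
  expect_error(rms_relative_error(c(1, 2), c(1, 0)), class = "adiposim_error")
  expect_error(rms_relative_error(1:3, 1:2), class = "adiposim_error")
})

test_that("RMS error is zero iff all measurements equal the reference", {
  ref <- c(54, 120, 299)
  expect_equal(rms_relative_error(ref, ref), 0)
  expect_gt(rms_relative_error(ref + c(0, 0, 0.1), ref), 0)
})

test_that("accuracy statistics are scale-invariant", {
  m <- c(110, 95, 180)
  r <- c(100, 100, 170)
  for (c_scale in c(0.25, 3, 1000)) {
    expect_equal(rms_relative_error(m * c_scale, r * c_scale),
                 rms_relative_error(m, r))
  }
})

test_that("reproducibility df follows the repeat design", {
  # 7 subjects x 3 repeats -> df = 14; 21 scans
  tb <- tibble::tibble(subject_id = rep(1:7, each = 3),
                       volume_ml = rep(c(2000, 2050, 1990), 7))
  rep7 <- reproducibility_rms_cv(tb)
  expect_equal(rep7$df, 14)
  expect_equal(rep7$n_scans, 21)
  # 1 subject x 4 + 3 subjects x 3 -> df = 9; 13 scans
  tb2 <- tibble::tibble(
    subject_id = rep(1:4, times = c(4, 3, 3, 3)),
    volume_ml = 1500 + seq_len(13)
  )
  rep4 <- reproducibility_rms_cv(tb2)
  expect_equal(rep4$df, 9)
  expect_equal(rep4$n_scans, 13)
})

test_that("RMS-CV equals the RMS of per-subject CVs and is scale-invariant", {
  set.seed(42)
  tb <- tibble::tibble(subject_id = rep(1:5, each = 3),
                       volume_ml = stats::rlnorm(15, log(2000), 0.03))
  rp <- reproducibility_rms_cv(tb)
  by_hand <- vapply(split(tb$volume_ml, tb$subject_id),
                    function(v) stats::sd(v) / mean(v), 0)
  expect_equal(rp$rms_cv, sqrt(mean(by_hand^2)) * 100, tolerance = 1e-10)
  scaled <- reproducibility_rms_cv(dplyr::mutate(tb, volume_ml = volume_ml * 7))
  expect_equal(scaled$rms_cv, rp$rms_cv, tolerance = 1e-10)
})

test_that("identical repeats give zero RMS-CV; short series are excluded", {
  tb <- tibble::tibble(subject_id = rep(1:3, each = 3), volume_ml = 500)
  expect_equal(reproducibility_rms_cv(tb)$rms_cv, 0)
  tb2 <- dplyr::bind_rows(tb, tibble::tibble(subject_id = 4, volume_ml = 600))
  expect_warning(rp <- reproducibility_rms_cv(tb2), "excluded")
  expect_equal(rp$df, 6)
  expect_equal(rp$n_subjects, 3)
})

test_that("Pearson r2 matches hand computation and flags degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r2(x, 2 * x + 1), 1)
  expect_equal(pearson_r2(x, c(1, 2, 2)), 0.75)   # r = sqrt(3)/2
  # symmetric design orthogonal to a linear trend
  expect_equal(pearson_r2(c(-1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-12)
  expect_error(pearson_r2(x, c(2, 2, 2)), class = "adiposim_error")
  expect_error(pearson_r2(1:2, 1:2), class = "adiposim_error")
})

test_that("Fisher z comparison matches the closed form", {
  expect_equal(compare_correlations_fisher_z(0.5, 30, 0.5, 50), 1)
  # z = (atanh(.9) - atanh(.3)) / sqrt(2/47) ~ 4.9 -> p << 0.001
  p <- compare_correlations_fisher_z(0.9, 50, 0.3, 50)
  z <- (atanh(0.9) - atanh(0.3)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
  expect_lt(p, 0.001)
  expect_equal(p, compare_correlations_fisher_z(0.3, 50, 0.9, 50))
  expect_error(compare_correlations_fisher_z(1, 10, 0.5, 10),
               class = "adiposim_error")
})

test_that("paired t test flags zero-variance differences and matches t.test", {
  a <- c(5, 6, 7, 8)
  same <- paired_t_test(a, a)
  expect_true(same$zero_variance)
  expect_true(is.na(same$p_value))
  shifted <- paired_t_test(a + 10, a)
  expect_true(shifted$zero_variance)   # constant shift: sd(diff) = 0
  expect_equal(shifted$estimate, 10)
  # near-constant shift with tiny jitter: finite, hugely significant t
  set.seed(9)
  b <- a + 10 + stats::rnorm(4, 0, 1e-4)
  res <- paired_t_test(b, a)
  ref <- stats::t.test(b, a, paired = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)
})

test_that("KS check accepts normal samples under the null", {
  set.seed(11)
  p_vals <- vapply(1:100, function(i) {
    ks_normality(stats::rnorm(1000))$p_value
  }, 0)
  expect_gte(mean(p_vals > 0.05), 0.95)
})

test_that("report tidiers expose the report contents", {
  rep_tbl <- tibble::tibble(subject_id = rep(1:3, each = 3),
                            volume_ml = c(100, 101, 99, 200, 202, 198,
                                          300, 303, 297))
  rp <- reproducibility_rms_cv(rep_tbl)
  expect_equal(nrow(tidy(rp)), 3)
  expect_equal(glance(rp)$df, rp$df)
  ar <- accuracy_report(c(110, 90, 100), c(100, 100, 100))
  expect_equal(nrow(tidy(ar)), 3)
  expect_equal(glance(ar)$rms_relative_error_pct, ar$rms_relative_error)
})
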