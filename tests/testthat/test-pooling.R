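test_that("median/IQR conversion follows the Wan-type estimators", {
  # published with-CAD row reporting 86 (51-141)
  conv <- median_iqr_to_mean_sd(86, 51, 141)
  expect_equal(conv$mean, (51 + 86 + 141) / 3)        # 92.67
  expect_equal(conv$sd, (141 - 51) / 1.35)            # 66.67
  expect_equal(conv$mean, 92.7, tolerance = 1e-3)
  expect_equal(conv$sd, 66.7, tolerance = 1e-3)
  # symmetric quartiles force mean = median exactly
  expect_identical(median_iqr_to_mean_sd(100, 90, 110)$mean, 100)
  # sample-size-dependent denominator
  n <- 100
  conv_n <- median_iqr_to_mean_sd(86, 51, 141, n = n)
  expect_equal(conv_n$sd,
               90 / (2 * qnorm((0.75 * n - 0.125) / (n + 0.25))))
  expect_warning(deg <- median_iqr_to_mean_sd(50, 50, 50), "degenerate")
  expect_equal(deg$sd, 0)
  expect_error(median_iqr_to_mean_sd(5, 10, 3), "q1.*q3")
})

test_that("CI-to-SE conversion uses the normal quantile at the level", {
  expect_equal(ci_to_se(39, 44), 5 / (2 * 1.959964), tolerance = 1e-6)
  expect_equal(ci_to_se(39, 44), 1.276, tolerance = 1e-3)
  a <- qnorm(0.975)
  expect_equal(ci_to_se(-a, a), 1)
  expect_warning(expect_equal(ci_to_se(7, 7), 0), "zero-width")
  expect_error(ci_to_se(4, 2), "<=")
  expect_error(ci_to_se(1, 2, level = 1.2), "level")
})

test_that("pooling closed forms hold in degenerate cases", {
  expect_error(pool_random_effects(data.frame()), "empty")
  eff3 <- data.frame(estimate = c(10, 10, 10), se = c(1, 1, 1))
  dl <- pool_random_effects(eff3, method = "dersimonian_laird")
  expect_equal(dl$mean, 10)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$ci_hi - dl$mean, qnorm(0.975) / sqrt(3), tolerance = 1e-10)
  # single study: pooled value is the study value
  one <- pool_random_effects(data.frame(estimate = 42, se = 3),
                             method = "dersimonian_laird")
  expect_equal(one$mean, 42)
  expect_equal(one$ci_hi, 42 + qnorm(0.975) * 3)
  expect_error(
    pool_random_effects(data.frame(estimate = c(1, 2), se = c(1, NA)),
                        method = "dersimonian_laird"),
    "unweighted")
})

test_that("DerSimonian-Laird collapses to fixed effect when tau2 is 0", {
  # equal SEs, spread narrower than chance: Q < k-1 clamps tau2 at 0
  eff <- data.frame(estimate = c(50, 50.2, 49.9, 50.1), se = rep(2, 4))
  dl <- pool_random_effects(eff, method = "dersimonian_laird")
  fe <- pool_random_effects(eff, method = "fixed_effect")
  expect_equal(dl$tau2, 0)
  expect_equal(dl$mean, fe$mean, tolerance = 1e-10)
  expect_equal(dl$ci_lo, fe$ci_lo, tolerance = 1e-10)
  expect_equal(dl$ci_hi, fe$ci_hi, tolerance = 1e-10)
})

test_that("DerSimonian-Laird agrees with the metafor reference", {
  eff <- data.frame(estimate = c(75.6, 136.6, 64, 32, 31.6),
                    se = c(11.3, 16.4, 9.6, 3.6, 8.0))
  mine <- pool_random_effects(eff, method = "dersimonian_laird")
  mf <- metafor::rma(yi = eff$estimate, sei = eff$se, method = "DL")
  expect_equal(mine$mean, as.numeric(coef(mf)), tolerance = 1e-10)
  expect_equal(mine$tau2, mf$tau2, tolerance = 1e-10)
  expect_equal(mine$ci_lo, mf$ci.lb, tolerance = 1e-10)
  expect_equal(mine$ci_hi, mf$ci.ub, tolerance = 1e-10)
  expect_equal(mine$q_stat, mf$QE, tolerance = 1e-10)
})

test_that("pooled means stay within the study range for both methods", {
  set.seed(301)
  for (i in 1:25) {
    k <- sample(2:10, 1)
    eff <- data.frame(estimate = rnorm(k, 80, 30),
                      se = runif(k, 0.5, 15))
    for (m in c("unweighted", "dersimonian_laird", "fixed_effect")) {
      p <- pool_random_effects(eff, method = m)
      expect_gte(p$mean, min(eff$estimate))
      expect_lte(p$mean, max(eff$estimate))
      expect_true(p$ci_lo <= p$mean && p$mean <= p$ci_hi)
    }
  }
})

test_that("CI width shrinks monotonically as all SEs scale down", {
  eff <- data.frame(estimate = c(60, 75, 90, 82), se = c(8, 10, 6, 12))
  widths <- vapply(c(1, 0.8, 0.6, 0.4, 0.2), function(f) {
    e <- eff; e$se <- e$se * f
    p <- pool_random_effects(e, method = "dersimonian_laird")
    p$ci_hi - p$ci_lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("DerSimonian-Laird recovers a known mean over replicates", {
  set.seed(7401)
  mu <- 77; tau <- 25; se_i <- 10; k <- 5; reps <- 500
  means <- vapply(seq_len(reps), function(r) {
    y <- rnorm(k, mu, sqrt(tau^2 + se_i^2))
    pool_random_effects(data.frame(estimate = y, se = rep(se_i, k)),
                        method = "dersimonian_laird")$mean
  }, numeric(1))
  mc_se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means) - mu), 2 * mc_se)
})

test_that("corpus pooling lands inside the published pooled intervals", {
  corpus <- load_corpus("table1")
  saved <- pool_reading_times(corpus, "saved_time_concurrent")
  expect_gte(saved$mean, 47); expect_lte(saved$mean, 107)
  expect_gt(saved$mean, 0)  # returned as a positive magnitude
  no_cad <- pool_reading_times(corpus, "no_cad")
  expect_gte(no_cad$mean, 111); expect_lte(no_cad$mean, 212)
  with_cad <- pool_reading_times(corpus, "with_cad_concurrent")
  expect_gte(with_cad$mean, 82); expect_lte(with_cad$mean, 154)
  expect_equal(saved$k_studies, 5)  # two reader rows pooled as one study
})

test_that("multi-reader rows are averaged within study by default", {
  corpus <- load_corpus("table1")
  eff <- extract_effects(corpus, "saved_time_concurrent")
  expect_equal(nrow(eff), 5)
  expect_equal(eff$estimate[eff$study_label == "Hempel (2022)"],
               (75.6 + 136.6) / 2)  # -106.1 s difference enters once
  indep <- extract_effects(corpus, "saved_time_concurrent",
                           multi_reader = "treat_as_independent")
  expect_equal(nrow(indep), 6)
})

test_that("a single-study corpus pools to that study's estimate", {
  row <- make_corpus_row(no_cad = 150, with_cad = 100, diff = -50)
  expect_warning(p <- pool_reading_times(validate_corpus(row),
                                         "saved_time_concurrent"),
                 "degenerate")
  expect_equal(p$mean, 50)
})

test_that("missing-SE imputation borrows the largest observed SE", {
  corpus <- load_corpus("table1")
  eff <- extract_effects(corpus, "saved_time_concurrent",
                         impute_missing_se = TRUE)
  expect_false(anyNA(eff$se))
  raw <- extract_effects(corpus, "saved_time_concurrent")
  expect_equal(max(eff$se), max(raw$se, na.rm = TRUE))
  # with a complete SE set, the inverse-variance pool runs
  p <- pool_random_effects(eff, method = "dersimonian_laird")
  expect_true(p$ci_lo <= p$mean && p$mean <= p$ci_hi)
})

test_that("second-reader summary spans the reported increases", {
  expect_equal(summarize_second_reader(load_corpus("table1")),
               list(min_increase = 33, max_increase = 41))
  one <- validate_corpus(
    make_corpus_row(reading_mode = "second_reader", diff = 41))
  expect_equal(summarize_second_reader(one),
               list(min_increase = 41, max_increase = 41))
  conc_only <- validate_corpus(make_corpus_row())
  expect_error(summarize_second_reader(conc_only), "no second-reader")
})
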