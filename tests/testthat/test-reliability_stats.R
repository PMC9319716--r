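test_that("two-way mean squares match the hand-worked decomposition", {
  # rows 1,2,3 identical across sessions: no session or error variation
  ms <- two_way_mean_squares(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ms$ms_rows, 2)            # 2 * var(row means)
  expect_equal(ms$ms_cols, 0)
  expect_equal(ms$ms_error, 0)
  expect_equal(ms$df_rows, 2L)
  expect_equal(ms$df_cols, 1L)
  expect_equal(ms$df_error, 2L)

  constant <- two_way_mean_squares(matrix(7, 4, 2))
  expect_equal(constant$ms_rows, 0)
  expect_equal(constant$ms_cols, 0)
  expect_equal(constant$ms_error, 0)
})

test_that("sums of squares are conserved and agree with stats::aov", {
  set.seed(401)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, 10, 4), n, k)
    ms <- two_way_mean_squares(x)
    ss <- ms$ms_rows * ms$df_rows + ms$ms_cols * ms$df_cols +
      ms$ms_error * ms$df_error
    expect_equal(ss, sum((x - mean(x))^2), tolerance = 1e-12)

    d <- data.frame(y = as.vector(x),
                    unit = factor(as.vector(row(x))),
                    session = factor(as.vector(col(x))))
    tab <- anova(stats::aov(y ~ unit + session, data = d))
    expect_equal(ms$ms_rows, tab["unit", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$ms_cols, tab["session", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-10)
  }
})

test_that("agreement ICC follows its algebraic special cases", {
  set.seed(402)
  x <- random_paired_matrix(n = 12)
  ms <- two_way_mean_squares(x)

  # MS_C = MS_E: formula reduces to (MS_R - MS_E) / MS_R
  ms_eq <- ms
  ms_eq$ms_cols <- ms_eq$ms_error
  expect_equal(icc_absolute_agreement_averaged(ms_eq),
               (ms$ms_rows - ms$ms_error) / ms$ms_rows)

  # constant session offset with no residual noise: ICC = MSR/(MSR + MSC/n) < 1
  a <- rnorm(10, 20, 5)
  off <- two_way_mean_squares(cbind(a, a + 3))
  expect_equal(off$ms_error, 0)
  icc <- icc_absolute_agreement_averaged(off)
  expect_equal(icc, off$ms_rows / (off$ms_rows + off$ms_cols / 10))
  expect_lt(icc, 1)

  expect_error(icc_absolute_agreement_averaged(two_way_mean_squares(matrix(5, 3, 2))),
               "degenerate")
})

test_that("confidence interval brackets the point estimate", {
  # in the study-like regime (n = 16 limbs, genuine between-limb variance)
  # the interval is always ordered and brackets the estimate
  set.seed(403)
  for (i in 1:100) {
    x <- random_paired_matrix(n = 16, unit_sd = runif(1, 5, 15),
                              noise_sd = runif(1, 1, 10))
    ms <- two_way_mean_squares(x)
    icc <- icc_absolute_agreement_averaged(ms)
    ci <- icc_confidence_interval(ms)
    expect_lte(ci[1], ci[2])
    expect_lte(ci[1], icc)
    expect_gte(ci[2], icc)
  }
  # in wider regimes (tiny n, vanishing unit variance) the F-based interval
  # can degenerate, but it then signals itself by inverted bounds; whenever
  # the bounds are ordered they still bracket the estimate
  for (i in 1:500) {
    x <- random_paired_matrix(n = sample(4:20, 1), unit_sd = runif(1, 0, 15),
                              noise_sd = runif(1, 1, 12))
    ms <- two_way_mean_squares(x)
    icc <- icc_absolute_agreement_averaged(ms)
    ci <- icc_confidence_interval(ms)
    if (!anyNA(ci) && ci[1] <= ci[2]) {
      expect_lte(ci[1], icc)
      expect_gte(ci[2], icc)
    }
  }
  # fully noiseless data collapse to a unit interval
  noiseless <- two_way_mean_squares(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(icc_confidence_interval(noiseless), c(1, 1))
})

test_that("ICC bands follow the stated half-open intervals", {
  expect_equal(classify_icc(c(0.37, 0.44, 0.40, 0.60, 0.75, 1, -0.2, 0.599, 0.749)),
               c("poor", "fair", "fair", "good", "excellent", "excellent",
                 "poor", "fair", "good"))
})

test_that("Bland-Altman statistics agree with direct computation and a paired t-test", {
  set.seed(404)
  s1 <- rnorm(16, 100, 20)
  s2 <- rnorm(16, 95, 20)
  ba <- bland_altman(s1, s2)
  expect_equal(ba$mean, mean(c(s1, s2)))
  expect_equal(ba$mean_diff, mean(s1 - s2))
  expect_equal(ba$sd_diff, sd(s1 - s2))
  expect_equal(ba$loa_low, ba$mean_diff - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, ba$mean_diff + 1.96 * ba$sd_diff)
  tt <- t.test(s1, s2, paired = TRUE)
  expect_equal(unname(ba$mean_diff_ci), as.numeric(tt$conf.int), tolerance = 1e-12)

  # swapping sessions negates the difference and mirrors the limits
  ba_sw <- bland_altman(s2, s1)
  expect_equal(ba_sw$mean_diff, -ba$mean_diff)
  expect_equal(ba_sw$loa_low, -ba$loa_high)
  expect_equal(ba_sw$loa_high, -ba$loa_low)

  same <- bland_altman(s1, s1)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("SEM and MDC identities hold to machine precision", {
  set.seed(405)
  sd_diff <- runif(100, 0, 300)
  sem <- sem_from_sd_diff(sd_diff)
  mdc <- mdc_from_sem(sem)
  expect_equal(sem * sqrt(2), sd_diff, tolerance = 1e-14)
  expect_equal(mdc, 1.96 * sd_diff, tolerance = 1e-14)
  expect_equal(sem_from_sd_diff(0), 0)
  expect_equal(mdc_from_sem(0), 0)
  expect_error(sem_from_sd_diff(-1), ">= 0")
  expect_error(mdc_from_sem(-1), ">= 0")
})

test_that("percentage metrics and MDC% bands follow the stated cut-offs", {
  pm <- percent_metrics(sem = 5.76, mdc = 15.97, mean = 56.80)
  expect_equal(pm$mdc_pct, 100 * 15.97 / 56.80)
  expect_equal(pm$mdc_pct_band, "acceptable")   # ~28.1%

  expect_equal(percent_metrics(1, 1, 1)$mdc_pct_band, "poor")  # 100%
  expect_equal(classify_mdc_pct(c(9.99, 10, 30, 30.01)),
               c("excellent", "acceptable", "acceptable", "poor"))
  expect_error(percent_metrics(1, 1, 0), "> 0")
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(406)
  n <- 1e5
  s1 <- rnorm(n, 50, 5)
  s2 <- s1 + rnorm(n, 0, 3)
  ba <- bland_altman(s1, s2)
  d <- s1 - s2
  inside <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("reliability_table reports unmatched limb-session pairs", {
  set.seed(407)
  cfg <- cohort_config(n_participants = 2, n_steps = 4, n_amiss = 0, seed = 9)
  summaries <- process_cohort(simulate_cohort(cfg))
  full <- reliability_table(summaries)
  expect_equal(nrow(full), 24L)
  expect_setequal(unique(full$region), c("whole", "hindfoot", "midfoot", "forefoot"))
  expect_equal(unique(full$n_units), 4L)

  broken <- summaries[!(summaries$participant == "P01" &
                          summaries$limb == "L" & summaries$session == 2), ]
  expect_error(reliability_table(broken), "P01:L session 2")
})
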