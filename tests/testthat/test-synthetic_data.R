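test_that("paired-measurement generator honours its degenerate and deterministic cases", {
  vc0 <- variance_components(5, 0, 0, 0, n_units = 4, k_sessions = 2)
  x <- simulate_paired_measurements(vc0, seed = 1)
  expect_equal(dim(x), c(4L, 2L))
  expect_true(all(x == 5))

  vc <- variance_components(10, 3, 1, 2)
  a <- simulate_paired_measurements(vc, seed = 42)
  b <- simulate_paired_measurements(vc, seed = 42)
  expect_identical(unclass(a), unclass(b))
  c_ <- simulate_paired_measurements(vc, seed = 43)
  expect_false(identical(unclass(a), unclass(c_)))

  expect_error(variance_components(0, -1, 0, 1), ">= 0")
  expect_error(variance_components(0, 1, 0, 1, n_units = 1), "n_units")
})

test_that("population ICC formula and high-reliability Monte Carlo recovery", {
  vc <- variance_components(0, 10, 0, 1, n_units = 16, k_sessions = 2)
  expect_equal(theoretical_icc(vc), 100 / (100 + 0.5))
  est <- vapply(1:1000, function(b) {
    pm <- simulate_paired_measurements(vc, seed = derive_seed(11, "mc", b))
    icc_absolute_agreement_averaged(two_way_mean_squares(pm))
  }, numeric(1))
  expect_lt(abs(mean(est) - theoretical_icc(vc)), 0.01)
})

test_that("simulated recordings have the programmed step count and physical pressures", {
  for (pattern in c("typical", "true_equinus", "drop_foot", "apparent_equinus")) {
    rec <- simulate_recording(gait_profile(pattern), n_steps = 15, seed = 21)
    expect_true(all(rec$frames >= 0))
    expect_equal(nrow(detect_steps(rec)), 15L)
  }
  expect_error(simulate_recording(gait_profile(), n_steps = 0), ">= 1")

  a <- simulate_recording(gait_profile(), n_steps = 5, seed = 3)
  b <- simulate_recording(gait_profile(), n_steps = 5, seed = 3)
  expect_identical(a$frames, b$frames)
})

test_that("true equinus suppresses hindfoot relative to forefoot loading in every step", {
  rec <- simulate_recording(gait_profile("true_equinus"), n_steps = 10, seed = 8)
  masks <- build_masks(rec$grid)
  fp <- detect_steps(rec)
  expect_equal(nrow(fp), 10L)
  for (i in seq_len(nrow(fp))) {
    hind <- step_variables(rec, fp[i, ], masks$hindfoot)
    fore <- step_variables(rec, fp[i, ], masks$forefoot)
    expect_lt(hind[["peak_pressure"]], fore[["peak_pressure"]])
  }
})

test_that("amiss injection is labelled, bounded, reproducible, and an identity at zero", {
  rec <- simulate_recording(gait_profile(), n_steps = 15, seed = 5)
  none <- inject_amiss_footprints(rec, 0, seed = 1)
  expect_identical(none$recording$frames, rec$frames)
  expect_equal(nrow(none$amiss), 0L)

  inj1 <- inject_amiss_footprints(rec, 3, seed = 2)
  inj2 <- inject_amiss_footprints(rec, 3, seed = 2)
  expect_identical(inj1$recording$frames, inj2$recording$frames)
  expect_identical(inj1$amiss, inj2$amiss)
  expect_equal(nrow(inj1$amiss), 3L)
  expect_true(all(inj1$amiss$step %in% 1:15))

  expect_error(inject_amiss_footprints(rec, 16, seed = 1), "exceeds")
})

test_that("cleaning removes exactly the injected amiss steps", {
  for (seed in c(101, 202)) {
    rec <- simulate_recording(gait_profile("apparent_equinus"), n_steps = 17,
                              seed = seed)
    inj <- inject_amiss_footprints(rec, 3, seed = seed + 1)
    fp <- clean_footprints(inj$recording, detect_steps(inj$recording))
    expect_equal(nrow(fp), 17L)
    expect_equal(which(!fp$valid), inj$amiss$step)
    expect_true(all(!is.na(fp$exclusion_reason[!fp$valid])))
  }
})

test_that("cohort simulation yields 32 session-paired recordings, deterministically", {
  cfg <- cohort_config(n_steps = 6, n_amiss = 1, seed = 77)
  cohort <- simulate_cohort(cfg)
  expect_s3_class(cohort, "insole_cohort")
  expect_length(cohort$recordings, 32L)
  meta <- do.call(rbind, lapply(cohort$recordings, function(r)
    data.frame(p = r$participant, l = r$limb, s = r$session)))
  expect_equal(nrow(unique(meta)), 32L)
  expect_setequal(unique(meta$s), 1:2)
  expect_equal(length(unique(meta$p)), 8L)

  cohort2 <- simulate_cohort(cfg)
  key <- names(cohort$recordings)[17]
  expect_identical(cohort$recordings[[key]]$frames,
                   cohort2$recordings[[key]]$frames)
  expect_identical(cohort$ground_truth$latent, cohort2$ground_truth$latent)
})
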