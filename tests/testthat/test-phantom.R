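# synthetic longitudinal nodule phantoms

test_that("a zero-day interval reproduces the baseline exactly", {
  p <- phantom_params(seed = 3, voi_size = 24, baseline_radius = 5,
                      interval_days = 0)
  pr <- simulate_pair(p)
  expect_identical(unclass(pr$baseline), unclass(pr$followup))
  expect_identical(pr$baseline_mask, pr$followup_mask)
})

test_that("one doubling time doubles the realized mask volume", {
  for (seed in c(2, 9)) {
    pr <- simulate_pair(phantom_params(seed = seed, voi_size = 32,
                                       baseline_radius = 6,
                                       volume_doubling_time = 300,
                                       interval_days = 300))
    ratio <- sum(pr$followup_mask) / sum(pr$baseline_mask)
    expect_gte(ratio, 1.8)
    expect_lte(ratio, 2.2)
  }
})

test_that("interior density drifts at the configured rate", {
  pr <- simulate_pair(phantom_params(seed = 4, voi_size = 32,
                                     baseline_radius = 7,
                                     volume_doubling_time = 1e6,
                                     density_baseline = 0.1,
                                     density_drift_rate = 0.1,
                                     interval_days = 300))
  rise <- mean(unclass(pr$followup)[pr$followup_mask == 1]) -
    mean(unclass(pr$baseline)[pr$baseline_mask == 1])
  expect_equal(rise, 0.3, tolerance = 0.05)
})

test_that("oversized growth raises an instructive error", {
  expect_error(simulate_pair(phantom_params(seed = 1, voi_size = 24,
                                            baseline_radius = 6,
                                            volume_doubling_time = 60,
                                            interval_days = 600)),
               "larger voi_size|outgrows")
})

test_that("cohort pairing follows the chronological rule", {
  cfg <- phantom_cohort_config("small", p_three_timepoints = 0)
  co <- simulate_cohort(5, seed = 2, cfg)
  expect_equal(length(co$pairs), 5L)
  expect_equal(nrow(co$manifest), 5L)

  cfg3 <- phantom_cohort_config("small", p_three_timepoints = 1)
  co3 <- simulate_cohort(1, seed = 2, cfg3)
  expect_equal(length(co3$pairs), 3L)
  expect_equal(unique(co3$manifest$patient_id), "P001")
  expect_setequal(paste(co3$manifest$baseline_label,
                        co3$manifest$followup_label),
                  c("T0 T1", "T0 T2", "T1 T2"))
  # longitudinal consistency: T0T2 interval = T0T1 + T1T2
  itv <- setNames(co3$manifest$interval_days,
                  paste0(co3$manifest$baseline_label,
                         co3$manifest$followup_label))
  expect_equal(itv[["T0T2"]], itv[["T0T1"]] + itv[["T1T2"]])
})

test_that("cohorts are bit-identical under a fixed seed", {
  a <- simulate_cohort(4, seed = 7, phantom_cohort_config("small"))
  b <- simulate_cohort(4, seed = 7, phantom_cohort_config("small"))
  expect_identical(a, b)
})

test_that("mask volume grows monotonically with the interval", {
  for (seed in c(1, 5, 11)) {
    vols <- sapply(c(0, 120, 240, 480), function(t) {
      sum(simulate_pair(phantom_params(seed = seed, voi_size = 32,
                                       baseline_radius = 4,
                                       volume_doubling_time = 240,
                                       interval_days = t))$followup_mask)
    })
    expect_true(all(diff(vols) >= 0))
  }
})

test_that("nodules contrast against the background beyond the noise floor", {
  co <- simulate_cohort(6, seed = 13, phantom_cohort_config("small"))
  for (pr in co$pairs) {
    v <- unclass(pr$baseline)
    inside <- mean(v[pr$baseline_mask == 1])
    outside <- mean(v[pr$baseline_mask == 0])
    expect_gt(inside - outside, pr$params$background_noise_sd)
  }
})

test_that("realized mask volume converges to the analytic ellipsoid volume", {
  rel_err <- sapply(c(4, 8, 12), function(r) {
    pr <- simulate_pair(phantom_params(seed = 21, voi_size = 40,
                                       baseline_radius = r,
                                       boundary_irregularity = 0,
                                       interval_days = 0))
    abs(sum(pr$baseline_mask) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  })
  expect_lt(rel_err[3], 0.05)
  expect_lt(rel_err[2], 0.10)
  expect_lt(rel_err[1], 0.20)
})

test_that("written cohorts round-trip through NIfTI and carry ground truth", {
  dir <- tempfile("cohort")
  co <- simulate_cohort(2, seed = 5, phantom_cohort_config("small"))
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_volume(man$baseline_path[1])
  expect_identical(back$intensities, unclass(co$pairs[[1]]$baseline))
  mback <- read_volume(man$baseline_mask_path[1])
  expect_identical(as.vector(mback$intensities),
                   as.vector(co$pairs[[1]]$baseline_mask))
  unlink(dir, recursive = TRUE)
})
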