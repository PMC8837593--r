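test_that("block_design validates its invariants", {
  expect_error(block_design("A", 10, 18, tr = 0, n_frames = 100), "tr")
  expect_error(block_design("A", -1, 18, tr = 1, n_frames = 100), "non-negative")
  expect_error(block_design(c("A", "A"), c(20, 10), c(5, 5), 1, 100),
               "strictly increasing")
  expect_error(block_design("A", 95, 18, tr = 1, n_frames = 100), "extends beyond")
  d <- block_design(c("A", "B"), c(10, 40), c(18, 18), 0.72, 120)
  expect_s3_class(d, "block_design")
  expect_equal(d$condition_names, c("A", "B"))
})

test_that("canonical_hrf matches the double-gamma density oracle", {
  # oracle: evaluate the double-gamma density on a fine grid and locate its peak
  fine <- seq(0, 32, by = 1e-3)
  dens <- dgamma(fine, shape = 6, rate = 1) - dgamma(fine, shape = 16, rate = 1) / 6
  t_peak <- fine[which.max(dens)]

  h <- canonical_hrf(0.72, 32)
  expect_equal(which.max(h), round(t_peak / 0.72) + 1L)  # index ~8, t ~5-6 s
  expect_gt(max(h), 0)
  expect_identical(h[1], 0)                               # gamma density at 0, shape > 1
  expect_true(is.finite(sum(h)))

  expect_identical(canonical_hrf(1, 32)[1], 0)
  expect_error(canonical_hrf(-1), "positive")
  expect_error(canonical_hrf(0.72, duration = 10), "at least 20")
})

test_that("convolve_design reduces to the boxcar for an identity kernel", {
  d <- block_design("A", 0, 40, tr = 1, n_frames = 40)  # block covers all frames
  reg <- convolve_design(d, hrf = 1)
  expect_equal(drop(reg), rep(1, 40))

  # no conditions at all -> zero-row regressor matrix
  d0 <- block_design(character(), numeric(), numeric(), tr = 1, n_frames = 20)
  expect_equal(nrow(convolve_design(d0, canonical_hrf(1))), 0L)
})

test_that("convolved regressor peak lags block onset by the kernel peak lag", {
  tr <- 0.72
  d <- block_design("A", onset = 14.4, duration = 10 * tr, tr = tr, n_frames = 120)
  h <- canonical_hrf(tr)
  reg <- drop(convolve_design(d, h))

  box <- as.numeric((seq_len(120) - 1) * tr >= 14.4 &
                    (seq_len(120) - 1) * tr < 14.4 + 10 * tr)
  expect_equal(reg, direct_convolve(box, h), tolerance = 1e-12)
  lag <- which.max(reg) - which(box == 1)[1]
  expect_equal(lag, which.max(h) - 1L, tolerance = 1)
})

test_that("cohort_spec rejects invalid worlds", {
  expect_error(cohort_spec(n_regions = 3), "n_regions")
  expect_error(cohort_spec(n_frames = 5), "n_frames")
  expect_error(cohort_spec(baseline_coupling = 0.6, modulation_amplitude = 0.5),
               "< 1")
  expect_error(cohort_spec(planted_pairs = rbind(c(1, 2), c(2, 3))),
               "at most one planted pair")
  expect_error(cohort_spec(planted_pairs = cbind(1, 99)), "out of range")
})

test_that("planted coupling has the stated range and zero-amplitude degeneracy", {
  spec <- cohort_spec(n_subjects = 2, n_regions = 4, n_frames = 100,
                      baseline_coupling = 0.2, modulation_amplitude = 0.5,
                      planted_pairs = cbind(1, 2), noise_sd = 0, seed = 1)
  set.seed(1)
  task <- simulate_subject(spec, "s1", "task", engagement = 1)
  w <- task$true_coupling[pair_row(1, 2, 4), ]
  expect_equal(max(w), 0.7, tolerance = 1e-12)
  expect_equal(min(w), 0.2, tolerance = 1e-12)

  # amplitude 0: task and rest ground truth identical
  spec0 <- cohort_spec(n_subjects = 2, n_regions = 4, n_frames = 50,
                       modulation_amplitude = 0, planted_pairs = cbind(1, 2),
                       seed = 1)
  set.seed(2); t0 <- simulate_subject(spec0, "s", "task")
  set.seed(3); r0 <- simulate_subject(spec0, "s", "rest")
  expect_identical(t0$true_coupling, r0$true_coupling)

  # no planted pairs: all ground-truth couplings are zero
  specn <- cohort_spec(n_subjects = 2, n_regions = 5, n_frames = 50,
                       planted_pairs = matrix(integer(), 0, 2), seed = 1)
  set.seed(4)
  expect_true(all(simulate_subject(specn, "s", "task")$true_coupling == 0))
})

test_that("empirical sliding correlation tracks the planted coupling", {
  # noise-free world: MAE between windowed correlation and w(t) below 0.15
  spec <- cohort_spec(n_subjects = 1, n_regions = 4, n_frames = 150,
                      noise_sd = 0, planted_pairs = cbind(1, 2), seed = 1)
  set.seed(42)
  maes <- replicate(50, {
    rec <- simulate_subject(spec, "s", "task", engagement = 1)
    sc <- sliding_cor(rec$timeseries[1, ], rec$timeseries[2, ], w = 30)
    w <- rec$true_coupling[pair_row(1, 2, 4), ]
    mean(abs(sc - w), na.rm = TRUE)
  })
  expect_lt(mean(maes), 0.15)
})

test_that("simulate_cohort is deterministic and honours degenerate settings", {
  spec <- cohort_spec(n_subjects = 6, n_regions = 4, n_frames = 30, seed = 9)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))

  spec0 <- cohort_spec(n_subjects = 6, n_regions = 4, n_frames = 30,
                       engagement_sd = 0, seed = 2)
  expect_true(all(simulate_cohort(spec0)$engagement == 1))

  co <- simulate_cohort(cohort_spec(n_subjects = 200, n_regions = 4,
                                    n_frames = 12, behavior_loading = 0,
                                    seed = 3))
  expect_lt(abs(cor(co$behavior$performance, co$engagement)), 0.15)

  co2 <- simulate_cohort(cohort_spec(n_subjects = 5, n_regions = 4,
                                     n_frames = 30, behavior_loading = 2,
                                     n_null_measures = 3, seed = 4))
  expect_named(co2$behavior,
               c("subject_id", "performance", "null_01", "null_02", "null_03",
                 "age", "sex"))
  expect_equal(nrow(co2$behavior), 5L)
})

test_that("task and rest are exchangeable under zero modulation", {
  # with amplitude 0 the two conditions are draws from one process: a KS test
  # on a per-recording summary statistic must not reject
  spec <- cohort_spec(n_subjects = 1, n_regions = 4, n_frames = 80,
                      modulation_amplitude = 0, planted_pairs = cbind(1, 2),
                      seed = 1)
  set.seed(7)
  stat <- function(cond) replicate(60, {
    rec <- simulate_subject(spec, "s", cond, engagement = rnorm(1, 1, 0.2))
    cor(rec$timeseries[1, ], rec$timeseries[2, ])
  })
  ks <- suppressWarnings(ks.test(stat("task"), stat("rest")))
  expect_gt(ks$p.value, 0.01)
})

test_that("pair bookkeeping matches the closed-form pair count", {
  expect_equal(nrow(pair_index(150)), 11175L)
  pi4 <- pair_index(4)
  expect_equal(pi4$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(pi4$j, c(2, 3, 4, 3, 4, 4))
  expect_equal(pair_row(pi4$i, pi4$j, 4), 1:6)
})
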