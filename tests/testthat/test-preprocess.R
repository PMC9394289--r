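test_that("a stimulus equal to the tiled baseline calibrates to zero", {
  fs <- 128
  base <- matrix(rnorm(2 * 3 * fs), nrow = 2)        # 2 channels, 3 s
  stim <- base[, rep(seq_len(3 * fs), 20)]           # tiled 20x to 60 s
  dat <- array(cbind(base, stim), c(1, 2, 63 * fs))
  ts <- trialset(dat, matrix(5, 1, 4), fs, baseline_seconds = 3)
  cal <- calibrate_baseline(ts)
  expect_equal(dim(cal$data)[3], 60 * fs)
  expect_lt(max(abs(cal$data)), 1e-12)
})

test_that("calibration cancels the injected trial-invariant artifact exactly", {
  # oracle: the same seeded generation without the artifact
  with_art <- generate_trialset(quick_config(2, seed = 5,
                                             baseline_artifact_amp = 25),
                                c(0, 1))
  without <- generate_trialset(quick_config(2, seed = 5,
                                            baseline_artifact_amp = 0),
                               c(0, 1))
  expect_gt(max(abs(with_art$data - without$data)), 1)  # artifact present
  cal_a <- calibrate_baseline(with_art)
  cal_0 <- calibrate_baseline(without)
  expect_lt(max(abs(cal_a$data - cal_0$data)), 1e-9)
})

test_that("calibration output spans exactly the stimulus window", {
  ts <- quick_trialset(2, seed = 3)                  # 3 + 12 s at 128 Hz
  cal <- calibrate_baseline(ts)
  expect_equal(dim(cal$data)[3], 12 * 128)
  expect_equal(cal$baseline_seconds, 0)

  ts60 <- generate_trialset(synth_config(n_trials_per_subject = 1, seed = 1),
                            1L)
  expect_equal(dim(calibrate_baseline(ts60)$data)[3], 60 * 128)
})

test_that("calibration rejects stimulus lengths that are not baseline multiples", {
  dat <- array(rnorm(2 * 5 * 128), c(1, 2, 5 * 128))
  ts <- trialset(dat, matrix(5, 1, 4), 128, baseline_seconds = 3)
  expect_error(calibrate_baseline(ts), "integer multiple")
})

test_that("calibration is idempotent on zero-baseline data", {
  fs <- 64
  dat <- array(rnorm(1 * 2 * 9 * fs), c(1, 2, 9 * fs))
  dat[, , 1:(3 * fs)] <- 0                           # silent baseline
  ts <- trialset(dat, matrix(5, 1, 4), fs, baseline_seconds = 3)
  cal <- calibrate_baseline(ts)
  expect_equal(cal$data[1, , ], dat[1, , -(1:(3 * fs))])
})

test_that("segment counts follow the closed formula", {
  ts <- calibrate_baseline(
    generate_trialset(synth_config(n_trials_per_subject = 1, seed = 2), 0L))
  expect_equal(dim(segment_trials(ts, 6, 3)$segments)[2], 19)   # (60-6)/3+1
  expect_equal(dim(segment_trials(ts, 60, 5)$segments)[2], 1)
  expect_equal(dim(segment_trials(ts, 6, 6)$segments)[2], 10)   # (60-6)/6+1

  # property sweep: random valid (T, S) against the printed formula
  set.seed(77)
  for (i in 1:50) {
    T <- sample(1:60, 1)
    S <- sample(1:20, 1)
    n <- dim(segment_trials(ts, T, S)$segments)[2]
    expect_equal(n, floor((60 - T) / S) + 1)
  }
})

test_that("segments tile the stimulus without crossing the trial end", {
  ts <- calibrate_baseline(quick_trialset(1, seed = 4))
  segs <- segment_trials(ts, 6, 3)
  fs <- ts$sampling_rate
  covered <- logical(dim(ts$data)[3])
  for (s in seq_len(dim(segs$segments)[2])) {
    idx <- (s - 1) * 3 * fs + seq_len(6 * fs)
    expect_lte(max(idx), dim(ts$data)[3])
    expect_equal(segs$segments[1, s, , ], ts$data[1, , idx])
    covered[idx] <- TRUE
  }
  expect_true(all(covered))                          # S <= T: full coverage
})

test_that("segmentation validates its window parameters", {
  ts <- calibrate_baseline(quick_trialset(1, seed = 4))
  expect_error(segment_trials(ts, 61, 3), "exceeds stimulus")
  expect_error(segment_trials(ts, 13, 3), "exceeds stimulus")
  expect_error(segment_trials(ts, 6, 0), "stride")
  expect_error(segment_trials(ts, 6, 1 / 3), "integer sample")
  expect_error(segment_trials(quick_trialset(1), 6, 3), "calibrate")
})

test_that("rating binarization follows the threshold and tie rule", {
  expect_equal(binarize_labels(7.2), 1L)
  expect_equal(binarize_labels(3.0, axis = "arousal"), 0L)
  expect_equal(binarize_labels(5.0), 0L)                       # tie -> low
  expect_equal(binarize_labels(5.0, tie_rule = "high"), 1L)
  r <- matrix(c(6, 2, 2, 6, 5, 5, 5, 5), 2, 4)
  expect_equal(binarize_labels(r, "valence"), c(1L, 0L))
  expect_equal(binarize_labels(r, "arousal"), c(0L, 1L))
  expect_error(binarize_labels(c(0.5, 7)), "\\[1, 9\\]")
})
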