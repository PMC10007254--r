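# Generators: determinism, exact lengths, class-dependent spectral structure.

test_that("seizure generator yields exact lengths and is deterministic", {
  sc <- seizure_scenario(duration_s = 60, seizure_onsets_s = 50,
                         n_channels = 4, fs_hz = 128, seed = 5)
  r1 <- generate_seizure_recording(sc)
  expect_equal(dim(r1$signal), c(4, 60 * 128))
  expect_false(any(!is.finite(r1$signal)))
  r2 <- generate_seizure_recording(sc)
  expect_identical(r1$signal, r2$signal)
  r3 <- generate_seizure_recording(seizure_scenario(60, 50, n_channels = 4,
                                                    fs_hz = 128, seed = 6))
  expect_false(identical(r1$signal, r3$signal))
  # early onset flags truncated preictal coverage instead of erroring
  expect_true("truncated_preictal" %in% r1$flags)
})

test_that("scenario validation rejects bad onsets and channel counts", {
  expect_error(seizure_scenario(100, c(50, 40)), "increasing")
  expect_error(seizure_scenario(100, 120), "within")
  expect_error(seizure_scenario(100, 50, n_channels = 1), "n_channels")
})

test_that("preictal bands carry band power at their assigned frequencies", {
  # 20-10 band at 16 Hz vs 40-30 band at 4 Hz, measured per channel with an
  # independent periodogram on the raw (unfiltered) signal
  sc <- seizure_scenario(duration_s = 3000, seizure_onsets_s = 2900,
                         n_channels = 6, fs_hz = 128, seed = 2)
  rec <- generate_seizure_recording(sc)
  seg <- function(lo, hi) rec$signal[, (lo * 128 + 1):(hi * 128)]
  s2010 <- seg(1700, 2300)   # [T-1200, T-600)
  s4030 <- seg(500, 1100)    # [T-2400, T-1800)
  p16_in <- mean(apply(s2010, 1, band_power, fs = 128, lo = 15, hi = 17))
  p16_out <- mean(apply(s4030, 1, band_power, fs = 128, lo = 15, hi = 17))
  p4_in <- mean(apply(s4030, 1, band_power, fs = 128, lo = 3, hi = 5))
  p4_out <- mean(apply(s2010, 1, band_power, fs = 128, lo = 3, hi = 5))
  expect_gt(p16_in / p16_out, 2)
  expect_gt(p4_in / p4_out, 2)
})

test_that("sleep EEG epochs carry the stage's dominant rhythm", {
  st <- rep(c("N3", "W"), each = 10)
  sc <- hypnogram_scenario(20, stage_labels = st, modality = "eeg", seed = 3)
  rec <- generate_sleep_recording(sc)
  expect_equal(ncol(rec$signal), 20 * 30 * 100)
  x_n3 <- rec$signal[1, 1:(10 * 3000)]
  x_w <- rec$signal[1, (10 * 3000 + 1):(20 * 3000)]
  slow_n3 <- band_power(x_n3, 100, 0.5, 2)
  slow_w <- band_power(x_w, 100, 0.5, 2)
  expect_gt(slow_n3 / slow_w, 2)
  alpha_w <- band_power(x_w, 100, 8, 12)
  alpha_n3 <- band_power(x_n3, 100, 8, 12)
  expect_gt(alpha_w / alpha_n3, 2)
})

test_that("ECG inter-beat variability is stage-dependent", {
  st <- rep(c("N3", "REM"), each = 20)
  sc <- hypnogram_scenario(40, stage_labels = st, modality = "ecg",
                           seed = 4, snr_db = Inf)   # noiseless template train
  rec <- generate_sleep_recording(sc)
  # independent peak detector: local maxima above half the QRS amplitude
  find_beats <- function(x, fs) {
    idx <- which(x > 0.5 & x >= c(-Inf, head(x, -1)) &
                   x >= c(tail(x, -1), Inf))
    idx[c(TRUE, diff(idx) > 0.2 * fs)] / fs
  }
  n_half <- 20 * 30 * 256
  ibi_n3 <- diff(find_beats(rec$signal[1, 1:n_half], 256))
  ibi_rem <- diff(find_beats(rec$signal[1, (n_half + 1):(2 * n_half)], 256))
  expect_lt(var(ibi_n3), var(ibi_rem))
  # and N3 beats are slower on average
  expect_gt(mean(ibi_n3), mean(ibi_rem))
})

test_that("unknown stage labels are rejected by name", {
  expect_error(generate_sleep_recording(
    hypnogram_scenario(2, stage_labels = c("W", "XX"), modality = "eeg")),
    "XX")
})

test_that("hypnogram generator matches its transition matrix", {
  expect_identical(generate_hypnogram(1, seed = 1), "W")
  expect_identical(generate_hypnogram(50, seed = 9),
                   generate_hypnogram(50, seed = 9))
  h <- generate_hypnogram(10000, seed = 1)
  P <- hypnogram_transition_matrix()
  expect_equal(sort(unique(h)), sort(rownames(P)))
  emp <- table(factor(head(h, -1), rownames(P)),
               factor(tail(h, -1), rownames(P)))
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - P)), 0.05)
  # all five stages show up in moderate-length records (fixed seeds)
  for (s in 1:5)
    expect_setequal(unique(generate_hypnogram(200, seed = s)), rownames(P))
})
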