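# Windowing arithmetic, state maps, labeling, stage mapping, balancing.

test_that("window counts follow floor((L - w)/step) + 1", {
  mk <- function(L_s, fs = 4) recording(matrix(0, 1, L_s * fs), fs)
  expect_equal(nrow(slice_windows(mk(600), window_rule(10, 8))$windows), 296)
  expect_equal(nrow(slice_windows(mk(300), window_rule(30, 22.5))$windows), 37)
  expect_equal(nrow(slice_windows(mk(10), window_rule(10, 0))$windows), 1)
  expect_equal(nrow(slice_windows(mk(9), window_rule(10, 0))$windows), 0)
  expect_error(window_rule(10, 10), "overlap")
})

test_that("window starts are an arithmetic progression and contents exact", {
  fs <- 8
  x <- seq_len(50 * fs)
  rec <- recording(matrix(x, 1), fs)
  ws <- slice_windows(rec, window_rule(10, 8))
  expect_equal(diff(ws$start_s), rep(2, nrow(ws$windows) - 1))
  for (k in seq_len(nrow(ws$windows)))
    expect_equal(ws$windows[k, ],
                 as.numeric(x[(ws$start_s[k] * fs + 1):
                                ((ws$start_s[k] + 10) * fs)]))
})

test_that("state map places preictal bands and interictal correctly", {
  sm <- build_state_map(3600, 7200)
  p2010 <- sm[sm$state == "preictal_20_10", ]
  expect_equal(c(p2010$start_s, p2010$end_s), c(2400, 3000))
  # early onset: bands clipped / empty rather than erroring
  sm2 <- build_state_map(1500, 7200)
  expect_false("preictal_40_30" %in% sm2$state)
  p3020 <- sm2[sm2$state == "preictal_30_20", ]
  expect_equal(c(p3020$start_s, p3020$end_s), c(0, 300))
  # two onsets: interictal bounded by the 50-min rule
  sm3 <- build_state_map(c(0, 7200), 7200)
  ii <- sm3[sm3$state == "interictal", ]
  expect_equal(c(ii$start_s, ii$end_s), c(0, 4200))
  # preictal bands of the later seizure do not intersect interictal
  pre <- sm3[sm3$state != "interictal", ]
  expect_true(all(pre$start_s >= 4200))
})

test_that("state intervals for distinct labels never overlap", {
  for (seedcase in list(c(3600, 5000), c(2500, 6100, 7000), 4000)) {
    sm <- build_state_map(seedcase, 7200)
    sm <- sm[order(sm$start_s), ]
    if (nrow(sm) > 1)
      expect_true(all(head(sm$end_s, -1) <= tail(sm$start_s, -1) + 1e-9))
  }
})

test_that("windows are labeled only under full containment", {
  fs <- 4
  rec <- recording(matrix(0, 1, 7200 * fs), fs, subject_id = "s7")
  ws <- slice_windows(rec, window_rule(10, 8))
  sm <- build_state_map(3600, 7200)
  ep <- label_windows(ws, sm)
  # oracle: exhaustive containment over all windows and intervals
  lab <- rep(NA_character_, length(ws$start_s))
  for (k in seq_along(ws$start_s)) {
    for (i in seq_len(nrow(sm))) {
      if (ws$start_s[k] >= sm$start_s[i] &&
          ws$start_s[k] + 10 <= sm$end_s[i]) lab[k] <- sm$state[i]
    }
  }
  expect_equal(unname(table(ep$labels)[sort(unique(ep$labels))]),
               unname(table(lab)[sort(unique(ep$labels))]))
  expect_true(all(ep$groups == "s7"))
  # a window straddling the 2400 s boundary is dropped
  expect_false(any(ep$start_s < 2400 & ep$start_s + 10 > 2400))
  # window [2400, 2410) with onset 3600 is preictal 20-10
  expect_equal(ep$labels[ep$start_s == 2400], "preictal_20_10")
})

test_that("hypnogram labeling respects single-stage runs", {
  fs <- 4
  stages <- c("W", "W", "N2", "N2", "N2", "REM")
  rec <- recording(matrix(0, 1, 180 * fs), fs,
                   annotations = list(type = "hypnogram", stages = stages,
                                      epoch_s = 30))
  ws <- slice_windows(rec, window_rule(30, 22.5))
  ep <- label_windows(ws)
  # runs: W [0,60), N2 [60,150), REM [150,180)
  expect_equal(sum(ep$labels == "W"), 5)     # starts 0..30 by 7.5
  expect_equal(sum(ep$labels == "N2"), 9)    # starts 60..120 by 7.5
  expect_equal(sum(ep$labels == "REM"), 1)   # start 150
  expect_false(any(ep$start_s > 30 & ep$start_s < 60))
})

test_that("R&K codes map onto AASM and the map is idempotent", {
  expect_equal(map_rk_to_aasm(c("W", "S1", "S2", "S3", "S4", "REM")),
               c("W", "N1", "N2", "N3", "N3", "REM"))
  expect_equal(map_rk_to_aasm("MOVEMENT"), "DROP")
  x <- c("W", "S4", "REM", "S1")
  expect_equal(map_rk_to_aasm(map_rk_to_aasm(x)), map_rk_to_aasm(x))
  expect_error(map_rk_to_aasm("S9"), "S9")
})

test_that("balancing undersamples exactly and reproducibly", {
  ep <- label_only_epochs(c(interictal = 100, preictal_20_10 = 80,
                            preictal_30_20 = 90))
  ep$windows <- matrix(seq_len(nrow(ep$windows)), ncol = 4,
                       nrow = nrow(ep$windows))
  b <- balance_states(ep, 80, seed = 4)
  expect_equal(unname(table(b$labels)), c(80, 80, 80), ignore_attr = TRUE)
  b2 <- balance_states(ep, 80, seed = 4)
  expect_identical(b$windows, b2$windows)
  # defaults to the minimum count; selection is a duplicate-free subset
  b3 <- balance_states(ep, seed = 1)
  expect_equal(unname(table(b3$labels)), c(80, 80, 80), ignore_attr = TRUE)
  expect_false(any(duplicated(b3$windows[, 1])))
  expect_true(all(b3$windows[, 1] %in% ep$windows[, 1]))
  expect_error(balance_states(ep, 80, states = c("interictal", "absent")),
               "absent")
  expect_error(balance_states(ep, 101), "exceeds")
})
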