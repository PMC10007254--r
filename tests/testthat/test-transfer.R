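# Freezing semantics, fine-tuning immutability, input adaptation.

test_that("freeze masks cover the expected layers", {
  seiz <- build_model(seizure_model_spec(), seed = 1)
  n12 <- freeze(seiz, freeze_spec("first_n_layers", n = 12))
  feat <- physiotransfer:::feature_layer_names(seiz$spec$layers)
  expect_setequal(n12$frozen, feat)
  n3 <- freeze(seiz, freeze_spec("first_n_layers", n = 3))
  expect_equal(n3$frozen,
               c("conv1d_1", "batch_normalization_1", "max_pooling1d_1"))
  n0 <- freeze(seiz, freeze_spec("first_n_layers", n = 0, strict = FALSE))
  expect_length(n0$frozen, 0)
  expect_error(freeze_spec("first_n_layers", n = 5), "3, 6, 9, 12")

  sleep <- build_model(sleep_model_spec(), seed = 1)
  b1 <- freeze(sleep, freeze_spec("named_blocks", blocks = "block_1"))
  expect_length(b1$frozen, 5)
  expect_setequal(b1$frozen, sleep$spec$block_boundaries$block_1)
  expect_error(freeze(sleep, freeze_spec("named_blocks",
                                         blocks = c("block_1", "block_3"))),
               "contiguous")
})

test_that("trainable parameters strictly decrease with freezing depth", {
  seiz <- seizure_model_spec()
  feat <- physiotransfer:::feature_layer_names(seiz$layers)
  tr_n <- vapply(c(3, 6, 9, 12), function(n)
    unname(count_parameters(seiz, head(feat, n))["trainable"]), numeric(1))
  expect_true(all(diff(tr_n) < 0))
  sleep <- sleep_model_spec()
  bb <- sleep$block_boundaries
  tr_b <- vapply(1:3, function(k)
    unname(count_parameters(sleep,
                            unlist(bb[seq_len(k)]))["trainable"]),
    numeric(1))
  expect_true(all(diff(tr_b) < 0))
})

test_that("fine-tuning leaves frozen parameters bit-identical", {
  ep <- tiny_epochs(16, seed = 2)
  pre <- fit_network(build_model(tiny_model_spec(n_classes = 2), seed = 1),
                     ep$windows, ep$labels,
                     hyper = train_hyper(batch_size = 16, lr = 3e-3,
                                         min_lr = 1e-4, max_epochs = 3),
                     seed = 1)$network
  fs <- freeze_spec("named_blocks", blocks = "block_1")
  tgt <- tiny_epochs(12, seed = 3)
  ft <- fine_tune(pre, tgt, fs,
                  hyper = train_hyper(batch_size = 8, lr = 3e-3,
                                      min_lr = 1e-4, max_epochs = 4),
                  seed = 5)
  frozen <- ft$network$frozen
  expect_setequal(frozen, pre$spec$block_boundaries$block_1)
  for (nm in frozen)
    expect_identical(ft$network$params[[nm]], pre$params[[nm]])
  # unfrozen layers did move
  expect_false(identical(ft$network$params$conv1d_2$W, pre$params$conv1d_2$W))
})

test_that("gradients on frozen tensors are exactly zero", {
  net <- freeze(build_model(tiny_model_spec(n_classes = 2), seed = 1),
                freeze_spec("named_blocks", blocks = "block_1"))
  set.seed(1)
  X <- matrix(rnorm(8 * 40), 8, 40)
  Y <- diag(2)[rep(1:2, 4), ]
  fwd <- network_forward(net, X, train = TRUE)
  gr <- network_backward(net, fwd, Y)
  for (nm in intersect(net$frozen, names(gr)))
    for (tn in names(gr[[nm]]))
      expect_true(all(gr[[nm]][[tn]] == 0))
  # an unfrozen conv still receives nonzero gradient
  expect_gt(max(abs(gr$conv1d_2$W)), 0)
})

test_that("fine-tuning rejects shape-mismatched targets by expected length", {
  net <- build_model(tiny_model_spec(input_len = 40, n_classes = 2), seed = 1)
  bad <- epoch_set(matrix(0, 4, 30), rep(c("a", "b"), 2), fs_hz = 1,
                   window_s = 30)
  expect_error(fine_tune(net, bad, freeze_spec("named_blocks",
                                               blocks = "block_1")),
               "40")
})

test_that("input adaptation resamples 256 Hz epochs onto the 3000-sample grid", {
  fs <- 256
  t <- seq_len(30 * fs) / fs
  rec <- recording(matrix(sin(2 * pi * 5 * t), 1), fs)
  out <- adapt_input(rec, 100)
  expect_equal(ncol(out$signal), 3000)
  expect_equal(out$fs_hz, 100)
  # the 5 Hz peak survives resampling (independent periodogram)
  p5 <- band_power(out$signal[1, ], 100, 4.5, 5.5)
  ptot <- band_power(out$signal[1, ], 100, 0.1, 49)
  expect_gt(p5 / ptot, 0.9)
  # identity at equal rates; strict mode refuses upsampling
  same <- adapt_input(rec, 256)
  expect_identical(same$signal, rec$signal)
  expect_error(adapt_input(out, 256), "strict")
})
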