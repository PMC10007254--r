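# Shared fixtures: a small architecture that exercises every layer kind, and
# quick epoch-set builders. Everything is generated in code at test time.

tiny_model_spec <- function(input_len = 40, n_classes = 3) {
  model_spec(list(
    layer_spec("conv1d_1", "conv1d", filter_size = 4, n_filters = 3,
               stride = 2),
    layer_spec("batch_normalization_1", "batch_norm", activation = "relu"),
    layer_spec("max_pooling1d_1", "max_pool1d", filter_size = 2, stride = 2),
    layer_spec("conv1d_2", "conv1d", filter_size = 3, n_filters = 4,
               stride = 1),
    layer_spec("batch_normalization_2", "batch_norm", activation = "relu"),
    layer_spec("average_pooling1d_1", "avg_pool1d", filter_size = 2,
               stride = 2),
    layer_spec("global_average_pooling1d", "global_avg_pool"),
    layer_spec("dense_1", "dense", units = 8, activation = "relu"),
    layer_spec("dense_2", "dense", units = n_classes,
               activation = "softmax")),
    input_len = input_len, n_classes = n_classes,
    block_boundaries = list(
      block_1 = c("conv1d_1", "batch_normalization_1", "max_pooling1d_1"),
      block_2 = c("conv1d_2", "batch_normalization_2",
                  "average_pooling1d_1")))
}

# two sinusoid classes a small network separates quickly
tiny_epochs <- function(n_per_class = 20, len = 40, fs = 40, seed = 1,
                        freqs = c(a = 4, b = 10)) {
  set.seed(seed)
  tt <- (seq_len(len) - 1) / fs
  W <- NULL
  labs <- character(0)
  for (cl in names(freqs)) {
    M <- t(sapply(seq_len(n_per_class), function(i)
      sin(2 * pi * freqs[[cl]] * tt + runif(1, 0, 2 * pi)) +
        rnorm(len, sd = 0.3)))
    W <- rbind(W, M)
    labs <- c(labs, rep(cl, n_per_class))
  }
  epoch_set(W, labs, fs_hz = fs, window_s = len / fs)
}

# dummy epoch set where only labels/groups matter (for split machinery)
label_only_epochs <- function(counts, groups = NULL, tags = NULL) {
  n <- sum(counts)
  labs <- rep(names(counts), counts)
  epoch_set(matrix(0, n, 4), labs,
            groups = groups %||% rep("s1", n),
            dataset_tags = tags %||% rep("d1", n),
            fs_hz = 1, window_s = 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent periodogram band power (rectangular window FFT), used as the
# oracle against generator band structure
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  sum(Mod(X[keep])^2) / n^2
}
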