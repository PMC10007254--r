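# Declarative 1D-CNN architecture specifications with closed-form shape
# inference and parameter accounting. All convolutions and poolings are
# "valid" (unpadded): out_len = floor((in_len - filter_size)/stride) + 1,
# which uniquely reproduces the printed layer output lengths of both
# architectures.

#' Layer specification
#'
#' @param name unique layer name (e.g. `"conv1d_1"`).
#' @param kind one of `conv1d`, `batch_norm`, `max_pool1d`, `avg_pool1d`,
#'   `global_avg_pool`, `dense`.
#' @param filter_size kernel/pool size (conv and pool kinds).
#' @param n_filters number of output channels (conv only).
#' @param stride stride (conv and pool kinds, >= 1).
#' @param units output units (dense only).
#' @param activation `"relu"`, `"softmax"` or `"linear"`; hidden batch-norm
#'   and dense layers default to relu, the terminal dense to softmax.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(name, kind, filter_size = NULL, n_filters = NULL,
                       stride = NULL, units = NULL, activation = "linear") {
  kinds <- c("conv1d", "batch_norm", "max_pool1d", "avg_pool1d",
             "global_avg_pool", "dense")
  if (!kind %in% kinds) stop("unknown layer kind: ", kind)
  if (kind == "conv1d" && (is.null(filter_size) || is.null(n_filters) ||
                           is.null(stride)))
    stop("conv1d requires filter_size, n_filters and stride")
  if (kind %in% c("max_pool1d", "avg_pool1d") &&
      (is.null(filter_size) || is.null(stride)))
    stop(kind, " requires filter_size and stride")
  if (kind == "dense" && is.null(units)) stop("dense requires units")
  if (!is.null(stride) && stride < 1) stop("stride must be >= 1")
  structure(list(name = name, kind = kind, filter_size = filter_size,
                 n_filters = n_filters, stride = stride, units = units,
                 activation = activation),
            class = "layer_spec")
}

#' Model specification
#'
#' @param layers ordered list of [layer_spec()] objects, ending with a dense
#'   layer of `n_classes` units.
#' @param input_len input length in samples.
#' @param input_channels input channel count.
#' @param n_classes number of output classes.
#' @param block_boundaries optional named list mapping block names to the
#'   layer names they contain (used by block-wise freezing).
#' @return a `model_spec`.
#' @export
model_spec <- function(layers, input_len, input_channels = 1, n_classes,
                       block_boundaries = NULL) {
  last <- layers[[length(layers)]]
  if (last$kind != "dense" || last$units != n_classes)
    stop("the final layer must be dense(n_classes)")
  nm <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("layer names must be unique")
  if (!is.null(block_boundaries)) {
    feat <- feature_layer_names(layers)
    blk <- unlist(block_boundaries, use.names = FALSE)
    if (!setequal(blk, feat))
      stop("block_boundaries must partition the pre-global feature layers")
  }
  structure(list(layers = layers, input_len = input_len,
                 input_channels = input_channels, n_classes = n_classes,
                 block_boundaries = block_boundaries),
            class = "model_spec")
}

# names of the ordered feature layers (conv/BN/pool before global pooling)
feature_layer_names <- function(layers) {
  kinds <- vapply(layers, `[[`, character(1), "kind")
  stopn <- match("global_avg_pool", kinds)
  if (is.na(stopn)) stopn <- length(layers) + 1
  vapply(layers[seq_len(stopn - 1)], `[[`, character(1), "name")
}

#' @export
print.model_spec <- function(x, ...) {
  sh <- infer_shapes(x)
  cat(sprintf("<model_spec> input %d x %d, %d classes\n",
              x$input_len, x$input_channels, x$n_classes))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %-22s %-16s %s\n", l$name, l$kind,
                paste(sh$length[i], "x", sh$channels[i])))
  }
  invisible(x)
}

#' Seizure-prediction CNN specification
#'
#' The 10-s, 512-Hz single-channel (post-GFP) architecture: four
#' conv/batch-norm/max-pool stages (filters 10x32 s2, 10x64 s2, 10x64 s2,
#' 10x128 s1; all pools size 3, stride 1), global average pooling, then
#' dense 256, 128 and a 2-class softmax.
#'
#' @return a [model_spec()] with `input_len = 5120`.
#' @export
seizure_model_spec <- function() {
  L <- list()
  cfg <- list(c(10, 32, 2), c(10, 64, 2), c(10, 64, 2), c(10, 128, 1))
  for (i in seq_along(cfg)) {
    p <- cfg[[i]]
    L <- c(L, list(
      layer_spec(paste0("conv1d_", i), "conv1d", filter_size = p[1],
                 n_filters = p[2], stride = p[3]),
      layer_spec(paste0("batch_normalization_", i), "batch_norm",
                 activation = "relu"),
      layer_spec(paste0("max_pooling1d_", i), "max_pool1d",
                 filter_size = 3, stride = 1)))
  }
  L <- c(L, list(
    layer_spec("global_average_pooling1d", "global_avg_pool"),
    layer_spec("dense_1", "dense", units = 256, activation = "relu"),
    layer_spec("dense_2", "dense", units = 128, activation = "relu"),
    layer_spec("dense_3", "dense", units = 2, activation = "softmax")))
  model_spec(L, input_len = 5120, input_channels = 1, n_classes = 2)
}

#' Sleep-staging CNN specification
#'
#' The 30-s, 100-Hz single-channel architecture in three named blocks:
#' block_1 and block_2 each hold two conv(5, s1) + batch-norm pairs and an
#' average pool (2, s2) with 16 and 32 filters; block_3 holds one conv(5, 32,
#' s1) + batch-norm and global average pooling; then dense 32 and a 5-class
#' softmax.
#'
#' @return a [model_spec()] with `input_len = 3000` and named blocks.
#' @export
sleep_model_spec <- function() {
  conv <- function(i, nf) layer_spec(paste0("conv1d_", i), "conv1d",
                                     filter_size = 5, n_filters = nf,
                                     stride = 1)
  bn <- function(i) layer_spec(paste0("batch_normalization_", i),
                               "batch_norm", activation = "relu")
  L <- list(conv(1, 16), bn(1), conv(2, 16), bn(2),
            layer_spec("average_pooling1d_1", "avg_pool1d",
                       filter_size = 2, stride = 2),
            conv(3, 32), bn(3), conv(4, 32), bn(4),
            layer_spec("average_pooling1d_2", "avg_pool1d",
                       filter_size = 2, stride = 2),
            conv(5, 32), bn(5),
            layer_spec("global_average_pooling1d", "global_avg_pool"),
            layer_spec("dense_1", "dense", units = 32, activation = "relu"),
            layer_spec("dense_2", "dense", units = 5,
                       activation = "softmax"))
  blocks <- list(
    block_1 = c("conv1d_1", "batch_normalization_1", "conv1d_2",
                "batch_normalization_2", "average_pooling1d_1"),
    block_2 = c("conv1d_3", "batch_normalization_3", "conv1d_4",
                "batch_normalization_4", "average_pooling1d_2"),
    block_3 = c("conv1d_5", "batch_normalization_5"))
  model_spec(L, input_len = 3000, input_channels = 1, n_classes = 5,
             block_boundaries = blocks)
}

#' Closed-form per-layer output shapes
#'
#' Valid (unpadded) convolution/pooling arithmetic:
#' `out_len = floor((in_len - filter_size)/stride) + 1`; batch norm preserves
#' shape; global average pooling collapses length to 1; dense layers output
#' their unit count.
#'
#' @param spec a [model_spec()].
#' @return a data.frame with one row per layer: `name`, `kind`, `length`,
#'   `channels`. An intermediate length below 1 is an error naming the layer.
#' @export
infer_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  len <- spec$input_len
  ch <- spec$input_channels
  out <- data.frame(name = character(), kind = character(),
                    length = integer(), channels = integer())
  for (l in spec$layers) {
    if (l$kind == "conv1d") {
      len <- floor((len - l$filter_size) / l$stride) + 1
      ch <- l$n_filters
    } else if (l$kind %in% c("max_pool1d", "avg_pool1d")) {
      len <- floor((len - l$filter_size) / l$stride) + 1
    } else if (l$kind == "global_avg_pool") {
      len <- 1
    } else if (l$kind == "dense") {
      len <- 1
      ch <- l$units
    } # batch_norm preserves shape
    if (len < 1)
      stop("layer ", l$name, " would have output length ", len)
    out <- rbind(out, data.frame(name = l$name, kind = l$kind,
                                 length = as.integer(len),
                                 channels = as.integer(ch)))
  }
  out
}

#' Exact parameter counts under a freeze set
#'
#' Counts conv weights and biases, batch-norm scale and shift terms, and
#' dense weights and biases (running batch-norm statistics are not
#' parameters). Trainable excludes the parameters of every layer in
#' `frozen_set`.
#'
#' @param spec a [model_spec()].
#' @param frozen_set character vector of frozen layer names (may be empty).
#' @return named numeric vector `c(total =, trainable =)`.
#' @export
count_parameters <- function(spec, frozen_set = character()) {
  stopifnot(inherits(spec, "model_spec"))
  nm <- vapply(spec$layers, `[[`, character(1), "name")
  bad <- setdiff(frozen_set, nm)
  if (length(bad)) stop("unknown layer name(s): ", paste(bad, collapse = ", "))
  sh <- infer_shapes(spec)
  in_ch <- c(spec$input_channels, sh$channels[-nrow(sh)])
  total <- trainable <- 0
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- switch(l$kind,
                conv1d = l$filter_size * in_ch[i] * l$n_filters + l$n_filters,
                batch_norm = 2 * sh$channels[i],
                dense = in_ch[i] * l$units + l$units,
                0)
    total <- total + p
    if (!(l$name %in% frozen_set)) trainable <- trainable + p
  }
  c(total = total, trainable = trainable)
}

#' Serialize / deserialize a model specification
#'
#' @param spec a [model_spec()].
#' @param path file path for the JSON document.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   returns the reconstructed [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  doc <- list(format = "physiotransfer/model_spec", version = "1.0",
              input_len = spec$input_len,
              input_channels = spec$input_channels,
              n_classes = spec$n_classes,
              block_boundaries = spec$block_boundaries,
              layers = lapply(spec$layers, function(l)
                l[!vapply(l, is.null, logical(1))]))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format) || doc$format != "physiotransfer/model_spec")
    stop("not a model_spec document")
  layers <- lapply(doc$layers, function(l)
    layer_spec(l$name, l$kind,
               filter_size = l$filter_size, n_filters = l$n_filters,
               stride = l$stride, units = l$units,
               activation = if (is.null(l$activation)) "linear" else l$activation))
  bb <- if (!is.null(doc$block_boundaries))
    lapply(doc$block_boundaries, function(b) unlist(b)) else NULL
  model_spec(layers, input_len = doc$input_len,
             input_channels = doc$input_channels, n_classes = doc$n_classes,
             block_boundaries = bb)
}
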