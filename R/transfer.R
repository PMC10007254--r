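# Layer/block-freezing transfer: freeze masks, fine-tuning, and input
# adaptation (resampling) so a target modality fits a pretrained input shape.

#' Freezing specification
#'
#' Two modes mirror the two experiments: `first_n_layers` freezes the first
#' `n` of the 12 ordered feature layers of the seizure network (each of its
#' four stages contributes conv, batch-norm and pool, so the admissible
#' depths 3, 6, 9 and 12 land on stage boundaries); `named_blocks` freezes
#' whole named blocks of the sleep network, contiguously from `block_1`.
#'
#' @param mode `"first_n_layers"` or `"named_blocks"`.
#' @param n number of leading feature layers to freeze; strict mode requires
#'   `n` in {3, 6, 9, 12}, permissive mode any `0 <= n <=` number of feature
#'   layers.
#' @param blocks character vector of block names, contiguous from
#'   `block_1`.
#' @param strict enforce the admissible depths?
#' @return a `freeze_spec`.
#' @export
freeze_spec <- function(mode = c("first_n_layers", "named_blocks"),
                        n = NULL, blocks = NULL, strict = TRUE) {
  mode <- match.arg(mode)
  if (mode == "first_n_layers") {
    if (is.null(n)) stop("first_n_layers requires n")
    if (strict && !n %in% c(3, 6, 9, 12))
      stop("n must be one of 3, 6, 9, 12 in strict mode")
    if (n < 0) stop("n must be non-negative")
  } else {
    if (is.null(blocks)) stop("named_blocks requires blocks")
  }
  structure(list(mode = mode, n = n, blocks = blocks, strict = strict),
            class = "freeze_spec")
}

#' Apply a freeze mask to a network
#'
#' Frozen layers are excluded from gradient updates, and frozen batch-norm
#' layers run on their stored statistics (inference mode) during training.
#' The mask is queryable as `net$frozen`.
#'
#' @param net a `cnn_network`.
#' @param fspec a [freeze_spec()].
#' @return the network with its freeze mask set.
#' @export
freeze <- function(net, fspec) {
  stopifnot(inherits(net, "cnn_network"), inherits(fspec, "freeze_spec"))
  spec <- net$spec
  if (fspec$mode == "first_n_layers") {
    feat <- feature_layer_names(spec$layers)
    if (fspec$n > length(feat))
      stop("n exceeds the ", length(feat), " feature layers")
    net$frozen <- head(feat, fspec$n)
  } else {
    bb <- spec$block_boundaries
    if (is.null(bb)) stop("this model spec defines no blocks")
    want <- fspec$blocks
    if (!all(want %in% names(bb)))
      stop("unknown block(s): ",
           paste(setdiff(want, names(bb)), collapse = ", "))
    first_k <- names(bb)[seq_along(want)]
    if (!setequal(want, first_k))
      stop("blocks must be contiguous from ", names(bb)[1])
    net$frozen <- unlist(bb[want], use.names = FALSE)
  }
  net
}

#' Fine-tune a pretrained network with frozen layers
#'
#' Applies the freeze mask, resets the optimizer state, and retrains the
#' unfrozen layers on the target windows. Frozen parameters are bit-identical
#' to their pretrained values afterwards.
#'
#' @param net the pretrained `cnn_network`.
#' @param epochs target [epoch_set()] (window length must match the network
#'   input; see [adapt_input()]).
#' @param fspec a [freeze_spec()].
#' @param hyper a [train_hyper()].
#' @param seed integer seed.
#' @param validation optional `list(x =, y =)`.
#' @return list with the fine-tuned `network` and training `history`.
#' @export
fine_tune <- function(net, epochs, fspec, hyper = train_hyper(), seed = 1,
                      validation = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (ncol(epochs$windows) != net$spec$input_len)
    stop("window length ", ncol(epochs$windows),
         " does not match the expected input length ", net$spec$input_len)
  net <- freeze(net, fspec)
  fit_network(net, epochs$windows, epochs$labels, validation = validation,
              hyper = hyper, seed = seed)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Resample a recording to a target rate
#'
#' Polyphase rational resampling (via the `signal` package) so that, e.g., a
#' 30-s epoch at 256 Hz becomes exactly 3000 samples at 100 Hz and can enter
#' a network trained on 100-Hz input. Annotation times are in seconds and
#' are unchanged.
#'
#' @param rec a [recording()].
#' @param target_fs target sampling rate; upsampling is an error in strict
#'   mode.
#' @param strict forbid upsampling?
#' @return the resampled [recording()].
#' @export
adapt_input <- function(rec, target_fs, strict = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs == rec$fs_hz) return(rec)
  if (target_fs > rec$fs_hz && strict)
    stop("upsampling from ", rec$fs_hz, " to ", target_fs,
         " Hz requested in strict mode")
  g <- gcd2(round(target_fs), round(rec$fs_hz))
  p <- round(target_fs) / g
  q <- round(rec$fs_hz) / g
  n_out <- round(ncol(rec$signal) * p / q)
  X <- matrix(0, nrow(rec$signal), n_out)
  for (ch in seq_len(nrow(rec$signal))) {
    y <- signal::resample(rec$signal[ch, ], p, q)
    if (length(y) >= n_out) X[ch, ] <- y[seq_len(n_out)]
    else X[ch, seq_along(y)] <- y
  }
  rec$signal <- X
  rec$fs_hz <- target_fs
  rec
}
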