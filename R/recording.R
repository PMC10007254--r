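#' Multichannel recording container
#'
#' A `recording` bundles a channels-by-samples signal matrix with its sampling
#' rate, channel names, provenance, and an annotation track: either a list of
#' seizure onset times (seconds) or a hypnogram (one sleep stage per scored
#' epoch).
#'
#' Intervals throughout the package are half-open `[start, end)` in seconds,
#' and sample indexing is 0-based in that arithmetic, so windowing composes
#' exactly with annotation times.
#'
#' @param signal numeric matrix, channels x samples (a vector is treated as a
#'   single channel).
#' @param fs_hz sampling rate in samples/second.
#' @param channel_names character vector, one name per channel.
#' @param annotations `NULL`, or a list with `type = "seizure"` and `onsets_s`
#'   (strictly increasing onset times in seconds), or `type = "hypnogram"` with
#'   `stages` (one label per epoch) and `epoch_s` (scored epoch length,
#'   default 30).
#' @param subject_id,source_dataset provenance strings carried through
#'   segmentation into epoch sets.
#' @param flags character vector of quality flags (e.g.
#'   `"truncated_preictal"`).
#' @return an object of class `recording`.
#' @export
recording <- function(signal, fs_hz, channel_names = NULL, annotations = NULL,
                      subject_id = "unknown", source_dataset = "unknown",
                      flags = character()) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  n_ch <- nrow(signal)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch)
    stop("channel_names length must equal the number of channels")
  dur <- ncol(signal) / fs_hz
  if (!is.null(annotations)) {
    if (!is.list(annotations) || is.null(annotations$type))
      stop("annotations must be a list with a 'type' field")
    if (annotations$type == "seizure") {
      on <- annotations$onsets_s
      if (length(on) && (any(diff(on) <= 0)))
        stop("seizure onsets must be strictly increasing")
      if (length(on) && (any(on < 0) || any(on >= dur)))
        stop("seizure onsets must lie within [0, duration)")
    } else if (annotations$type == "hypnogram") {
      if (is.null(annotations$epoch_s)) annotations$epoch_s <- 30
      n_ep <- length(annotations$stages)
      if (n_ep * annotations$epoch_s > dur + 1e-9)
        stop("hypnogram extends beyond the signal duration")
    } else stop("unknown annotation type: ", annotations$type)
  }
  structure(list(signal = signal, fs_hz = fs_hz,
                 channel_names = channel_names, annotations = annotations,
                 subject_id = subject_id, source_dataset = source_dataset,
                 flags = flags),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs_hz,
              ncol(x$signal) / x$fs_hz))
  cat(sprintf("  subject: %s  dataset: %s\n", x$subject_id, x$source_dataset))
  if (!is.null(x$annotations))
    cat(sprintf("  annotations: %s\n", x$annotations$type))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param x a [recording()].
#' @return duration in seconds.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "recording"))
  ncol(x$signal) / x$fs_hz
}

#' Labeled fixed-length window collection
#'
#' An `epoch_set` holds single-channel windows as a windows-by-samples matrix
#' together with per-window label, subject and dataset provenance.
#'
#' @param windows numeric matrix, one row per window.
#' @param labels character vector of state labels, one per window.
#' @param groups character vector of subject ids, one per window.
#' @param dataset_tags character vector of source-dataset tags, one per window.
#' @param fs_hz sampling rate of the windows.
#' @param window_s window length in seconds.
#' @param start_s optional numeric vector of absolute window start times.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(windows, labels, groups = NULL, dataset_tags = NULL,
                      fs_hz, window_s, start_s = NULL) {
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = length(labels))
  n <- nrow(windows)
  if (is.null(groups)) groups <- rep("unknown", n)
  if (is.null(dataset_tags)) dataset_tags <- rep("unknown", n)
  if (length(labels) != n || length(groups) != n || length(dataset_tags) != n)
    stop("windows, labels, groups and dataset_tags must have equal length")
  if (!is.null(start_s) && length(start_s) != n)
    stop("start_s must have one entry per window")
  structure(list(windows = windows, labels = as.character(labels),
                 groups = as.character(groups),
                 dataset_tags = as.character(dataset_tags),
                 fs_hz = fs_hz, window_s = window_s, start_s = start_s),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d window(s) x %d samples (%g s @ %g Hz)\n",
              nrow(x$windows), ncol(x$windows), x$window_s, x$fs_hz))
  if (nrow(x$windows)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Subset an epoch set by window index
#' @param x an [epoch_set()].
#' @param i integer (or logical) index vector.
#' @return an `epoch_set` restricted to the selected windows.
#' @export
subset_epochs <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$windows[i, , drop = FALSE], x$labels[i], x$groups[i],
            x$dataset_tags[i], x$fs_hz, x$window_s,
            if (!is.null(x$start_s)) x$start_s[i])
}

#' Concatenate epoch sets
#' @param ... `epoch_set` objects with identical sampling rate and window
#'   length.
#' @return a single combined `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(s) nrow(s$windows) > 0, logical(1))]
  if (!length(sets)) stop("nothing to bind")
  fs <- unique(vapply(sets, `[[`, numeric(1), "fs_hz"))
  ws <- unique(vapply(sets, `[[`, numeric(1), "window_s"))
  if (length(fs) != 1 || length(ws) != 1)
    stop("epoch sets differ in sampling rate or window length")
  starts <- lapply(sets, `[[`, "start_s")
  epoch_set(do.call(rbind, lapply(sets, `[[`, "windows")),
            unlist(lapply(sets, `[[`, "labels")),
            unlist(lapply(sets, `[[`, "groups")),
            unlist(lapply(sets, `[[`, "dataset_tags")),
            fs, ws,
            if (!any(vapply(starts, is.null, logical(1)))) unlist(starts))
}
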