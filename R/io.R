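# Readers and writers: EDF signals, the two-column hypnogram/annotation text
# dialect, and the lossless epoch-set container (JSON sidecar + raw float64).

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16-bit integers over a symmetric per-channel
#' physical range (the channel's absolute maximum), one-second data records.
#' The duration must be a whole number of seconds at integer sampling rates.
#' Annotations are not embedded; write them with [write_annotations()].
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer Hz")
  fs <- round(fs)
  n <- ncol(rec$signal)
  if (n %% fs != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- n %/% fs
  ns <- nrow(rec$signal)
  pmaxs <- pmax(apply(abs(rec$signal), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 + 256 * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad(rec$subject_id, 80),
    edf_pad(rec$source_dataset, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44), edf_pad(n_rec, 8),
    edf_pad("1", 8), edf_pad(ns, 4)), con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  fld(rec$channel_names, 16)
  fld(rep("", ns), 80)                        # transducer
  fld(rep("uV", ns), 8)                       # physical dimension
  fld(sprintf("%.6g", -pmaxs), 8)
  fld(sprintf("%.6g", pmaxs), 8)
  fld(rep("-32767", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)                        # prefiltering
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  scale <- 32767 / pmaxs
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      d <- as.integer(round(rec$signal[ch, idx] * scale[ch]))
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads the selected channels (by name; EDF files list channels in file
#' order but montage order varies, so matching is by name) into a
#' [recording()]. Selected channels must share one sampling rate; a
#' mixed-rate file is handled by selecting a homogeneous subset.
#'
#' @param path EDF file path.
#' @param channels channel names to load; `NULL` loads all.
#' @return a [recording()] (without annotations).
#' @export
load_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                      # version
  subject <- rd(80)
  dataset <- rd(80)
  rd(8); rd(8)                               # date, time
  rd(8); rd(44)                              # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF file declares no channels")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))                  # samples per record
  rdv(32)
  if (is.null(channels)) channels <- labels
  sel <- match(channels, labels)
  if (anyNA(sel))
    stop("channel(s) absent: ",
         paste(channels[is.na(sel)], collapse = ", "))
  fs_sel <- spr[sel] / rec_dur
  if (length(unique(fs_sel)) != 1)
    stop("selected channels have mixed sampling rates; select a homogeneous subset")
  X <- matrix(0, length(sel), n_rec * spr[sel[1]])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      j <- match(ch, sel)
      if (!is.na(j)) {
        idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
        X[j, idx] <- pmin_[ch] + (d - dmin[ch]) * gain[ch]
      }
    }
  }
  recording(X, fs_sel[1], channel_names = labels[sel],
            subject_id = subject, source_dataset = dataset)
}

#' Write annotations as onset/duration/label text
#'
#' The dialect is a comma- or tab-separated table with a header
#' `onset_s,duration_s,label`, one row per annotated interval. Used for
#' both hypnograms (label = stage) and seizure onsets (duration 0,
#' label = `"seizure"`).
#'
#' @param onset_s,duration_s,label equal-length annotation columns.
#' @param path output path.
#' @param sep `","` or `"\t"`.
#' @return `path` invisibly.
#' @export
write_annotations <- function(onset_s, duration_s, label, path, sep = ",") {
  df <- data.frame(onset_s = onset_s, duration_s = duration_s, label = label)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a hypnogram in the annotation text dialect
#'
#' Consecutive identical stages are merged into one row (onset, duration,
#' stage); [load_hypnogram()] is its inverse.
#'
#' @param stages one stage per epoch.
#' @param path output path.
#' @param epoch_s scored epoch length (s).
#' @param sep separator.
#' @return `path` invisibly.
#' @export
write_hypnogram <- function(stages, path, epoch_s = 30, sep = ",") {
  r <- rle(as.character(stages))
  ends <- cumsum(r$lengths) * epoch_s
  write_annotations(ends - r$lengths * epoch_s, r$lengths * epoch_s,
                    r$values, path, sep = sep)
}

#' Load a hypnogram from annotation text
#'
#' Expands each (onset, duration, stage) row to repeated `epoch_s` epochs.
#' Rows must tile the time axis from 0 without gaps or overlaps; offending
#' intervals are listed in the error. Stage codes are returned as stored
#' (R&K codes map downstream through [map_rk_to_aasm()]).
#'
#' @param path annotation file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param epoch_s epoch length (s); durations must be whole multiples.
#' @return character vector, one stage per epoch.
#' @export
load_hypnogram <- function(path, dialect = c("csv", "tsv"), epoch_s = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "csv") "," else "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$onset_s), , drop = FALSE]
  expected <- c(0, cumsum(df$duration_s))[seq_len(nrow(df))]
  bad <- which(abs(df$onset_s - expected) > 1e-9)
  if (length(bad))
    stop("gapped or overlapping annotation interval(s) at onset(s): ",
         paste(df$onset_s[bad], collapse = ", "))
  if (any(abs(df$duration_s %% epoch_s) > 1e-9))
    stop("durations must be whole multiples of ", epoch_s, " s")
  rep(df$label, times = df$duration_s / epoch_s)
}

#' Load seizure onsets from annotation text
#'
#' @param path annotation file written by [write_annotations()] with
#'   label `"seizure"`.
#' @param dialect `"csv"` or `"tsv"`.
#' @return numeric vector of onset seconds.
#' @export
load_seizure_onsets <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "csv") "," else "\t",
                          stringsAsFactors = FALSE)
  sort(df$onset_s[df$label == "seizure"])
}

EPOCHSET_VERSION <- "1.0"

#' Save / load an epoch set losslessly
#'
#' The container is a JSON sidecar (`<path>.json`: metadata, labels,
#' provenance, container version) plus raw little-endian float64 windows
#' (`<path>.bin`). Round trips are bit-identical; a version mismatch is an
#' error.
#'
#' @param epochs an [epoch_set()].
#' @param path path prefix (two files are written/read: `.json`, `.bin`).
#' @return `save_epochset` returns `path` invisibly; `load_epochset` the
#'   reconstructed [epoch_set()].
#' @export
save_epochset <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  meta <- list(format = "physiotransfer/epoch_set",
               version = EPOCHSET_VERSION,
               n_windows = nrow(epochs$windows),
               n_samples = ncol(epochs$windows),
               fs_hz = epochs$fs_hz, window_s = epochs$window_s,
               labels = epochs$labels, groups = epochs$groups,
               dataset_tags = epochs$dataset_tags,
               start_s = epochs$start_s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(epochs$windows)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_epochset
#' @export
load_epochset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "physiotransfer/epoch_set")
    stop("not an epoch_set container")
  if (!identical(meta$version, EPOCHSET_VERSION))
    stop("epoch_set container version mismatch: file has ", meta$version,
         ", reader expects ", EPOCHSET_VERSION)
  n <- meta$n_windows * meta$n_samples
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  W <- matrix(v, nrow = meta$n_windows, ncol = meta$n_samples, byrow = TRUE)
  as_chr <- function(x, n) if (is.null(x) || !length(x)) character(n)
    else as.character(x)
  epoch_set(W, as_chr(meta$labels, meta$n_windows),
            as_chr(meta$groups, meta$n_windows),
            as_chr(meta$dataset_tags, meta$n_windows),
            meta$fs_hz, meta$window_s,
            if (!is.null(meta$start_s) && length(meta$start_s))
              as.numeric(meta$start_s))
}
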