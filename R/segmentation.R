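# Windowing and labeling: overlapping fixed-length windows, epileptic-state
# interval maps, sleep-stage labeling, R&K -> AASM mapping, class balancing.

#' Windowing rule
#'
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows, `0 <= overlap_s <
#'   window_s`. The step is `window_s - overlap_s`.
#' @return a `window_rule` list with derived `step_s`.
#' @export
window_rule <- function(window_s, overlap_s = 0) {
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("overlap_s must satisfy 0 <= overlap_s < window_s")
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 step_s = window_s - overlap_s),
            class = "window_rule")
}

#' Slice a single-channel recording into overlapping windows
#'
#' Window `k` (0-based) covers `[k*step_s, k*step_s + window_s)` seconds, so
#' the number of windows is `floor((L_s - window_s)/step_s) + 1` for a signal
#' of `L_s` seconds. A signal shorter than one window yields an empty set,
#' not an error. Both the window and the step must map to whole samples.
#'
#' @param rec a single-channel [recording()].
#' @param rule a [window_rule()].
#' @return a `window_set`: windows matrix (one row per window), absolute
#'   start times, sampling rate and provenance.
#' @export
slice_windows <- function(rec, rule) {
  stopifnot(inherits(rec, "recording"), inherits(rule, "window_rule"))
  if (nrow(rec$signal) != 1)
    stop("slice_windows expects a single-channel recording (apply gfp or select a channel first)")
  w <- rule$window_s * rec$fs_hz
  st <- rule$step_s * rec$fs_hz
  if (abs(w - round(w)) > 1e-9 || abs(st - round(st)) > 1e-9)
    stop("window and step must be whole numbers of samples at this rate")
  w <- round(w); st <- round(st)
  L <- ncol(rec$signal)
  n_win <- if (L < w) 0L else floor((L - w) / st) + 1L
  W <- matrix(0, n_win, w)
  x <- rec$signal[1, ]
  for (k in seq_len(n_win)) W[k, ] <- x[((k - 1) * st + 1):((k - 1) * st + w)]
  structure(list(windows = W,
                 start_s = (seq_len(n_win) - 1) * rule$step_s,
                 fs_hz = rec$fs_hz, window_s = rule$window_s,
                 subject_id = rec$subject_id,
                 source_dataset = rec$source_dataset,
                 annotations = rec$annotations),
            class = "window_set")
}

#' Epileptic state map from seizure onsets
#'
#' For each onset `T` the three preictal bands are `[T-2400, T-1800)`,
#' `[T-1800, T-1200)` and `[T-1200, T-600)` seconds (40-30, 30-20 and
#' 20-10 min before onset), clipped to `[0, duration)`. Interictal intervals
#' are the periods after the previous seizure (onset plus
#' `seizure_end_offset_s`) and at least `interictal_gap_s` (default 50 min)
#' before the next onset, minus any preictal band. The stretch before the
#' first seizure is eligible; the tail after the last seizure is not (no
#' following onset can satisfy the separation rule).
#'
#' @param seizure_onsets_s sorted onset times in seconds.
#' @param duration_s recording duration in seconds.
#' @param interictal_gap_s minimum separation from the next onset (s).
#' @param seizure_end_offset_s assumed seizure duration appended to each
#'   onset before interictal time may resume (s).
#' @return a `state_map` data.frame with columns `state`, `start_s`, `end_s`
#'   (half-open intervals; empty intervals omitted).
#' @export
build_state_map <- function(seizure_onsets_s, duration_s,
                            interictal_gap_s = 3000,
                            seizure_end_offset_s = 0) {
  on <- sort(seizure_onsets_s)
  rows <- list()
  clip <- function(lo, hi) c(max(0, lo), min(duration_s, hi))
  bands <- list(preictal_40_30 = c(-2400, -1800),
                preictal_30_20 = c(-1800, -1200),
                preictal_20_10 = c(-1200, -600))
  pre <- list()
  for (j in seq_along(on)) {
    # a time point is preictal only for the NEXT onset, so each onset's
    # bands are confined to the stretch since the previous seizure
    lo_j <- if (j == 1) 0 else on[j - 1] + seizure_end_offset_s
    for (b in names(bands)) {
      iv <- clip(max(on[j] + bands[[b]][1], lo_j),
                 max(on[j] + bands[[b]][2], lo_j))
      if (iv[2] > iv[1]) {
        rows[[length(rows) + 1]] <- data.frame(state = b, start_s = iv[1],
                                               end_s = iv[2])
        pre[[length(pre) + 1]] <- iv
      }
    }
  }
  # interictal candidates between consecutive seizures (and before the first)
  for (j in seq_along(on)) {
    lo <- if (j == 1) 0 else on[j - 1] + seizure_end_offset_s
    iv <- clip(lo, on[j] - interictal_gap_s)
    if (iv[2] <= iv[1]) next
    segs <- list(iv)
    for (p in pre) {           # subtract any overlapping preictal band
      segs <- unlist(lapply(segs, function(s) {
        if (p[2] <= s[1] || p[1] >= s[2]) return(list(s))
        out <- list()
        if (p[1] > s[1]) out <- c(out, list(c(s[1], p[1])))
        if (p[2] < s[2]) out <- c(out, list(c(p[2], s[2])))
        out
      }), recursive = FALSE)
    }
    for (s in segs)
      rows[[length(rows) + 1]] <- data.frame(state = "interictal",
                                             start_s = s[1], end_s = s[2])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(state = character(), start_s = numeric(), end_s = numeric())
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("state_map", "data.frame")
  out
}

#' Map R&K sleep-stage codes to AASM
#'
#' `W -> W`, `S1 -> N1`, `S2 -> N2`, `S3 -> N3`, `S4 -> N3`, `REM -> REM`;
#' `MOVEMENT`/`UNKNOWN` map to the drop marker `"DROP"`. AASM codes pass
#' through unchanged (the map is idempotent). Unrecognized codes are an
#' error naming the code.
#'
#' @param stage character vector of stage codes.
#' @return character vector of AASM codes (or `"DROP"`).
#' @export
map_rk_to_aasm <- function(stage) {
  map <- c(W = "W", S1 = "N1", S2 = "N2", S3 = "N3", S4 = "N3", REM = "REM",
           N1 = "N1", N2 = "N2", N3 = "N3",
           MOVEMENT = "DROP", UNKNOWN = "DROP", DROP = "DROP")
  stage <- as.character(stage)
  bad <- setdiff(unique(stage), names(map))
  if (length(bad))
    stop("unrecognized stage code(s): ", paste(bad, collapse = ", "))
  unname(map[stage])
}

#' Label windows by state interval or hypnogram containment
#'
#' A window is labeled only if it lies entirely inside one state interval
#' (seizure experiment) or entirely inside a run of consecutive 30-s epochs
#' scored with a single stage (sleep experiment); windows straddling a
#' boundary are dropped. Hypnogram stages are mapped through
#' [map_rk_to_aasm()]; `DROP` epochs never label a window.
#'
#' @param ws a `window_set` from [slice_windows()].
#' @param state_map a `state_map` from [build_state_map()], or `NULL` to use
#'   the hypnogram annotation carried by the window set.
#' @return an [epoch_set()] of the retained, labeled windows.
#' @export
label_windows <- function(ws, state_map = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(state_map)) {
    ann <- ws$annotations
    if (is.null(ann) || ann$type != "hypnogram")
      stop("no state_map given and the window set carries no hypnogram")
    stages <- map_rk_to_aasm(ann$stages)
    ep <- ann$epoch_s
    # runs of identical stage -> half-open intervals
    r <- rle(stages)
    ends <- cumsum(r$lengths) * ep
    starts <- ends - r$lengths * ep
    state_map <- data.frame(state = r$values, start_s = starts, end_s = ends)
    state_map <- state_map[state_map$state != "DROP", , drop = FALSE]
  }
  w0 <- ws$start_s
  w1 <- ws$start_s + ws$window_s
  lab <- rep(NA_character_, length(w0))
  for (i in seq_len(nrow(state_map))) {
    inside <- w0 >= state_map$start_s[i] & w1 <= state_map$end_s[i]
    lab[inside] <- state_map$state[i]
  }
  keep <- !is.na(lab)
  epoch_set(ws$windows[keep, , drop = FALSE], lab[keep],
            groups = rep(ws$subject_id, sum(keep)),
            dataset_tags = rep(ws$source_dataset, sum(keep)),
            fs_hz = ws$fs_hz, window_s = ws$window_s,
            start_s = w0[keep])
}

#' Balance class counts by seeded undersampling
#'
#' Uniform undersampling without replacement to exactly `per_state_n`
#' windows per state (default: the minimum state count). Provenance fields
#' are preserved; selection is reproducible from `seed`.
#'
#' @param epochs an [epoch_set()].
#' @param per_state_n target count per state, or `NULL` for the minimum.
#' @param seed integer seed.
#' @param states optional character vector of states that must be present;
#'   a listed state with zero windows is an error.
#' @return the balanced [epoch_set()].
#' @export
balance_states <- function(epochs, per_state_n = NULL, seed = 1,
                           states = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  cnt <- table(epochs$labels)
  if (!is.null(states)) {
    missing <- setdiff(states, names(cnt))
    if (length(missing))
      stop("state(s) with zero windows: ", paste(missing, collapse = ", "))
    cnt <- cnt[states]
  }
  if (!length(cnt)) stop("epoch set has no windows")
  if (is.null(per_state_n)) per_state_n <- min(cnt)
  if (any(cnt < per_state_n))
    stop("per_state_n exceeds the available count for: ",
         paste(names(cnt)[cnt < per_state_n], collapse = ", "))
  keep <- with_seed(seed, {
    unlist(lapply(names(cnt), function(s) {
      idx <- which(epochs$labels == s)
      sort(sample(idx, per_state_n))
    }))
  })
  subset_epochs(epochs, sort(keep))
}
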