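# Synthetic EEG/ECG generators. These emulate the statistical structure the
# downstream analysis assumes -- state-dependent band-limited oscillations over
# a 1/f background, stage-dependent cardiac rhythm -- not physiology.

#' Evaluate an expression under a temporary RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' 1/f ("pink") noise
#'
#' White Gaussian noise shaped by the standard 3-pole/3-zero pinking filter
#' (Kasdin), normalized to unit standard deviation. Draws from the current
#' RNG stream.
#'
#' @param n number of samples.
#' @return numeric vector of length `n` with sd 1.
#' @export
pink_noise <- function(n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- iir_filter(b, a, rnorm(n))
  x / sd(x)
}

#' Seizure recording scenario
#'
#' Describes a synthetic multichannel EEG recording with timestamped seizure
#' onsets. Defaults mirror a 29-channel 10-20 montage sampled at 512 Hz.
#' Each preictal band carries a band-limited oscillation with a distinct
#' center frequency and amplitude (defaults: 4, 8 and 16 Hz at relative
#' amplitudes 1, 1.5 and 2 for preictal 40-30, 30-20 and 20-10); the
#' interictal background is 1/f noise plus white noise at `snr_db`.
#'
#' @param duration_s recording length in seconds.
#' @param seizure_onsets_s strictly increasing onset times within
#'   `[0, duration_s)`.
#' @param n_channels number of EEG channels (>= 2).
#' @param fs_hz sampling rate.
#' @param seed integer seed; identical scenarios produce bit-identical signals.
#' @param state_oscillations named list mapping preictal band names to
#'   `list(freq_hz=, amp=)`; see defaults above.
#' @param snr_db pink-background to white-noise power ratio in dB.
#' @return a `seizure_scenario` list.
#' @export
seizure_scenario <- function(duration_s, seizure_onsets_s,
                             n_channels = 29, fs_hz = 512, seed = 1,
                             state_oscillations = list(
                               preictal_40_30 = list(freq_hz = 4, amp = 1.0),
                               preictal_30_20 = list(freq_hz = 8, amp = 1.5),
                               preictal_20_10 = list(freq_hz = 16, amp = 2.0)),
                             snr_db = 3) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  on <- seizure_onsets_s
  if (length(on)) {
    if (any(diff(on) <= 0)) stop("seizure onsets must be strictly increasing")
    if (any(on < 0) || any(on >= duration_s))
      stop("all onsets must lie within [0, duration_s)")
  }
  structure(list(duration_s = duration_s, seizure_onsets_s = on,
                 n_channels = n_channels, fs_hz = fs_hz, seed = seed,
                 state_oscillations = state_oscillations, snr_db = snr_db),
            class = "seizure_scenario")
}

#' Generate a synthetic multichannel seizure recording
#'
#' Every channel is an independent 1/f background plus white noise; inside
#' each preictal band (40-30, 30-20, 10-20 min before an onset) a sinusoid at
#' the band's center frequency is added with a channel-specific random gain,
#' so the oscillation survives the across-channel global field power
#' reduction as both an amplitude and a rhythm cue. Onsets closer than 40 min
#' to the start of the recording yield the flag `"truncated_preictal"` on the
#' returned recording (their early bands are clipped), not an error.
#'
#' @param scenario a [seizure_scenario()].
#' @return a [recording()] with a seizure annotation track.
#' @export
generate_seizure_recording <- function(scenario) {
  stopifnot(inherits(scenario, "seizure_scenario"))
  sc <- scenario
  n <- round(sc$duration_s * sc$fs_hz)
  tt <- (seq_len(n) - 1) / sc$fs_hz
  white_sd <- sqrt(10^(-sc$snr_db / 10))
  sig <- with_seed(sc$seed, {
    X <- matrix(0, sc$n_channels, n)
    for (ch in seq_len(sc$n_channels))
      X[ch, ] <- pink_noise(n) + rnorm(n, sd = white_sd)
    X
  })
  # add band oscillations (channel gains drawn from a separate, seeded stream
  # so background noise and gains are independently reproducible)
  offsets <- list(preictal_40_30 = c(-2400, -1800),
                  preictal_30_20 = c(-1800, -1200),
                  preictal_20_10 = c(-1200, -600))
  sig <- with_seed(sc$seed + 1L, {
    for (band in names(sc$state_oscillations)) {
      os <- sc$state_oscillations[[band]]
      gains <- rnorm(sc$n_channels)
      for (T_on in sc$seizure_onsets_s) {
        lo <- max(0, T_on + offsets[[band]][1])
        hi <- max(0, T_on + offsets[[band]][2])
        if (hi <= lo) next
        idx <- which(tt >= lo & tt < hi)
        if (!length(idx)) next
        osc <- os$amp * sin(2 * pi * os$freq_hz * tt[idx])
        sig[, idx] <- sig[, idx] + outer(gains, osc)
      }
    }
    sig
  })
  flags <- character()
  if (length(sc$seizure_onsets_s) && any(sc$seizure_onsets_s < 2400))
    flags <- "truncated_preictal"
  recording(sig, sc$fs_hz,
            channel_names = paste0("EEG", seq_len(sc$n_channels)),
            annotations = list(type = "seizure",
                               onsets_s = sc$seizure_onsets_s),
            subject_id = paste0("synth", sc$seed),
            source_dataset = "synthetic_seizure", flags = flags)
}

# Stage-dependent rhythm parameters for synthetic sleep EEG: a dominant
# oscillation (center frequency, relative amplitude) over the 1/f background.
sleep_eeg_rhythms <- list(
  W   = list(freqs = 10,          amps = 1.5),
  N1  = list(freqs = 5.5,         amps = 1.2),
  N2  = list(freqs = c(5.5, 13),  amps = c(1.2, 2.0), burst = 2), # spindles
  N3  = list(freqs = 1,           amps = 3.0),
  REM = list(freqs = c(4.5, 7.5), amps = c(0.5, 0.5))
)

# Stage-dependent heart rate (mean bpm, sd bpm across beats)
sleep_ecg_rates <- list(
  W = c(75, 5), N1 = c(70, 4), N2 = c(65, 3), N3 = c(58, 2), REM = c(72, 8)
)

#' Sleep recording scenario
#'
#' @param n_epochs number of 30-s scored epochs.
#' @param stage_labels optional stage sequence (AASM `W,N1,N2,N3,REM` or R&K
#'   `W,S1,S2,S3,S4,REM`), one per epoch; generated by [generate_hypnogram()]
#'   when `NULL`.
#' @param modality `"eeg"` (single-channel Fpz-Cz-like EEG) or `"ecg"`
#'   (single-lead ECG).
#' @param fs_hz sampling rate; defaults to 100 Hz for EEG, 256 Hz for ECG.
#' @param epoch_s scored epoch length in seconds.
#' @param seed integer seed.
#' @param snr_db signal-to-additive-noise ratio in dB; `Inf` disables noise.
#' @return a `hypnogram_scenario` list.
#' @export
hypnogram_scenario <- function(n_epochs, stage_labels = NULL,
                               modality = c("eeg", "ecg"), fs_hz = NULL,
                               epoch_s = 30, seed = 1, snr_db = 3) {
  modality <- match.arg(modality)
  if (is.null(fs_hz)) fs_hz <- if (modality == "eeg") 100 else 256
  if (is.null(stage_labels))
    stage_labels <- generate_hypnogram(n_epochs, seed = seed)
  if (length(stage_labels) != n_epochs)
    stop("stage_labels must have one entry per epoch")
  structure(list(n_epochs = n_epochs, epoch_s = epoch_s,
                 stage_labels = as.character(stage_labels),
                 modality = modality, fs_hz = fs_hz, seed = seed,
                 snr_db = snr_db),
            class = "hypnogram_scenario")
}

#' Generate a synthetic sleep recording (EEG or ECG)
#'
#' EEG epochs carry the stage's dominant rhythm (W: 10 Hz alpha; N1: 5.5 Hz
#' theta; N2: theta plus 13 Hz spindle bursts; N3: 1 Hz high-amplitude slow
#' waves; REM: mixed low-amplitude 4.5/7.5 Hz) over a 1/f background. ECG
#' epochs are a QRS-like Ricker-wavelet beat train whose per-beat rate is
#' drawn from the stage's mean +/- sd (W 75+/-5, N1 70+/-4, N2 65+/-3,
#' N3 58+/-2, REM 72+/-8 beats/min). R&K labels are accepted and stored as
#' given; an unknown stage label is an error naming the label.
#'
#' @param scenario a [hypnogram_scenario()].
#' @return a [recording()] with the hypnogram attached as annotation.
#' @export
generate_sleep_recording <- function(scenario) {
  stopifnot(inherits(scenario, "hypnogram_scenario"))
  sc <- scenario
  stages_aasm <- map_rk_to_aasm(sc$stage_labels)
  if (any(stages_aasm == "DROP"))
    stop("cannot synthesize MOVEMENT/UNKNOWN epochs")
  n_per <- round(sc$epoch_s * sc$fs_hz)
  n <- n_per * sc$n_epochs
  x <- with_seed(sc$seed, {
    if (sc$modality == "eeg") {
      noise_sd <- if (is.finite(sc$snr_db)) sqrt(10^(-sc$snr_db / 10)) else 0
      bg <- pink_noise(n) + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
      tt <- (seq_len(n_per) - 1) / sc$fs_hz
      for (e in seq_len(sc$n_epochs)) {
        p <- sleep_eeg_rhythms[[stages_aasm[e]]]
        seg <- numeric(n_per)
        for (j in seq_along(p$freqs)) {
          osc <- p$amps[j] * sin(2 * pi * p$freqs[j] * tt + runif(1, 0, 2 * pi))
          if (!is.null(p$burst) && j == p$burst) {
            # spindle bursts: 1-s gaussian envelopes every 3 s
            env <- rowSums(sapply(seq(1.5, sc$epoch_s - 1.5, by = 3),
                                  function(c0) exp(-(tt - c0)^2 / (2 * 0.25^2))))
            osc <- osc * env
          }
          seg <- seg + osc
        }
        idx <- ((e - 1) * n_per + 1):(e * n_per)
        bg[idx] <- bg[idx] + seg
      }
      bg
    } else {
      out <- numeric(n)
      # Ricker (mexican-hat) QRS template, ~24 ms characteristic width
      s_qrs <- 0.012
      tw <- seq(-0.06, 0.06, by = 1 / sc$fs_hz)
      templ <- (1 - (tw / s_qrs)^2) * exp(-tw^2 / (2 * s_qrs^2))
      half <- (length(templ) - 1) / 2
      for (e in seq_len(sc$n_epochs)) {
        r <- sleep_ecg_rates[[stages_aasm[e]]]
        t_beat <- 0.3
        while (t_beat < sc$epoch_s) {
          center <- round(((e - 1) * sc$epoch_s + t_beat) * sc$fs_hz) + 1
          idx <- (center - half):(center + half)
          keep <- idx >= 1 & idx <= n
          out[idx[keep]] <- out[idx[keep]] + templ[keep]
          bpm <- max(30, rnorm(1, r[1], r[2]))
          t_beat <- t_beat + 60 / bpm
        }
      }
      if (is.finite(sc$snr_db)) {
        # 1/f background plus white noise, as for the EEG generators
        noise_sd <- sd(out) * sqrt(10^(-sc$snr_db / 10))
        out <- out + noise_sd * (pink_noise(n) + rnorm(n)) / sqrt(2)
      }
      out
    }
  })
  recording(matrix(x, nrow = 1), sc$fs_hz,
            channel_names = if (sc$modality == "eeg") "Fpz-Cz" else "ECG",
            annotations = list(type = "hypnogram", stages = sc$stage_labels,
                               epoch_s = sc$epoch_s),
            subject_id = paste0("synth", sc$seed),
            source_dataset = paste0("synthetic_sleep_", sc$modality))
}

#' Sleep-stage transition matrix of the hypnogram generator
#'
#' First-order Markov transition probabilities over `W, N1, N2, N3, REM`;
#' diagonally dominant so stages persist over several 30-s epochs, as real
#' hypnograms do.
#'
#' @return a 5x5 row-stochastic matrix.
#' @export
hypnogram_transition_matrix <- function() {
  st <- c("W", "N1", "N2", "N3", "REM")
  P <- matrix(c(
    0.80, 0.15, 0.03, 0.01, 0.01,
    0.05, 0.70, 0.20, 0.02, 0.03,
    0.02, 0.05, 0.75, 0.12, 0.06,
    0.01, 0.02, 0.15, 0.80, 0.02,
    0.05, 0.05, 0.10, 0.02, 0.78), 5, 5, byrow = TRUE,
    dimnames = list(st, st))
  P
}

#' Generate a synthetic hypnogram
#'
#' Samples a stage sequence from the first-order Markov chain of
#' [hypnogram_transition_matrix()], starting in wake.
#'
#' @param n_epochs number of 30-s epochs (>= 1).
#' @param seed integer seed.
#' @return character vector of stages in `W, N1, N2, N3, REM`.
#' @export
generate_hypnogram <- function(n_epochs, seed = 1) {
  stopifnot(n_epochs >= 1)
  P <- hypnogram_transition_matrix()
  st <- rownames(P)
  with_seed(seed, {
    out <- character(n_epochs)
    out[1] <- "W"
    for (i in seq_len(n_epochs - 1))
      out[i + 1] <- sample(st, 1, prob = P[out[i], ])
    out
  })
}
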