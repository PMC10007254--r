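# End-to-end orchestration of the two experiments on synthetic recordings,
# plus the desk-scale benchmark builders the acceptance checks use. Real EDF
# directories can be substituted for the generators by loading recordings
# with load_edf()/load_hypnogram() and entering at the same stages.

SEIZURE_BANDS <- c("preictal_40_30", "preictal_30_20", "preictal_20_10")

#' Synthetic interictal/preictal benchmark windows
#'
#' Generates a 29-channel, 512-Hz seizure recording (onset at 3500 s of
#' 3600 s, giving full preictal bands and an interictal stretch), runs the
#' conditioning chain (detrend, 0.5-50 Hz bandpass, global field power),
#' slices 10-s windows with 8-s overlap, labels by the epileptic state map
#' and balances to `n_per_state` windows per requested state.
#'
#' @param n_per_state windows per state (at most 246 for this scenario).
#' @param states states to keep.
#' @param seed integer seed.
#' @param n_channels,snr_db generator parameters.
#' @return an [epoch_set()] with 5120-sample windows.
#' @export
synth_seizure_epochs <- function(n_per_state = 200,
                                 states = c("interictal", SEIZURE_BANDS),
                                 seed = 1, n_channels = 29, snr_db = 3) {
  sc <- seizure_scenario(duration_s = 3600, seizure_onsets_s = 3500,
                         n_channels = n_channels, seed = seed,
                         snr_db = snr_db)
  rec <- generate_seizure_recording(sc)
  rec <- detrend(rec)
  rec <- apply_filter(rec, filter_spec("bandpass", 0.5, 50))
  rec <- gfp(rec)
  ws <- slice_windows(rec, window_rule(10, 8))
  sm <- build_state_map(sc$seizure_onsets_s, sc$duration_s)
  ep <- label_windows(ws, sm)
  ep <- subset_epochs(ep, ep$labels %in% states)
  balance_states(ep, n_per_state, seed = seed, states = states)
}

#' Synthetic five-stage sleep benchmark windows
#'
#' Builds a hypnogram of shuffled 5-epoch single-stage runs (so 30-s windows
#' stepping by 7.5 s find whole runs to sit in), generates the EEG or ECG
#' recording, applies the arm's conditioning (EEG: detrend + 30-Hz lowpass;
#' ECG: detrend + 0.5-40-Hz bandpass + resampling to 100 Hz), slices 30-s
#' windows with 22.5-s overlap, labels by stage-run containment and balances
#' per stage.
#'
#' @param n_per_state windows per stage.
#' @param modality `"eeg"` or `"ecg"`.
#' @param seed integer seed.
#' @param snr_db generator noise level.
#' @return an [epoch_set()] with 3000-sample windows at 100 Hz.
#' @export
synth_sleep_epochs <- function(n_per_state = 200, modality = c("eeg", "ecg"),
                               seed = 1, snr_db = 3) {
  modality <- match.arg(modality)
  stages <- c("W", "N1", "N2", "N3", "REM")
  run_len <- 5                       # epochs per run -> 4*5-3 = 17 windows
  runs_per_stage <- ceiling(n_per_state / (4 * run_len - 3))
  labels <- with_seed(seed + 7L, {
    runs <- sample(rep(stages, runs_per_stage))
    rep(runs, each = run_len)
  })
  sc <- hypnogram_scenario(length(labels), stage_labels = labels,
                           modality = modality, seed = seed,
                           snr_db = snr_db)
  rec <- generate_sleep_recording(sc)
  rec <- detrend(rec)
  if (modality == "eeg") {
    rec <- apply_filter(rec, filter_spec("lowpass", high_hz = 30))
  } else {
    rec <- apply_filter(rec, filter_spec("bandpass", 0.5, 40))
    rec <- adapt_input(rec, 100)
  }
  ws <- slice_windows(rec, window_rule(30, 22.5))
  ep <- label_windows(ws)
  balance_states(ep, n_per_state, seed = seed, states = stages)
}

#' Experiment configuration
#'
#' Assembles one run of either experiment. Defaults are desk-sized
#' (`n_per_state = 200`, short training) so a full run finishes in minutes
#' on a CPU; scale `n_per_state`, `repeats` and `hyper$max_epochs` up for
#' larger studies.
#'
#' @param experiment `"seizure"` or `"sleep"`.
#' @param data_source only `"synthetic"` is built in; for real EDF data load
#'   recordings yourself and call the stage functions.
#' @param regime `"recordwise"`, `"subjectwise"` or `"patient_specific"`
#'   (seizure); the sleep experiment runs its `arms` instead.
#' @param freeze a [freeze_spec()] (patient-specific and transfer runs);
#'   the seizure experiment uses `first_n_layers`, the sleep experiment
#'   `named_blocks`.
#' @param hyper a [train_hyper()]; defaults per experiment (seizure: lr
#'   2e-4/min 1e-5; sleep: lr 1e-3/min 1e-4 with early-stop patience 10).
#' @param n_per_state windows per state.
#' @param repeats number of repeated runs.
#' @param seed base seed.
#' @param cv_k folds for cross-validation (10 seizure, 5 sleep).
#' @param train_folds how many folds to actually train (1 = train once with
#'   the first fold as validation; `cv_k` = full cross-validation).
#' @param arms sleep experiment arms, subset of `eeg`, `ecg`, `transfer`.
#' @param target_fraction fraction of the target-domain training windows
#'   used for transfer/fine-tuning (and its from-scratch comparator).
#' @param n_channels EEG channel count for the seizure generator.
#' @param split_ratio train fraction (0.9 seizure, 0.8 sleep).
#' @param output_dir optional directory for the run manifest and reports.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(experiment = c("seizure", "sleep"),
                              data_source = "synthetic",
                              regime = "recordwise", freeze = NULL,
                              hyper = NULL, n_per_state = 200, repeats = 1,
                              seed = 1, cv_k = NULL, train_folds = 1,
                              arms = c("eeg", "ecg", "transfer"),
                              target_fraction = 1, n_channels = 29,
                              split_ratio = NULL, output_dir = NULL) {
  experiment <- match.arg(experiment)
  if (data_source != "synthetic")
    stop("only the synthetic data source is built in")
  if (experiment == "seizure") {
    if (!regime %in% c("recordwise", "subjectwise", "patient_specific"))
      stop("invalid seizure regime: ", regime)
    if (!is.null(freeze) && freeze$mode != "first_n_layers")
      stop("the seizure experiment freezes by first_n_layers")
    if (is.null(hyper))
      hyper <- train_hyper(batch_size = 128, lr = 2e-4, min_lr = 1e-5,
                           max_epochs = 20)
    if (is.null(cv_k)) cv_k <- 10
    if (is.null(split_ratio)) split_ratio <- 0.9
  } else {
    if (!is.null(freeze) && freeze$mode != "named_blocks")
      stop("the sleep experiment freezes by named_blocks")
    if (is.null(hyper))
      hyper <- train_hyper(batch_size = 128, lr = 1e-3, min_lr = 1e-4,
                           early_stop_patience = 10, max_epochs = 20)
    if (is.null(cv_k)) cv_k <- 5
    if (is.null(split_ratio)) split_ratio <- 0.8
    arms <- match.arg(arms, several.ok = TRUE)
  }
  structure(list(experiment = experiment, data_source = data_source,
                 regime = regime, freeze = freeze, hyper = hyper,
                 n_per_state = n_per_state, repeats = repeats, seed = seed,
                 cv_k = cv_k, train_folds = train_folds, arms = arms,
                 target_fraction = target_fraction,
                 n_channels = n_channels,
                 split_ratio = split_ratio, output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields map directly onto [experiment_config()] arguments; `hyper`
#' and `freeze` sub-maps onto [train_hyper()] and [freeze_spec()].
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_experiment_config requires the yaml package")
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$hyper)) doc$hyper <- do.call(train_hyper, doc$hyper)
  if (!is.null(doc$freeze)) doc$freeze <- do.call(freeze_spec, doc$freeze)
  do.call(experiment_config, doc)
}

train_and_eval <- function(epochs, plan, spec, hyper, seed, cv_k,
                           train_folds, positive_label = NULL,
                           pretrained = NULL, fspec = NULL) {
  plan <- make_folds(plan, epochs, cv_k, seed = seed)
  levels <- sort(unique(epochs$labels))
  nets <- list()
  for (f in seq_len(train_folds)) {
    net <- if (is.null(pretrained)) build_model(spec, seed = seed + f)
      else freeze(pretrained, fspec)
    fit <- train_model(net, epochs, plan, hyper = hyper, seed = seed + f,
                       val_fold = f)
    val_acc <- tail(fit$history$val_acc, 1)
    nets[[f]] <- list(fit = fit, val_acc = val_acc)
  }
  best <- which.max(vapply(nets, `[[`, numeric(1), "val_acc"))
  net <- nets[[best]]$fit$network
  P <- predict_in_batches(net, epochs$windows[plan$test_idx, , drop = FALSE])
  pred <- net$class_levels[max.col(P)]
  list(report = eval_report(epochs$labels[plan$test_idx], pred,
                            label_order = levels,
                            positive_label = positive_label),
       history = nets[[best]]$fit$history, network = net, plan = plan)
}

#' Run the seizure experiment end-to-end on synthetic data
#'
#' Conditioning (detrend, 0.5-50 Hz bandpass, GFP), 10 s / 8 s overlap
#' windowing, state labeling and balancing, then the chosen split regime and
#' one binary interictal-vs-preictal classifier per preictal band.
#' Patient-specific runs pretrain on a source subject pool and fine-tune the
#' unfrozen layers on the target subject's windows.
#'
#' @param config an [experiment_config()] with `experiment = "seizure"`.
#' @return list with per-band repeat reports/summaries and the run
#'   `manifest`.
#' @export
run_experiment1 <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "seizure")
  spec <- seizure_model_spec()
  bands <- SEIZURE_BANDS
  out <- list()
  counts <- list()
  cache <- new.env(parent = emptyenv())
  build <- function(seed) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- synth_seizure_epochs(
        config$n_per_state, states = c("interictal", SEIZURE_BANDS),
        seed = seed, n_channels = config$n_channels)
    cache[[key]]
  }
  for (band in bands) {
    proc <- function(seed) {
      if (config$regime == "patient_specific") {
        all_src <- build(seed * 101L)
        src <- subset_epochs(all_src,
                             all_src$labels %in% c("interictal", band))
        plan_s <- split_recordwise(src, config$split_ratio, seed = seed)
        res_s <- train_and_eval(src, plan_s, spec, config$hyper, seed,
                                config$cv_k, config$train_folds,
                                positive_label = band)
        tgt_n <- max(2, round(config$n_per_state * config$target_fraction))
        tgt <- synth_seizure_epochs(tgt_n, states = c("interictal", band),
                                    seed = seed * 101L + 1L,
                                    n_channels = config$n_channels)
        plan_t <- split_recordwise(tgt, config$split_ratio, seed = seed)
        fspec <- if (is.null(config$freeze))
          freeze_spec("first_n_layers", n = 6) else config$freeze
        net <- freeze(res_s$network, fspec)
        tr <- plan_t$train_idx
        fit <- fit_network(net,
                           tgt$windows[tr, , drop = FALSE], tgt$labels[tr],
                           hyper = config$hyper, seed = seed)
        P <- predict_in_batches(fit$network,
                                tgt$windows[plan_t$test_idx, , drop = FALSE])
        pred <- fit$network$class_levels[max.col(P)]
        eval_report(tgt$labels[plan_t$test_idx], pred,
                    label_order = sort(unique(tgt$labels)),
                    positive_label = band)
      } else if (config$regime == "subjectwise") {
        all_a <- build(seed * 101L)
        a <- subset_epochs(all_a, all_a$labels %in% c("interictal", band))
        all_b <- build(seed * 101L + 1L)
        b <- subset_epochs(all_b, all_b$labels %in% c("interictal", band))
        a$dataset_tags[] <- "dataset_A"
        b$dataset_tags[] <- "dataset_B"
        b$groups[] <- paste0(b$groups, "_B")
        both <- bind_epochs(a, b)
        plan <- split_subjectwise(both, "dataset_A", "dataset_B")
        plan$seed <- seed
        res <- train_and_eval(both, plan, spec, config$hyper, seed,
                              config$cv_k, config$train_folds,
                              positive_label = band)
        res$report
      } else {
        all_ep <- build(seed * 101L)
        ep <- subset_epochs(all_ep, all_ep$labels %in% c("interictal", band))
        counts[[band]] <<- as.list(table(ep$labels))
        plan <- split_recordwise(ep, config$split_ratio, seed = seed)
        res <- train_and_eval(ep, plan, spec, config$hyper, seed,
                              config$cv_k, config$train_folds,
                              positive_label = band)
        res$report
      }
    }
    out[[band]] <- repeat_experiment(proc, config$repeats,
                                     base_seed = config$seed)
  }
  manifest <- run_manifest(config, counts)
  res <- list(bands = out, manifest = manifest)
  write_run_outputs(res, config)
  res
}

#' Run the sleep experiment end-to-end on synthetic data
#'
#' EEG arm: detrend + 30-Hz lowpass, 30 s / 22.5 s windows, AASM labels,
#' five-class model. ECG arm: detrend + 0.5-40-Hz bandpass, resampling to
#' 100 Hz, same windowing and model. Transfer arm: pretrain on the EEG
#' windows, freeze the configured blocks, fine-tune the rest on (a fraction
#' of) the ECG training windows.
#'
#' @param config an [experiment_config()] with `experiment = "sleep"`.
#' @return list with per-arm repeat reports/summaries and the run
#'   `manifest`.
#' @export
run_experiment2 <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "sleep")
  spec <- sleep_model_spec()
  fspec <- if (is.null(config$freeze))
    freeze_spec("named_blocks", blocks = "block_1") else config$freeze
  out <- list()
  for (arm in config$arms) {
    proc <- function(seed) {
      if (arm == "eeg" || arm == "ecg") {
        ep <- synth_sleep_epochs(config$n_per_state, modality = arm,
                                 seed = seed * 211L)
        plan <- split_recordwise(ep, config$split_ratio, seed = seed)
        res <- train_and_eval(ep, plan, spec, config$hyper, seed,
                              config$cv_k, config$train_folds)
        res$report
      } else {
        eeg <- synth_sleep_epochs(config$n_per_state, modality = "eeg",
                                  seed = seed * 211L)
        plan_e <- split_recordwise(eeg, config$split_ratio, seed = seed)
        res_e <- train_and_eval(eeg, plan_e, spec, config$hyper, seed,
                                config$cv_k, config$train_folds)
        ecg <- synth_sleep_epochs(config$n_per_state, modality = "ecg",
                                  seed = seed * 211L + 1L)
        plan_c <- split_recordwise(ecg, config$split_ratio, seed = seed)
        tr <- plan_c$train_idx
        if (config$target_fraction < 1) {
          keep <- with_seed(seed + 31L, {
            unlist(lapply(unique(ecg$labels[tr]), function(s) {
              idx <- tr[ecg$labels[tr] == s]
              sample(idx, max(1, round(length(idx) *
                                         config$target_fraction)))
            }))
          })
          tr <- sort(keep)
        }
        fit <- fine_tune(res_e$network,
                         subset_epochs(ecg, tr), fspec,
                         hyper = config$hyper, seed = seed)
        P <- predict_in_batches(fit$network,
                                ecg$windows[plan_c$test_idx, , drop = FALSE])
        pred <- fit$network$class_levels[max.col(P)]
        eval_report(ecg$labels[plan_c$test_idx], pred,
                    label_order = sort(unique(ecg$labels)))
      }
    }
    out[[arm]] <- repeat_experiment(proc, config$repeats,
                                    base_seed = config$seed)
  }
  manifest <- run_manifest(config, list())
  res <- list(arms = out, manifest = manifest)
  write_run_outputs(res, config)
  res
}

run_manifest <- function(config, counts) {
  list(package_version =
         as.character(utils::packageVersion("physiotransfer")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       experiment = config$experiment, regime = config$regime,
       n_per_state = config$n_per_state, repeats = config$repeats,
       seed = config$seed, cv_k = config$cv_k,
       split_ratio = config$split_ratio,
       hyper = unclass(config$hyper),
       freeze = if (!is.null(config$freeze)) unclass(config$freeze),
       window_counts = counts)
}

write_run_outputs <- function(res, config) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res$manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  groups <- if (!is.null(res$bands)) res$bands else res$arms
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    s <- groups[[g]]$summary
    s$group <- g
    s
  }))
  utils::write.csv(summ, file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(NULL)
}
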