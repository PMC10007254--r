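# Training: Adam with reduce-on-plateau and early stopping, the recordwise /
# subjectwise split regimes, stratified k-fold construction, and repeat
# aggregation.

#' Training hyperparameters
#'
#' Defaults follow the seizure-prediction configuration (Adam, batch 128,
#' learning rate 2e-4 with reduce-on-plateau floor 1e-5); the sleep-staging
#' configuration uses `lr = 1e-3`, `min_lr = 1e-4` and early stopping with
#' patience 10.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param batch_size minibatch size.
#' @param lr initial learning rate; must exceed `min_lr`.
#' @param min_lr floor for reduce-on-plateau.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping, or `NULL` to disable.
#' @param plateau_factor,plateau_patience reduce-on-plateau multiplier and
#'   patience (epochs).
#' @param max_epochs maximum training epochs.
#' @param stop_at_acc optional validation-accuracy threshold at which
#'   training stops early (the target is reached; useful for learnability
#'   checks).
#' @return a `train_hyper` list.
#' @export
train_hyper <- function(optimizer = "adam", batch_size = 128, lr = 2e-4,
                        min_lr = 1e-5, early_stop_patience = NULL,
                        plateau_factor = 0.5, plateau_patience = 5,
                        max_epochs = 100, stop_at_acc = NULL) {
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  if (min_lr >= lr) stop("min_lr must be below lr")
  structure(list(optimizer = optimizer, batch_size = batch_size, lr = lr,
                 min_lr = min_lr, early_stop_patience = early_stop_patience,
                 plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 max_epochs = max_epochs, stop_at_acc = stop_at_acc),
            class = "train_hyper")
}

onehot <- function(y, levels) {
  Y <- matrix(0, length(y), length(levels))
  j <- match(y, levels)
  if (anyNA(j)) stop("labels outside the class levels: ",
                     paste(unique(y[is.na(j)]), collapse = ", "))
  Y[cbind(seq_along(y), j)] <- 1
  Y
}

predict_in_batches <- function(net, X, chunk = 256) {
  n <- nrow(X)
  out <- NULL
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    P <- network_forward(net, X[s:e, , drop = FALSE], train = FALSE)$probs
    out <- rbind(out, P)
  }
  out
}

eval_network <- function(net, X, y, levels) {
  P <- predict_in_batches(net, X)
  j <- match(y, levels)
  p_true <- P[cbind(seq_len(nrow(P)), j)]
  list(loss = -mean(log(pmax(p_true, 1e-12))),
       acc = mean(max.col(P) == j))
}

adam_step <- function(net, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    if (nm %in% net$frozen) next
    g <- grads[[nm]]
    for (tn in names(g)) {
      key <- paste0(nm, ".", tn)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- 0 * g[[tn]]
        state$v[[key]] <- 0 * g[[tn]]
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g[[tn]]
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g[[tn]]^2
      net$params[[nm]][[tn]] <- net$params[[nm]][[tn]] -
        lr * (state$m[[key]] / c1) / (sqrt(state$v[[key]] / c2) + eps)
    }
  }
  list(net = net, state = state)
}

#' Fit a network on labeled windows
#'
#' Minibatch Adam on softmax cross-entropy. The learning rate halves after
#' `plateau_patience` epochs without validation-loss improvement, never below
#' `min_lr`; optional early stopping (patience on validation loss) restores
#' the best-validation weights. Frozen layers receive no updates and frozen
#' batch-norm layers run on stored statistics throughout. Fully reproducible
#' from `seed` (single-threaded).
#'
#' @param net a `cnn_network` (possibly carrying a freeze mask).
#' @param x windows matrix, one row per window.
#' @param y labels, one per window.
#' @param validation optional `list(x =, y =)` held-out windows.
#' @param hyper a [train_hyper()].
#' @param seed integer seed controlling shuffling.
#' @param class_levels label order defining output columns; defaults to the
#'   sorted unique training labels.
#' @param verbose print per-epoch progress?
#' @return list with the fitted `network` and a per-epoch `history`
#'   data.frame (epoch, lr, train_loss, train_acc, val_loss, val_acc).
#' @export
fit_network <- function(net, x, y, validation = NULL,
                        hyper = train_hyper(), seed = 1,
                        class_levels = NULL, verbose = FALSE) {
  if (is.null(class_levels))
    class_levels <- if (!is.null(net$class_levels)) net$class_levels
      else sort(unique(as.character(y)))
  if (length(class_levels) != net$spec$n_classes)
    stop("need exactly ", net$spec$n_classes, " class levels")
  net$class_levels <- class_levels
  y <- as.character(y)
  n <- nrow(x)
  state <- list(t = 0, m = list(), v = list())
  lr <- hyper$lr
  hist <- NULL
  best_loss <- Inf
  best_params <- net$params
  plateau_wait <- 0
  stop_wait <- 0
  with_seed(seed, {
    for (ep in seq_len(hyper$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (s in seq(1, n, by = hyper$batch_size)) {
        idx <- ord[s:min(n, s + hyper$batch_size - 1)]
        xb <- x[idx, , drop = FALSE]
        yb <- onehot(y[idx], class_levels)
        fwd <- network_forward(net, xb, train = TRUE)
        p_true <- rowSums(fwd$probs * yb)
        loss <- -mean(log(pmax(p_true, 1e-12)))
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(fwd$probs) ==
                                         max.col(yb))
        grads <- network_backward(net, fwd, yb)
        upd <- adam_step(net, grads, state, lr)
        net <- upd$net
        state <- upd$state
        net <- bn_update_running(net, fwd)
      }
      val <- if (!is.null(validation))
        eval_network(net, validation$x, as.character(validation$y),
                     class_levels)
      else list(loss = NA_real_, acc = NA_real_)
      monitor <- if (!is.null(validation)) val$loss else ep_loss / n
      hist <- rbind(hist, data.frame(
        epoch = ep, lr = lr, train_loss = ep_loss / n,
        train_acc = ep_correct / n, val_loss = val$loss, val_acc = val$acc))
      if (verbose)
        message(sprintf("epoch %d lr %.2g loss %.4f acc %.3f val %.4f/%.3f",
                        ep, lr, ep_loss / n, ep_correct / n, val$loss,
                        val$acc))
      if (monitor < best_loss - 1e-8) {
        best_loss <- monitor
        best_params <- net$params
        plateau_wait <- 0
        stop_wait <- 0
      } else {
        plateau_wait <- plateau_wait + 1
        stop_wait <- stop_wait + 1
      }
      if (!is.null(hyper$stop_at_acc) && !is.null(validation) &&
          isTRUE(val$acc >= hyper$stop_at_acc)) break
      if (!is.null(hyper$early_stop_patience) &&
          stop_wait >= hyper$early_stop_patience) break
      if (plateau_wait >= hyper$plateau_patience && lr > hyper$min_lr) {
        lr <- max(hyper$min_lr, lr * hyper$plateau_factor)
        plateau_wait <- 0
      }
    }
  })
  if (!is.null(hyper$early_stop_patience)) net$params <- best_params
  net <- recalibrate_bn(net, x, hyper$batch_size)
  list(network = net, history = hist)
}

#' Train on a split plan
#'
#' Convenience wrapper over [fit_network()]: trains on the plan's training
#' indices with one fold (default the first) held out for validation.
#'
#' @param net a `cnn_network`.
#' @param epochs an [epoch_set()].
#' @param plan a `split_plan` (with folds for validation, see
#'   [make_folds()]).
#' @param hyper a [train_hyper()].
#' @param seed integer seed.
#' @param val_fold which fold to hold out (ignored when the plan has none).
#' @return as [fit_network()].
#' @export
train_model <- function(net, epochs, plan, hyper = train_hyper(), seed = 1,
                        val_fold = 1) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(plan, "split_plan"))
  tr <- plan$train_idx
  validation <- NULL
  if (!is.null(plan$folds)) {
    hold <- plan$folds[[val_fold]]
    tr <- setdiff(tr, hold)
    validation <- list(x = epochs$windows[hold, , drop = FALSE],
                       y = epochs$labels[hold])
  }
  fit_network(net, epochs$windows[tr, , drop = FALSE], epochs$labels[tr],
              validation = validation, hyper = hyper, seed = seed)
}

#' Recordwise (pooled, stratified) train/test split
#'
#' Windows are pooled over subjects and split at random within each state:
#' `floor(ratio * n)` to training, the remainder to test. Subject identity
#' deliberately leaks across the sides (that is what a recordwise split is).
#'
#' @param epochs an [epoch_set()].
#' @param ratio training fraction in (0, 1); default 0.9.
#' @param seed integer seed.
#' @return a `split_plan` with disjoint `train_idx`/`test_idx` covering all
#'   windows.
#' @export
split_recordwise <- function(epochs, ratio = 0.9, seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  cnt <- table(epochs$labels)
  if (any(cnt < 2))
    stop("state(s) with fewer than 2 windows: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  train_idx <- with_seed(seed, {
    unlist(lapply(names(cnt), function(s) {
      idx <- which(epochs$labels == s)
      sample(idx, floor(ratio * length(idx)))
    }))
  })
  train_idx <- sort(train_idx)
  structure(list(regime = "recordwise", train_idx = train_idx,
                 test_idx = setdiff(seq_along(epochs$labels), train_idx),
                 folds = NULL, repeat_index = 1L, seed = seed),
            class = "split_plan")
}

#' Subjectwise (cross-dataset) split
#'
#' Membership is decided solely by the dataset tag; any subject appearing
#' under both tags is an integrity violation and an error.
#'
#' @param epochs an [epoch_set()].
#' @param train_dataset_tag,test_dataset_tag tags selecting the two sides.
#' @return a `split_plan`.
#' @export
split_subjectwise <- function(epochs, train_dataset_tag, test_dataset_tag) {
  stopifnot(inherits(epochs, "epoch_set"))
  for (tag in c(train_dataset_tag, test_dataset_tag))
    if (!tag %in% epochs$dataset_tags) stop("dataset tag not present: ", tag)
  tr <- which(epochs$dataset_tags == train_dataset_tag)
  te <- which(epochs$dataset_tags == test_dataset_tag)
  shared <- intersect(unique(epochs$groups[tr]), unique(epochs$groups[te]))
  if (length(shared))
    stop("subject(s) present in both datasets: ",
         paste(shared, collapse = ", "))
  structure(list(regime = "subjectwise", train_idx = tr, test_idx = te,
                 folds = NULL, repeat_index = 1L, seed = NA_integer_),
            class = "split_plan")
}

#' Stratified k-fold assignment over the training set
#'
#' Deals each state's training windows round-robin into `k` near-equal
#' folds, so per-state proportions in every fold are within one window of
#' the global proportion. Every training window lands in exactly one fold;
#' test windows never do.
#'
#' @param plan a `split_plan`.
#' @param epochs the [epoch_set()] the plan indexes.
#' @param k number of folds (>= 2).
#' @param seed integer seed (defaults to the plan's).
#' @return the plan with a `folds` list of index vectors.
#' @export
make_folds <- function(plan, epochs, k, seed = NULL) {
  stopifnot(inherits(plan, "split_plan"), k >= 2)
  if (length(plan$train_idx) < k) stop("training set smaller than k")
  if (is.null(seed)) seed <- if (is.na(plan$seed)) 1L else plan$seed
  labs <- epochs$labels[plan$train_idx]
  folds <- with_seed(seed, {
    f <- vector("list", k)
    for (s in unique(labs)) {
      idx <- sample(plan$train_idx[labs == s])
      for (i in seq_along(idx)) {
        j <- (i - 1) %% k + 1
        f[[j]] <- c(f[[j]], idx[i])
      }
    }
    lapply(f, sort)
  })
  plan$folds <- folds
  plan
}

#' Repeat a seeded experiment and aggregate
#'
#' Runs `procedure(seed)` for seeds `base_seed, base_seed + 1, ...` and
#' aggregates the returned evaluation reports as mean and standard deviation
#' per metric.
#'
#' @param procedure function of one integer seed returning an `eval_report`.
#' @param n_repeats number of repeats (>= 1).
#' @param base_seed first seed.
#' @return list with `reports` (one per repeat) and `summary` (see
#'   [aggregate_reports()]).
#' @export
repeat_experiment <- function(procedure, n_repeats, base_seed = 1) {
  stopifnot(n_repeats >= 1)
  reports <- lapply(seq_len(n_repeats) - 1L, function(r) {
    rep <- procedure(base_seed + r)
    rep$repeat_index <- r + 1L
    rep
  })
  list(reports = reports, summary = aggregate_reports(reports))
}
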