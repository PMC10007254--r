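# Split regimes, fold construction, the training loop, repeat aggregation.

test_that("recordwise split reproduces the stratified 90:10 constants", {
  ep <- label_only_epochs(c(interictal = 198, preictal_20_10 = 198))
  plan <- split_recordwise(ep, 0.9, seed = 1)
  for (s in unique(ep$labels)) {
    expect_equal(sum(ep$labels[plan$train_idx] == s), 178)
    expect_equal(sum(ep$labels[plan$test_idx] == s), 20)
  }
  expect_length(intersect(plan$train_idx, plan$test_idx), 0)
  expect_setequal(c(plan$train_idx, plan$test_idx),
                  seq_along(ep$labels))
  expect_error(split_recordwise(label_only_epochs(c(a = 1, b = 50))),
               "fewer than 2")
  expect_error(split_recordwise(ep, 1.2), "ratio")
})

test_that("an 80:20 split of 16,000 windows per state trains 12,800", {
  ep <- label_only_epochs(c(W = 16000, N2 = 16000))
  plan <- split_recordwise(ep, 0.8, seed = 2)
  expect_equal(sum(ep$labels[plan$train_idx] == "W"), 12800)
  expect_equal(sum(ep$labels[plan$test_idx] == "W"), 3200)
})

test_that("subjectwise split follows dataset tags and rejects leakage", {
  ep <- label_only_epochs(c(a = 40, b = 40),
                          groups = rep(c("s1", "s2"), 40),
                          tags = rep(c("siena", "zenodo"), each = 40))
  ep$groups <- c(rep("s1", 40), rep("s2", 40))
  plan <- split_subjectwise(ep, "siena", "zenodo")
  expect_equal(sort(plan$train_idx), 1:40)
  expect_equal(sort(plan$test_idx), 41:80)
  expect_error(split_subjectwise(ep, "siena", "missing"), "not present")
  ep_bad <- ep
  ep_bad$groups[] <- "shared_subject"
  expect_error(split_subjectwise(ep_bad, "siena", "zenodo"),
               "shared_subject")
})

test_that("folds are stratified, near-equal and partition the training set", {
  ep <- label_only_epochs(c(x = 60, y = 40))
  plan <- split_recordwise(ep, 0.9, seed = 3)   # 54 + 36 = 90 train
  plan <- make_folds(plan, ep, 10)
  sizes <- lengths(plan$folds)
  expect_equal(sum(sizes), length(plan$train_idx))
  expect_lte(diff(range(sizes)), 2)  # within one window per state
  all_fold <- unlist(plan$folds)
  expect_setequal(all_fold, plan$train_idx)
  expect_false(any(duplicated(all_fold)))
  # no test window in any fold; per-state proportions within one window
  expect_length(intersect(all_fold, plan$test_idx), 0)
  glob <- sum(ep$labels[plan$train_idx] == "x") / length(plan$train_idx)
  for (f in plan$folds) {
    expect_lte(abs(sum(ep$labels[f] == "x") - glob * length(f)), 1)
  }
  expect_error(make_folds(plan, ep, 1), "k >= 2")
})

test_that("training is deterministic and respects the learning-rate floor", {
  ep <- tiny_epochs(24, seed = 5)
  hy <- train_hyper(batch_size = 16, lr = 5e-3, min_lr = 1e-3,
                    plateau_patience = 1, max_epochs = 8)
  f1 <- fit_network(build_model(tiny_model_spec(n_classes = 2), seed = 3),
                    ep$windows, ep$labels, hyper = hy, seed = 9)
  f2 <- fit_network(build_model(tiny_model_spec(n_classes = 2), seed = 3),
                    ep$windows, ep$labels, hyper = hy, seed = 9)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$history, f2$history)
  expect_true(all(f1$history$lr >= hy$min_lr))
  expect_true(all(is.finite(f1$history$train_loss)))
})

test_that("a separable two-class problem is learned quickly", {
  ep <- tiny_epochs(30, seed = 6)
  val <- tiny_epochs(15, seed = 7)
  hy <- train_hyper(batch_size = 16, lr = 3e-3, min_lr = 1e-4,
                    max_epochs = 25, stop_at_acc = 0.95)
  fit <- fit_network(build_model(tiny_model_spec(n_classes = 2), seed = 1),
                     ep$windows, ep$labels,
                     validation = list(x = val$windows, y = val$labels),
                     hyper = hy, seed = 1)
  net <- fit$network
  P <- predict(net, val$windows)
  expect_gte(mean(net$class_levels[max.col(P)] == val$labels), 0.95)
})

test_that("train_model wraps plans: held-out fold validates, test untouched", {
  ep <- tiny_epochs(20, seed = 8)
  plan <- make_folds(split_recordwise(ep, 0.9, seed = 1), ep, 3)
  hy <- train_hyper(batch_size = 16, lr = 3e-3, min_lr = 1e-4,
                    max_epochs = 2)
  fit <- train_model(build_model(tiny_model_spec(n_classes = 2), seed = 1),
                     ep, plan, hyper = hy, seed = 1)
  expect_false(any(is.na(fit$history$val_acc)))
  expect_equal(nrow(fit$history), 2)
})

test_that("repeat aggregation reports mean and sample sd per metric", {
  # two reports with accuracy 0.9 and 1.0
  r1 <- eval_report(c(rep("a", 10), rep("b", 10)),
                    c(rep("a", 9), "b", rep("b", 9), "a"), c("a", "b"),
                    positive_label = "a")
  r2 <- eval_report(rep(c("a", "b"), each = 10), rep(c("a", "b"), each = 10),
                    c("a", "b"), positive_label = "a")
  agg <- aggregate_reports(list(r1, r2))
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, 0.95)
  expect_equal(acc$sd, sd(c(0.9, 1.0)))
  # single report: sd 0 and flagged
  agg1 <- aggregate_reports(list(r1))
  expect_true(all(agg1$sd == 0))
  expect_true(attr(agg1, "single_report"))
  # repeat_experiment aggregates identical runs with zero spread
  out <- repeat_experiment(function(seed) r2, n_repeats = 3, base_seed = 1)
  expect_length(out$reports, 3)
  s <- out$summary
  expect_equal(s$sd[s$metric == "accuracy"], 0)
  expect_equal(s$mean[s$metric == "accuracy"], 1)
})
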