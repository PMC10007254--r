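# Architecture specs, closed-form shape inference, parameter accounting,
# network construction, gradient correctness.

test_that("seizure architecture matches its printed layout", {
  spec <- seizure_model_spec()
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv1d"), 4)
  expect_equal(sum(kinds == "batch_norm"), 4)
  expect_equal(sum(kinds == "max_pool1d"), 4)
  expect_equal(sum(kinds == "global_avg_pool"), 1)
  # 12 pre-global feature layers
  expect_length(physiotransfer:::feature_layer_names(spec$layers), 12)
  last <- spec$layers[[length(spec$layers)]]
  expect_equal(last$units, 2)
  sh <- infer_shapes(spec)
  expect_equal(sh$length[sh$kind %in% c("conv1d", "max_pool1d")],
               c(2556, 2554, 1273, 1271, 631, 629, 620, 618))
  expect_equal(sh$channels[sh$name == "global_average_pooling1d"], 128)
  expect_equal(sh$channels[sh$kind == "dense"], c(256, 128, 2))
})

test_that("sleep architecture matches its printed layout and blocks", {
  spec <- sleep_model_spec()
  expect_named(spec$block_boundaries, c("block_1", "block_2", "block_3"))
  # block_1: two conv, two BN, one pooling layer
  b1 <- spec$block_boundaries$block_1
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  names(kinds) <- vapply(spec$layers, `[[`, character(1), "name")
  expect_equal(as.vector(table(kinds[b1])[c("conv1d", "batch_norm",
                                            "avg_pool1d")]),
               c(2L, 2L, 1L))
  last <- spec$layers[[length(spec$layers)]]
  expect_equal(last$units, 5)
  sh <- infer_shapes(spec)
  expect_equal(sh$length[sh$kind %in% c("conv1d", "avg_pool1d")],
               c(2996, 2992, 1496, 1492, 1488, 744, 740))
  expect_equal(sh$channels[sh$kind == "dense"], c(32, 5))
})

test_that("shape inference rejects over-deep stacks by layer name", {
  spec <- model_spec(list(
    layer_spec("conv1d_1", "conv1d", filter_size = 30, n_filters = 2,
               stride = 4),
    layer_spec("pool_big", "max_pool1d", filter_size = 10, stride = 1),
    layer_spec("dense_1", "dense", units = 2, activation = "softmax")),
    input_len = 35, n_classes = 2)
  expect_error(infer_shapes(spec), "pool_big")
})

test_that("model specs survive JSON serialization", {
  for (spec in list(seizure_model_spec(), sleep_model_spec())) {
    path <- tempfile(fileext = ".json")
    write_model_spec(spec, path)
    spec2 <- read_model_spec(path)
    expect_equal(infer_shapes(spec2), infer_shapes(spec))
    expect_equal(spec2$block_boundaries, spec$block_boundaries)
    expect_equal(count_parameters(spec2), count_parameters(spec))
  }
})

test_that("parameter counts match a per-tensor enumeration of the network", {
  for (spec in list(tiny_model_spec(), seizure_model_spec(),
                    sleep_model_spec())) {
    net <- build_model(spec, seed = 1)
    # oracle: count every learnable tensor element actually allocated
    oracle <- sum(vapply(names(net$params), function(nm) {
      p <- net$params[[nm]]
      sum(vapply(p[names(p) %in% c("W", "b", "gamma", "beta")], length,
                 numeric(1)))
    }, numeric(1)))
    cnt <- count_parameters(spec)
    expect_equal(unname(cnt["total"]), oracle)
    expect_equal(unname(cnt["trainable"]), oracle)
  }
})

test_that("trainable counts exclude frozen layers and stay monotone", {
  spec <- seizure_model_spec()
  feat <- physiotransfer:::feature_layer_names(spec$layers)
  cnt_all <- count_parameters(spec, feat)
  # with every feature layer frozen only the dense stack remains trainable
  net <- build_model(spec, seed = 1)
  dense_only <- sum(vapply(grep("^dense", names(net$params), value = TRUE),
                           function(nm) length(net$params[[nm]]$W) +
                             length(net$params[[nm]]$b), numeric(1)))
  expect_equal(unname(cnt_all["trainable"]), dense_only)
  tr <- vapply(c(0, 3, 6, 9, 12), function(n)
    unname(count_parameters(spec, head(feat, n))["trainable"]), numeric(1))
  expect_true(all(diff(tr) < 0))
  expect_error(count_parameters(spec, "no_such_layer"), "no_such_layer")
})

test_that("built networks are seeded and runtime shapes equal closed form", {
  for (spec in list(seizure_model_spec(), sleep_model_spec())) {
    n1 <- build_model(spec, seed = 7)
    n2 <- build_model(spec, seed = 7)
    expect_identical(n1$params, n2$params)
    n3 <- build_model(spec, seed = 8)
    expect_false(identical(n1$params, n3$params))
    probe <- network_probe_shapes(n1)
    sh <- infer_shapes(spec)
    expect_equal(probe$length, sh$length)
    expect_equal(probe$channels, sh$channels)
  }
})

test_that("softmax outputs are row-stochastic", {
  net <- build_model(tiny_model_spec(), seed = 2)
  set.seed(1)
  P <- network_forward(net, matrix(rnorm(6 * 40), 6, 40))$probs
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("backward gradients match central finite differences", {
  spec <- tiny_model_spec()
  net <- build_model(spec, seed = 1)
  set.seed(4)
  X <- matrix(rnorm(5 * 40), 5, 40)
  Y <- diag(3)[c(1, 2, 3, 1, 2), ]
  lossfun <- function(nn)
    -mean(log(rowSums(network_forward(nn, X, train = TRUE)$probs * Y)))
  fwd <- network_forward(net, X, train = TRUE)
  gr <- network_backward(net, fwd, Y)
  eps <- 1e-6
  for (nm in names(gr)) for (tn in names(gr[[nm]])) {
    G <- gr[[nm]][[tn]]
    for (i in sample(length(G), min(4, length(G)))) {
      np <- net; np$params[[nm]][[tn]][i] <- np$params[[nm]][[tn]][i] + eps
      nm2 <- net; nm2$params[[nm]][[tn]][i] <- nm2$params[[nm]][[tn]][i] - eps
      num <- (lossfun(np) - lossfun(nm2)) / (2 * eps)
      expect_lt(abs(num - G[i]) / max(1e-4, abs(num) + abs(G[i])), 1e-3)
    }
  }
})
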