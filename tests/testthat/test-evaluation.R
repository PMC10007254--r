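# Metrics against brute-force and hand-computed oracles.

test_that("confusion matrices tally true/predicted pairs", {
  M <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(M), rbind(c(2, 0), c(0, 1)))
  M1 <- confusion_matrix("a", "b", c("a", "b"))
  expect_equal(sum(M1), 1)
  expect_equal(M1["a", "b"], 1)
  set.seed(1)
  y <- sample(c("x", "y", "z"), 200, replace = TRUE)
  p <- sample(c("x", "y", "z"), 200, replace = TRUE)
  M2 <- confusion_matrix(y, p, c("x", "y", "z"))
  for (i in c("x", "y", "z")) for (j in c("x", "y", "z"))
    expect_equal(M2[i, j], sum(y == i & p == j))
  expect_error(confusion_matrix("a", "q", c("a", "b")), "q")
  expect_error(confusion_matrix(c("a", "a"), "a", c("a")), "equal length")
})

test_that("binary metrics follow their definitions", {
  M <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE,
              dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- binary_metrics(M, "pos")
  expect_equal(unname(m), c(0.85, 0.9, 0.8))
  perfect <- matrix(c(5, 0, 0, 5), 2, 2,
                    dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_equal(unname(binary_metrics(perfect, "pos")), c(1, 1, 1))
  # zero denominator -> NA, not 0
  no_neg <- matrix(c(5, 0, 0, 0), 2, 2,
                   dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_true(is.na(binary_metrics(no_neg, "pos")["specificity"]))
  # random case against an independent per-sample count
  set.seed(2)
  y <- sample(c("pos", "neg"), 100, replace = TRUE)
  p <- sample(c("pos", "neg"), 100, replace = TRUE)
  m2 <- binary_metrics(confusion_matrix(y, p, c("pos", "neg")), "pos")
  expect_equal(unname(m2["accuracy"]), mean(y == p))
  expect_equal(unname(m2["sensitivity"]),
               sum(y == "pos" & p == "pos") / sum(y == "pos"))
  expect_equal(unname(m2["specificity"]),
               sum(y == "neg" & p == "neg") / sum(y == "neg"))
})

test_that("Cohen's kappa matches the hand formula", {
  perfect <- diag(c(10, 15, 5))
  expect_equal(cohen_kappa(perfect), 1)
  chance <- matrix(25, 2, 2)
  expect_equal(cohen_kappa(chance), 0)
  M <- matrix(c(22, 7, 1, 9, 30, 6, 2, 4, 19), 3, 3, byrow = TRUE)
  n <- sum(M)
  po <- sum(diag(M)) / n
  pe <- sum(rowSums(M) * colSums(M)) / n^2
  expect_equal(cohen_kappa(M), (po - pe) / (1 - pe))
  expect_gte(cohen_kappa(M), -1)
  expect_lte(cohen_kappa(M), 1)
  # degenerate single-class table -> NA marker
  expect_true(is.na(cohen_kappa(matrix(c(10, 0, 0, 0), 2, 2))))
})

test_that("macro F1 averages per-class F1 and handles empty classes", {
  perfect <- diag(c(4, 4, 4))
  expect_equal(as.numeric(f1_macro(perfect)), 1)
  # one class never predicted contributes F1 = 0
  M <- matrix(c(5, 0, 0, 5, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  M[3, 1] <- 4   # class 3 present but always predicted as 1
  f <- f1_macro(M)
  percls <- numeric(3)
  for (k in 1:3) {
    tp <- M[k, k]
    p <- if (sum(M[, k]) == 0) 0 else tp / sum(M[, k])
    r <- tp / sum(M[k, ])
    percls[k] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  expect_equal(as.numeric(f), mean(percls))
  # zero-support class excluded and reported
  M2 <- matrix(c(3, 1, 0, 1, 3, 0, 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  f2 <- f1_macro(M2)
  expect_equal(attr(f2, "excluded"), "c")
  expect_equal(as.numeric(f2), mean(c(0.75, 0.75)))
})

test_that("report accuracy equals direct per-sample agreement", {
  set.seed(3)
  y <- sample(c("W", "N1", "N2", "N3", "REM"), 150, replace = TRUE)
  p <- ifelse(runif(150) < 0.7, y,
              sample(c("W", "N1", "N2", "N3", "REM"), 150, replace = TRUE))
  rep <- eval_report(y, p, c("W", "N1", "N2", "N3", "REM"))
  expect_equal(rep$accuracy, mean(y == p))
  expect_equal(sum(rep$confusion), 150)
  expect_gte(rep$kappa, -1)
  expect_lte(rep$kappa, 1)
})
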