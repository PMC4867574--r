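test_that("round error is the weighted misclassification mass", {
  n <- 10L
  D <- rep(1 / n, n)
  labels <- rep(c(1L, -1L), 5)
  expect_equal(round_error(labels, labels, D), 0)
  half_wrong <- c(labels[1:5], -labels[6:10])
  expect_equal(round_error(half_wrong, labels, D), 0.5)
  expect_error(round_error(labels, labels, rep(0.3, n)), "sum to 1")

  # uniform weights over 19216 training windows, 248 misclassified
  N <- 19216L
  lab <- rep(1L, N)
  pred <- lab; pred[1:248] <- -1L
  e1 <- round_error(pred, lab, rep(1 / N, N))
  expect_equal(round(e1, 3), 0.013)
})

test_that("classifier weight follows alpha = 0.5*log((1-e)/e)", {
  expect_equal(round_alpha(0.5), 0)
  expect_equal(round_alpha(0.3533), 0.3023, tolerance = 5e-4 / 0.3023)
  expect_equal(round_alpha(0.4337), 0.1334, tolerance = 5e-4 / 0.1334)
  expect_error(round_alpha(0), "strictly inside")
  expect_error(round_alpha(1), "strictly inside")

  # antisymmetry about chance, strictly decreasing
  es <- seq(0.05, 0.95, by = 0.05)
  expect_equal(round_alpha(es), -round_alpha(1 - es))
  expect_true(all(diff(round_alpha(es)) < 0))
})

test_that("weight updates rescale and renormalize exactly", {
  D <- c(0.5, 0.5)
  labels <- c(1L, 1L); pred <- c(1L, -1L)
  D2 <- update_weights(D, 0.5 * log(3), pred, labels)
  expect_equal(D2, c(0.25, 0.75))

  # all-correct predictions leave D unchanged
  expect_equal(update_weights(D, 1.7, labels, labels), D)

  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    D <- runif(n); D <- D / sum(D)
    labels <- sample(c(-1L, 1L), n, replace = TRUE)
    pred <- sample(c(-1L, 1L), n, replace = TRUE)
    D2 <- update_weights(D, runif(1, -1, 2), pred, labels)
    expect_equal(sum(D2), 1, tolerance = 1e-12)
    expect_true(all(D2 >= 0))
  }
})

test_that("ensemble scoring equals a brute-force weighted-probability oracle", {
  set.seed(14)
  for (rounds in c(1, 3, 8)) {
    alpha <- runif(rounds, 0.1, 2)
    probs <- matrix(runif(rounds * 12), nrow = rounds)
    got <- mirstart:::.combine_round_probs(alpha, probs)
    oracle <- numeric(12)
    for (j in 1:12) {
      s <- 0
      for (m in seq_len(rounds)) s <- s + alpha[m] * probs[m, j]
      oracle[j] <- s
    }
    expect_equal(unname(got), oracle)
  }
})

test_that("an RBF round separates linearly separable and XOR toys", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60, -2, 0.3), ncol = 2),
             matrix(rnorm(60, 2, 0.3), ncol = 2))
  labels <- rep(c(-1L, 1L), each = 30)
  rd <- train_round(x, labels, grid_C = 2, grid_g = 0.5)
  expect_equal(mean(mirstart:::.round_predict(rd, x) == labels), 1)

  # XOR pattern: no linear rule exceeds 0.75 on the 4 corner points
  corners <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  xor_lab <- c(-1L, 1L, 1L, -1L)
  best_linear <- 0
  for (theta in seq(0, 2 * pi, length.out = 72)) {
    w <- c(cos(theta), sin(theta))
    for (b in seq(-2, 2, by = 0.05)) {
      acc <- mean(sign(corners %*% w + b) == xor_lab)
      best_linear <- max(best_linear, acc)
    }
  }
  expect_lte(best_linear, 0.75)

  xx <- corners[rep(1:4, each = 15), ] + matrix(rnorm(120, 0, 0.05),
                                                ncol = 2)
  ll <- rep(xor_lab, each = 15)
  rd2 <- train_round(xx, ll, grid_C = 2, grid_g = c(0.5, 2))
  expect_gt(mean(mirstart:::.round_predict(rd2, xx) == ll), 0.9)

  expect_error(train_round(x, rep(1L, nrow(x))), "single class")
})

test_that("calibrated probabilities are in [0,1] and rank with decisions", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, -1, 0.5), ncol = 2),
             matrix(rnorm(40, 1, 0.5), ncol = 2))
  labels <- rep(c(-1L, 1L), each = 20)
  rd <- train_round(x, labels, grid_C = 2, grid_g = 0.5)
  p <- mirstart:::.round_prob(rd, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[labels == 1L]), mean(p[labels == -1L]))
})

test_that("boosted training logs non-decreasing subset sizes and valid alphas", {
  fit <- fit_tiny_model(n = 30, rounds = 3)
  expect_s3_class(fit, "mirstart")
  expect_true(all(diff(fit$round_log$subset_size) >= 0))
  expect_true(all(is.finite(fit$alpha)))
  expect_true(all(fit$round_log$e_m < 0.5))
  expect_equal(length(fit$rounds), nrow(fit$round_log))
})

test_that("training is deterministic under a fixed seed", {
  f1 <- fit_tiny_model(n = 25, rounds = 2, seed = 17)
  f2 <- fit_tiny_model(n = 25, rounds = 2, seed = 17)
  expect_identical(f1$round_log, f2$round_log)
  hp <- simulate_hairpins(1, seed = 55)[[1]]
  expect_identical(score_candidates(f1, hp), score_candidates(f2, hp))
})

test_that("candidate ranking sorts by score with smaller-start tie-break", {
  fit <- fit_tiny_model(n = 25, rounds = 1)
  hp <- simulate_hairpins(1, seed = 77)[[1]]
  ranked <- score_candidates(fit, hp)
  expect_true(all(diff(ranked$score) <= 1e-12))
  expect_identical(sort(ranked$start),
                   seq_len(nchar(hp$sequence) - fit$window_len + 1L))
  expect_equal(ranked$end, ranked$start + fit$window_len - 1L)

  top <- predict_top_k(fit, hp, k = 5)
  expect_identical(top, ranked[1:5, ])
  expect_identical(predict_top_k(fit, hp, k = 1)$start, ranked$start[1])
  expect_warning(all_ranked <- predict_top_k(fit, hp, k = 1e4),
                 "returning all")
  expect_equal(nrow(all_ranked), nrow(ranked))
})

test_that("model accessors expose round weights and the round log", {
  fit <- fit_tiny_model(n = 25, rounds = 2)
  expect_identical(unname(coef(fit)), fit$alpha)
  expect_output(print(fit), "round log")
  expect_output(summary(fit), "alpha")
})
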