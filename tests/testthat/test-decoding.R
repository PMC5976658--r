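test_that("synergy_features slices the coefficient tensor correctly", {
  # hand-built 2-trial tensor, K = 2, N = 3
  A <- array(seq_len(2 * 2 * 3), dim = c(2, 2, 3))
  model <- list(A = A, K = 2, N = 3)
  Xt <- synergy_features(model, 1, "temporal")
  expect_equal(dim(Xt), c(2, 3))
  expect_equal(Xt[1, ], c(A[1, 1, 1], A[1, 1, 2], A[1, 1, 3]))
  Xs <- synergy_features(model, 3, "spatial")
  expect_equal(dim(Xs), c(2, 2))
  expect_equal(Xs[2, ], c(A[2, 1, 3], A[2, 2, 3]))
  Xf <- synergy_features(model, mode = "full")
  expect_equal(dim(Xf), c(2, 6))
  expect_equal(Xf[1, ], as.vector(A[1, , ]))
  expect_error(synergy_features(model, 3, "temporal"), "out of range")
  # dimensions on a larger model: temporal gives N features, full K*N
  model2 <- list(A = array(1, dim = c(4, 4, 5)))
  expect_equal(ncol(synergy_features(model2, 2, "temporal")), 5)
  expect_equal(ncol(synergy_features(model2, mode = "full")), 20)
})

test_that("chance level is 100/V", {
  expect_equal(round(chance_level(9)), 11)
  expect_equal(round(chance_level(3)), 33)
  expect_equal(chance_level(2), 50)
  expect_error(chance_level(1))
})

test_that("LOOCV LDA separates well-separated clouds and collapses on junk", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 10, 0.2), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  res <- decode_loocv(X, y)
  expect_equal(res$percent_correct, 100)
  expect_equal(rowSums(res$confusion$D), c(a = 1, b = 1))
  # constant features: majority-class prediction
  X0 <- matrix(1, 30, 2)
  y0 <- rep(c("a", "b", "c"), times = c(15, 10, 5))
  res0 <- decode_loocv(X0, y0)
  expect_equal(res0$percent_correct, 100 * 15 / 30)
  expect_true(all(res0$predictions == "a"))
  # diagonal sum reproduces percent correct; rows of D sum to 1
  set.seed(3)
  Xr <- matrix(rnorm(200), 100, 2)
  yr <- rep(1:4, each = 25)
  rr <- decode_loocv(Xr, yr)
  expect_equal(100 * sum(diag(rr$confusion$counts)) / rr$confusion$n_trials,
               rr$percent_correct)
  expect_equal(unname(rowSums(rr$confusion$D)), rep(1, 4))
  expect_equal(sum(rr$confusion$counts), rr$confusion$n_trials)
})

test_that("singleton classes are skipped with a warning", {
  set.seed(4)
  X <- matrix(rnorm(22), 11, 2)
  y <- c(rep("a", 5), rep("b", 5), "c")
  expect_warning(res <- decode_loocv(X, y), "single trial")
  expect_equal(res$confusion$n_trials, 10)
})

test_that("decode_loocv agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, 0, 1), n, 2),
             matrix(rnorm(2 * n, 1.2, 1), n, 2),
             matrix(rnorm(2 * n, c(0, 2.5), 1), n, 2))
  y <- rep(c("a", "b", "c"), each = n)
  ours <- decode_loocv(X, y)
  oracle <- MASS::lda(X, grouping = y, CV = TRUE)$class
  agree <- mean(as.character(ours$predictions) == as.character(oracle))
  expect_gte(agree, 0.98)
  expect_lt(abs(ours$percent_correct -
                  100 * mean(as.character(oracle) == y)), 2)
})

test_that("shuffled labels decode at chance (binomial null band)", {
  set.seed(6)
  n <- 500
  V <- 4
  X <- matrix(rnorm(2 * n), n, 2)
  X[, 1] <- X[, 1] + rep(seq_len(V), length.out = n)  # informative features
  y <- sample(rep(seq_len(V), length.out = n))        # labels shuffled away
  res <- decode_loocv(X, y)
  band <- qbinom(c(0.005, 0.995), n, 1 / V) / n * 100
  expect_gte(res$percent_correct, band[1])
  expect_lte(res$percent_correct, band[2])
})

test_that("collinear features are handled by shrinkage, not a crash", {
  set.seed(7)
  x1 <- rnorm(40) + rep(c(0, 3), each = 20)
  X <- cbind(x1, 2 * x1, x1 + 1e-12)  # rank deficient
  y <- rep(c("a", "b"), each = 20)
  res <- decode_loocv(X, y)
  expect_gt(res$lambda, 0)
  expect_gt(res$percent_correct, 80)
})

test_that("permutation gain test is calibrated and detects real gain", {
  set.seed(8)
  n <- 120
  V <- 4
  y <- rep(seq_len(V), each = n / V)
  base <- matrix(rnorm(n), n, 1) + 1.5 * (y %% 2)       # informative col
  # added component informative: small p-value
  addi <- matrix(y + rnorm(n, 0, 0.3), n, 1)
  g1 <- decoding_gain_test(cbind(base, addi), 2, y, n_perm = 40, seed = 1)
  expect_lte(g1$p_value, 0.05)
  # added component pure noise: type-I error controlled across replicates
  set.seed(9)
  rejections <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    noise <- matrix(rnorm(n), n, 1)
    g0 <- decoding_gain_test(cbind(base, noise), 2, y, n_perm = 40,
                             seed = 100 + r)
    if (g0$p_value <= 0.05) rejections <- rejections + 1
  }
  # binomial(30, 0.05) 99.5th percentile = 5
  expect_lte(rejections, qbinom(0.995, n_rep, 0.05))
})
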