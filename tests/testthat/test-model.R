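test_that("encoding lengths follow the window formulas for any odd window", {
  for (w in seq(5, 21, by = 2)) {
    cfg <- encodingConfig(w)
    expect_equal(cfg$stateLength, w * 21 + 2)
    expect_equal(cfg$pairLength, 2 * w * 21 + 6)
  }
  # the canonical default: 15-residue window -> 317 and 636 values
  expect_equal(encodingConfig(15)$stateLength, 317)
  expect_equal(encodingConfig(15)$pairLength, 636)
  expect_error(encodingConfig(8), "odd")
})

test_that("state encoding marks terminal overlap and collapses cleanly", {
  seq <- paste(c("C", rep("A", 30)), collapse = "")
  ch <- toyChain("b", seq, profile = "uniform")
  x <- encodeStateInput(ch, 1, 0, 0)
  # positions 1..7 of the window fall before the N-terminus
  for (s in 1:7) {
    block <- x[((s - 1) * 21 + 1):(s * 21)]
    expect_equal(block, c(rep(0, 20), 1))
  }
  # in-chain positions: indicator 0, uniform frequencies 0.05
  for (s in 8:15) {
    block <- x[((s - 1) * 21 + 1):(s * 21)]
    expect_equal(block, c(rep(0.05, 20), 0))
  }
  expect_equal(tail(x, 2), c(0, 0))
  expect_length(x, 317)

  mid <- toyChain("m", paste(c(rep("A", 15), "C", rep("A", 15)), collapse = ""),
                  profile = "uniform")
  xm <- encodeStateInput(mid, 16, 0, 0)
  ind <- xm[seq(21, 15 * 21, by = 21)]
  expect_true(all(ind == 0))
})

test_that("state encoding standardises the scores and rejects non-cysteines", {
  ch <- toyChain("s", paste(c(rep("A", 10), "C", rep("A", 10)), collapse = ""),
                 profile = "uniform")
  x <- encodeStateInput(ch, 11, 3, -1, scoreCenter = c(1, 1), scoreScale = c(2, 4))
  expect_equal(tail(x, 2), c(1, -0.5))
  expect_error(encodeStateInput(ch, 5, 0, 0), "not a cysteine")
})

test_that("pair encoding: one-hot states, symmetry, rejection of degenerate pairs", {
  seq <- paste(c(rep("A", 8), "C", rep("G", 10), "C", rep("A", 8)), collapse = "")
  ch <- toyChain("p", seq, profile = "uniform")
  x <- encodePairInput(ch, 9, 20, stateProbs = c(0.9, 0.2), pairScores = c(0, 0))
  expect_length(x, 636)
  expect_equal(x[631:634], c(1, 0, 0, 1))  # bonded one-hot, free one-hot
  # swapping the pair (and its state probabilities) gives the same vector
  x2 <- encodePairInput(ch, 20, 9, stateProbs = c(0.2, 0.9), pairScores = c(0, 0))
  expect_identical(x, x2)
  # a probability at the threshold counts as bonded
  x3 <- encodePairInput(ch, 9, 20, stateProbs = c(0.5, 0.5), pairScores = c(0, 0))
  expect_equal(x3[631:634], c(1, 0, 1, 0))
  expect_error(encodePairInput(ch, 9, 9, c(1, 1), c(0, 0)), "distinct")
})

test_that("a zero-weight network outputs exactly 0.5 and bounds hold", {
  net <- new("FeedForwardNet", nIn = 4L, nHidden = 3L,
             W1 = matrix(0, 3, 4), b1 = numeric(3), W2 = matrix(0, 1, 3),
             b2 = 0, seed = 0L, history = data.frame())
  expect_equal(predictProb(net, rep(1, 4)), 0.5)
  withr::with_seed(1, {
    for (r in 1:20) {
      x <- rnorm(4, sd = 10)
      p <- predictProb(net, x)
      expect_true(p > 0 && p < 1)
    }
  })
  expect_error(predictProb(net, rep(1, 5)), "dimension error")
})

test_that("the forward pass matches a hand-rolled 2-2-1 computation", {
  W1 <- rbind(c(0.3, -0.7), c(1.1, 0.4))
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(0.8, -1.3), 1, 2)
  b2 <- 0.05
  net <- new("FeedForwardNet", nIn = 2L, nHidden = 2L, W1 = W1, b1 = b1,
             W2 = W2, b2 = b2, seed = 0L, history = data.frame())
  for (x in list(c(0, 0), c(1, -1), c(2.5, 0.3))) {
    expect_equal(predictProb(net, x), manualForward(W1, b1, W2, b2, x),
                 tolerance = 1e-12)
  }
})

test_that("backprop gradients match central finite differences", {
  withr::with_seed(7, {
    X <- matrix(rnorm(6 * 5), 6, 5)
    y <- rbinom(6, 1, 0.5)
    w <- runif(6, 0.5, 2)
    W1 <- matrix(rnorm(3 * 5, sd = 0.5), 3, 5)
    b1 <- rnorm(3, sd = 0.1)
    W2 <- matrix(rnorm(3, sd = 0.5), 1, 3)
    b2 <- rnorm(1, sd = 0.1)
  })
  g <- CysBond:::.mlpLossGrad(W1, b1, W2, b2, X, y, w, l2 = 0.01)
  eps <- 1e-6
  num <- function(get, set) {
    # central finite differences over every coordinate of one parameter
    val <- get()
    out <- val
    for (k in seq_along(val)) {
      vp <- val; vp[k] <- vp[k] + eps
      vm <- val; vm[k] <- vm[k] - eps
      lp <- CysBond:::.mlpLoss(set(vp)$W1, set(vp)$b1, set(vp)$W2, set(vp)$b2, X, y, w, 0.01)
      lm <- CysBond:::.mlpLoss(set(vm)$W1, set(vm)$b1, set(vm)$W2, set(vm)$b2, X, y, w, 0.01)
      out[k] <- (lp - lm) / (2 * eps)
    }
    out
  }
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  for (nm in names(params)) {
    setP <- function(v) { p <- params; p[[nm]] <- v; p }
    getP <- function() params[[nm]]
    numeric0 <- num(getP, setP)
    analytic <- g[[paste0("g", nm)]]
    relErr <- max(abs(analytic - numeric0)) / max(1e-8, max(abs(numeric0)))
    expect_lt(relErr, 1e-5)
  }
})

test_that("training learns XOR, is seed-deterministic, and fits degenerate labels", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  net <- trainNetwork(X, y, nHidden = 4, seed = 11, epochs = 4000, lr = 0.5,
                      momentum = 0.9, l2 = 0, batchSize = Inf, valFraction = 0)
  expect_equal(as.integer(predictProb(net, X) >= 0.5), y)

  net2 <- trainNetwork(X, y, nHidden = 4, seed = 11, epochs = 4000, lr = 0.5,
                       momentum = 0.9, l2 = 0, batchSize = Inf, valFraction = 0)
  expect_identical(net@W1, net2@W1)
  expect_identical(net@W2, net2@W2)

  withr::with_seed(3, X0 <- matrix(rnorm(40), 20, 2))
  net0 <- trainNetwork(X0, rep(0, 20), nHidden = 3, seed = 2, epochs = 2000,
                       lr = 1, momentum = 0.9, l2 = 0, batchSize = Inf,
                       valFraction = 0, classWeight = FALSE)
  expect_true(all(predictProb(net0, X0) <= 0.01))
})

test_that("training errors on empty or inconsistent data", {
  expect_error(trainNetwork(matrix(0, 0, 3), numeric(0), 2), "empty")
  expect_error(trainNetwork(matrix(0, 4, 3), c(0, 1), 2), "labels")
  expect_error(trainNetwork(matrix(0, 2, 3), c(0.5, 2), 2), "0/1")
})

test_that("full-batch loss is non-increasing at a small learning rate", {
  withr::with_seed(5, {
    X <- matrix(rnorm(60), 30, 2)
    y <- as.integer(X[, 1] + X[, 2] > 0)
  })
  net <- trainNetwork(X, y, nHidden = 4, seed = 9, epochs = 60, lr = 0.05,
                      momentum = 0, l2 = 0, batchSize = Inf, valFraction = 0,
                      classWeight = FALSE)
  expect_true(all(diff(net@history$trainLoss) <= 1e-10))
})

test_that("the trained network agrees with an independent learner on separable data", {
  skip_if_not_installed("nnet")
  withr::with_seed(13, {
    X <- matrix(rnorm(400), 200, 2)
    y <- as.integer(X[, 1] - 0.5 * X[, 2] > 0)
  })
  ours <- trainNetwork(X, y, nHidden = 4, seed = 3, epochs = 300, lr = 0.3,
                       momentum = 0.9, l2 = 1e-5, batchSize = 32,
                       valFraction = 0, classWeight = FALSE)
  accOurs <- mean((predictProb(ours, X) >= 0.5) == y)
  ref <- withr::with_seed(4,
    nnet::nnet(X, y, size = 4, entropy = TRUE, maxit = 300, trace = FALSE))
  accRef <- mean((predict(ref, X) >= 0.5) == y)
  expect_gte(accOurs, 0.95)
  expect_gte(accRef, 0.95)
})
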