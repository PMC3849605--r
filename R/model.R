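#' Input-encoding configuration for the neural networks
#'
#' Each residue of a profile window contributes 21 values: its 20 profile
#' frequencies and 1 indicator set when the window position falls outside
#' the chain (terminal overlap). The bonding-state input adds the two
#' context scores (bonded, free); the pair input concatenates two windows
#' and adds the thresholded state predictions of both cysteines (2 x 2
#' one-hot) and the two connectivity context scores.
#'
#' @param nnWindow odd network window size in residues (default 15).
#' @return list with `nnWindow`, `perResidue` (21), `stateLength`
#'   (`nnWindow * 21 + 2`; 317 by default) and `pairLength`
#'   (`2 * nnWindow * 21 + 6`; 636 by default).
#' @export
encodingConfig <- function(nnWindow = 15L) {
  nnWindow <- .checkOddK(nnWindow, 1L)
  list(nnWindow = nnWindow, perResidue = 21L,
       stateLength = nnWindow * 21L + 2L,
       pairLength = 2L * nnWindow * 21L + 6L)
}

.windowBlock <- function(profile, pos, nnWindow) {
  h <- (nnWindow - 1L) %/% 2L
  L <- nrow(profile)
  out <- numeric(nnWindow * 21L)
  for (s in seq_len(nnWindow)) {
    p <- pos - h + (s - 1L)
    at <- (s - 1L) * 21L
    if (p >= 1L && p <= L) out[at + 1:20] <- profile[p, ]
    else out[at + 21L] <- 1
  }
  out
}

#' Encode the bonding-state network input of a cysteine
#'
#' @param chain an [AnnotatedChain-class] with a profile.
#' @param pos 1-based cysteine position.
#' @param scoreBonded,scoreFree the two context scores of the cysteine
#'   (raw energies; standardised with `scoreCenter`/`scoreScale`).
#' @param cfg an [encodingConfig()].
#' @param scoreCenter,scoreScale length-2 standardisation constants for the
#'   (bonded, free) scores, typically the training-set mean and standard
#'   deviation stored on the model.
#' @return numeric vector of length `cfg$stateLength` (317 by default).
#' @export
encodeStateInput <- function(chain, pos, scoreBonded, scoreFree,
                             cfg = encodingConfig(),
                             scoreCenter = c(0, 0), scoreScale = c(1, 1)) {
  if (substr(chainSeq(chain), pos, pos) != "C")
    stop("encoding error: position ", pos, " is not a cysteine")
  if (!hasProfile(chain)) stop("encoding error: chain has no profile")
  z <- (c(scoreBonded, scoreFree) - scoreCenter) / scoreScale
  ## clip standardized scores: rare extreme energies would otherwise
  ## saturate the hidden layer
  z <- pmin(pmax(z, -6), 6)
  c(.windowBlock(profileMatrix(chain), pos, cfg$nnWindow), z)
}

#' Encode the connectivity network input of a cysteine pair
#'
#' The pair is canonically ordered `posI < posJ` before encoding, so
#' swapping the arguments (with their state probabilities) yields the same
#' vector.
#'
#' @inheritParams encodeStateInput
#' @param posI,posJ distinct 1-based cysteine positions.
#' @param stateProbs length-2 predicted bonding probabilities of
#'   (`posI`, `posJ`); each is thresholded into a bonded/free one-hot pair.
#' @param pairScores length-2 context scores (connected, unconnected).
#' @param threshold bonding-state decision threshold (default 0.5,
#'   bonded when probability >= threshold).
#' @return numeric vector of length `cfg$pairLength` (636 by default).
#' @export
encodePairInput <- function(chain, posI, posJ, stateProbs, pairScores,
                            cfg = encodingConfig(), threshold = 0.5,
                            scoreCenter = c(0, 0), scoreScale = c(1, 1)) {
  if (posI == posJ) stop("encoding error: pair positions must be distinct")
  if (posI > posJ) {
    tmp <- posI; posI <- posJ; posJ <- tmp
    stateProbs <- rev(stateProbs)
  }
  for (p in c(posI, posJ))
    if (substr(chainSeq(chain), p, p) != "C")
      stop("encoding error: position ", p, " is not a cysteine")
  P <- profileMatrix(chain)
  oneHot <- function(prob) if (prob >= threshold) c(1, 0) else c(0, 1)
  z <- (pairScores - scoreCenter) / scoreScale
  z <- pmin(pmax(z, -6), 6)
  c(.windowBlock(P, posI, cfg$nnWindow),
    .windowBlock(P, posJ, cfg$nnWindow),
    oneHot(stateProbs[1]), oneHot(stateProbs[2]), z)
}

## ---- feed-forward network --------------------------------------------------

.mlpForwardRaw <- function(W1, b1, W2, b2, X) {
  H <- plogis(X %*% t(W1) + matrix(b1, nrow(X), length(b1), byrow = TRUE))
  p <- plogis(H %*% t(W2) + b2)
  list(H = H, p = as.vector(p))
}

## cross-entropy loss and its analytic backprop gradients
.mlpLossGrad <- function(W1, b1, W2, b2, X, y, w, l2 = 0) {
  n <- nrow(X)
  fw <- .mlpForwardRaw(W1, b1, W2, b2, X)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w) +
    l2 / 2 * (sum(W1^2) + sum(W2^2))
  dz2 <- w * (fw$p - y) / sum(w)                        # n
  gW2 <- matrix(dz2, 1, n) %*% fw$H + l2 * W2           # 1 x h
  gb2 <- sum(dz2)
  dH <- dz2 %o% as.vector(W2)                           # n x h
  dZ1 <- dH * fw$H * (1 - fw$H)
  gW1 <- crossprod(dZ1, X) + l2 * W1                    # h x in
  gb1 <- colSums(dZ1)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

.mlpLoss <- function(W1, b1, W2, b2, X, y, w, l2 = 0) {
  .mlpLossGrad(W1, b1, W2, b2, X, y, w, l2)$loss
}

#' Train a single-hidden-layer feed-forward network
#'
#' Logistic hidden and output units trained by backpropagation
#' (cross-entropy loss, mini-batch stochastic gradient descent with
#' momentum and optional L2 decay). A fraction of the examples is held out
#' as a validation split for early stopping; the weights of the best
#' validation epoch are kept. Fully deterministic given `seed`.
#'
#' @param X numeric matrix of inputs (examples x features).
#' @param y 0/1 labels.
#' @param nHidden hidden layer size.
#' @param seed integer seed controlling initialisation, the validation
#'   split and batch order.
#' @param epochs maximum number of passes over the data.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param l2 L2 weight-decay coefficient.
#' @param batchSize mini-batch size (`Inf` = full batch).
#' @param valFraction fraction held out for early stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @param classWeight logical; weight examples inversely to class
#'   frequency. Off by default: the decision threshold is fixed at 0.5, and
#'   balanced reweighting would shift the posterior so that 0.5 no longer
#'   corresponds to the corpus prior, over-calling the minority class.
#' @param valX,valY optional explicit validation set (overrides
#'   `valFraction`).
#' @return A [FeedForwardNet-class].
#' @export
trainNetwork <- function(X, y, nHidden, seed = 1L, epochs = 100L, lr = 0.2,
                         momentum = 0.9, l2 = 1e-4, batchSize = 128L,
                         valFraction = 0.1, patience = 10L,
                         classWeight = FALSE, valX = NULL, valY = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("training error: empty data")
  if (length(y) != nrow(X)) stop("training error: labels do not match inputs")
  if (!all(y %in% c(0, 1))) stop("training error: labels must be 0/1")
  nIn <- ncol(X)
  withLocalSeed(seed, {
    if (is.null(valX) && valFraction > 0 && nrow(X) >= 10L) {
      nVal <- max(1L, floor(valFraction * nrow(X)))
      idx <- sample.int(nrow(X))
      valSel <- idx[seq_len(nVal)]
      valX <- X[valSel, , drop = FALSE]; valY <- y[valSel]
      X <- X[idx[-seq_len(nVal)], , drop = FALSE]; y <- y[idx[-seq_len(nVal)]]
    }
    n <- nrow(X)
    w <- rep(1, n)
    if (classWeight && length(unique(y)) == 2L) {
      w[y == 1] <- n / (2 * sum(y == 1))
      w[y == 0] <- n / (2 * sum(y == 0))
    }
    sc <- 1 / sqrt(nIn)
    W1 <- matrix(runif(nHidden * nIn, -sc, sc), nHidden, nIn)
    b1 <- numeric(nHidden)
    W2 <- matrix(runif(nHidden, -1 / sqrt(nHidden), 1 / sqrt(nHidden)), 1, nHidden)
    b2 <- 0
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- 0
    bs <- if (!is.finite(batchSize)) n else min(as.integer(batchSize), n)
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    stale <- 0L
    hist <- data.frame(epoch = integer(0), trainLoss = numeric(0), valLoss = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        sel <- ord[start:min(start + bs - 1L, n)]
        g <- .mlpLossGrad(W1, b1, W2, b2, X[sel, , drop = FALSE], y[sel], w[sel], l2)
        vW1 <- momentum * vW1 - lr * g$gW1; W1 <- W1 + vW1
        vb1 <- momentum * vb1 - lr * g$gb1; b1 <- b1 + vb1
        vW2 <- momentum * vW2 - lr * g$gW2; W2 <- W2 + vW2
        vb2 <- momentum * vb2 - lr * g$gb2; b2 <- b2 + vb2
      }
      trainLoss <- .mlpLoss(W1, b1, W2, b2, X, y, w, l2)
      valLoss <- if (!is.null(valX))
        .mlpLoss(W1, b1, W2, b2, valX, valY, rep(1, length(valY)), l2) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = trainLoss, valLoss = valLoss))
      if (!is.null(valX)) {
        if (valLoss < best$loss - 1e-7) {
          best <- list(loss = valLoss, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= patience) break
        }
      }
    }
    if (is.finite(best$loss)) {
      W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
    }
    new("FeedForwardNet", nIn = as.integer(nIn), nHidden = as.integer(nHidden),
        W1 = W1, b1 = b1, W2 = W2, b2 = as.numeric(b2),
        seed = as.integer(seed), history = hist)
  })
}

#' Predicted probability of a trained network
#'
#' @param net a [FeedForwardNet-class].
#' @param x numeric vector of length `nIn`, or a matrix with `nIn` columns.
#' @return probability (or vector of probabilities) strictly in (0, 1).
#' @export
predictProb <- function(net, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != net@nIn)
    stop("dimension error: expected ", net@nIn, " inputs, got ", ncol(X))
  .mlpForwardRaw(net@W1, net@b1, net@W2, net@b2, X)$p
}
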