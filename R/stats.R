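## ---- window geometry -------------------------------------------------------

.checkOddK <- function(K, minK = 1L) {
  K <- as.integer(K)
  if (is.na(K) || K < minK || K %% 2L != 1L)
    stop("window size K must be an odd integer >= ", minK)
  K
}

#' First-order neighbour offsets of a statistics window
#'
#' For a window of K residues centred on a cysteine there are K - 1
#' first-order neighbour positions.
#'
#' @param K odd window size (centre included); the default statistics
#'   window is 7, which spans the i-3 ... i+3 motif range.
#' @return integer vector of the K - 1 nonzero offsets, increasing.
#' @examples
#' enumerateFirstOrderOffsets(7)
#' @export
enumerateFirstOrderOffsets <- function(K) {
  K <- .checkOddK(K, 1L)
  h <- (K - 1L) %/% 2L
  if (h == 0L) return(integer(0))
  setdiff(seq.int(-h, h), 0L)
}

#' Second-order offset pairs of a statistics window
#'
#' All unordered pairs of distinct nonzero offsets within the window:
#' choose(K - 1, 2) pairs, covering both-left, straddling and both-right
#' neighbour geometries.
#'
#' @param K odd window size, at least 3.
#' @return integer matrix with columns `k1 < k2`, one row per pair, in
#'   lexicographic order.
#' @examples
#' nrow(enumerateSecondOrderOffsetPairs(7))  # 15
#' @export
enumerateSecondOrderOffsetPairs <- function(K) {
  K <- .checkOddK(K, 3L)
  offs <- enumerateFirstOrderOffsets(K)
  pairs <- t(combn(offs, 2L))
  colnames(pairs) <- c("k1", "k2")
  pairs
}

#' Neighbour slots and slot-pairs for a disulfide-bonded cysteine pair
#'
#' A bonded pair has 2(K - 1) neighbour slots: (cysteine 1 or 2, offset).
#' Second-order statistics range over all unordered pairs of distinct
#' slots, deduplicated under the symmetry that exchanges the two cysteines
#' (the bond is unordered); orbits fixed by the swap are counted once.
#' For K = 7 this gives 12 slots and 36 symmetry-distinct slot-pairs.
#'
#' @param K odd window size, at least 3.
#' @return list with elements `slots` (data frame: `cys` in 1:2, `offset`),
#'   `slotPairs` (data frame: slot indices `u < v`, `orbit` id, `flip`
#'   flag telling whether the pair maps onto its orbit representative with
#'   its two slots exchanged) and `orbits` (data frame of representative
#'   slot index pairs `u`, `v` with the orbit `size`).
#' @examples
#' ps <- enumeratePairOffsetSlots(3)
#' nrow(ps$slots)   # 4
#' nrow(ps$orbits)  # 4
#' @export
enumeratePairOffsetSlots <- function(K) {
  K <- .checkOddK(K, 3L)
  offs <- enumerateFirstOrderOffsets(K)
  m <- length(offs)
  slots <- data.frame(cys = rep(1:2, each = m), offset = rep(offs, 2L))
  nS <- nrow(slots)
  ## swap permutation: (1,k) <-> (2,k); offset index preserved
  sigma <- c((m + 1L):nS, 1L:m)
  pairs <- t(combn(seq_len(nS), 2L))
  u <- pairs[, 1]; v <- pairs[, 2]
  iu <- pmin(sigma[u], sigma[v]); iv <- pmax(sigma[u], sigma[v])
  isCanon <- (u < iu) | (u == iu & v <= iv)
  repU <- ifelse(isCanon, u, iu)
  repV <- ifelse(isCanon, v, iv)
  ## when the image pair is the representative and sorting reversed the
  ## two slots, the residue axes exchange on accumulation
  flip <- !isCanon & (iu == sigma[v])
  key <- paste(repU, repV)
  orbitIds <- match(key, unique(key))
  orbits <- data.frame(u = repU, v = repV, orbit = orbitIds)
  orbits <- unique(orbits[order(orbits$orbit), ])
  size <- as.vector(table(orbitIds)[as.character(orbits$orbit)])
  list(
    slots = slots,
    slotPairs = data.frame(u = u, v = v, orbit = orbitIds, flip = flip),
    orbits = data.frame(u = orbits$u, v = orbits$v, size = size)
  )
}

## ---- accumulation ----------------------------------------------------------

## stack profile rows at pos + k over a list of (chain, positions) samples;
## out-of-range rows are zero and flagged in the mask
.neighbourMatrix <- function(chains, chainIdx, pos, k) {
  n <- length(pos)
  M <- matrix(0, nrow = n, ncol = 20, dimnames = list(NULL, AA_ALPHABET20))
  mask <- logical(n)
  tgt <- pos + k
  for (ci in unique(chainIdx)) {
    sel <- which(chainIdx == ci)
    P <- profileMatrix(chains[[ci]])
    L <- nrow(P)
    ok <- sel[tgt[sel] >= 1L & tgt[sel] <= L]
    if (length(ok)) {
      M[ok, ] <- P[tgt[ok], , drop = FALSE]
      mask[ok] <- TRUE
    }
  }
  list(M = M, mask = mask)
}

.corpusComposition <- function(chains) {
  tot <- numeric(20)
  n <- 0L
  for (ch in chains) {
    P <- profileMatrix(ch)
    tot <- tot + colSums(P)
    n <- n + nrow(P)
  }
  ## one uniform pseudo-position keeps every residue's composition positive
  ## (tiny one-hot corpora may miss amino acids entirely)
  comp <- (tot + 1 / 20) / (n + 1)
  names(comp) <- AA_ALPHABET20
  comp
}

.accumulateOrders <- function(chains, chainIdx, posA, posB = NULL, w, classIdx,
                              classes, firstPos, secondPairs, K) {
  ## firstPos: data frame with columns `anchor` (1 = posA, 2 = posB) and
  ## `offset`; secondPairs: data frame with columns u, v (indices into
  ## firstPos), `dest` (destination second-order index) and `flip`.
  nP <- nrow(firstPos)
  neigh <- vector("list", nP)
  for (s in seq_len(nP)) {
    anchor <- if (firstPos$anchor[s] == 1L) posA else posB
    neigh[[s]] <- .neighbourMatrix(chains, chainIdx, anchor, firstPos$offset[s])
  }
  nDest <- max(secondPairs$dest)
  firstNum <- firstDen <- secondNum <- secondDen <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    sel <- which(classIdx == ci)
    fN <- matrix(0, 20, nP, dimnames = list(AA_ALPHABET20, NULL))
    fD <- numeric(nP)
    for (s in seq_len(nP)) {
      M <- neigh[[s]]$M[sel, , drop = FALSE]
      fN[, s] <- colSums(M * w[sel])
      fD[s] <- sum(w[sel] * neigh[[s]]$mask[sel])
    }
    sN <- array(0, c(20, 20, nDest), dimnames = list(AA_ALPHABET20, AA_ALPHABET20, NULL))
    sD <- numeric(nDest)
    for (p in seq_len(nrow(secondPairs))) {
      u <- secondPairs$u[p]; v <- secondPairs$v[p]; d <- secondPairs$dest[p]
      wm <- w[sel] * neigh[[u]]$mask[sel] * neigh[[v]]$mask[sel]
      Mu <- neigh[[u]]$M[sel, , drop = FALSE]
      Mv <- neigh[[v]]$M[sel, , drop = FALSE]
      C <- crossprod(Mu * wm, Mv)
      if (secondPairs$flip[p]) C <- t(C)
      sN[, , d] <- sN[, , d] + C
      sD[d] <- sD[d] + sum(wm)
    }
    firstNum[[cl]] <- fN; firstDen[[cl]] <- fD
    secondNum[[cl]] <- sN; secondDen[[cl]] <- sD
  }
  list(firstNum = firstNum, firstDen = firstDen,
       secondNum = secondNum, secondDen = secondDen)
}

#' Accumulate bonding-state context statistics
#'
#' Profile-weighted first- and second-order observed statistics of the
#' neighbourhoods of bonded and free cysteines. Each usable cysteine i
#' contributes with weight PSSM(C at i); a neighbour at offset k
#' contributes its profile row, and an offset pair (k1, k2) the outer
#' product of the two rows. Offsets falling outside the chain contribute
#' nothing to numerator or denominator of that offset. The reference state
#' (all usable cysteines regardless of class) is the class sum and is
#' recovered with [refProb()].
#'
#' @param chains non-empty list of [AnnotatedChain-class] with profiles and
#'   bond annotations.
#' @param K odd statistics window size (default 7).
#' @param .allowEmpty internal: return zero-filled statistics instead of
#'   erroring when the chains contribute no samples (used by group-wise
#'   accumulation).
#' @return A [ContextStatistics-class] with `kind = "state"`, classes
#'   `bonded` / `free`.
#' @export
accumulateStateStatistics <- function(chains, K = 7L, .allowEmpty = FALSE) {
  K <- .checkOddK(K, 3L)
  if (!length(chains) && !.allowEmpty) stop("no chains supplied")
  stopifnot(all(vapply(chains, hasProfile, TRUE)))
  chainIdx <- integer(0); pos <- integer(0); classIdx <- integer(0); w <- numeric(0)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    p <- usableCys(ch)
    if (!length(p)) next
    lab <- cysLabels(ch)
    chainIdx <- c(chainIdx, rep.int(ci, length(p)))
    pos <- c(pos, p)
    classIdx <- c(classIdx, ifelse(lab == 1L, 1L, 2L))
    w <- c(w, profileMatrix(ch)[p, "C"])
  }
  if (!length(pos) && !.allowEmpty)
    stop("empty statistics: no usable cysteines in the corpus")
  classes <- c("bonded", "free")
  offs <- enumerateFirstOrderOffsets(K)
  firstPos <- data.frame(anchor = 1L, offset = offs)
  op <- enumerateSecondOrderOffsetPairs(K)
  secondPairs <- data.frame(u = match(op[, 1], offs), v = match(op[, 2], offs),
                            dest = seq_len(nrow(op)), flip = FALSE)
  acc <- .accumulateOrders(chains, chainIdx, pos, NULL, w, classIdx,
                           classes, firstPos, secondPairs, K)
  idx <- data.frame(k1 = op[, 1], k2 = op[, 2])
  new("ContextStatistics", kind = "state", K = K, classes = classes,
      firstNum = acc$firstNum, firstDen = acc$firstDen,
      secondNum = acc$secondNum, secondDen = acc$secondDen,
      secondIndex = idx,
      composition = .corpusComposition(chains),
      classWeight = setNames(c(sum(w[classIdx == 1L]), sum(w[classIdx == 2L])), classes),
      nChains = length(chains))
}

#' Enumerate the sampled cysteine pairs of a corpus
#'
#' Connected pairs are the annotated bonds; unconnected pairs are all other
#' same-chain pairs of usable cysteines with sequence separation at least
#' `minSeparation`, optionally subsampled to `negativeRatio` negatives per
#' positive.
#' @keywords internal
.collectPairSamples <- function(chains, minSeparation = 2L,
                                negativeRatio = Inf, seed = NULL) {
  chainIdx <- integer(0); pi <- integer(0); pj <- integer(0); classIdx <- integer(0)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    p <- usableCys(ch)
    b <- bonds(ch)
    bondKey <- if (nrow(b)) paste(b[, 1], b[, 2]) else character(0)
    if (length(p) >= 2L) {
      allp <- t(combn(p, 2L))
      keep <- (allp[, 2] - allp[, 1]) >= minSeparation
      key <- paste(allp[, 1], allp[, 2])
      isBond <- key %in% bondKey
      sel <- isBond | keep
      allp <- allp[sel, , drop = FALSE]; isBond <- isBond[sel]
      chainIdx <- c(chainIdx, rep.int(ci, nrow(allp)))
      pi <- c(pi, allp[, 1]); pj <- c(pj, allp[, 2])
      classIdx <- c(classIdx, ifelse(isBond, 1L, 2L))
    }
  }
  if (is.finite(negativeRatio)) {
    nPos <- sum(classIdx == 1L)
    negs <- which(classIdx == 2L)
    nKeep <- min(length(negs), ceiling(negativeRatio * nPos))
    if (nKeep < length(negs)) {
      keepNeg <- withLocalSeed(if (is.null(seed)) 1L else seed,
                               sample(negs, nKeep))
      sel <- sort(c(which(classIdx == 1L), keepNeg))
      chainIdx <- chainIdx[sel]; pi <- pi[sel]; pj <- pj[sel]; classIdx <- classIdx[sel]
    }
  }
  list(chainIdx = chainIdx, pi = pi, pj = pj, classIdx = classIdx)
}

#' Accumulate connectivity (cysteine-pair) context statistics
#'
#' As [accumulateStateStatistics()], but the sample unit is an unordered
#' same-chain cysteine pair: the connected class accumulates over annotated
#' bonds, the unconnected class over the sampled non-bonded pairs, and each
#' sample is weighted by the product of the two cysteine profile
#' frequencies. First-order statistics range over the 2(K - 1) neighbour
#' slots (cysteine 1 = the N-terminal member); second-order statistics over
#' the symmetry-distinct slot-pair orbits of [enumeratePairOffsetSlots()].
#'
#' @inheritParams accumulateStateStatistics
#' @param minSeparation minimum sequence separation of sampled unconnected
#'   pairs (default 2; disulfides link nonadjacent cysteines).
#' @param negativeRatio maximum number of unconnected pairs sampled per
#'   connected pair (default `Inf`: use all).
#' @param seed seed used only when subsampling negatives.
#' @param .allowEmpty internal: return zero-filled statistics instead of
#'   erroring when no bonded pairs are present (used by group-wise
#'   accumulation).
#' @return A [ContextStatistics-class] with `kind = "pair"`, classes
#'   `connected` / `unconnected`.
#' @export
accumulatePairStatistics <- function(chains, K = 7L, minSeparation = 2L,
                                     negativeRatio = Inf, seed = NULL,
                                     .allowEmpty = FALSE) {
  K <- .checkOddK(K, 3L)
  if (!length(chains) && !.allowEmpty) stop("no chains supplied")
  stopifnot(all(vapply(chains, hasProfile, TRUE)))
  smp <- .collectPairSamples(chains, minSeparation, negativeRatio, seed)
  if (!any(smp$classIdx == 1L) && !.allowEmpty)
    stop("empty statistics: no bonded pairs in the corpus")
  w <- numeric(length(smp$pi))
  for (ci in unique(smp$chainIdx)) {
    sel <- which(smp$chainIdx == ci)
    P <- profileMatrix(chains[[ci]])
    w[sel] <- P[smp$pi[sel], "C"] * P[smp$pj[sel], "C"]
  }
  classes <- c("connected", "unconnected")
  ps <- enumeratePairOffsetSlots(K)
  firstPos <- data.frame(anchor = ps$slots$cys, offset = ps$slots$offset)
  secondPairs <- data.frame(u = ps$slotPairs$u, v = ps$slotPairs$v,
                            dest = ps$slotPairs$orbit, flip = ps$slotPairs$flip)
  acc <- .accumulateOrders(chains, smp$chainIdx, smp$pi, smp$pj, w, smp$classIdx,
                           classes, firstPos, secondPairs, K)
  idx <- data.frame(
    cys1 = ps$slots$cys[ps$orbits$u], k1 = ps$slots$offset[ps$orbits$u],
    cys2 = ps$slots$cys[ps$orbits$v], k2 = ps$slots$offset[ps$orbits$v],
    size = ps$orbits$size)
  new("ContextStatistics", kind = "pair", K = K, classes = classes,
      firstNum = acc$firstNum, firstDen = acc$firstDen,
      secondNum = acc$secondNum, secondDen = acc$secondDen,
      secondIndex = idx,
      composition = .corpusComposition(chains),
      classWeight = setNames(c(sum(w[smp$classIdx == 1L]), sum(w[smp$classIdx == 2L])), classes),
      nChains = length(chains))
}

## ---- probability accessors -------------------------------------------------

.safeDiv <- function(num, den) ifelse(den > 0, num / den, 0)

#' Observed and reference probabilities of a statistics object
#'
#' Raw (unsmoothed) probability estimates: numerator over denominator.
#' `refProb` gives the reference state — the class sum, i.e. all usable
#' cysteines (or all sampled pairs) regardless of class.
#'
#' @param stats a [ContextStatistics-class].
#' @param order 1 or 2.
#' @param class one of the object's class labels (for `obsProb`).
#' @return order 1: 20 x positions matrix; order 2: 20 x 20 x pairs array.
#' @export
obsProb <- function(stats, order = 1L, class) {
  stopifnot(class %in% stats@classes)
  if (order == 1L) {
    num <- stats@firstNum[[class]]
    sweep2 <- sweep(num, 2, pmax(stats@firstDen[[class]], .Machine$double.xmin), "/")
    sweep2[, stats@firstDen[[class]] <= 0] <- 0
    sweep2
  } else {
    num <- stats@secondNum[[class]]
    den <- stats@secondDen[[class]]
    out <- num
    for (p in seq_along(den)) out[, , p] <- .safeDiv(num[, , p], den[p])
    out
  }
}

#' @rdname obsProb
#' @export
refProb <- function(stats, order = 1L) {
  if (order == 1L) {
    num <- Reduce(`+`, stats@firstNum)
    den <- Reduce(`+`, stats@firstDen)
    out <- sweep(num, 2, pmax(den, .Machine$double.xmin), "/")
    out[, den <= 0] <- 0
    out
  } else {
    num <- Reduce(`+`, stats@secondNum)
    den <- Reduce(`+`, stats@secondDen)
    out <- num
    for (p in seq_along(den)) out[, , p] <- .safeDiv(num[, , p], den[p])
    out
  }
}

#' Smoothed probability tables
#'
#' Applies the pseudocount rule (w + lambda * comp) / (W + lambda), where
#' `comp` is the corpus amino-acid composition (outer product of
#' compositions at second order) and W the accumulated profile mass behind
#' the estimate. Guarantees strictly positive probabilities wherever the
#' composition is positive, so downstream log-ratios are finite.
#'
#' @param stats a [ContextStatistics-class].
#' @param lambda pseudocount profile mass (default 1).
#' @return list with elements `first` and `second`, each a named list over
#'   the classes plus `"ref"`.
#' @export
smoothedProb <- function(stats, lambda = 1) {
  comp <- stats@composition
  comp2 <- comp %o% comp
  labels <- c(stats@classes, "ref")
  firstN <- c(stats@firstNum, list(ref = Reduce(`+`, stats@firstNum)))
  firstD <- c(stats@firstDen, list(ref = Reduce(`+`, stats@firstDen)))
  secondN <- c(stats@secondNum, list(ref = Reduce(`+`, stats@secondNum)))
  secondD <- c(stats@secondDen, list(ref = Reduce(`+`, stats@secondDen)))
  first <- second <- list()
  for (cl in labels) {
    fN <- firstN[[cl]]; fD <- firstD[[cl]]
    ## (fN[, s] + lambda * comp) / (fD[s] + lambda), column by column
    first[[cl]] <- sweep(fN, 2, fD + lambda, "/") + outer(comp, lambda / (fD + lambda))
    sN <- secondN[[cl]]; sD <- secondD[[cl]]
    out <- sN
    for (p in seq_along(sD)) out[, , p] <- (sN[, , p] + lambda * comp2) / (sD[p] + lambda)
    second[[cl]] <- out
  }
  list(first = first, second = second, lambda = lambda, composition = comp)
}
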