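## ---- stage 1: bonding states ----------------------------------------------

#' Predict per-cysteine bonding states
#'
#' Scores every cysteine of the query with the state potential table,
#' encodes the profile window plus the two standardised context scores, and
#' runs the bonding-state network. A cysteine is predicted bonded when its
#' probability is at least the threshold (ties count as bonded).
#'
#' @param predictor a trained [DisulfidePredictor-class].
#' @param chain an [AnnotatedChain-class] with a profile.
#' @return list of class `StatePrediction`: `table` (data frame with
#'   columns `pos`, `prob`, `bonded`), `threshold`.
#' @export
predictStates <- function(predictor, chain) {
  cys <- cysPositions(chain)
  thr <- predictor@cfg$stateThreshold
  if (!length(cys)) {
    return(structure(list(
      table = data.frame(pos = integer(0), prob = numeric(0), bonded = logical(0)),
      threshold = thr), class = "StatePrediction"))
  }
  cfg <- encodingConfig(predictor@cfg$nnWindow)
  P <- profileMatrix(chain)
  probs <- vapply(cys, function(p) {
    sc <- stateScores(predictor@stateTable, P, p)
    x <- encodeStateInput(chain, p, sc["bonded"], sc["free"], cfg,
                          predictor@stateScoreCenter, predictor@stateScoreScale)
    predictProb(predictor@stateNet, x)
  }, 0)
  structure(list(
    table = data.frame(pos = cys, prob = probs, bonded = probs >= thr),
    threshold = thr), class = "StatePrediction")
}

#' Candidate disulfide pairs among predicted-bonded cysteines
#'
#' All unordered pairs of predicted-bonded cysteines separated by at least
#' `minSeparation` residues (disulfides link nonadjacent cysteines).
#'
#' @param pred a `StatePrediction` (from [predictStates()]) or an integer
#'   vector of bonded cysteine positions.
#' @param minSeparation minimum sequence separation (default 2).
#' @return integer matrix with columns `i < j` (possibly 0 rows).
#' @export
enumerateCandidatePairs <- function(pred, minSeparation = 2L) {
  pos <- if (inherits(pred, "StatePrediction")) pred$table$pos[pred$table$bonded]
         else sort(as.integer(pred))
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (length(pos) < 2L) return(empty)
  pairs <- t(combn(sort(pos), 2L))
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= minSeparation, , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

## ---- stage 2: connectivity -------------------------------------------------

#' Resolve pairwise bond probabilities into a consistent pattern
#'
#' Maximum-weight matching on the graph whose vertices are the candidate
#' cysteines and whose edge weights are the predicted pair probabilities;
#' each cysteine ends up in at most one bond. This formalises the
#' conflict-resolution logic of the two-stage method: a high-probability
#' edge is rejected when committing to it forces a poorly supported
#' complement (e.g. with pair probabilities 4-18: 0.37, 4-29: 0.32,
#' 4-60: 0.66, 18-29: 0.84, 18-60: 0.90, 29-60: 0.34 the greedy pick 18-60
#' loses to the pattern {4-60, 18-29} with total 1.50). Matched edges below
#' `minBondProb` are dropped from the final pattern. Exact (bitmask dynamic
#' programming) up to 22 cysteines, greedy beyond; deterministic
#' tie-breaking by lexicographic pair order.
#'
#' @param pairProbs data frame with columns `i`, `j`, `prob`, or a named
#'   numeric vector with names `"i-j"`.
#' @param minBondProb matched edges below this probability are dropped.
#'   The default 0 keeps every matched edge: stage 1 already decides which
#'   cysteines bond, and stage 2 only resolves the pairing among them, so
#'   a probability cutoff here would re-litigate the bonding-state call
#'   and routinely delete the forced single pair of two-cysteine chains.
#' @return A [DisulfidePattern-class]; attribute `"prob"` carries the
#'   retained per-bond probabilities.
#' @export
assignConnectivity <- function(pairProbs, minBondProb = 0) {
  if (is.numeric(pairProbs) && !is.null(names(pairProbs))) {
    parts <- do.call(rbind, strsplit(names(pairProbs), "-"))
    pairProbs <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                            prob = as.numeric(pairProbs))
  }
  if (!nrow(pairProbs)) return(disulfidePattern())
  stopifnot(all(c("i", "j") %in% names(pairProbs)))
  pcol <- if ("prob" %in% names(pairProbs)) "prob" else "p"
  prob <- pairProbs[[pcol]]
  if (any(prob < 0 | prob > 1)) stop("pair probabilities must be in [0, 1]")
  i <- pmin(pairProbs$i, pairProbs$j)
  j <- pmax(pairProbs$i, pairProbs$j)
  verts <- sort(unique(c(i, j)))
  n <- length(verts)
  W <- matrix(NA_real_, n, n)
  W[cbind(match(i, verts), match(j, verts))] <- prob
  W[cbind(match(j, verts), match(i, verts))] <- prob
  m <- if (n <= 22L) maxWeightMatchingDP(W) else .greedyMatching(W)
  sel <- which(m > seq_len(n))
  if (!length(sel)) return(disulfidePattern())
  out <- cbind(verts[sel], verts[m[sel]])
  key <- paste(out[, 1], out[, 2])
  outProb <- prob[match(key, paste(i, j))]
  keep <- outProb >= minBondProb
  pat <- disulfidePattern(out[keep, , drop = FALSE])
  attr(pat, "prob") <- outProb[keep]
  pat
}

## greedy fallback for graphs too large for the exact DP
.greedyMatching <- function(W) {
  n <- nrow(W)
  m <- integer(n)
  edges <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
  if (!nrow(edges)) return(m)
  wts <- W[edges]
  ord <- order(-wts, edges[, 1], edges[, 2])
  for (e in ord) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (m[a] == 0L && m[b] == 0L) { m[a] <- b; m[b] <- a }
  }
  m
}

#' Predicted probabilities for candidate pairs
#'
#' Encodes and scores each candidate pair with the connectivity network.
#'
#' @param predictor a [DisulfidePredictor-class].
#' @param chain an [AnnotatedChain-class] with profile.
#' @param statePred a `StatePrediction` for the chain.
#' @param pairs integer matrix of candidate pairs (columns `i`, `j`).
#' @return data frame with columns `i`, `j`, `prob`.
#' @export
pairProbabilities <- function(predictor, chain, statePred, pairs) {
  if (!nrow(pairs))
    return(data.frame(i = integer(0), j = integer(0), prob = numeric(0)))
  cfg <- encodingConfig(predictor@cfg$nnWindow)
  P <- profileMatrix(chain)
  stateProb <- setNames(statePred$table$prob, statePred$table$pos)
  probs <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    sc <- pairScores(predictor@pairTable, P, i, j)
    x <- encodePairInput(chain, i, j,
                         stateProbs = c(stateProb[as.character(i)], stateProb[as.character(j)]),
                         pairScores = sc, cfg = cfg,
                         threshold = predictor@cfg$stateThreshold,
                         scoreCenter = predictor@pairScoreCenter,
                         scoreScale = predictor@pairScoreScale)
    predictProb(predictor@connNet, x)
  }, 0)
  data.frame(i = pairs[, 1], j = pairs[, 2], prob = probs)
}

#' Full two-stage disulfide prediction for one chain
#'
#' Runs bonding-state prediction, enumerates candidate pairs among the
#' predicted-bonded cysteines, scores them with the connectivity network
#' and resolves a consistent disulfide pattern by maximum-weight matching.
#'
#' @param predictor a trained [DisulfidePredictor-class].
#' @param chain an [AnnotatedChain-class] with a profile attached.
#' @return list of class `ChainPrediction`: `id`, `state`
#'   (a `StatePrediction`), `pairs` (data frame `i`, `j`, `prob`),
#'   `pattern` (a [DisulfidePattern-class]) and `bondProb` (probabilities
#'   of the retained bonds).
#' @export
predictChain <- function(predictor, chain) {
  if (!hasProfile(chain)) stop("chain has no profile attached")
  if (predictor@stateNet@nIn != encodingConfig(predictor@cfg$nnWindow)$stateLength ||
      predictor@connNet@nIn != encodingConfig(predictor@cfg$nnWindow)$pairLength)
    stop("compatibility error: network input sizes do not match the encoding config")
  st <- predictStates(predictor, chain)
  pairs <- enumerateCandidatePairs(st, predictor@cfg$minSeparation)
  pp <- pairProbabilities(predictor, chain, st, pairs)
  pat <- assignConnectivity(pp, predictor@cfg$minBondProb)
  structure(list(id = chainId(chain), state = st, pairs = pp,
                 pattern = pat, bondProb = attr(pat, "prob")),
            class = "ChainPrediction")
}

#' @export
print.ChainPrediction <- function(x, ...) {
  cat("Disulfide prediction for chain", x$id, "\n")
  cat("Bonding states (threshold", x$state$threshold, "):\n")
  st <- x$state$table
  for (r in seq_len(nrow(st)))
    cat(sprintf("  CYS(%d)  p(bonded) = %.2f  -> %s\n", st$pos[r], st$prob[r],
                if (st$bonded[r]) "bonded" else "free"))
  if (nrow(x$pairs)) {
    cat("Candidate pairs:\n")
    for (r in seq_len(nrow(x$pairs)))
      cat(sprintf("  CYS(%d)-CYS(%d)  p = %.2f\n",
                  x$pairs$i[r], x$pairs$j[r], x$pairs$prob[r]))
  }
  b <- bonds(x$pattern)
  if (nrow(b)) {
    cat("Final pattern:\n")
    for (r in seq_len(nrow(b)))
      cat(sprintf("  CYS(%d)-CYS(%d)  p = %.2f\n", b[r, 1], b[r, 2], x$bondProb[r]))
  } else cat("Final pattern: no disulfide bonds\n")
  invisible(x)
}

## ---- training --------------------------------------------------------------

## tableFor(i) returns the potential table used to score chain i's
## examples; at training time this is the jackknife table excluding the
## chain's own group, so encoded scores match the prediction-time
## distribution instead of memorising the chain's own contribution
.stateExamples <- function(chains, tableFor, cfg, center = NULL, scale = NULL) {
  if (is(tableFor, "PotentialTable")) {
    tab <- tableFor
    tableFor <- function(i) tab
  }
  labs <- integer(0); ids <- character(0); poss <- integer(0)
  rawScores <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    pos <- usableCys(ch)
    if (!length(pos)) next
    lab <- cysLabels(ch)
    P <- profileMatrix(ch)
    tab <- tableFor(ci)
    for (p in pos) rawScores[[length(rawScores) + 1L]] <- stateScores(tab, P, p)
    labs <- c(labs, unname(lab))
    ids <- c(ids, rep(chainId(ch), length(pos)))
    poss <- c(poss, pos)
  }
  if (!length(labs)) stop("no usable cysteines to encode")
  S <- do.call(rbind, rawScores)
  if (is.null(center)) {
    center <- colMeans(S)
    scale <- pmax(apply(S, 2, sd), 1e-8)
  }
  k <- 0L
  X <- matrix(0, length(labs), cfg$stateLength)
  for (ch in chains) {
    pos <- usableCys(ch)
    for (p in pos) {
      k <- k + 1L
      X[k, ] <- encodeStateInput(ch, p, S[k, 1], S[k, 2], cfg, center, scale)
    }
  }
  list(X = X, y = labs, chain = ids, pos = poss, center = center, scale = scale)
}

.connExamples <- function(chains, predictor = NULL, tableFor, cfg,
                          minSeparation = 2L, threshold = 0.5,
                          center = NULL, scale = NULL) {
  ## examples are pairs of truly bonded cysteines; the encoded state
  ## probabilities come from the trained first stage when available
  if (is(tableFor, "PotentialTable")) {
    tab <- tableFor
    tableFor <- function(i) tab
  }
  labs <- integer(0); ids <- character(0)
  raw <- list(); meta <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    b <- bonds(ch)
    bondedPos <- sort(unique(as.vector(b)))
    if (length(bondedPos) < 2L) next
    pairs <- enumerateCandidatePairs(bondedPos, minSeparation)
    if (!nrow(pairs)) next
    bondKey <- paste(b[, 1], b[, 2])
    sp <- if (!is.null(predictor)) predictStates(predictor, ch) else NULL
    P <- profileMatrix(ch)
    tab <- tableFor(ci)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      raw[[length(raw) + 1L]] <- pairScores(tab, P, i, j)
      pi <- if (is.null(sp)) c(1, 1)
            else setNames(sp$table$prob, sp$table$pos)[as.character(c(i, j))]
      meta[[length(meta) + 1L]] <- list(ch = ch, i = i, j = j, stateProbs = unname(pi))
      labs <- c(labs, as.integer(paste(i, j) %in% bondKey))
      ids <- c(ids, chainId(ch))
    }
  }
  if (!length(labs)) stop("no bonded cysteine pairs to encode")
  S <- do.call(rbind, raw)
  if (is.null(center)) {
    center <- colMeans(S)
    scale <- pmax(apply(S, 2, sd), 1e-8)
  }
  X <- matrix(0, length(labs), cfg$pairLength)
  for (k in seq_along(meta)) {
    m <- meta[[k]]
    X[k, ] <- encodePairInput(m$ch, m$i, m$j, m$stateProbs, S[k, ], cfg,
                              threshold, center, scale)
  }
  list(X = X, y = labs, chain = ids, center = center, scale = scale)
}

## combine additive statistics accumulated over disjoint chain groups
.sumStats <- function(parts, composition, nChains) {
  out <- parts[[1]]
  for (p in parts[-1]) {
    for (cl in out@classes) {
      out@firstNum[[cl]] <- out@firstNum[[cl]] + p@firstNum[[cl]]
      out@firstDen[[cl]] <- out@firstDen[[cl]] + p@firstDen[[cl]]
      out@secondNum[[cl]] <- out@secondNum[[cl]] + p@secondNum[[cl]]
      out@secondDen[[cl]] <- out@secondDen[[cl]] + p@secondDen[[cl]]
    }
    out@classWeight <- out@classWeight + p@classWeight
  }
  out@composition <- composition
  out@nChains <- as.integer(nChains)
  out
}

#' Train the full two-stage predictor
#'
#' Builds state and pair context statistics and potential tables on the
#' training chains, then trains the bonding-state network (100 hidden
#' nodes by default) and the connectivity network (150 hidden nodes by
#' default) on the encoded examples. Connectivity examples are pairs of
#' truly bonded cysteines; their encoded state probabilities come from the
#' freshly trained first stage.
#'
#' @param chains training chains (annotated, with profiles); the corpus
#'   filtering rules ([filterChains()]) are applied first.
#' @param K statistics window size (default 7).
#' @param nnWindow network window size (default 15).
#' @param stateHidden,connHidden hidden-layer sizes (defaults 100, 150).
#' @param seed master seed; sub-seeds for the two networks derive from it.
#' @param lambda,rt smoothing mass and energy scale for [buildPotentials()].
#' @param stateThreshold bonding-state decision threshold (default 0.5).
#' @param minBondProb final-pattern probability cutoff (default 0: keep
#'   all matched edges; see [assignConnectivity()]).
#' @param minSeparation minimum bond sequence separation (default 2).
#' @param negativeRatio negative-pair subsampling for the pair statistics
#'   (default `Inf` = all).
#' @param valChains optional held-out chains supplying the early-stopping
#'   validation examples (as in the N-fold rotation); when `NULL` a random
#'   fraction of the training examples is held out instead.
#' @param jackknifeGroups number of chain groups for jackknife feature
#'   generation: each training chain's context scores are computed from
#'   potential tables built on the other groups, so the encoded score
#'   distribution matches prediction time instead of memorising the
#'   chain's own contribution to the statistics (set 1 to disable).
#' @param stateArgs,connArgs lists of extra arguments to [trainNetwork()].
#' @return A [DisulfidePredictor-class].
#' @export
trainPredictor <- function(chains, K = 7L, nnWindow = 15L,
                           stateHidden = 100L, connHidden = 150L, seed = 1L,
                           lambda = 1, rt = 1, stateThreshold = 0.5,
                           minBondProb = 0, minSeparation = 2L,
                           negativeRatio = Inf, valChains = NULL,
                           jackknifeGroups = 10L,
                           stateArgs = list(), connArgs = list()) {
  chains <- filterChains(chains)
  if (!length(chains)) stop("no chains left after corpus filtering")
  ## the connectivity net feeds the matcher, which wants balanced
  ## calibration; the state net keeps prior calibration for its 0.5 cut
  connArgs <- utils::modifyList(list(classWeight = TRUE), connArgs)
  cfg <- encodingConfig(nnWindow)
  G <- max(1L, min(as.integer(jackknifeGroups), length(chains)))
  groupOf <- rep_len(seq_len(G), length(chains))
  comp <- .corpusComposition(chains)
  sParts <- lapply(seq_len(G), function(g)
    accumulateStateStatistics(chains[groupOf == g], K, .allowEmpty = TRUE))
  pParts <- lapply(seq_len(G), function(g)
    accumulatePairStatistics(chains[groupOf == g], K, minSeparation,
                             negativeRatio, seed = deriveSeed(seed, 5L + g),
                             .allowEmpty = TRUE))
  sstats <- .sumStats(sParts, comp, length(chains))
  pstats <- .sumStats(pParts, comp, length(chains))
  if (sum(sstats@classWeight) <= 0) stop("empty statistics: no usable cysteines in the corpus")
  if (sstats@classWeight["bonded"] <= 0 || pstats@classWeight["connected"] <= 0)
    stop("empty statistics: no bonded pairs in the corpus")
  stateTable <- buildPotentials(sstats, rt, lambda)
  pairTable <- buildPotentials(pstats, rt, lambda)
  ## leave-group-out tables for scoring each training group
  stateTabLOO <- pairTabLOO <- vector("list", G)
  for (g in seq_len(G)) {
    if (G == 1L) {
      stateTabLOO[[g]] <- stateTable
      pairTabLOO[[g]] <- pairTable
    } else {
      stateTabLOO[[g]] <- buildPotentials(
        .sumStats(sParts[-g], comp, length(chains)), rt, lambda)
      pairTabLOO[[g]] <- buildPotentials(
        .sumStats(pParts[-g], comp, length(chains)), rt, lambda)
    }
  }

  se <- .stateExamples(chains, function(i) stateTabLOO[[groupOf[i]]], cfg)
  stateVal <- if (!is.null(valChains) && length(valChains))
    .stateExamples(valChains, stateTable, cfg, se$center, se$scale)
  stateNet <- do.call(trainNetwork, c(list(
    X = se$X, y = se$y, nHidden = stateHidden, seed = deriveSeed(seed, 1L),
    valX = stateVal$X, valY = stateVal$y), stateArgs))

  predictor <- new("DisulfidePredictor",
    stateNet = stateNet, connNet = new("FeedForwardNet",
      nIn = cfg$pairLength, nHidden = 1L,
      W1 = matrix(0, 1, cfg$pairLength), b1 = 0, W2 = matrix(0, 1, 1), b2 = 0,
      seed = 0L, history = data.frame()),
    stateTable = stateTable, pairTable = pairTable,
    cfg = list(K = K, nnWindow = nnWindow, stateThreshold = stateThreshold,
               minBondProb = minBondProb, minSeparation = minSeparation),
    stateScoreCenter = se$center, stateScoreScale = se$scale,
    pairScoreCenter = c(0, 0), pairScoreScale = c(1, 1))

  ce <- .connExamples(chains, predictor, function(i) pairTabLOO[[groupOf[i]]],
                      cfg, minSeparation, stateThreshold)
  connVal <- if (!is.null(valChains) && length(valChains)) {
    ok <- any(vapply(valChains, function(ch) nrow(bonds(ch)) > 0, TRUE))
    if (ok) tryCatch(.connExamples(valChains, predictor, pairTable, cfg,
                                   minSeparation, stateThreshold,
                                   ce$center, ce$scale), error = function(e) NULL)
  }
  connNet <- do.call(trainNetwork, c(list(
    X = ce$X, y = ce$y, nHidden = connHidden, seed = deriveSeed(seed, 2L),
    valX = connVal$X, valY = connVal$y), connArgs))

  predictor@connNet <- connNet
  predictor@pairScoreCenter <- ce$center
  predictor@pairScoreScale <- ce$scale
  predictor
}
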