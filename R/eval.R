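#' Binary classification metrics from a count table
#'
#' Sensitivity `Sn = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)` and
#' Matthews correlation coefficient
#' `Mcc = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' an error.
#'
#' @param tp,tn,fp,fn non-negative counts; alternatively pass a single
#'   named vector/list as `tp`.
#' @return named list with `Sn`, `Sp`, `Mcc`.
#' @examples
#' computeMetrics(tp = 3, tn = 8, fp = 2, fn = 1)
#' @export
computeMetrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    c0 <- as.list(tp)
    names(c0) <- tolower(names(c0))
    tp <- c0$tp; tn <- c0$tn; fp <- c0$fp; fn <- c0$fn
  }
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  ## double arithmetic: the Mcc denominator overflows integer counts
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fn * fp) / sqrt(den) else NA_real_
  list(Sn = sn, Sp = sp, Mcc = mcc)
}

#' Residue-level and protein-level accuracy
#'
#' `Qc` is the pooled fraction of correctly classified cysteines over all
#' chains; `Qp` is the fraction of chains whose cysteines are all
#' correctly classified. `Qp <= Qc` always.
#'
#' @param truth,pred lists of equal length; element `i` holds the 0/1
#'   labels of chain `i`'s cysteines (same order in both lists).
#' @return named list with `Qc`, `Qp` (NA markers for empty input).
#' @export
computeQMetrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (!length(truth)) return(list(Qc = NA_real_, Qp = NA_real_))
  nc <- 0L; pc <- 0L; np <- 0L; pp <- 0L
  for (i in seq_along(truth)) {
    t0 <- as.integer(truth[[i]]); p0 <- as.integer(pred[[i]])
    stopifnot(length(t0) == length(p0))
    if (!length(t0)) next
    nc <- nc + length(t0)
    pc <- pc + sum(t0 == p0)
    np <- np + 1L
    if (all(t0 == p0)) pp <- pp + 1L
  }
  list(Qc = if (nc > 0) pc / nc else NA_real_,
       Qp = if (np > 0) pp / np else NA_real_)
}

#' Chain-level N-fold cross-validation split with role rotation
#'
#' Partitions the chains into N near-equal subsets (sizes differing by at
#' most one). In fold t, subset t is the test set, the cyclically
#' following subset is the validation set (used for neural-network early
#' stopping) and the remaining N - 2 subsets are the training set, so each
#' chain is tested exactly once. The partition is deterministic given the
#' seed and independent of the input order (chains are sorted by id before
#' the seeded shuffle).
#'
#' @param ids character vector of chain ids (or a list of chains).
#' @param N number of folds, at least 3.
#' @param seed integer seed.
#' @return list of N folds, each a list with integer index vectors
#'   `train`, `validation`, `test` (indices into the input order).
#' @export
kfoldSplit <- function(ids, N, seed = 1L) {
  if (is.list(ids)) ids <- vapply(ids, chainId, "")
  N <- as.integer(N)
  if (is.na(N) || N < 3L) stop("N must be at least 3 (train/validation/test roles)")
  if (length(ids) < N) stop("need at least N chains")
  ord <- order(ids)
  shuffled <- withLocalSeed(seed, sample(ord))
  subset <- rep(seq_len(N), length.out = length(ids))
  membership <- split(shuffled, subset)
  lapply(seq_len(N), function(t) {
    testS <- t
    valS <- t %% N + 1L
    list(train = sort(unlist(membership[-c(testS, valS)], use.names = FALSE)),
         validation = sort(membership[[valS]]),
         test = sort(membership[[testS]]))
  })
}

.stateMetricsForChains <- function(predictor, chains) {
  truth <- list(); pred <- list()
  tp <- tn <- fp <- fn <- 0L
  for (ch in chains) {
    pos <- usableCys(ch)
    if (!length(pos)) next
    lab <- cysLabels(ch)
    sp <- predictStates(predictor, ch)
    phat <- setNames(sp$table$bonded, sp$table$pos)[as.character(pos)]
    truth[[length(truth) + 1L]] <- unname(lab)
    pred[[length(pred) + 1L]] <- as.integer(phat)
    tp <- tp + sum(lab == 1 & phat); fn <- fn + sum(lab == 1 & !phat)
    tn <- tn + sum(lab == 0 & !phat); fp <- fp + sum(lab == 0 & phat)
  }
  c(computeMetrics(tp = tp, tn = tn, fp = fp, fn = fn),
    computeQMetrics(truth, pred))
}

.connMetricsForChains <- function(predictor, chains) {
  ## pair-level counts over candidate pairs of truly bonded cysteines,
  ## positives = pairs retained in the predicted pattern
  tp <- tn <- fp <- fn <- 0L
  recovered <- 0L; plantedOnCorrect <- 0L; allStatesCorrect <- 0L; nChains <- 0L
  for (ch in chains) {
    b <- bonds(ch)
    if (!nrow(b)) next
    nChains <- nChains + 1L
    res <- predictChain(predictor, ch)
    predB <- bonds(res$pattern)
    predKey <- if (nrow(predB)) paste(predB[, 1], predB[, 2]) else character(0)
    bondKey <- paste(b[, 1], b[, 2])
    bondedPos <- sort(unique(as.vector(b)))
    pairs <- enumerateCandidatePairs(bondedPos, predictor@cfg$minSeparation)
    if (nrow(pairs)) {
      key <- paste(pairs[, 1], pairs[, 2])
      isBond <- key %in% bondKey
      isPred <- key %in% predKey
      tp <- tp + sum(isBond & isPred); fn <- fn + sum(isBond & !isPred)
      tn <- tn + sum(!isBond & !isPred); fp <- fp + sum(!isBond & isPred)
    }
    ## planted-bond recovery restricted to chains with all states correct
    lab <- cysLabels(ch)
    sp <- res$state
    phat <- setNames(sp$table$bonded, sp$table$pos)[as.character(usableCys(ch))]
    if (all(as.integer(phat) == unname(lab))) {
      allStatesCorrect <- allStatesCorrect + 1L
      plantedOnCorrect <- plantedOnCorrect + length(bondKey)
      recovered <- recovered + sum(bondKey %in% predKey)
    }
  }
  c(computeMetrics(tp = tp, tn = tn, fp = fp, fn = fn),
    list(Qc = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else NA_real_,
         bondRecovery = if (plantedOnCorrect > 0) recovered / plantedOnCorrect else NA_real_,
         chainsAllStatesCorrect = allStatesCorrect, chainsWithBonds = nChains))
}

#' N-fold cross-validation of the two-stage predictor
#'
#' For each fold, a predictor is trained on the N - 2 training subsets
#' (with the validation subset driving early stopping) and evaluated on
#' the test subset. The overall row is the unweighted mean of the per-fold
#' metrics; a fold whose Sn (or other metric) is undefined is excluded
#' from that metric's mean with a warning.
#'
#' @param chains annotated chains with profiles.
#' @param N number of folds (default 5).
#' @param seed integer seed (fold assignment and per-fold training).
#' @param connectivity also evaluate stage-2 pair metrics (slower).
#' @param ... passed to [trainPredictor()].
#' @return list with `perFold` (data frame, one row per fold) and
#'   `average` (named numeric vector).
#' @export
crossValidate <- function(chains, N = 5L, seed = 1L, connectivity = FALSE, ...) {
  folds <- kfoldSplit(chains, N, seed)
  rows <- list()
  for (t in seq_along(folds)) {
    f <- folds[[t]]
    predictor <- trainPredictor(chains[f$train], seed = deriveSeed(seed, 10L + t),
                                valChains = chains[f$validation], ...)
    m <- .stateMetricsForChains(predictor, chains[f$test])
    row <- data.frame(fold = t, Sn = m$Sn, Sp = m$Sp, Mcc = m$Mcc,
                      Qc = m$Qc, Qp = m$Qp)
    if (connectivity) {
      cm <- .connMetricsForChains(predictor, chains[f$test])
      row$connSn <- cm$Sn; row$connSp <- cm$Sp; row$connQc <- cm$Qc
      row$bondRecovery <- cm$bondRecovery
    }
    rows[[t]] <- row
  }
  perFold <- do.call(rbind, rows)
  metricCols <- setdiff(names(perFold), "fold")
  avg <- vapply(metricCols, function(cl) {
    v <- perFold[[cl]]
    if (anyNA(v)) {
      warning("fold(s) with undefined ", cl, " excluded from the average")
      v <- v[!is.na(v)]
    }
    if (length(v)) mean(v) else NA_real_
  }, 0)
  list(perFold = perFold, average = avg)
}
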