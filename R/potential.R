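#' Build mean-force potential tables from context statistics
#'
#' Converts smoothed observed/reference probabilities into pseudo-energies
#' via the inverse-Boltzmann relation. First order:
#' `U1(R, k | class) = -RT * ln( Pobs(class | R(k)) / Pref(R(k)) )`.
#' Second order uses the symmetric correction that isolates the genuine
#' two-neighbour effect and vanishes when the two positions are
#' independent:
#' `U2 = -RT * ln[ Pobs2 * Pref1(k1) * Pref1(k2) /
#'                (Pref2 * Pobs1(k1) * Pobs1(k2)) ]`.
#'
#' @param stats a [ContextStatistics-class] (state or pair kind).
#' @param rt energy scale constant RT (default 1; the absolute scale is
#'   absorbed by the downstream network weights).
#' @param lambda pseudocount mass passed to [smoothedProb()].
#' @return A [PotentialTable-class].
#' @export
buildPotentials <- function(stats, rt = 1, lambda = 1) {
  stopifnot(rt > 0, lambda > 0)
  sm <- smoothedProb(stats, lambda)
  classes <- stats@classes
  idx <- stats@secondIndex
  ## columns of the first-order table addressed by each second-order pair
  if (stats@kind == "state") {
    offs <- enumerateFirstOrderOffsets(stats@K)
    op <- enumerateSecondOrderOffsetPairs(stats@K)
    colA <- match(op[, 1], offs)
    colB <- match(op[, 2], offs)
  } else {
    ps <- enumeratePairOffsetSlots(stats@K)
    orb <- ps$orbits
    colA <- orb$u
    colB <- orb$v
  }
  first <- second <- list()
  for (cl in classes) {
    first[[cl]] <- -rt * log(sm$first[[cl]] / sm$first$ref)
    sArr <- sm$second[[cl]]
    out <- sArr
    for (p in seq_len(dim(sArr)[3])) {
      fObsA <- sm$first[[cl]][, colA[p]]
      fObsB <- sm$first[[cl]][, colB[p]]
      fRefA <- sm$first$ref[, colA[p]]
      fRefB <- sm$first$ref[, colB[p]]
      out[, , p] <- -rt * log(
        (sArr[, , p] * (fRefA %o% fRefB)) /
        (sm$second$ref[, , p] * (fObsA %o% fObsB)))
    }
    second[[cl]] <- out
  }
  new("PotentialTable", kind = stats@kind, K = stats@K, classes = classes,
      first = first, second = second, secondIndex = idx,
      rt = rt, lambda = lambda, composition = stats@composition)
}

.profileRow <- function(profile, p) {
  if (p >= 1L && p <= nrow(profile)) profile[p, ] else NULL
}

#' Context score of a cysteine for a bonding-state class
#'
#' The overall mean-force potential of the cysteine's neighbourhood: the
#' profile-expected sum of all first-order potentials over the window's
#' offsets plus all second-order potentials over offset pairs. Offsets
#' truncated by the chain termini are skipped.
#'
#' @param table a state-kind [PotentialTable-class].
#' @param profile positions x 20 profile matrix.
#' @param pos 1-based cysteine position.
#' @param class `"bonded"` or `"free"`.
#' @return scalar energy (units of RT); lower = more favourable.
#' @export
stateScore <- function(table, profile, pos, class) {
  stopifnot(table@kind == "state", class %in% table@classes)
  if (pos < 1L || pos > nrow(profile)) stop("position out of range")
  offs <- enumerateFirstOrderOffsets(table@K)
  rows <- lapply(offs, function(k) .profileRow(profile, pos + k))
  score <- 0
  F1 <- table@first[[class]]
  for (s in seq_along(offs)) {
    if (!is.null(rows[[s]])) score <- score + sum(rows[[s]] * F1[, s])
  }
  S2 <- table@second[[class]]
  idx <- table@secondIndex
  offIdx <- match(idx$k1, offs)
  offIdx2 <- match(idx$k2, offs)
  for (p in seq_len(nrow(idx))) {
    r1 <- rows[[offIdx[p]]]; r2 <- rows[[offIdx2[p]]]
    if (!is.null(r1) && !is.null(r2))
      score <- score + as.numeric(r1 %*% S2[, , p] %*% r2)
  }
  score
}

#' Both state scores of a cysteine
#' @inheritParams stateScore
#' @return named numeric vector `c(bonded = , free = )`.
#' @export
stateScores <- function(table, profile, pos) {
  vapply(setNames(table@classes, table@classes),
         function(cl) stateScore(table, profile, pos, cl), 0)
}

#' Context score of a cysteine pair for a connectivity class
#'
#' Profile-expected sum of first-order potentials over the 2(K - 1)
#' neighbour slots of the pair and of second-order potentials over all
#' slot-pairs (each evaluated with its symmetry-orbit table). Symmetric in
#' the two positions; slots truncated by the termini are skipped.
#'
#' @param table a pair-kind [PotentialTable-class].
#' @param profile positions x 20 profile matrix.
#' @param posI,posJ distinct 1-based cysteine positions.
#' @param class `"connected"` or `"unconnected"`.
#' @return scalar energy (units of RT).
#' @export
pairScore <- function(table, profile, posI, posJ, class) {
  stopifnot(table@kind == "pair", class %in% table@classes)
  if (posI == posJ) stop("pair positions must be distinct")
  i <- min(posI, posJ); j <- max(posI, posJ)
  if (i < 1L || j > nrow(profile)) stop("position out of range")
  ps <- enumeratePairOffsetSlots(table@K)
  anchors <- ifelse(ps$slots$cys == 1L, i, j)
  rows <- lapply(seq_len(nrow(ps$slots)), function(s)
    .profileRow(profile, anchors[s] + ps$slots$offset[s]))
  score <- 0
  F1 <- table@first[[class]]
  for (s in seq_along(rows))
    if (!is.null(rows[[s]])) score <- score + sum(rows[[s]] * F1[, s])
  S2 <- table@second[[class]]
  sp <- ps$slotPairs
  for (p in seq_len(nrow(sp))) {
    r1 <- rows[[sp$u[p]]]; r2 <- rows[[sp$v[p]]]
    if (is.null(r1) || is.null(r2)) next
    M <- S2[, , sp$orbit[p]]
    if (sp$flip[p]) M <- t(M)
    score <- score + as.numeric(r1 %*% M %*% r2)
  }
  score
}

#' Both pair scores of a cysteine pair
#' @inheritParams pairScore
#' @return named numeric vector `c(connected = , unconnected = )`.
#' @export
pairScores <- function(table, profile, posI, posJ) {
  vapply(setNames(table@classes, table@classes),
         function(cl) pairScore(table, profile, posI, posJ, cl), 0)
}
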