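# Independent brute-force oracles and tiny fixture builders. All oracles are
# literal transcriptions (plain loops / enumerations), deliberately kept free
# of the package's vectorised code paths.

AA20 <- CysBond::AA_ALPHABET20

oneHotProfile <- function(seq) {
  letters20 <- strsplit(seq, "")[[1]]
  P <- matrix(0, length(letters20), 20, dimnames = list(NULL, AA20))
  for (i in seq_along(letters20)) {
    if (letters20[i] %in% AA20) P[i, letters20[i]] <- 1 else P[i, ] <- 1 / 20
  }
  P
}

uniformProfile <- function(seq) {
  L <- nchar(seq)
  matrix(1 / 20, L, 20, dimnames = list(NULL, AA20))
}

toyChain <- function(id, seq, bonds = NULL, profile = c("onehot", "uniform", "random"),
                     excluded = integer(0)) {
  profile <- match.arg(profile)
  P <- switch(profile,
    onehot = oneHotProfile(seq),
    uniform = uniformProfile(seq),
    random = {
      g <- matrix(rgamma(nchar(seq) * 20, shape = 0.5), nchar(seq), 20)
      g <- g / rowSums(g)
      colnames(g) <- AA20
      g
    })
  annotatedChain(id, seq, profile = P, bonds = bonds, excludedCys = excluded)
}

# ---- statistics oracles (plain triple loops) --------------------------------

# first/second-order state statistics by direct looping over chains,
# cysteines, offsets and residue types
bruteStateStats <- function(chains, K) {
  offs <- setdiff(seq.int(-(K - 1) / 2, (K - 1) / 2), 0)
  op <- t(combn(offs, 2))
  init <- function() list(
    n1 = matrix(0, 20, length(offs), dimnames = list(AA20, NULL)),
    d1 = numeric(length(offs)),
    n2 = array(0, c(20, 20, nrow(op)), dimnames = list(AA20, AA20, NULL)),
    d2 = numeric(nrow(op)))
  acc <- list(bonded = init(), free = init())
  for (ch in chains) {
    P <- profileMatrix(ch)
    L <- nrow(P)
    lab <- cysLabels(ch)
    for (ci in seq_along(lab)) {
      i <- as.integer(names(lab)[ci])
      cl <- if (lab[ci] == 1) "bonded" else "free"
      w <- P[i, "C"]
      for (s in seq_along(offs)) {
        p <- i + offs[s]
        if (p >= 1 && p <= L) {
          acc[[cl]]$n1[, s] <- acc[[cl]]$n1[, s] + w * P[p, ]
          acc[[cl]]$d1[s] <- acc[[cl]]$d1[s] + w
        }
      }
      for (r in seq_len(nrow(op))) {
        p1 <- i + op[r, 1]; p2 <- i + op[r, 2]
        if (p1 >= 1 && p1 <= L && p2 >= 1 && p2 <= L) {
          acc[[cl]]$n2[, , r] <- acc[[cl]]$n2[, , r] + w * (P[p1, ] %o% P[p2, ])
          acc[[cl]]$d2[r] <- acc[[cl]]$d2[r] + w
        }
      }
    }
  }
  acc
}

# pair statistics by direct looping; slots are (cys index, offset) with
# cys 1 = N-terminal member, second-order folded into swap-symmetry orbits
brutePairStats <- function(chains, K, minSeparation = 2) {
  ps <- enumeratePairOffsetSlots(K)
  nS <- nrow(ps$slots)
  nO <- nrow(ps$orbits)
  init <- function() list(
    n1 = matrix(0, 20, nS, dimnames = list(AA20, NULL)), d1 = numeric(nS),
    n2 = array(0, c(20, 20, nO), dimnames = list(AA20, AA20, NULL)), d2 = numeric(nO))
  acc <- list(connected = init(), unconnected = init())
  for (ch in chains) {
    P <- profileMatrix(ch)
    L <- nrow(P)
    b <- bonds(ch)
    bondKey <- if (nrow(b)) paste(b[, 1], b[, 2]) else character(0)
    pos <- usableCys(ch)
    if (length(pos) < 2) next
    prs <- t(combn(pos, 2))
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1]; j <- prs[r, 2]
      isBond <- paste(i, j) %in% bondKey
      if (!isBond && j - i < minSeparation) next
      cl <- if (isBond) "connected" else "unconnected"
      w <- P[i, "C"] * P[j, "C"]
      slotPos <- ifelse(ps$slots$cys == 1, i, j) + ps$slots$offset
      for (s in seq_len(nS)) {
        p <- slotPos[s]
        if (p >= 1 && p <= L) {
          acc[[cl]]$n1[, s] <- acc[[cl]]$n1[, s] + w * P[p, ]
          acc[[cl]]$d1[s] <- acc[[cl]]$d1[s] + w
        }
      }
      for (q in seq_len(nrow(ps$slotPairs))) {
        u <- ps$slotPairs$u[q]; v <- ps$slotPairs$v[q]
        o <- ps$slotPairs$orbit[q]
        pu <- slotPos[u]; pv <- slotPos[v]
        if (pu >= 1 && pu <= L && pv >= 1 && pv <= L) {
          contrib <- w * (P[pu, ] %o% P[pv, ])
          if (ps$slotPairs$flip[q]) contrib <- t(contrib)
          acc[[cl]]$n2[, , o] <- acc[[cl]]$n2[, , o] + contrib
          acc[[cl]]$d2[o] <- acc[[cl]]$d2[o] + w
        }
      }
    }
  }
  acc
}

# ---- potential / scoring oracles --------------------------------------------

# profile-expected sum of first- and second-order potentials, plain loops
bruteStateScore <- function(table, P, pos, class) {
  offs <- enumerateFirstOrderOffsets(table@K)
  op <- enumerateSecondOrderOffsetPairs(table@K)
  L <- nrow(P)
  total <- 0
  for (s in seq_along(offs)) {
    p <- pos + offs[s]
    if (p < 1 || p > L) next
    for (a in 1:20) total <- total + P[p, a] * table@first[[class]][a, s]
  }
  for (r in seq_len(nrow(op))) {
    p1 <- pos + op[r, 1]; p2 <- pos + op[r, 2]
    if (p1 < 1 || p1 > L || p2 < 1 || p2 > L) next
    for (a in 1:20) for (b in 1:20)
      total <- total + P[p1, a] * P[p2, b] * table@second[[class]][a, b, r]
  }
  unname(total)
}

brutePairScore <- function(table, P, i, j, class) {
  ii <- min(i, j); jj <- max(i, j)
  ps <- enumeratePairOffsetSlots(table@K)
  L <- nrow(P)
  slotPos <- ifelse(ps$slots$cys == 1, ii, jj) + ps$slots$offset
  total <- 0
  for (s in seq_len(nrow(ps$slots))) {
    p <- slotPos[s]
    if (p < 1 || p > L) next
    for (a in 1:20) total <- total + P[p, a] * table@first[[class]][a, s]
  }
  for (q in seq_len(nrow(ps$slotPairs))) {
    pu <- slotPos[ps$slotPairs$u[q]]; pv <- slotPos[ps$slotPairs$v[q]]
    if (pu < 1 || pu > L || pv < 1 || pv > L) next
    M <- table@second[[class]][, , ps$slotPairs$orbit[q]]
    if (ps$slotPairs$flip[q]) M <- t(M)
    for (a in 1:20) for (b in 1:20)
      total <- total + P[pu, a] * P[pv, b] * M[a, b]
  }
  unname(total)
}

# ---- matching oracle --------------------------------------------------------

# exhaustive enumeration of all matchings of an edge list; returns the best
# total weight and one optimal edge set
enumMatchings <- function(edges) {
  # edges: data.frame(i, j, prob)
  best <- list(weight = 0, sel = integer(0))
  n <- nrow(edges)
  recurse <- function(idx, used, weight, sel) {
    if (weight > best$weight + 1e-12) best <<- list(weight = weight, sel = sel)
    if (idx > n) return()
    for (k in idx:n) {
      a <- edges$i[k]; b <- edges$j[k]
      if (!(a %in% used) && !(b %in% used))
        recurse(k + 1, c(used, a, b), weight + edges$prob[k], c(sel, k))
    }
  }
  recurse(1, integer(0), 0, integer(0))
  best
}

# ---- misc -------------------------------------------------------------------

# literal transcription of the standard metric formulas
oracleMetrics <- function(tp, tn, fp, fn) {
  list(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
       Mcc = (tp * tn - fn * fp) /
         sqrt((tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)))
}

# manual forward pass of a 2-2-1 logistic network
manualForward <- function(W1, b1, W2, b2, x) {
  h <- 1 / (1 + exp(-(W1 %*% x + b1)))
  as.numeric(1 / (1 + exp(-(W2 %*% h + b2))))
}

# random small corpus with all-distant cysteines (full window coverage)
randomToyCorpus <- function(nChains = 4, L = 40, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(nChains), function(c0) {
      s <- sample(setdiff(AA20, "C"), L, replace = TRUE)
      cysAt <- sort(sample(8:(L - 8), 4))
      # keep cysteines >= 4 apart so windows never collide ambiguously
      while (min(diff(cysAt)) < 4) cysAt <- sort(sample(8:(L - 8), 4))
      s[cysAt] <- "C"
      b <- if (c0 %% 2 == 0) rbind(cysAt[c(1, 3)]) else rbind(cysAt[c(1, 2)], cysAt[c(3, 4)])
      toyChain(sprintf("toy%02d", c0), paste(s, collapse = ""),
               bonds = b, profile = "random")
    })
  })
}
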