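# helper: statistics with a single class populated -> obs == ref exactly
allBondedStats <- function(seed = 3) {
  withr::with_seed(seed, {
    chains <- lapply(1:3, function(c0) {
      s <- sample(setdiff(AA20, "C"), 44, replace = TRUE)
      cysAt <- c(10, 18, 26, 34)
      s[cysAt] <- "C"
      toyChain(sprintf("ab%d", c0), paste(s, collapse = ""),
               bonds = rbind(cysAt[1:2], cysAt[3:4]), profile = "random")
    })
  })
  accumulateStateStatistics(chains, 7)
}

test_that("observed == reference gives exactly zero potentials", {
  st <- allBondedStats()
  tab <- buildPotentials(st, rt = 1, lambda = 1)
  expect_true(all(tab@first$bonded == 0))
  expect_true(all(tab@second$bonded == 0))
})

test_that("potentials equal the log-ratio recomputation oracle", {
  chains <- randomToyCorpus(nChains = 5, L = 44, seed = 17)
  for (stats in list(accumulateStateStatistics(chains, 7),
                     accumulatePairStatistics(chains, 7))) {
    tab <- buildPotentials(stats, rt = 1, lambda = 1)
    sm <- smoothedProb(stats, 1)
    for (cl in stats@classes) {
      expect_lt(max(abs(tab@first[[cl]] - (-log(sm$first[[cl]] / sm$first$ref)))), 1e-12)
      for (p in seq_len(dim(sm$second[[cl]])[3])) {
        # second order: symmetric correction against the factorized baseline
        if (stats@kind == "state") {
          offs <- enumerateFirstOrderOffsets(7)
          op <- enumerateSecondOrderOffsetPairs(7)
          cA <- match(op[p, 1], offs); cB <- match(op[p, 2], offs)
        } else {
          orb <- enumeratePairOffsetSlots(7)$orbits
          cA <- orb$u[p]; cB <- orb$v[p]
        }
        expected <- -log(sm$second[[cl]][, , p] *
                           (sm$first$ref[, cA] %o% sm$first$ref[, cB]) /
                         (sm$second$ref[, , p] *
                           (sm$first[[cl]][, cA] %o% sm$first[[cl]][, cB])))
        expect_lt(max(abs(tab@second[[cl]][, , p] - expected)), 1e-12)
      }
    }
  }
})

test_that("an e-fold observed enrichment gives potential -1 at rt = 1", {
  st <- allBondedStats()
  # duplicate the single class into two equal ones (potentials all zero),
  # then scale the bonded numerator at one entry so that obs = e * ref
  st2 <- st
  st2@firstNum$free <- st@firstNum$bonded
  st2@firstDen$free <- st@firstDen$bonded
  st2@secondNum$free <- st@secondNum$bonded
  st2@secondDen$free <- st@secondDen$bonded
  st2@classWeight["free"] <- st2@classWeight["bonded"]
  tab0 <- buildPotentials(st2, rt = 1, lambda = 1e-9)
  expect_lt(max(abs(tab0@first$bonded)), 1e-6)
  # unequal class masses: free = alpha * bonded numerators over 9x the
  # denominator makes obs(bonded)/ref = 10/(1 + alpha) = e at every entry
  alpha <- 10 / exp(1) - 1
  st2@firstNum$free <- alpha * st2@firstNum$bonded
  st2@firstDen$free <- 9 * st2@firstDen$bonded
  tab1 <- buildPotentials(st2, rt = 1, lambda = 1e-9)
  expect_lt(max(abs(tab1@first$bonded - (-1))), 1e-5)
  expect_true(all(tab1@first$free > 0))
})

test_that("increasing an observed entry decreases its first-order potential", {
  chains <- randomToyCorpus(nChains = 4, L = 44, seed = 23)
  st <- accumulateStateStatistics(chains, 7)
  tab1 <- buildPotentials(st)
  st@firstNum$bonded["C", 3] <- st@firstNum$bonded["C", 3] + 0.5
  tab2 <- buildPotentials(st)
  expect_lt(tab2@first$bonded["C", 3], tab1@first$bonded["C", 3])
})

test_that("state scores: zero table, one-hot collapse, brute-force oracle", {
  chains <- randomToyCorpus(nChains = 4, L = 44, seed = 29)
  st <- accumulateStateStatistics(chains, 7)
  tab <- buildPotentials(st)

  zero <- tab
  zero@first <- lapply(zero@first, function(m) m * 0)
  zero@second <- lapply(zero@second, function(a) a * 0)
  P <- profileMatrix(chains[[1]])
  pos <- usableCys(chains[[1]])[2]
  expect_equal(stateScore(zero, P, pos, "bonded"), 0)

  # one-hot profile: the expectation collapses to a plain sum of entries
  seq1 <- chainSeq(chains[[1]])
  Po <- oneHotProfile(seq1)
  offs <- enumerateFirstOrderOffsets(7)
  op <- enumerateSecondOrderOffsetPairs(7)
  letters20 <- strsplit(seq1, "")[[1]]
  plain <- 0
  for (s in seq_along(offs)) {
    p <- pos + offs[s]
    if (p >= 1 && p <= nchar(seq1)) plain <- plain + tab@first$bonded[letters20[p], s]
  }
  for (r in seq_len(nrow(op))) {
    p1 <- pos + op[r, 1]; p2 <- pos + op[r, 2]
    if (p1 >= 1 && p2 <= nchar(seq1) && p1 <= nchar(seq1) && p2 >= 1)
      plain <- plain + tab@second$bonded[letters20[p1], letters20[p2], r]
  }
  expect_equal(stateScore(tab, Po, pos, "bonded"), unname(plain), tolerance = 1e-9)

  # random profile vs brute-force double/triple loop
  for (cl in c("bonded", "free")) {
    expect_equal(stateScore(tab, P, pos, cl),
                 bruteStateScore(tab, P, pos, cl), tolerance = 1e-9)
  }
  # near-terminus position exercises the truncation path
  expect_equal(stateScore(tab, P, usableCys(chains[[1]])[1], "bonded"),
               bruteStateScore(tab, P, usableCys(chains[[1]])[1], "bonded"),
               tolerance = 1e-9)
})

test_that("pair scores: zero table, symmetry, brute-force oracle", {
  chains <- randomToyCorpus(nChains = 4, L = 44, seed = 31)
  ps <- accumulatePairStatistics(chains, 7)
  tab <- buildPotentials(ps)
  P <- profileMatrix(chains[[2]])
  cy <- usableCys(chains[[2]])
  i <- cy[1]; j <- cy[3]

  zero <- tab
  zero@first <- lapply(zero@first, function(m) m * 0)
  zero@second <- lapply(zero@second, function(a) a * 0)
  expect_equal(pairScore(zero, P, i, j, "connected"), 0)

  expect_equal(pairScore(tab, P, i, j, "connected"),
               pairScore(tab, P, j, i, "connected"), tolerance = 1e-12)
  expect_error(pairScore(tab, P, i, i, "connected"), "distinct")

  for (cl in c("connected", "unconnected")) {
    expect_equal(pairScore(tab, P, i, j, cl),
                 brutePairScore(tab, P, i, j, cl), tolerance = 1e-9)
  }
})

test_that("scores scale linearly in rt", {
  chains <- randomToyCorpus(nChains = 3, L = 44, seed = 37)
  st <- accumulateStateStatistics(chains, 7)
  t1 <- buildPotentials(st, rt = 1)
  t3 <- buildPotentials(st, rt = 3)
  P <- profileMatrix(chains[[1]])
  pos <- usableCys(chains[[1]])[2]
  expect_equal(stateScore(t3, P, pos, "bonded"),
               3 * stateScore(t1, P, pos, "bonded"), tolerance = 1e-9)
})

test_that("all potentials are finite even for sparse corpora", {
  ch <- toyChain("sparse", "AAACAAAACAAAACAAAA", bonds = rbind(c(4L, 9L)),
                 profile = "onehot")
  st <- accumulateStateStatistics(list(ch), 7)
  tab <- buildPotentials(st)
  expect_true(all(is.finite(unlist(tab@first))))
  expect_true(all(is.finite(unlist(tab@second))))
})
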