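test_that("first-order offsets enumerate the K-1 nonzero window positions", {
  expect_equal(enumerateFirstOrderOffsets(7), c(-3, -2, -1, 1, 2, 3))
  expect_length(enumerateFirstOrderOffsets(15), 14)
  expect_equal(enumerateFirstOrderOffsets(1), integer(0))
  expect_error(enumerateFirstOrderOffsets(6), "odd")
  expect_error(enumerateFirstOrderOffsets(-3), "odd integer")
})

test_that("second-order offset pairs are the choose(K-1, 2) combinations", {
  expect_equal(unname(enumerateSecondOrderOffsetPairs(3)), rbind(c(-1, 1)))
  # frozen by brute-force enumeration of C(6,2) and C(14,2)
  expect_equal(nrow(enumerateSecondOrderOffsetPairs(7)), 15)
  expect_equal(nrow(enumerateSecondOrderOffsetPairs(15)), 91)
  # geometry covers both-left, straddling, both-right
  op <- enumerateSecondOrderOffsetPairs(7)
  expect_true(any(op[, 1] < 0 & op[, 2] < 0))
  expect_true(any(op[, 1] < 0 & op[, 2] > 0))
  expect_true(any(op[, 1] > 0 & op[, 2] > 0))
})

test_that("pair slots and swap-symmetry orbits have the expected counts", {
  ps3 <- enumeratePairOffsetSlots(3)
  expect_equal(nrow(ps3$slots), 4)       # 2(K-1)
  expect_equal(nrow(ps3$orbits), 4)      # frozen: C(4,2)=6 pairs, 2 fixed, (6+2)/2
  ps7 <- enumeratePairOffsetSlots(7)
  expect_equal(nrow(ps7$slots), 12)
  expect_equal(nrow(ps7$orbits), 36)     # frozen: (C(12,2)=66 + 6 fixed)/2
  # orbit sizes account for every slot-pair exactly once
  expect_equal(sum(ps7$orbits$size), 66)
  # every slot-pair maps to a valid orbit
  expect_true(all(ps7$slotPairs$orbit %in% seq_len(36)))
})

test_that("a single bonded cysteine with one-hot profiles gives indicator statistics", {
  #      123456
  ch <- toyChain("t", "AACSAC", bonds = rbind(c(3L, 6L)), profile = "onehot")
  st <- accumulateStateStatistics(list(ch), 3)
  obs <- obsProb(st, 1, "bonded")
  offs <- enumerateFirstOrderOffsets(3)
  kPlus1 <- match(1, offs)
  # neighbour of CYS3 at +1 is S; CYS6's +1 neighbour is truncated by the
  # C-terminus, so it contributes to neither numerator nor denominator
  expect_equal(unname(obs["S", kPlus1]), 1)
  expect_equal(unname(st@firstDen$bonded[kPlus1]), 1)
})

test_that("uniform profiles carry no class information: obs equals ref", {
  chains <- list(
    toyChain("u1", "AAACAAAACAAAACAAAACAAA", bonds = rbind(c(4L, 9L)), profile = "uniform"),
    toyChain("u2", "AAACAAAACAAAACAAAACAAA", bonds = rbind(c(14L, 19L)), profile = "uniform"))
  st <- accumulateStateStatistics(chains, 7)
  for (cl in c("bonded", "free")) {
    expect_equal(obsProb(st, 1, cl), refProb(st, 1), tolerance = 1e-12)
    expect_equal(obsProb(st, 2, cl), refProb(st, 2), tolerance = 1e-12)
  }
  ps <- accumulatePairStatistics(chains, 7)
  for (cl in c("connected", "unconnected")) {
    expect_equal(obsProb(ps, 1, cl), refProb(ps, 1), tolerance = 1e-12)
    expect_equal(obsProb(ps, 2, cl), refProb(ps, 2), tolerance = 1e-12)
  }
})

test_that("state statistics match the brute-force triple loop on a toy corpus", {
  chains <- randomToyCorpus(nChains = 5, L = 44, seed = 7)
  for (K in c(3, 7)) {
    st <- accumulateStateStatistics(chains, K)
    oracle <- bruteStateStats(chains, K)
    for (cl in c("bonded", "free")) {
      expect_equal(st@firstNum[[cl]], oracle[[cl]]$n1, tolerance = 1e-12)
      expect_equal(st@firstDen[[cl]], oracle[[cl]]$d1, tolerance = 1e-12)
      expect_equal(st@secondNum[[cl]], oracle[[cl]]$n2, tolerance = 1e-12)
      expect_equal(st@secondDen[[cl]], oracle[[cl]]$d2, tolerance = 1e-12)
    }
  }
})

test_that("pair statistics match the brute-force loop on a toy corpus", {
  chains <- randomToyCorpus(nChains = 4, L = 44, seed = 11)
  for (K in c(3, 7)) {
    ps <- accumulatePairStatistics(chains, K)
    oracle <- brutePairStats(chains, K)
    for (cl in c("connected", "unconnected")) {
      expect_equal(ps@firstNum[[cl]], oracle[[cl]]$n1, tolerance = 1e-12)
      expect_equal(ps@firstDen[[cl]], oracle[[cl]]$d1, tolerance = 1e-12)
      expect_equal(ps@secondNum[[cl]], oracle[[cl]]$n2, tolerance = 1e-12)
      expect_equal(ps@secondDen[[cl]], oracle[[cl]]$d2, tolerance = 1e-12)
    }
  }
})

test_that("a single bonded pair with one-hot profiles gives indicator pair statistics", {
  #        123456789
  ch <- toyChain("p", "AGCSAECWD", bonds = rbind(c(3L, 7L)), profile = "onehot")
  ps <- accumulatePairStatistics(list(ch), 3)
  obs <- obsProb(ps, 1, "connected")
  slots <- enumeratePairOffsetSlots(3)$slots
  # slot (cys1, +1) is position 4 = S; slot (cys2, -1) is position 6 = E
  s1 <- which(slots$cys == 1 & slots$offset == 1)
  s2 <- which(slots$cys == 2 & slots$offset == -1)
  expect_equal(unname(obs["S", s1]), 1)
  expect_equal(unname(obs["E", s2]), 1)
  expect_true(all(obs %in% c(0, 1)))
})

test_that("planted neighbour enrichment appears in the observed statistics", {
  cfg <- syntheticConfig(nChains = 150, seed = 21,
                         neighborEffects = neighborEffect("C", 3, 6))
  chains <- generateCorpus(cfg)
  st <- accumulateStateStatistics(chains, 7)
  offs <- enumerateFirstOrderOffsets(7)
  k3 <- match(3, offs)
  expect_gt(obsProb(st, 1, "bonded")["C", k3], refProb(st, 1)["C", k3])
})

test_that("statistics are invariant under corpus duplication", {
  chains <- randomToyCorpus(nChains = 3, L = 44, seed = 5)
  st1 <- accumulateStateStatistics(chains, 7)
  st2 <- accumulateStateStatistics(c(chains, chains), 7)
  for (cl in c("bonded", "free")) {
    expect_equal(obsProb(st1, 1, cl), obsProb(st2, 1, cl), tolerance = 1e-12)
    expect_equal(obsProb(st1, 2, cl), obsProb(st2, 2, cl), tolerance = 1e-12)
  }
  expect_equal(refProb(st1, 1), refProb(st2, 1), tolerance = 1e-12)
})

test_that("with a single class present, observed equals reference", {
  # every usable cysteine bonded
  ch <- toyChain("allb", "AAACAAAACAAAACAAAACAA",
                 bonds = rbind(c(4L, 9L), c(14L, 19L)), profile = "random")
  st <- accumulateStateStatistics(list(ch), 7)
  expect_equal(obsProb(st, 1, "bonded"), refProb(st, 1), tolerance = 1e-12)
  expect_equal(obsProb(st, 2, "bonded"), refProb(st, 2), tolerance = 1e-12)
  expect_equal(unname(st@classWeight["free"]), 0)
})

test_that("class mixture of observed statistics reconstructs the reference", {
  # all cysteines far from the termini: full window coverage, so the class
  # priors are the plain profile-mass fractions
  chains <- randomToyCorpus(nChains = 5, L = 44, seed = 13)
  st <- accumulateStateStatistics(chains, 7)
  wB <- st@classWeight["bonded"]; wF <- st@classWeight["free"]
  mix <- (wB * obsProb(st, 1, "bonded") + wF * obsProb(st, 1, "free")) / (wB + wF)
  expect_equal(mix, refProb(st, 1), tolerance = 1e-9)
  mix2 <- (wB * obsProb(st, 2, "bonded") + wF * obsProb(st, 2, "free")) / (wB + wF)
  expect_equal(mix2, refProb(st, 2), tolerance = 1e-9)
})

test_that("degenerate corpora raise the empty-statistics errors", {
  noCys <- annotatedChain("none", paste(rep("A", 50), collapse = ""),
                          profile = matrix(1 / 20, 50, 20))
  expect_error(accumulateStateStatistics(list(noCys), 7), "no usable cysteines")
  noBond <- toyChain("nb", "AAACAAAACAAAACAAAA", profile = "uniform")
  expect_error(accumulatePairStatistics(list(noBond), 7), "no bonded pairs")
})
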