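test_that("the generator is fully reproducible given the seed", {
  cfg <- syntheticConfig(nChains = 15, seed = 77)
  a <- generateCorpus(cfg)
  b <- generateCorpus(cfg)
  expect_identical(lapply(a, chainSeq), lapply(b, chainSeq))
  expect_identical(lapply(a, bonds), lapply(b, bonds))
  expect_identical(lapply(a, profileMatrix), lapply(b, profileMatrix))
  c0 <- generateCorpus(syntheticConfig(nChains = 15, seed = 78))
  expect_false(identical(lapply(a, chainSeq), lapply(c0, chainSeq)))
})

test_that("generated patterns are valid nonadjacent matchings with clean exclusions", {
  chains <- generateCorpus(syntheticConfig(nChains = 40, seed = 5))
  for (ch in chains) {
    b <- bonds(ch)
    expect_true(validObject(ch))
    if (nrow(b)) {
      expect_true(!anyDuplicated(as.vector(b)))
      expect_true(all(b[, 2] - b[, 1] >= 2))
    }
    expect_length(excludedCys(ch), 0)
    # bonded labels agree with the pattern after the odd-cysteine relabel
    lab <- cysLabels(ch)
    expect_setequal(as.integer(names(lab)[lab == 1]), as.vector(b))
  }
})

test_that("the realized bonded fraction hits the calibration target", {
  chains <- generateCorpus(syntheticConfig(nChains = 500, seed = 31))
  labs <- unlist(lapply(chains, cysLabels))
  expect_lt(abs(mean(labs) - 0.2127), 0.03)
})

test_that("a planted neighbour effect raises the empirical bonding odds", {
  hits <- 0
  for (s in 1:5) {
    chains <- generateCorpus(syntheticConfig(
      nChains = 200, seed = 100 + s,
      neighborEffects = neighborEffect("C", 3, 4)))
    withC <- c(); without <- c()
    for (ch in chains) {
      letters20 <- strsplit(chainSeq(ch), "")[[1]]
      lab <- cysLabels(ch)
      pos <- as.integer(names(lab))
      has <- pos + 3 <= length(letters20) & letters20[pmin(pos + 3, length(letters20))] == "C"
      withC <- c(withC, lab[has]); without <- c(without, lab[!has])
    }
    orEmp <- (mean(withC) / (1 - mean(withC))) / (mean(without) / (1 - mean(without)))
    if (orEmp > 2) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("with all multipliers at 1 no spurious first-order signal appears", {
  chains <- generateCorpus(syntheticConfig(nChains = 400, seed = 19))
  st <- accumulateStateStatistics(chains, 7)
  obs <- obsProb(st, 1, "bonded")
  ref <- refProb(st, 1)
  # standard error of the weighted estimate per (residue, offset) cell
  W <- st@firstDen$bonded
  se <- sqrt(pmax(ref * (1 - ref), 1e-12) / rep(W, each = 20))
  z <- abs(obs - ref) / se
  expect_lt(mean(z > 3), 0.05)
})

test_that("an infeasible configuration raises a calibration error", {
  expect_error(
    generateCorpus(syntheticConfig(nChains = 3, lengthRange = c(60, 60),
                                   cysDensity = 0.001, seed = 1)),
    "calibration error")
})

test_that("corpus files round-trip through the io module", {
  chains <- generateCorpus(syntheticConfig(nChains = 4, seed = 9))
  dir <- withr::local_tempdir()
  writeCorpusFiles(chains, dir)
  back <- readFastaChains(file.path(dir, "corpus.fasta"))
  ann <- readBondAnnotations(file.path(dir, "bonds.tsv"))
  for (id in names(chains)) {
    expect_equal(chainSeq(back[[id]]), chainSeq(chains[[id]]))
    if (nrow(bonds(chains[[id]])))
      expect_equal(unname(ann[[id]]$bonds), unname(bonds(chains[[id]])))
    P <- parsePSSM(file.path(dir, paste0(id, ".pssm")))
    expect_equal(attr(P, "query"), chainSeq(chains[[id]]))
    expect_lt(max(abs(P - profileMatrix(chains[[id]]))), 0.015)
  }
})

test_that("the worked-example fixture carries the documented probabilities", {
  fx <- make153LFixture()
  expect_equal(cysPositions(fx$chain), c(4L, 18L, 29L, 60L))
  tab <- fx$pairProbs
  expect_equal(tab$prob[tab$i == 18 & tab$j == 60], 0.90)
  expect_equal(tab$prob[tab$i == 4 & tab$j == 29], 0.32)
  expect_equal(unname(fx$stateProbs), c(0.82, 0.84, 0.95, 0.94))
  expect_true(all(fx$stateProbs > 0.5))
  expect_true(samePattern(assignConnectivity(tab), fx$nativePattern))
})

test_that("strong-signal training beats the majority-class baseline decisively", {
  # dense preset variant: enough bonded cysteines per chain that the
  # odd-cysteine parity noise leaves headroom above baseline + 0.10
  chains <- generateCorpus(strongSignalConfig(nChains = 2000, seed = 1,
                                              cysDensity = 0.10))
  tr <- chains[1:1600]; va <- chains[1601:1800]; te <- chains[1801:2000]
  predictor <- trainPredictor(
    tr, seed = 7, valChains = va,
    stateArgs = list(epochs = 200, batchSize = 128, lr = 0.25, patience = 20),
    connArgs = list(epochs = 60, batchSize = 128, lr = 0.1, patience = 10))
  sm <- CysBond:::.stateMetricsForChains(predictor, te)
  baseline <- 1 - mean(unlist(lapply(te, cysLabels)))
  expect_gte(sm$Qc, 0.85)
  expect_gte(sm$Qc - baseline, 0.10)
})
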