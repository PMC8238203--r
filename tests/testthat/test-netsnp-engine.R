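fakeResult <- function(locus, mcvtVal) {
  m <- matrix(mcvtVal, 2, 1)
  methods::new("TSnpResult", locus = locus, nat = m * 0, ref = m * 0, alt = m,
               mcvt = mcvtVal, dispersion = 0, nReps = 1L, mfaIsAlt = TRUE,
               seed = 1L)
}

fakeBand <- function(sample = seq(-0.2, 0.2, length.out = 101), alpha = 0.05) {
  lu <- stats::quantile(sample, c(alpha / 2, 1 - alpha / 2), type = 7)
  methods::new("NullBand", sample = sample, lower = unname(lu[1]),
               upper = unname(lu[2]), alpha = alpha, nRandom = length(sample),
               repsPerSnp = 1L, seed = 1L)
}

test_that("genotype assignment is local, commuting and non-mutating", {
  x <- matrix(runif(20, -1, 1), 5, 4)
  sc <- list(lo = rep(0, 4), hi = rep(2, 4))
  x0 <- x
  y <- assignGenotype(x, 2, 2, sc)
  expect_identical(x, x0)                        # original untouched
  expect_true(all(y[, 2] == 1))                  # code 2 on 0..2 scale -> +1
  expect_identical(y[, -2], x[, -2])             # locality
  ab <- assignGenotype(assignGenotype(x, 1, 1, sc), 3, 0, sc)
  ba <- assignGenotype(assignGenotype(x, 3, 0, sc), 1, 1, sc)
  expect_identical(ab, ba)                       # disjoint writes commute
  # assigning the code every individual already holds is the identity
  codes <- matrix(2, 5, 1)
  sc1 <- list(lo = 0, hi = 2)
  xs <- applyFeatureScaling(codes, sc1)$x
  expect_identical(assignGenotype(xs, 1, 2, sc1), xs)
  expect_error(assignGenotype(x, 9, 1, sc), "out of range")
  expect_error(assignGenotype(x, 1, 3, sc), "code")
})

test_that("planted risk and protective loci shift mCVt in the right direction", {
  ch <- smallCohort()
  pool <- poolOf(ch)
  cfg <- netConfig(hidden = c(12, 5), maxEpochs = 150, seed = 1)
  risk <- evaluateTsnp(ch$store, pool, plantedKey(ch, "risk1"), nReps = 3,
                       config = cfg, topK = 20, seed = 101)
  prot <- evaluateTsnp(ch$store, pool, plantedKey(ch, "prot1"), nReps = 3,
                       config = cfg, topK = 20, seed = 102)
  expect_gt(risk@mcvt, 0)
  expect_lt(prot@mcvt, 0)
  # ALT-vs-NAT shift positive in every repetition for the risk locus
  shifts <- colMeans(risk@alt) - colMeans(risk@nat)
  expect_true(all(shifts > 0))
  # sign coherence: mean DIF agrees with the mCVt - mean(NAT) shift
  expect_equal(sign(mean(difScores(risk))), sign(risk@mcvt - mean(risk@nat)))
  expect_equal(sign(mean(difScores(prot))), sign(prot@mcvt - mean(prot@nat)))
  # DIF is ALT - REF elementwise by construction
  expect_equal(difScores(risk), risk@alt - risk@ref)
  # determinism
  risk2 <- evaluateTsnp(ch$store, pool, plantedKey(ch, "risk1"), nReps = 3,
                        config = cfg, topK = 20, seed = 101)
  expect_identical(risk@mcvt, risk2@mcvt)
  expect_identical(risk@alt, risk2@alt)
  expect_error(evaluateTsnp(ch$store, pool, "9:9:Z"), "absent")
})

test_that("classification against a null band follows the quantile rule", {
  band <- fakeBand()
  res <- list(fakeResult("1:1:A", -0.35), fakeResult("1:2:A", 0.01),
              fakeResult("1:3:A", 0.31))
  cls <- classifyTsnps(res, band)
  expect_identical(cls$class, c("protective", "indeterminate", "risk"))
  expect_true(all(cls$pEmpirical > 0 & cls$pEmpirical <= 1))
  expect_lt(cls$pEmpirical[1], 0.05)
  expect_gt(cls$pEmpirical[2], 0.5)
  expect_error(classifyTsnps(list(), band), "empty")
})

test_that("null band validates inputs and degenerates gracefully at alpha = 1", {
  ch <- microCohort()
  pool <- poolOf(ch)
  expect_error(nullBandMcvt(ch$store, pool, nRandom = 10), ">= 100")
  expect_error(nullBandMcvt(ch$store, pool, nRandom = 1000), "exceeds")
  band <- nullBandMcvt(ch$store, pool, nRandom = 100, alpha = 1,
                       config = microNet(), repsPerSnp = 1, topK = 10, seed = 4)
  expect_identical(band@lower, min(band@sample))
  expect_identical(band@upper, max(band@sample))
  inside <- classifyTsnps(lapply(band@sample[1:5], function(v)
    fakeResult("1:1:A", v)), band)
  expect_true(all(inside$class == "indeterminate"))
})

test_that("APOE genotype assignment encodes allele pairs and matches identity", {
  expect_equal(unname(apoeCodePair("e22")), c(2, 0))
  expect_equal(unname(apoeCodePair("e34")), c(0, 1))
  expect_equal(unname(apoeCodePair("e44")), c(0, 2))
  expect_error(apoeCodePair("e55"), "unknown")
  ch <- smallCohort()
  pool <- poolOf(ch)
  e2 <- plantedKey(ch, "e2like"); e4 <- plantedKey(ch, "e4like")
  rk <- rankSnps(ch$store, pool, topK = 20)
  feats <- unique(c(e2, e4, rk$keys))[1:20]
  sp <- balancedSplit(ch$samples, nTrain = 300, nHoldout = 150, seed = 5)
  net <- trainClassifier(ch$store, sp@trainIds, sp@validationIds, feats,
                         netConfig(hidden = c(12, 5), maxEpochs = 150, seed = 3))
  hf <- buildFeatureMatrix(ch$store, sp@holdoutIds, feats, scaling = net@scaling)
  cvNat <- predictCv(net, hf$x)
  cv33 <- apoeGenotypeAssignment(net, hf$x, e2, e4, "e33")
  # individuals whose true genotype is e33 keep their NAT value exactly
  is33 <- sampleInfo(ch$store)[sp@holdoutIds, "apoe"] %in% "e33"
  expect_equal(cv33[is33], cvNat[is33])
  # risk alleles push everyone right of the protective assignment
  cv22 <- apoeGenotypeAssignment(net, hf$x, e2, e4, "e22")
  cv44 <- apoeGenotypeAssignment(net, hf$x, e2, e4, "e44")
  expect_lt(mean(cv22), mean(cv33))
  expect_gt(mean(cv44), mean(cv33))
  expect_error(apoeGenotypeAssignment(net, hf$x, "9:9:Z", e4, "e22"),
               "not among")
})
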