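# The scoring engine: a target SNP is scored by forcing every holdout
# individual homozygous for its minor frequency allele and measuring how the
# trained classifier's output shifts; significance is calibrated against
# randomly chosen target SNPs.

#' Force one feature column to a fixed genotype code
#'
#' Returns a copy of the (scaled) feature matrix with the given column set to
#' the scaled representation of `code`; every other column is untouched and
#' the input matrix is never modified.
#'
#' @param features Samples-by-features scaled matrix.
#' @param column Column index to overwrite.
#' @param code Genotype code in \{0, 1, 2\}.
#' @param scaling The feature scaling (`list(lo, hi)`) the matrix was built with.
#' @return The modified copy.
#' @export
assignGenotype <- function(features, column, code, scaling) {
  if (column < 1 || column > ncol(features))
    stop("column index out of range", call. = FALSE)
  if (!code %in% c(0, 1, 2)) stop("code must be in {0, 1, 2}", call. = FALSE)
  lo <- scaling$lo[column]; hi <- scaling$hi[column]
  v <- if (hi > lo) max(-1, min(1, -1 + 2 * (code - lo) / (hi - lo))) else 0
  features[, column] <- v
  features
}

# One repetition's sample partition for a target-SNP evaluation: a fresh ~70%
# balanced training subset (validation carved from it), holdout drawn from
# the untouched remainder.
tsnpPartition <- function(info, poolIds, trainFrac, validationFrac, nHoldout,
                          balancedHoldout, holdoutIds = NULL) {
  pool <- info[poolIds, , drop = FALSE]
  if (!is.null(holdoutIds)) pool <- pool[!(rownames(pool) %in% holdoutIds), , drop = FALSE]
  trainIds <- character(0); valIds <- character(0)
  for (co in unique(pool$cohort)) {
    d <- pool[pool$cohort == co, , drop = FALSE]
    k <- floor(trainFrac * min(sum(d$status == "case"), sum(d$status == "control")))
    if (k == 0) next
    ca <- sampleIdx(rownames(d)[d$status == "case"], k)
    ct <- sampleIdx(rownames(d)[d$status == "control"], k)
    kv <- floor(validationFrac * k)
    valIds <- c(valIds, ca[seq_len(kv)], ct[seq_len(kv)])
    trainIds <- c(trainIds, ca[seq_len(k) > kv], ct[seq_len(k) > kv])
  }
  if (is.null(holdoutIds)) {
    rest <- info[!(rownames(info) %in% c(trainIds, valIds)), , drop = FALSE]
    holdoutIds <- if (balancedHoldout) {
      hca <- rownames(rest)[rest$status == "case"]
      hct <- rownames(rest)[rest$status == "control"]
      h <- min(floor(nHoldout / 2), length(hca), length(hct))
      c(sampleIdx(hca, h), sampleIdx(hct, h))
    } else {
      sampleIdx(rownames(rest), min(nHoldout, nrow(rest)))
    }
  }
  list(train = trainIds, validation = valIds, holdout = holdoutIds)
}

#' Score a target SNP by forced-genotype assignment
#'
#' Per repetition: a fresh ~`trainFrac` balanced training subset is drawn
#' from the pool, SNPs are ranked by training-set FishP, the feature matrix
#' is the top `topK - 1` SNPs plus the target (the target is never
#' duplicated: if it already ranks in the top `topK - 1`, the next-ranked SNP
#' fills the matrix), a network is trained, and the holdout is scored three
#' ways: NAT (true genotypes), REF (target forced homozygous on the
#' reference scale) and ALT (target forced homozygous for its minor
#' frequency allele). When the minor allele is the reference allele, ALT
#' forces code 0 and REF code 2 (MFA semantics). `mcvt` is the mean ALT
#' score over all individuals and repetitions.
#'
#' @param store A `GenotypeStore`.
#' @param poolIds Sample ids of the case:control-balanced pool.
#' @param target Locus key (`"chr:pos:alt"`) of the target SNP.
#' @param nReps Number of repetitions (default 20).
#' @param config A [NetConfig-class].
#' @param topK Feature-matrix size (default 50).
#' @param trainFrac Fraction of the pool trained on per repetition.
#' @param validationFrac Fraction of the training subset used for validation.
#' @param nHoldout Holdout size per repetition (default: 30% of the pool).
#' @param exclusions Optional exclusion lists applied to the ranked features
#'   (never to the target itself).
#' @param balancedHoldout Draw the holdout with equal case/control counts
#'   (default `TRUE`, which centers the NAT baseline near CV = 0).
#' @param fixedHoldout Draw the holdout once and reuse it across repetitions
#'   instead of redrawing per repetition.
#' @param seed Master seed; repetition r uses `childSeed(seed, target, r)`.
#' @return A [TSnpResult-class].
#' @export
evaluateTsnp <- function(store, poolIds, target, nReps = 20,
                         config = netConfig(), topK = 50, trainFrac = 0.7,
                         validationFrac = 0.15, nHoldout = NULL,
                         exclusions = NULL, balancedHoldout = TRUE,
                         fixedHoldout = FALSE, seed = 1) {
  if (!target %in% locusKeys(store))
    stop("target locus absent from store: ", target, call. = FALSE)
  info <- sampleInfo(store)
  poolIds <- as.character(poolIds)
  if (is.null(nHoldout)) nHoldout <- max(2, 2 * floor(0.15 * length(poolIds)))
  mfaAll <- minorAlleleStats(store, poolIds)
  mfaIsAlt <- mfaAll$mfaIsAlt[match(target, mfaAll$key)]
  altCode <- if (mfaIsAlt) 2 else 0
  refCode <- if (mfaIsAlt) 0 else 2
  fixedHold <- if (fixedHoldout) {
    withSeed(childSeed(seed, target, "holdout"),
             tsnpPartition(info, poolIds, trainFrac, validationFrac, nHoldout,
                           balancedHoldout)$holdout)
  } else NULL
  nat <- ref <- alt <- NULL
  for (r in seq_len(nReps)) {
    rs <- childSeed(seed, target, r)
    part <- withSeed(rs, tsnpPartition(info, poolIds, trainFrac, validationFrac,
                                       nHoldout, balancedHoldout, fixedHold))
    rankIds <- c(part$train, part$validation)
    rk <- rankSnps(store, rankIds, exclusions = exclusions, topK = topK)
    others <- setdiff(rk$assoc$key, target)
    featureLoci <- c(others[seq_len(min(topK - 1, length(others)))], target)
    cfg <- config; cfg@seed <- childSeed(rs, "init")
    net <- trainClassifier(store, part$train, part$validation, featureLoci, cfg)
    hf <- buildFeatureMatrix(store, part$holdout, featureLoci, scaling = net@scaling)
    tcol <- length(featureLoci)
    cvNat <- predictCv(net, hf$x)
    cvRef <- predictCv(net, assignGenotype(hf$x, tcol, refCode, net@scaling))
    cvAlt <- predictCv(net, assignGenotype(hf$x, tcol, altCode, net@scaling))
    if (is.null(nat)) {
      nh <- length(cvNat)
      nat <- ref <- alt <- matrix(NA_real_, nh, nReps)
    }
    nat[seq_along(cvNat), r] <- cvNat
    ref[seq_along(cvRef), r] <- cvRef
    alt[seq_along(cvAlt), r] <- cvAlt
  }
  repMeans <- colMeans(alt, na.rm = TRUE)
  methods::new("TSnpResult", locus = target, nat = nat, ref = ref, alt = alt,
               mcvt = mean(alt, na.rm = TRUE),
               dispersion = if (nReps > 1) stats::sd(repMeans) / sqrt(nReps) else 0,
               nReps = as.integer(nReps), mfaIsAlt = mfaIsAlt,
               seed = as.integer(seed))
}

#' Null mCVt band from randomly chosen target SNPs
#'
#' Draws `nRandom` target SNPs uniformly from all store loci, scores each
#' with a reduced repetition count (`repsPerSnp`, default 5, versus 20 for
#' real targets -- a tractability trade-off recorded in the object), and
#' stores the empirical central interval at level `1 - alpha`. With
#' `alpha = 1` the band degenerates to the full sample range (no SNP can be
#' called significant).
#'
#' @inheritParams evaluateTsnp
#' @param nRandom Number of random target SNPs (>= 100).
#' @param alpha Two-sided significance level (default 0.05).
#' @param repsPerSnp Repetitions per random SNP (default 5).
#' @param ... Passed on to [evaluateTsnp()] (`topK`, sizes, exclusions, ...).
#' @return A [NullBand-class].
#' @export
nullBandMcvt <- function(store, poolIds, nRandom = 1000, alpha = 0.05,
                         config = netConfig(), repsPerSnp = 5, seed = 1, ...) {
  if (nRandom < 100) stop("nRandom must be >= 100", call. = FALSE)
  if (nRandom > nrow(store))
    stop("nRandom exceeds the number of store loci", call. = FALSE)
  keys <- withSeed(childSeed(seed, "null-targets"),
                   sample(locusKeys(store), nRandom))
  vals <- vapply(keys, function(k)
    evaluateTsnp(store, poolIds, k, nReps = repsPerSnp, config = config,
                 seed = childSeed(seed, "null", k), ...)@mcvt,
    numeric(1))
  if (alpha >= 1) {
    lowup <- range(vals)
  } else {
    lowup <- unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), type = 7))
  }
  methods::new("NullBand", sample = unname(vals), lower = lowup[1],
               upper = lowup[2], alpha = alpha, nRandom = as.integer(nRandom),
               repsPerSnp = as.integer(repsPerSnp), seed = as.integer(seed))
}

#' Call scored SNPs protective, risk, or indeterminate against a null band
#'
#' A SNP is protective iff its mCVt falls below the band's lower quantile,
#' risk iff above the upper quantile, indeterminate otherwise. The empirical
#' two-sided p is `2 * min` of the rank-based tail proportions against the
#' stored null sample (with the +1 correction), capped at 1.
#'
#' @param results A list of [TSnpResult-class] objects.
#' @param band A [NullBand-class].
#' @return `data.frame` with `locus`, `mcvt`, `dispersion`, `class`
#'   (`"protective"`/`"risk"`/`"indeterminate"`) and `pEmpirical`.
#' @export
classifyTsnps <- function(results, band) {
  if (length(results) == 0) stop("empty results list", call. = FALSE)
  m <- vapply(results, function(r) r@mcvt, numeric(1))
  n <- length(band@sample)
  pLo <- (1 + vapply(m, function(v) sum(band@sample <= v), 1)) / (1 + n)
  pHi <- (1 + vapply(m, function(v) sum(band@sample >= v), 1)) / (1 + n)
  data.frame(locus = vapply(results, function(r) r@locus, ""),
             mcvt = m,
             dispersion = vapply(results, function(r) r@dispersion, numeric(1)),
             class = ifelse(m < band@lower, "protective",
                            ifelse(m > band@upper, "risk", "indeterminate")),
             pEmpirical = pmin(1, 2 * pmin(pLo, pHi)),
             stringsAsFactors = FALSE)
}

#' Two-locus APOE-style genotype code pair
#'
#' Encodes the six APOE genotypes on two pseudo-loci counting the e2 and e4
#' alleles: e22 -> (2, 0), e23 -> (1, 0), e24 -> (1, 1), e33 -> (0, 0),
#' e34 -> (0, 1), e44 -> (0, 2).
#'
#' @param genotype One of `"e22" "e23" "e24" "e33" "e34" "e44"`.
#' @return Named numeric vector `c(e2 = , e4 = )`.
#' @export
apoeCodePair <- function(genotype) {
  map <- list(e22 = c(2, 0), e23 = c(1, 0), e24 = c(1, 1),
              e33 = c(0, 0), e34 = c(0, 1), e44 = c(0, 2))
  if (!genotype %in% names(map)) stop("unknown APOE genotype: ", genotype, call. = FALSE)
  stats::setNames(map[[genotype]], c("e2", "e4"))
}

#' Assign an APOE genotype to every holdout individual and score
#'
#' Sets the two APOE-coding feature columns (e2-allele count and e4-allele
#' count) of every individual to the pair encoding the requested genotype
#' and returns the resulting classifier values. Assigning each individual's
#' true genotype reproduces the baseline NAT distribution.
#'
#' @param net A [TrainedNet-class] whose features include both APOE loci.
#' @param features Scaled holdout feature matrix.
#' @param e2Locus,e4Locus Locus keys of the e2- and e4-coding features.
#' @param genotype APOE genotype label (see [apoeCodePair()]).
#' @return Numeric vector of per-individual CVs.
#' @export
apoeGenotypeAssignment <- function(net, features, e2Locus, e4Locus, genotype) {
  c2 <- match(e2Locus, net@featureLoci)
  c4 <- match(e4Locus, net@featureLoci)
  if (is.na(c2) || is.na(c4))
    stop("APOE loci are not among the network's features", call. = FALSE)
  pair <- apoeCodePair(genotype)
  x <- assignGenotype(features, c2, pair[["e2"]], net@scaling)
  x <- assignGenotype(x, c4, pair[["e4"]], net@scaling)
  predictCv(net, x)
}
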