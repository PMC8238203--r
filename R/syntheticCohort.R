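# Synthetic cohort generator: an exome-study-like genotype/phenotype dataset
# with a rare-skewed MAF spectrum, 24 cohorts of varying case:control
# imbalance, two common planted loci emulating APOE e4 (risk) and e2
# (protective) plus graded rare planted loci, and age-of-diagnosis / Braak
# phenotypes driven by the planted genetic burden. Ground truth is recorded
# in a manifest so every downstream module is testable without any download.

#' Default planted-effect table
#'
#' Two common loci emulating APOE e4 (MAF 0.147, per-allele control/case
#' odds 0.30, age shift -8.4 yr/allele) and e2 (MAF 0.076, odds 2.41,
#' +3.8 yr/allele), plus eight rare loci (MAF 0.02) with graded odds
#' \{3.0, 2.41, 2.0, 1.5\} protective and \{0.33, 0.41, 0.5, 0.67\} risk and
#' +/-0.5 yr/allele age shifts.
#'
#' @return `data.frame` with columns `name`, `maf`, `odds`, `tag`,
#'   `ageShift`, `gene`, `chr`.
#' @export
defaultPlantedEffects <- function() {
  data.frame(
    name = c("e4like", "e2like", paste0("prot", 1:4), paste0("risk", 1:4)),
    maf = c(0.147, 0.076, rep(0.02, 8)),
    odds = c(0.30, 2.41, 3.0, 2.41, 2.0, 1.5, 0.33, 0.41, 0.5, 0.67),
    tag = c("risk", "protective", rep("protective", 4), rep("risk", 4)),
    ageShift = c(-8.4, 3.8, rep(0.5, 4), rep(-0.5, 4)),
    gene = c("APOE", "APOE", paste0("PG", 1:8)),
    chr = c("19", "19", as.character(c(1, 3, 5, 7, 9, 11, 13, 15))),
    stringsAsFactors = FALSE)
}

#' Parameterization of the synthetic cohort generator
#'
#' @param nSamples,nSnps Cohort dimensions (defaults 6000 x 10000).
#' @param nCohorts Number of cohorts (default 24). Half are balanced, a
#'   quarter case-heavy and a quarter control-heavy (`cohortCaseFrac`
#'   exposes the per-cohort case fractions), so cohort filtering is
#'   exercised.
#' @param rareWeight Share of loci drawn from the rare MAF component
#'   (default 0.96, realizing > 95 percent of loci with MAF < 0.01 after
#'   binomial sampling noise).
#' @param mafRare,mafCommon Uniform ranges of the rare and common MAF
#'   components.
#' @param planted Planted-effect table (see [defaultPlantedEffects()]);
#'   `odds` are per-minor-allele control/case odds applied multiplicatively.
#' @param baselineOdds Control/case odds for individuals with no planted
#'   minor allele (default 0.89).
#' @param ldCompanionRho Correlation of the TOMM40-like companion locus
#'   copied from the e4-like anchor (0 disables the LD block).
#' @param missingRate Per-cell missing-call rate (default 0.002).
#' @param ageModel `list(caseBase, controlBase, noiseSd)` in years; planted
#'   `ageShift`s act per allele on case age of diagnosis.
#' @param braakModel `list(weight, thresholds, noiseSd, autopsyFrac)`:
#'   stages 1-6 arise from a monotone step function of
#'   `weight * standardized burden + noise` through the increasing
#'   thresholds; only an `autopsyFrac` share of individuals (default 0.28)
#'   receives a Braak value.
#' @param cohortCaseFrac Optional explicit per-cohort case fractions.
#' @param seed Master seed.
#' @return A list of class `"SynthSpec"`.
#' @export
synthSpec <- function(nSamples = 6000, nSnps = 10000, nCohorts = 24,
                      rareWeight = 0.96, mafRare = c(0.001, 0.0075),
                      mafCommon = c(0.01, 0.35),
                      planted = defaultPlantedEffects(),
                      baselineOdds = 0.89, ldCompanionRho = 0.8,
                      missingRate = 0.002,
                      ageModel = list(caseBase = 75.4, controlBase = 86.1,
                                      noiseSd = 7),
                      braakModel = list(weight = 1.2,
                                        thresholds = c(-1.5, -0.8, -0.2, 0.4, 1.1),
                                        noiseSd = 1, autopsyFrac = 0.28),
                      cohortCaseFrac = NULL, seed = 1) {
  if (!is.null(planted) && nrow(planted) > 0) {
    if (anyDuplicated(planted$name)) stop("planted loci must be distinct", call. = FALSE)
    if (any(planted$odds <= 0)) stop("planted odds must be > 0", call. = FALSE)
    if (nrow(planted) > nSnps) stop("more planted loci than nSnps", call. = FALSE)
  }
  if (is.unsorted(braakModel$thresholds, strictly = TRUE))
    stop("braak thresholds must be strictly increasing", call. = FALSE)
  if (is.null(cohortCaseFrac)) {
    nb <- floor(nCohorts / 2); nq <- floor(nCohorts / 4)
    cohortCaseFrac <- c(rep(0.5, nb),
                        c(0.70, 0.70, 0.85, 0.85, 0.90, 0.65)[seq_len(nq)],
                        c(0.30, 0.30, 0.15, 0.15, 0.10, 0.35)[seq_len(nCohorts - nb - nq)])
  }
  structure(list(nSamples = nSamples, nSnps = nSnps, nCohorts = nCohorts,
                 rareWeight = rareWeight, mafRare = mafRare,
                 mafCommon = mafCommon, planted = planted,
                 baselineOdds = baselineOdds, ldCompanionRho = ldCompanionRho,
                 missingRate = missingRate, ageModel = ageModel,
                 braakModel = braakModel, cohortCaseFrac = cohortCaseFrac,
                 seed = seed),
            class = "SynthSpec")
}

# Sparse genotype draw for one locus: counts of het / hom-alt individuals
# are multinomial in (2pq, q^2), carriers get random sample slots.
drawLocus <- function(n, maf) {
  pr <- c(2 * maf * (1 - maf), maf^2)
  k <- stats::rmultinom(1, n, c(1 - sum(pr), pr))[, 1]
  idx <- sample.int(n, k[2] + k[3])
  list(j = idx, x = rep(c(1, 2), c(k[2], k[3])))
}

#' Generate a synthetic genotype/phenotype cohort with known ground truth
#'
#' Genotypes are drawn per locus as binomial(2, MAF), independently except
#' for the declared LD companion (copied from its anchor with the stated
#' correlation). Case/control status follows per-allele multiplicative
#' control/case odds over the planted loci; cohort labels realize the
#' configured imbalance profile; age of diagnosis and Braak stage are driven
#' by the planted burden as configured.
#'
#' @param spec A [synthSpec()].
#' @return `list(store, samples, manifest)`: the [GenotypeStore-class] (with
#'   phenotypes in its `colData`), the sample table, and a manifest
#'   recording every planted locus with its true effect.
#' @export
generateCohort <- function(spec = synthSpec()) {
  n <- spec$nSamples; L <- spec$nSnps
  withSeed(spec$seed, {
    # --- locus table and MAF spectrum ---
    chr <- as.character(rep_len(1:22, L))
    pos <- 10000L + 50L * seq_len(L)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    maf <- ifelse(stats::runif(L) < spec$rareWeight,
                  stats::runif(L, spec$mafRare[1], spec$mafRare[2]),
                  stats::runif(L, spec$mafCommon[1], spec$mafCommon[2]))
    gene <- paste0("G", chr, "_", seq_len(L))
    planted <- spec$planted
    pidx <- integer(0)
    if (!is.null(planted) && nrow(planted) > 0) {
      pidx <- floor(seq(0.08, 0.92, length.out = nrow(planted)) * L)
      maf[pidx] <- planted$maf
      chr[pidx] <- planted$chr
      gene[pidx] <- planted$gene
    }
    # LD companion emulating the APOE/TOMM40 linkage pair
    compIdx <- NA_integer_
    anchorIdx <- if (length(pidx)) pidx[match("e4like", planted$name)] else NA_integer_
    if (!is.na(anchorIdx) && spec$ldCompanionRho > 0) {
      compIdx <- anchorIdx + 1L
      maf[compIdx] <- planted$maf[match("e4like", planted$name)]
      chr[compIdx] <- "19"
      gene[compIdx] <- "TOMM40"
    }
    # --- genotypes (sparse triplets) ---
    ii <- vector("list", L); jj <- vector("list", L); xx <- vector("list", L)
    for (l in seq_len(L)) {
      if (!is.na(compIdx) && l == compIdx) next
      d <- drawLocus(n, maf[l])
      ii[[l]] <- rep.int(l, length(d$j)); jj[[l]] <- d$j; xx[[l]] <- d$x
    }
    if (!is.na(compIdx)) {
      keepAnchor <- stats::runif(n) < spec$ldCompanionRho
      anchor <- numeric(n)
      anchor[jj[[anchorIdx]]] <- xx[[anchorIdx]]
      fresh <- drawLocus(n, maf[compIdx])
      comp <- numeric(n)
      comp[fresh$j] <- fresh$x
      comp[keepAnchor] <- anchor[keepAnchor]
      nz <- which(comp != 0)
      ii[[compIdx]] <- rep.int(compIdx, length(nz)); jj[[compIdx]] <- nz
      xx[[compIdx]] <- comp[nz]
    }
    i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
    # --- missing calls overwrite whatever was there ---
    nMiss <- stats::rbinom(1, n * L, spec$missingRate)
    if (nMiss > 0) {
      cells <- sample(as.numeric(n) * L, nMiss)
      mi <- ((cells - 1) %% L) + 1
      mj <- floor((cells - 1) / L) + 1
      clash <- (i - 1) + as.numeric(j - 1) * L
      drop <- clash %in% ((mi - 1) + as.numeric(mj - 1) * L)
      i <- c(i[!drop], mi); j <- c(j[!drop], mj); x <- c(x[!drop], rep(-1, nMiss))
    }
    g <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(L, n))
    # --- status from planted per-allele odds ---
    logOddsControl <- rep(log(spec$baselineOdds), n)
    dosage <- matrix(0, length(pidx), n)
    if (length(pidx)) {
      dos <- as.matrix(g[pidx, , drop = FALSE])
      dos[dos < 0] <- 0
      dosage <- dos
      logOddsControl <- logOddsControl + colSums(dos * log(planted$odds))
    }
    pControl <- 1 / (1 + exp(-logOddsControl))
    status <- ifelse(stats::runif(n) < pControl, "control", "case")
    # --- cohorts realizing the imbalance profile ---
    pc <- spec$cohortCaseFrac
    wCase <- pc / sum(pc); wCtrl <- (1 - pc) / sum(1 - pc)
    cohortLabels <- sprintf("C%02d", seq_len(spec$nCohorts))
    cohort <- character(n)
    isCase <- status == "case"
    cohort[isCase] <- sample(cohortLabels, sum(isCase), TRUE, prob = wCase)
    cohort[!isCase] <- sample(cohortLabels, sum(!isCase), TRUE, prob = wCtrl)
    # --- age of diagnosis / age at last visit ---
    am <- spec$ageModel
    shift <- if (length(pidx)) colSums(dosage * planted$ageShift) else rep(0, n)
    age <- ifelse(isCase,
                  am$caseBase + shift + stats::rnorm(n, 0, am$noiseSd),
                  am$controlBase + stats::rnorm(n, 0, am$noiseSd))
    age <- pmax(age, 41)
    # --- Braak stage from standardized burden ---
    bm <- spec$braakModel
    burden <- if (length(pidx)) colSums(dosage * (-log(planted$odds))) else rep(0, n)
    bz <- if (stats::sd(burden) > 0) as.vector(scale(burden)) else rep(0, n)
    latent <- bm$weight * bz + stats::rnorm(n, 0, bm$noiseSd)
    stage <- 1L + rowSums(outer(latent, bm$thresholds, ">"))
    autopsied <- sample.int(n, round(bm$autopsyFrac * n))
    braak <- rep(NA_integer_, n)
    braak[autopsied] <- stage[autopsied]
    # --- APOE genotype label from the two common planted loci ---
    apoe <- rep(NA_character_, n)
    i2 <- match("e2like", planted$name); i4 <- match("e4like", planted$name)
    if (length(pidx) && !is.na(i2) && !is.na(i4)) {
      n2 <- dosage[i2, ]; n4 <- dosage[i4, ]
      ok <- n2 + n4 <= 2
      al <- cbind(n2, pmax(0, 2 - n2 - n4), n4)
      apoe[ok] <- vapply(which(ok), function(s) {
        a <- rep(c("2", "3", "4"), al[s, ])
        paste0("e", a[1], a[2])
      }, "")
    }
    samples <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)), cohort = cohort,
      status = status, age = round(age, 1), braak = braak, apoe = apoe,
      stringsAsFactors = FALSE)
    loci <- data.frame(chr = chr, pos = pos, ref = ref, alt = alt,
                       gene = gene, stringsAsFactors = FALSE)
    store <- GenotypeStore(g, loci, samples)
    manifest <- list(
      planted = if (length(pidx)) data.frame(
        key = locusKeys(store)[pidx], planted, stringsAsFactors = FALSE)
        else data.frame(),
      companion = if (!is.na(compIdx)) locusKeys(store)[compIdx] else NA_character_,
      spec = spec, seed = spec$seed)
  })
  list(store = store, samples = samples, manifest = manifest)
}

#' Score classified target SNPs against the generator's ground truth
#'
#' @param manifest Manifest from [generateCohort()].
#' @param classified `data.frame` from [classifyTsnps()].
#' @return `list(signRecovery, rankCorrelation, fpr, nPlantedTested,
#'   nNullTested)`: the fraction of tested planted loci whose mCVt sign
#'   matches their tag, the Spearman correlation between `|log odds|` and
#'   `|mCVt|` over tested planted loci, and the significant fraction among
#'   tested non-planted loci.
#' @export
truthEval <- function(manifest, classified) {
  pl <- manifest$planted
  tested <- classified$locus
  hit <- intersect(tested, pl$key)
  if (length(hit) == 0)
    stop("no tested locus is a planted locus", call. = FALSE)
  m <- classified$mcvt[match(hit, classified$locus)]
  tag <- pl$tag[match(hit, pl$key)]
  odds <- pl$odds[match(hit, pl$key)]
  sign_ok <- ifelse(tag == "risk", m > 0, m < 0)
  nullTested <- setdiff(tested, pl$key)
  fpr <- if (length(nullTested))
    mean(classified$class[match(nullTested, classified$locus)] != "indeterminate")
  else NA_real_
  list(signRecovery = mean(sign_ok),
       rankCorrelation = suppressWarnings(
         stats::cor(abs(log(odds)), abs(m), method = "spearman")),
       fpr = fpr,
       nPlantedTested = length(hit), nNullTested = length(nullTested))
}
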