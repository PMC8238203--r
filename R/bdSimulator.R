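# Constructed ("bad") disease simulation: disease status is randomly
# assigned from carrier genotypes at two designated loci via fixed
# control/case odds, and ages of diagnosis are ascribed from empirical
# distributions -- the negative-control machinery for the scoring engine.

#' Specification of a constructed disease
#'
#' Default odds are the published control/case odds: 0.30 for carriers of
#' the e4-like allele, 2.41 for carriers of the e2-like allele, 0.89 for
#' carriers of neither. Individuals carrying both minor alleles fall in the
#' e4 group (precedence), since the three-way odds do not cover the joint
#' case.
#'
#' @param e4Locus,e2Locus Locus keys of the two special loci (carrier
#'   frequencies near 0.147 and 0.076 respectively in the emulated data).
#' @param odds Named control/case odds for groups `e4`, `e2`, `neither`.
#' @param seed Integer seed.
#' @return A list of class `"BDSpec"`.
#' @export
bdSpec <- function(e4Locus, e2Locus,
                   odds = c(e4 = 0.30, e2 = 2.41, neither = 0.89), seed = 1) {
  if (any(odds <= 0)) stop("odds must be > 0", call. = FALSE)
  if (!is.null(e4Locus) && !is.null(e2Locus) && identical(e4Locus, e2Locus))
    stop("the two special loci must be distinct", call. = FALSE)
  structure(list(e4Locus = e4Locus, e2Locus = e2Locus,
                 odds = odds[c("e4", "e2", "neither")], seed = seed),
            class = "BDSpec")
}

#' Randomize case/control labels from genotype groups
#'
#' Each individual is labelled control with probability `odds/(1 + odds)`
#' for its group's control/case odds, independently across individuals.
#'
#' @param groups Character vector in `c("e4", "e2", "neither")`.
#' @param odds Named control/case odds per group.
#' @param seed Integer seed; the same seed reproduces the labels exactly.
#' @return Character vector `"case"`/`"control"`.
#' @export
bdAssignLabels <- function(groups, odds = c(e4 = 0.30, e2 = 2.41, neither = 0.89),
                           seed = 1) {
  if (!all(groups %in% names(odds)))
    stop("unknown genotype group(s): ",
         paste(setdiff(unique(groups), names(odds)), collapse = ", "), call. = FALSE)
  pControl <- odds[groups] / (1 + odds[groups])
  withSeed(seed, ifelse(stats::runif(length(groups)) < pControl, "control", "case"))
}

# Carrier groups for a BDSpec: >= 1 minor allele at the e4 locus (precedence),
# else >= 1 at the e2 locus, else neither. Carrier coding is dominant.
bdGroups <- function(store, spec, ids = NULL) {
  keys <- c(spec$e4Locus, spec$e2Locus)
  miss <- setdiff(keys, locusKeys(store))
  if (length(miss)) stop("BD locus absent from store: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  codes <- denseCodes(store, loci = keys, ids = ids, missingToZero = TRUE)
  g <- ifelse(codes[1, ] > 0, "e4", ifelse(codes[2, ] > 0, "e2", "neither"))
  for (k in c("e4", "e2", "neither"))
    if (!any(g == k)) stop("genotype group '", k, "' is empty (locus monomorphic?)",
                           call. = FALSE)
  stats::setNames(g, colnames(codes))
}

#' Assign a constructed disease over a genotyped population
#'
#' @param store A `GenotypeStore`.
#' @param spec A [bdSpec()].
#' @param ids Sample subset (default: all samples).
#' @return `data.frame` with `sample_id`, `group`, `status`.
#' @export
assignBdStatus <- function(store, spec, ids = NULL) {
  g <- bdGroups(store, spec, ids)
  status <- bdAssignLabels(unname(g), spec$odds, seed = spec$seed)
  data.frame(sample_id = names(g), group = unname(g), status = status,
             stringsAsFactors = FALSE)
}

#' Ascribe ages of diagnosis from group-wise empirical age distributions
#'
#' Each case's age is drawn by inverse-CDF sampling from its genotype
#' group's empirical reference ages (linear interpolation between order
#' statistics), so sampled ages always lie within the group's observed
#' range.
#'
#' @param bd Output of [assignBdStatus()] (needs `group` and `status`).
#' @param referenceAges Named list mapping each group to a non-empty numeric
#'   age vector.
#' @param seed Integer seed.
#' @return The `bd` frame with an `age` column (cases only; NA for controls).
#' @export
ascribeBdAge <- function(bd, referenceAges, seed = 1) {
  need <- setdiff(unique(bd$group), names(referenceAges))
  if (length(need)) stop("missing reference ages for group(s): ",
                         paste(need, collapse = ", "), call. = FALSE)
  if (any(!vapply(referenceAges, length, 1L)))
    stop("every reference age list must be non-empty", call. = FALSE)
  bd$age <- NA_real_
  iCase <- which(bd$status == "case")
  u <- withSeed(seed, stats::runif(length(iCase)))
  for (g in unique(bd$group[iCase])) {
    sel <- bd$group[iCase] == g
    bd$age[iCase[sel]] <- as.numeric(
      stats::quantile(referenceAges[[g]], u[sel], type = 7, names = FALSE))
  }
  bd
}

#' Full negative-control run of the scoring pipeline on constructed diseases
#'
#' For each BD: assigns status and ages, balances cohorts, scores `nTsnps`
#' target SNPs drawn from the lowest-FishP loci off the BD chromosome,
#' classifies them against a random-SNP band, and regresses the per-case
#' burden (raw and mCVt-weighted counts over the scored sets) on BD age of
#' diagnosis. The headline check is non-significance of those slopes for
#' loci off the BD chromosome.
#'
#' @param store A `GenotypeStore` (its `colData` provides cohorts and, for
#'   age ascription, case ages grouped by carrier genotype).
#' @param specs List of [bdSpec()] objects (one per BD).
#' @param nTsnps Targets scored per BD.
#' @param nRandom,repsPerSnp,alpha Null-band settings (see [nullBandMcvt()]).
#' @param nReps Repetitions per scored target.
#' @param config A [NetConfig-class].
#' @param topK Feature-matrix size.
#' @param seed Master seed.
#' @return `data.frame`: one row per (BD, burden predictor) with the GLM
#'   slope, F and p against BD age of diagnosis.
#' @export
bdNullValidation <- function(store, specs, nTsnps = 8, nRandom = 100,
                             repsPerSnp = 2, alpha = 0.05, nReps = 3,
                             config = netConfig(), topK = 50, seed = 1) {
  info <- sampleInfo(store)
  out <- list()
  for (bi in seq_along(specs)) {
    spec <- specs[[bi]]
    bd <- assignBdStatus(store, spec)
    groups <- bdGroups(store, spec)
    # reference ages: true case ages per carrier group
    caseAges <- split(info$age[info$status == "case"],
                      groups[rownames(info)[info$status == "case"]])
    bd <- ascribeBdAge(bd, caseAges, seed = childSeed(seed, "age", bi))
    bdChr <- lociInfo(store)$chr[match(spec$e4Locus, locusKeys(store))]
    samples <- data.frame(sample_id = bd$sample_id, cohort = info[bd$sample_id, "cohort"],
                          status = bd$status, age = bd$age, stringsAsFactors = FALSE)
    bdStore <- GenotypeStore(genoCodes(store), lociInfo(store), samples)
    cohorts <- filterCohorts(samples)
    pool <- balancedPool(samples, cohorts)
    offChr <- lociInfo(bdStore)$chr != bdChr
    rk <- rankSnps(bdStore, pool, topK = nTsnps + sum(!offChr))
    targets <- utils::head(rk$assoc$key[rk$assoc$chr != bdChr], nTsnps)
    band <- nullBandMcvt(bdStore, pool, nRandom = nRandom, alpha = alpha,
                         config = config, repsPerSnp = repsPerSnp,
                         seed = childSeed(seed, "band", bi), topK = topK)
    res <- lapply(targets, function(k)
      evaluateTsnp(bdStore, pool, k, nReps = nReps, config = config,
                   topK = topK, seed = childSeed(seed, "tsnp", bi, k)))
    cls <- classifyTsnps(res, band)
    iCase <- bd$sample_id[bd$status == "case"]
    sets <- list(protective = cls$locus[cls$class == "protective"],
                 risk = cls$locus[cls$class == "risk"])
    wts <- stats::setNames(abs(cls$mcvt), cls$locus)
    for (wMode in c("none", "cvt")) {
      bu <- burdenCounts(bdStore, iCase, sets, weights = wts, weighting = wMode)
      for (side in c("protective", "risk")) {
        xcol <- if (wMode == "none") paste0(side, "Count") else paste0("weighted", toupper(substr(side, 1, 1)), substr(side, 2, 99))
        xv <- bu[[xcol]]
        age <- bd$age[match(iCase, bd$sample_id)]
        fit <- if (stats::sd(xv) > 0) glmSlopeTest(xv, age) else
          list(beta = NA_real_, Fstat = NA_real_, p = NA_real_, n = length(xv))
        out[[length(out) + 1L]] <- data.frame(
          bd = bi, predictor = xcol, weighting = wMode,
          beta = fit$beta, Fstat = fit$Fstat, p = fit$p, n = fit$n,
          nProtective = length(sets$protective), nRisk = length(sets$risk))
      }
    }
  }
  do.call(rbind, out)
}

#' Largest case:control-balanced pool over retained cohorts
#'
#' Every retained cohort contributes all of its `min(cases, controls)`
#' case:control pairs, giving the maximal exactly balanced sample pool
#' (prevalence 0.5) from which training subsets are drawn.
#'
#' @param samples `data.frame` with `sample_id`, `cohort`, `status`.
#' @param cohorts Retained cohort labels (default [filterCohorts()]).
#' @param seed Seed for the within-cohort draws.
#' @return Character vector of sample ids.
#' @export
balancedPool <- function(samples, cohorts = filterCohorts(samples), seed = 1) {
  samples <- samples[samples$cohort %in% cohorts, , drop = FALSE]
  ids <- character(0)
  withSeed(seed, {
    for (co in unique(samples$cohort)) {
      d <- samples[samples$cohort == co, , drop = FALSE]
      k <- min(sum(d$status == "case"), sum(d$status == "control"))
      if (k == 0) next
      ids <- c(ids, sampleIdx(as.character(d$sample_id[d$status == "case"]), k),
               sampleIdx(as.character(d$sample_id[d$status == "control"]), k))
    }
  })
  ids
}
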