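# Per-SNP Fisher's exact association on allele counts, ranking, and Q-Q
# calibration against shuffled case/control labels.

#' Two-sided Fisher's exact p-value on a 2x2 allele-count table
#'
#' Exact two-sided p by the point-probability rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables whose point probability does
#' not exceed that of the observed table (relative tolerance 1e-7 on the
#' comparison, the common exact-test convention). Vectorized over tables;
#' the table is (case minor, case reference, control minor, control
#' reference) allele counts.
#'
#' @param caseMinor,caseRef,ctrlMinor,ctrlRef Non-negative count vectors
#'   (recycled to a common length).
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisherFishp(10, 10, 10, 10)            # identical groups -> 1
#' fisherFishp(12, 88, 2, 98)
fisherFishp <- function(caseMinor, caseRef, ctrlMinor, ctrlRef) {
  n <- max(length(caseMinor), length(caseRef), length(ctrlMinor), length(ctrlRef))
  a <- rep_len(as.numeric(caseMinor), n); b <- rep_len(as.numeric(caseRef), n)
  cc <- rep_len(as.numeric(ctrlMinor), n); d <- rep_len(as.numeric(ctrlRef), n)
  if (any(c(a, b, cc, d) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(a + b + cc + d == 0)) stop("all-zero table has no defined p-value", call. = FALSE)
  m <- a + cc          # minor-allele margin
  w <- b + d           # reference-allele margin
  k <- a + b           # case-allele margin
  lo <- pmax(0, k - w)
  hi <- pmin(k, m)
  dobs <- stats::dhyper(a, m, w, k)
  p <- numeric(n)
  lens <- hi - lo + 1
  # chunk the table expansion so memory stays bounded for large batches
  csum <- cumsum(lens)
  starts <- 1L
  while (starts <= n) {
    end <- max(starts, findInterval(csum[starts] - lens[starts] + 5e6, csum))
    idxs <- starts:end
    reps <- lens[idxs]
    tab <- rep.int(idxs, reps)
    x <- sequence(reps) - 1 + rep.int(lo[idxs], reps)
    dd <- stats::dhyper(x, m[tab], w[tab], k[tab])
    keep <- dd <= dobs[tab] * (1 + 1e-7)
    s <- rowsum(dd * keep, tab, reorder = TRUE)
    p[idxs] <- s[, 1]
    starts <- end + 1L
  }
  pmin(p, 1)
}

# Sparse helpers reused across shuffles: D = alt dosage with missing zeroed,
# M = missing indicator (both loci x subset-samples).
alleleCountMatrices <- function(store, ids = NULL) {
  g <- genoCodes(store)
  if (!is.null(ids)) g <- g[, ids, drop = FALSE]
  D <- g; M <- g
  D@x[D@x < 0] <- 0
  D <- Matrix::drop0(D)
  M@x <- as.numeric(M@x == -1)
  M <- Matrix::drop0(M)
  list(D = D, M = M, n = ncol(g))
}

# Allele-count 2x2 tables for a case-indicator z over the subset columns.
# mfaIsAlt fixes the minor-allele identity (computed once on the full subset,
# so it is stable across label shuffles).
alleleTables <- function(mats, z, mfaIsAlt) {
  nCase <- sum(z)
  caseAlt <- as.vector(mats$D %*% z)
  caseMiss <- as.vector(mats$M %*% z)
  totAlt <- as.vector(Matrix::rowSums(mats$D))
  totMiss <- as.vector(Matrix::rowSums(mats$M))
  caseAll <- 2 * (nCase - caseMiss)
  ctrlAll <- 2 * ((mats$n - nCase) - (totMiss - caseMiss))
  ctrlAlt <- totAlt - caseAlt
  caseMinor <- ifelse(mfaIsAlt, caseAlt, caseAll - caseAlt)
  ctrlMinor <- ifelse(mfaIsAlt, ctrlAlt, ctrlAll - ctrlAlt)
  data.frame(caseMinor = caseMinor, caseRef = caseAll - caseMinor,
             ctrlMinor = ctrlMinor, ctrlRef = ctrlAll - ctrlMinor)
}

#' Per-SNP association table on a sample subset
#'
#' Builds the allele-level 2x2 table (two alleles per non-missing individual,
#' missing genotypes excluded from both margins) for every locus and computes
#' the Fisher FishP. Loci whose MAF is undefined in the subset are returned
#' with `NA` FishP.
#'
#' @param store A `GenotypeStore`.
#' @param ids Sample ids/indices of the (typically balanced training) subset.
#' @return `data.frame` with `key`, `chr`, `pos`, `gene`, `maf`, `mfa`
#'   (`"alt"`/`"ref"`), `fishp` and the four table counts.
#' @export
snpAssoc <- function(store, ids = NULL) {
  st <- minorAlleleStats(store, ids)
  mats <- alleleCountMatrices(store, ids)
  info <- if (is.null(ids)) sampleInfo(store) else sampleInfo(store)[ids, , drop = FALSE]
  z <- as.numeric(info$status == "case")
  tab <- alleleTables(mats, z, st$mfaIsAlt)
  fishp <- rep(NA_real_, nrow(tab))
  ok <- st$defined & (tab$caseMinor + tab$caseRef + tab$ctrlMinor + tab$ctrlRef) > 0
  if (any(ok))
    fishp[ok] <- fisherFishp(tab$caseMinor[ok], tab$caseRef[ok],
                             tab$ctrlMinor[ok], tab$ctrlRef[ok])
  li <- lociInfo(store)
  data.frame(key = st$key, chr = li$chr, pos = li$pos, gene = li$gene,
             maf = st$maf, mfa = ifelse(st$mfaIsAlt, "alt", "ref"),
             fishp = fishp, tab, stringsAsFactors = FALSE)
}

#' Rank SNPs by training-set FishP and select features
#'
#' Sorts loci ascending by FishP (ties broken by chromosome then position),
#' removes loci matching the exclusion lists *before* selection, and returns
#' the first `topK` (or the loci in a rank `window`, e.g. `c(51, 100)`).
#' Loci with undefined MAF in the subset are dropped with a message.
#'
#' @param store A `GenotypeStore`.
#' @param ids Training sample ids (expected case:control balanced; a warning
#'   is raised otherwise).
#' @param exclusions Optional `list(genes = ..., loci = ...)` of gene labels
#'   and/or locus keys to remove before selection.
#' @param topK Number of loci to return (default 50).
#' @param window Optional rank window `c(from, to)` overriding `topK`.
#' @return `list(keys = character(), assoc = data.frame)` where `assoc` is
#'   the full sorted table.
#' @export
rankSnps <- function(store, ids, exclusions = NULL, topK = 50, window = NULL) {
  info <- sampleInfo(store)[ids, , drop = FALSE]
  if (sum(info$status == "case") != sum(info$status == "control"))
    warning("training subset is not case:control balanced")
  assoc <- snpAssoc(store, ids)
  nUndef <- sum(is.na(assoc$fishp))
  if (nUndef > 0)
    message(nUndef, " locus/loci with undefined MAF in subset dropped from ranking")
  assoc <- assoc[!is.na(assoc$fishp), , drop = FALSE]
  if (!is.null(exclusions)) {
    drop <- rep(FALSE, nrow(assoc))
    if (!is.null(exclusions$genes))
      drop <- drop | (!is.na(assoc$gene) & assoc$gene %in% exclusions$genes)
    if (!is.null(exclusions$loci)) drop <- drop | assoc$key %in% exclusions$loci
    assoc <- assoc[!drop, , drop = FALSE]
  }
  assoc <- assoc[order(assoc$fishp, assoc$chr, assoc$pos), , drop = FALSE]
  sel <- if (!is.null(window)) seq(window[1], window[2]) else seq_len(topK)
  if (max(sel) > nrow(assoc))
    stop("selection asks for rank ", max(sel), " but only ", nrow(assoc),
         " rankable loci are available", call. = FALSE)
  list(keys = assoc$key[sel], assoc = assoc)
}

#' Q-Q calibration of FishP against shuffled case/control labels
#'
#' Recomputes FishP under `nShuffles` label permutations (case/control totals
#' preserved) and returns sorted -log10 p quantiles for the observed labels
#' and for every shuffle. The pointwise range of the shuffle quantiles is the
#' chance band; shuffle-vs-shuffle pairs reproduce the published gray cloud.
#'
#' @param store A `GenotypeStore`.
#' @param ids Sample subset (default: all samples).
#' @param nShuffles Number of label shuffles (>= 2; default 100).
#' @param seed Integer seed.
#' @param excludeChromosome Optional chromosome label whose loci are removed
#'   before quantile computation (the chromosome-exclusion variant).
#' @return `list(observed, nullQuantiles (nShuffles x nLoci), keys)`, each
#'   quantile vector sorted ascending.
#' @export
qqNullBand <- function(store, ids = NULL, nShuffles = 100, seed = 1,
                       excludeChromosome = NULL) {
  if (nShuffles < 2) stop("nShuffles must be >= 2 (band undefined)", call. = FALSE)
  st <- minorAlleleStats(store, ids)
  mats <- alleleCountMatrices(store, ids)
  info <- if (is.null(ids)) sampleInfo(store) else sampleInfo(store)[ids, , drop = FALSE]
  z <- as.numeric(info$status == "case")
  keep <- st$defined
  if (!is.null(excludeChromosome))
    keep <- keep & !(lociInfo(store)$chr %in% excludeChromosome)
  pOf <- function(zz) {
    tab <- alleleTables(mats, zz, st$mfaIsAlt)[keep, , drop = FALSE]
    ok <- (tab$caseMinor + tab$caseRef + tab$ctrlMinor + tab$ctrlRef) > 0
    p <- rep(1, nrow(tab))
    p[ok] <- fisherFishp(tab$caseMinor[ok], tab$caseRef[ok],
                         tab$ctrlMinor[ok], tab$ctrlRef[ok])
    sort(-log10(p))
  }
  observed <- pOf(z)
  nullQ <- withSeed(seed, {
    t(vapply(seq_len(nShuffles), function(s) pOf(sample(z)), observed))
  })
  list(observed = observed, nullQuantiles = nullQ,
       keys = locusKeys(store)[keep])
}

#' Fraction of quantile ranks at which the observed curve lies inside the
#' shuffle band
#'
#' @param qq Output of [qqNullBand()].
#' @return Proportion in `[0, 1]`.
#' @export
qqBandCoverage <- function(qq) {
  lo <- apply(qq$nullQuantiles, 2, min)
  hi <- apply(qq$nullQuantiles, 2, max)
  mean(qq$observed >= lo & qq$observed <= hi)
}
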