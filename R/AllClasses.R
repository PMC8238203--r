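#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypeStore: sparse per-locus genotype codes with locus and sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `"geno"`
#' is a sparse integer-coded matrix (loci in rows, samples in columns) with
#' entries in \{-1, 1, 2\}: 1 = heterozygous, 2 = homozygous alternate,
#' -1 = missing call. Code 0 (homozygous reference) is the implicit sparse
#' default, which is what makes the representation ~100-fold smaller than the
#' VCF it came from while remaining lossless. `rowData` carries the locus
#' table (chromosome, position, ref, alt, gene); `colData` carries per-sample
#' phenotypes (cohort, status, age, braak, apoe).
#'
#' @export
setClass("GenotypeStore", contains = "SummarizedExperiment")

setValidity("GenotypeStore", function(object) {
  g <- SummarizedExperiment::assay(object, "geno")
  if (!inherits(g, "sparseMatrix")) return("assay 'geno' must be a sparse Matrix")
  x <- g@x
  if (length(x) && !all(x %in% c(-1, 1, 2)))
    return("stored genotype codes must be in {-1, 1, 2} (0 is implicit)")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chr", "pos", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    return("rowData must contain chr, pos, ref, alt")
  if (nrow(rd) > 0) {
    if (any(rd$pos < 1)) return("positions must be >= 1 (1-based, VCF convention)")
    if (any(rd$ref == rd$alt)) return("ref and alt alleles must differ")
    key <- paste(rd$chr, rd$pos, rd$alt, sep = ":")
    if (anyDuplicated(key)) return("loci must be unique by (chr, pos, alt)")
  }
  TRUE
})

#' Configuration of the pattern-recognition network and its SCG trainer
#'
#' Defaults mirror the published training setup: two hidden layers of 50 and
#' 10 tanh units, scaled conjugate gradient with `maxEpochs = 1000`,
#' `minGrad = 1e-6`, `maxFails = 10` consecutive validation failures,
#' second-derivative step scale `wtSigma = 5e-5`, Hessian-indefiniteness
#' regulator `lambda0 = 5e-7`, and a cross-entropy performance with
#' regularization ratio `reg = 0.1`.
#'
#' @export
setClass("NetConfig", representation(
  hidden = "numeric", maxEpochs = "numeric", minGrad = "numeric",
  maxFails = "numeric", wtSigma = "numeric", lambda0 = "numeric",
  reg = "numeric", seed = "numeric"))

setValidity("NetConfig", function(object) {
  if (length(object@hidden) < 1) return("hidden must be non-empty")
  if (any(object@hidden < 1)) return("hidden layer sizes must be >= 1")
  if (object@reg < 0 || object@reg >= 1) return("reg must be in [0, 1)")
  for (s in c("maxEpochs", "minGrad", "wtSigma", "lambda0"))
    if (slot(object, s) < 0) return(paste(s, "must be >= 0"))
  TRUE
})

#' @rdname NetConfig-class
#' @param hidden Integer vector of hidden-layer sizes.
#' @param maxEpochs,minGrad,maxFails,wtSigma,lambda0,reg,seed Trainer settings;
#'   see the class description.
#' @return A `NetConfig` object.
#' @export
netConfig <- function(hidden = c(50, 10), maxEpochs = 1000, minGrad = 1e-6,
                      maxFails = 10, wtSigma = 5e-5, lambda0 = 5e-7,
                      reg = 0.1, seed = 1) {
  new("NetConfig", hidden = hidden, maxEpochs = maxEpochs, minGrad = minGrad,
      maxFails = maxFails, wtSigma = wtSigma, lambda0 = lambda0,
      reg = reg, seed = seed)
}

#' A trained pattern-recognition network with frozen weights
#'
#' Weights are fixed once training returns; applying the network never
#' mutates it. `featureLoci` records the ordered SNP feature list,
#' `scaling` the per-feature affine map fitted on the training set, and
#' `history` per-epoch training/validation performance and gradient norm.
#'
#' @export
setClass("TrainedNet", representation(
  weights = "list",        # list of layers, each list(W = matrix, b = numeric)
  featureLoci = "character",
  scaling = "list",        # list(lo = numeric, hi = numeric) per feature
  classes = "character",
  config = "NetConfig",
  history = "data.frame",
  stopReason = "character"))

#' Per-target-SNP scoring result
#'
#' `nat`, `ref`, `alt` are holdout-by-repetition matrices of classifier
#' values with true genotypes, the target forced homozygous reference-scale,
#' and the target forced homozygous minor allele respectively; `dif` is
#' `alt - ref` (accessor [difScores()]). `mcvt` is the mean of all ALT scores
#' over individuals and repetitions and `dispersion` the standard error of
#' the per-repetition means.
#'
#' @export
setClass("TSnpResult", representation(
  locus = "character", nat = "matrix", ref = "matrix", alt = "matrix",
  mcvt = "numeric", dispersion = "numeric", nReps = "integer",
  mfaIsAlt = "logical", seed = "integer"))

setValidity("TSnpResult", function(object) {
  if (object@nReps < 1L) return("nReps must be >= 1")
  if (length(object@mcvt) == 1 && !is.na(object@mcvt) &&
      (object@mcvt < -0.5 - 1e-12 || object@mcvt > 0.5 + 1e-12))
    return("mcvt must lie in [-0.5, 0.5]")
  TRUE
})

#' Null distribution of mCVt from randomly chosen target SNPs
#'
#' Holds the empirical mCVt sample obtained by scoring randomly drawn target
#' SNPs, together with the central interval at level `1 - alpha` used to call
#' a scored SNP protective (below), risk (above), or indeterminate (inside).
#'
#' @export
setClass("NullBand", representation(
  sample = "numeric", lower = "numeric", upper = "numeric",
  alpha = "numeric", nRandom = "integer", repsPerSnp = "integer",
  seed = "integer"))

setValidity("NullBand", function(object) {
  if (length(object@sample) < 2) return("null sample must hold >= 2 values")
  if (object@lower > object@upper) return("lower must be <= upper")
  TRUE
})

#' Replayable training/validation/holdout partition
#'
#' Pairwise-disjoint identifier lists; the training partition is exactly
#' case:control balanced within every retained cohort.
#'
#' @export
setClass("SplitSpec", representation(
  trainIds = "character", validationIds = "character", holdoutIds = "character",
  perCohort = "data.frame", seed = "integer"))

setValidity("SplitSpec", function(object) {
  ids <- c(object@trainIds, object@validationIds, object@holdoutIds)
  if (anyDuplicated(ids)) return("partitions must be pairwise disjoint")
  TRUE
})

setMethod("show", "GenotypeStore", function(object) {
  g <- SummarizedExperiment::assay(object, "geno")
  cat(sprintf("GenotypeStore: %d loci x %d samples (%d stored codes, %.2f%% dense)\n",
              nrow(object), ncol(object), length(g@x),
              100 * length(g@x) / max(1, prod(dim(object)))))
  callNextMethod()
})

setMethod("show", "TrainedNet", function(object) {
  sizes <- vapply(object@weights, function(l) ncol(l$W), 1L)
  cat(sprintf("TrainedNet: %d features -> [%s] -> %d classes; stopped on %s after %d epochs\n",
              length(object@featureLoci),
              paste(utils::head(sizes, -1), collapse = ","),
              utils::tail(sizes, 1), object@stopReason, nrow(object@history)))
})

setMethod("show", "TSnpResult", function(object) {
  cat(sprintf("TSnpResult %s: mCVt = %.4f (SE %.4f) over %d repetitions x %d holdout individuals\n",
              object@locus, object@mcvt, object@dispersion, object@nReps,
              nrow(object@alt)))
})

setMethod("show", "NullBand", function(object) {
  cat(sprintf("NullBand: %d random target SNPs, central %.0f%% interval [%.4f, %.4f]\n",
              object@nRandom, 100 * (1 - object@alpha), object@lower, object@upper))
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %d train / %d validation / %d holdout (seed %d)\n",
              length(object@trainIds), length(object@validationIds),
              length(object@holdoutIds), object@seed))
})

#' @rdname TSnpResult-class
#' @param x A `TSnpResult`.
#' @return `difScores` returns the elementwise `alt - ref` matrix;
#'   `mcvt` the mean ALT classifier value.
#' @export
difScores <- function(x) x@alt - x@ref

#' @rdname TSnpResult-class
#' @export
mcvt <- function(x) x@mcvt
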