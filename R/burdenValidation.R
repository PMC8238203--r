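# Per-individual burden counts over classified target-SNP sets (raw and
# mCVt-weighted) and single-predictor GLM slope tests against age of
# diagnosis and Braak stage -- the validation surface of the method.

#' Per-individual burden over protective and risk SNP sets
#'
#' Burden is minor-allele dosage (0/1/2; missing = 0) summed over the set's
#' loci; the weighted variant sums `dosage * |mCVt|` within each
#' sign-separated set (set membership already encodes direction). A
#' carrier-indicator mode (each locus contributing at most 1) is available.
#'
#' @param store A `GenotypeStore`.
#' @param ids Sample ids/indices.
#' @param sets `list(protective = keys, risk = keys)` (either may be empty).
#' @param weights Named `|mCVt|` vector (by locus key); required for
#'   `weighting = "cvt"`.
#' @param weighting `"none"` (unit weights: weighted sums equal counts) or
#'   `"cvt"`.
#' @param carrierIndicator Count carriers instead of allele dosage.
#' @return `data.frame` with `sample_id`, `protectiveCount`, `riskCount`,
#'   `weightedProtective`, `weightedRisk`.
#' @export
burdenCounts <- function(store, ids, sets, weights = NULL,
                         weighting = c("none", "cvt"),
                         carrierIndicator = FALSE) {
  weighting <- match.arg(weighting)
  allKeys <- locusKeys(store)
  oneSide <- function(keys) {
    if (length(keys) == 0)
      return(list(count = rep(0, length(ids)), wsum = rep(0, length(ids))))
    miss <- setdiff(keys, allKeys)
    if (length(miss)) stop("set locus absent from store: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    dos <- denseCodes(store, loci = keys, ids = ids, missingToZero = TRUE)
    if (carrierIndicator) dos <- (dos > 0) + 0
    w <- if (weighting == "cvt") {
      if (is.null(weights) || !all(keys %in% names(weights)))
        stop("cvt weighting needs a |mCVt| weight for every set locus", call. = FALSE)
      abs(weights[keys])
    } else rep(1, length(keys))
    list(count = colSums(dos), wsum = colSums(dos * w))
  }
  pr <- oneSide(sets$protective)
  ri <- oneSide(sets$risk)
  info <- sampleInfo(store)[ids, , drop = FALSE]
  data.frame(sample_id = rownames(info),
             protectiveCount = unname(pr$count), riskCount = unname(ri$count),
             weightedProtective = unname(pr$wsum), weightedRisk = unname(ri$wsum),
             stringsAsFactors = FALSE)
}

#' Single-predictor GLM slope test
#'
#' Ordinary least squares with intercept; the slope is tested by the F
#' statistic on (1, n - 2) degrees of freedom (identical to the squared-t
#' formulation). Implemented in closed form so that null-calibration sweeps
#' over thousands of regressions stay cheap; equality with `lm()`/`anova()`
#' is covered by tests.
#'
#' @param x Predictor vector (non-constant).
#' @param y Response vector.
#' @return `list(beta, intercept, Fstat, df1, df2, p, n)`.
#' @export
glmSlopeTest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant predictor", call. = FALSE)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - beta * mean(x)
  res <- y - intercept - beta * x
  rss <- sum(res^2)
  ssReg <- beta^2 * sxx
  Fstat <- if (rss > 0) ssReg / (rss / (n - 2)) else Inf
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(beta = beta, intercept = intercept, Fstat = Fstat,
       df1 = 1L, df2 = n - 2L, p = p, n = n)
}

#' Burden-vs-phenotype validation report
#'
#' One slope test per (predictor, response) cell: predictors are the CV (if
#' supplied), raw and mCVt-weighted protective/risk burden counts, and
#' optionally a published-SNP list (raw and weighted); responses are age of
#' diagnosis (cases only) and Braak stage (autopsied individuals). Expected
#' sign conventions: protective burden correlates positively with age of
#' diagnosis and negatively with Braak; risk burden the reverse.
#'
#' @param store A `GenotypeStore` whose `colData` carries `status`, `age`
#'   and optionally `braak`.
#' @param sets `list(protective = keys, risk = keys)` of classified SNPs.
#' @param weights Named `|mCVt|` vector by locus key.
#' @param cv Optional named CV vector (by sample id).
#' @param publishedLoci Optional key vector of previously published SNPs.
#' @param publishedWeights Optional named `|mCVt|` for the published list.
#' @return `data.frame`: one row per regression (predictor, response, n,
#'   beta, F, df, p).
#' @export
validationReport <- function(store, sets, weights = NULL, cv = NULL,
                             publishedLoci = NULL, publishedWeights = NULL) {
  info <- sampleInfo(store)
  rows <- list()
  addRow <- function(predictor, response, x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return()
    fit <- glmSlopeTest(x[ok], y[ok])
    rows[[length(rows) + 1L]] <<- data.frame(
      predictor = predictor, response = response, n = fit$n,
      beta = fit$beta, Fstat = fit$Fstat, df1 = fit$df1, df2 = fit$df2,
      p = fit$p, stringsAsFactors = FALSE)
  }
  targets <- list(
    age = rownames(info)[info$status == "case" & !is.na(info$age)],
    braak = if ("braak" %in% colnames(info) && any(!is.na(info$braak)))
      rownames(info)[!is.na(info$braak)] else NULL)
  if (is.null(targets$braak)) warning("no autopsied individuals; Braak rows omitted")
  for (resp in names(targets)) {
    ids <- targets[[resp]]
    if (is.null(ids) || length(ids) < 3) next
    y <- if (resp == "age") info[ids, "age"] else as.numeric(info[ids, "braak"])
    raw <- burdenCounts(store, ids, sets, weighting = "none")
    if (!is.null(cv)) addRow("cv", resp, as.numeric(cv[ids]), y)
    addRow("protectiveCount", resp, raw$protectiveCount, y)
    addRow("riskCount", resp, raw$riskCount, y)
    if (!is.null(weights)) {
      wtd <- burdenCounts(store, ids, sets, weights = weights, weighting = "cvt")
      addRow("weightedProtective", resp, wtd$weightedProtective, y)
      addRow("weightedRisk", resp, wtd$weightedRisk, y)
    }
    if (!is.null(publishedLoci)) {
      pubSets <- list(protective = character(0), risk = publishedLoci)
      pubRaw <- burdenCounts(store, ids, pubSets, weighting = "none")
      addRow("publishedCount", resp, pubRaw$riskCount, y)
      if (!is.null(publishedWeights)) {
        pubW <- burdenCounts(store, ids, pubSets, weights = publishedWeights,
                             weighting = "cvt")
        addRow("weightedPublished", resp, pubW$weightedRisk, y)
      }
    }
  }
  do.call(rbind, rows)
}
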