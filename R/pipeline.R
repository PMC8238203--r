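# End-to-end orchestration: compress -> filter/balance -> rank -> train ->
# evaluate -> score target SNPs -> classify -> burden validation, with every
# stage seed derived from one master seed and every artifact written to a
# run directory so a run can be replayed bit-identically.

#' Assemble a pipeline configuration
#'
#' @param nTrain,nHoldout,validationFrac Split sizes (see [balancedSplit()]).
#' @param topK Feature-matrix size (default 50).
#' @param exclusions Optional `list(genes, loci)` removed from feature ranking.
#' @param net A [NetConfig-class].
#' @param nTargets Number of lowest-FishP loci scored as target SNPs.
#' @param nReps Repetitions per target SNP (default 20).
#' @param nRandom,repsPerSnp,alpha Null-band settings (see [nullBandMcvt()]).
#' @param prevalence Prevalence grid for [prevalenceMetrics()].
#' @param seed Master seed; each stage uses `childSeed(seed, stage)`.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(nTrain = 3200, nHoldout = 1500, validationFrac = 0.15,
                           topK = 50, exclusions = NULL, net = netConfig(),
                           nTargets = 20, nReps = 20, nRandom = 1000,
                           repsPerSnp = 5, alpha = 0.05,
                           prevalence = seq(0.05, 0.5, 0.05), seed = 1) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full pipeline on a genotype store
#'
#' @param store A `GenotypeStore` (use [readVcfGenotypes()] first for VCF
#'   input) whose `colData` carries cohort/status/age (and optionally braak).
#' @param config A [pipelineConfig()].
#' @param outDir Run directory (created if needed).
#' @return Invisibly, a list with the split, association table, trained net,
#'   metrics, classified target-SNP table and validation report.
#' @export
runPipeline <- function(store, config = pipelineConfig(), outDir = tempfile("run")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file.path(outDir, "log.txt")
  logStage <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste(..., collapse = " ")),
        file = logCon, append = TRUE)
  }
  samples <- sampleInfo(store)
  samples$sample_id <- rownames(samples)

  cohorts <- filterCohorts(samples)
  logStage("filter", length(cohorts), "of", length(unique(samples$cohort)),
           "cohorts retained")
  split <- balancedSplit(samples, cohorts, nTrain = config$nTrain,
                         nHoldout = config$nHoldout,
                         validationFrac = config$validationFrac,
                         seed = childSeed(config$seed, "split"))
  writeSplitSpec(split, file.path(outDir, "split.json"))
  logStage("balance", "train", length(split@trainIds), "validation",
           length(split@validationIds), "holdout", length(split@holdoutIds))

  rankIds <- c(split@trainIds, split@validationIds)
  rk <- rankSnps(store, rankIds, exclusions = config$exclusions,
                 topK = config$topK)
  utils::write.table(rk$assoc, file.path(outDir, "assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logStage("rank", "top FishP", format(rk$assoc$fishp[1], digits = 3))

  netCfg <- config$net
  netCfg@seed <- childSeed(config$seed, "train")
  net <- trainClassifier(store, split@trainIds, split@validationIds,
                         rk$keys, netCfg)
  writeTrainedNet(net, file.path(outDir, "net.json"))
  logStage("train", "stopped on", net@stopReason, "after",
           nrow(net@history), "epochs")

  hf <- buildFeatureMatrix(store, split@holdoutIds, rk$keys,
                           scaling = net@scaling)
  cvHold <- predictCv(net, hf$x)
  roc <- rocCurve(cvHold + 0.5, hf$y)
  metrics <- list(
    accuracy = cvAccuracy(cvHold, hf$y),
    accuracyOuterQuartiles = cvAccuracy(cvHold, hf$y, "outer_quantile", 0.5),
    accuracyOuter25 = cvAccuracy(cvHold, hf$y, "outer_quantile", 0.25),
    auc = roc$auc,
    prevalence = prevalenceMetrics(cvHold, hf$y, config$prevalence))
  logit <- logisticBaseline(
    buildFeatureMatrix(store, c(split@trainIds, split@validationIds), rk$keys,
                       scaling = net@scaling)$x,
    buildFeatureMatrix(store, c(split@trainIds, split@validationIds), rk$keys,
                       scaling = net@scaling)$y,
    hf$x, hf$y)
  metrics$logisticAccuracy <- logit$accuracy
  metrics$mcnemar <- mcnemarTest(as.numeric(cvHold > 0), logit$predictions, hf$y)
  jsonlite::write_json(metrics[c("accuracy", "accuracyOuterQuartiles",
                                 "accuracyOuter25", "auc", "logisticAccuracy")],
                       file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  logStage("eval", "accuracy", round(metrics$accuracy, 1), "auc",
           round(metrics$auc, 3))

  pool <- balancedPool(samples, cohorts, seed = childSeed(config$seed, "pool"))
  targets <- utils::head(rk$assoc$key, config$nTargets)
  band <- nullBandMcvt(store, pool, nRandom = config$nRandom,
                       alpha = config$alpha, config = config$net,
                       repsPerSnp = config$repsPerSnp,
                       seed = childSeed(config$seed, "band"),
                       topK = config$topK, exclusions = config$exclusions)
  results <- lapply(targets, function(k)
    evaluateTsnp(store, pool, k, nReps = config$nReps, config = config$net,
                 topK = config$topK, exclusions = config$exclusions,
                 seed = childSeed(config$seed, "tsnp", k)))
  cls <- classifyTsnps(results, band)
  assocIdx <- match(cls$locus, rk$assoc$key)
  cls$fishp <- rk$assoc$fishp[assocIdx]
  cls$maf <- rk$assoc$maf[assocIdx]
  cls$gene <- rk$assoc$gene[assocIdx]
  utils::write.table(cls, file.path(outDir, "tsnp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logStage("score", sum(cls$class == "protective"), "protective,",
           sum(cls$class == "risk"), "risk,",
           sum(cls$class == "indeterminate"), "indeterminate")

  sets <- list(protective = cls$locus[cls$class == "protective"],
               risk = cls$locus[cls$class == "risk"])
  weights <- stats::setNames(abs(cls$mcvt), cls$locus)
  cvAll <- stats::setNames(
    predictCv(net, buildFeatureMatrix(store, samples$sample_id, rk$keys,
                                      scaling = net@scaling)$x),
    samples$sample_id)
  report <- validationReport(store, sets, weights = weights, cv = cvAll)
  utils::write.table(report, file.path(outDir, "validation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logStage("validate", nrow(report), "regressions")

  jsonlite::write_json(
    list(seed = config$seed, nTrain = config$nTrain, nHoldout = config$nHoldout,
         topK = config$topK, nTargets = config$nTargets, nReps = config$nReps,
         nRandom = config$nRandom, alpha = config$alpha,
         files = as.list(tools::md5sum(list.files(outDir, full.names = TRUE)))),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(split = split, assoc = rk$assoc, net = net,
                 metrics = metrics, band = band, tsnps = cls,
                 validation = report, dir = outDir))
}
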