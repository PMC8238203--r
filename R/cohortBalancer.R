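# Cohort filtering and case:control-balanced partitioning. Training sets are
# balanced exactly (prevalence 0.5) within every retained cohort, so the
# classifier cannot exploit cohort-specific case:control imbalance.

#' Retain cohorts that are large and balanced enough for training
#'
#' A cohort is kept iff it has at least `minTotal` individuals and its
#' minority class (cases or controls) is at least `minMinorityFrac` of its
#' majority class.
#'
#' @param samples `data.frame` with columns `cohort` and `status`.
#' @param minMinorityFrac Minimum minority/majority ratio (default 0.20).
#' @param minTotal Minimum cohort size (default 20).
#' @return Character vector of retained cohort labels.
#' @export
filterCohorts <- function(samples, minMinorityFrac = 0.20, minTotal = 20) {
  if (nrow(samples) == 0L) stop("empty sample table", call. = FALSE)
  if (anyNA(samples$cohort) || anyNA(samples$status))
    stop("every sample needs a cohort label and a status", call. = FALSE)
  tab <- table(samples$cohort, factor(samples$status, c("case", "control")))
  lo <- pmin(tab[, 1], tab[, 2])
  hi <- pmax(tab[, 1], tab[, 2])
  keep <- (tab[, 1] + tab[, 2]) >= minTotal & hi > 0 & lo / hi >= minMinorityFrac
  rownames(tab)[keep]
}

#' Draw a balanced training / validation / holdout partition
#'
#' The training pool takes an equal number of cases and controls from every
#' retained cohort (allocation proportional to each cohort's capacity
#' `min(cases, controls)`); a `validationFrac` share of the pool is carved
#' off (per cohort, in case/control pairs) as the validation partition, so
#' both training and validation are exactly balanced. The holdout partition
#' is drawn from the remaining retained-cohort samples and is *not* forced
#' to prevalence 0.5 unless `balancedHoldout = TRUE`.
#'
#' @param samples `data.frame` with `sample_id`, `cohort`, `status`.
#' @param cohorts Retained cohort labels; default [filterCohorts()] output.
#' @param nTrain Total size of the training pool (training + validation);
#'   must be even.
#' @param nHoldout Holdout size.
#' @param validationFrac Fraction of the training pool used for validation
#'   (default 0.15).
#' @param balancedHoldout Force the holdout to equal case/control counts.
#' @param seed Integer seed; the same seed reproduces the partition exactly.
#' @return A [SplitSpec-class].
#' @export
balancedSplit <- function(samples, cohorts = filterCohorts(samples), nTrain,
                          nHoldout, validationFrac = 0.15,
                          balancedHoldout = FALSE, seed = 1) {
  if (nTrain %% 2 != 0) stop("nTrain must be even (case:control pairs)", call. = FALSE)
  samples <- samples[samples$cohort %in% cohorts, , drop = FALSE]
  samples$sample_id <- as.character(samples$sample_id)
  byC <- split(samples, samples$cohort)
  cap <- vapply(byC, function(d) min(sum(d$status == "case"),
                                     sum(d$status == "control")), 1L)
  pairs <- nTrain / 2
  if (sum(cap) < pairs) {
    stop(sprintf("infeasible split: %d case:control pairs requested, capacity %d (per-cohort: %s)",
                 pairs, sum(cap),
                 paste(names(cap), cap, sep = "=", collapse = ", ")), call. = FALSE)
  }
  # largest-remainder allocation proportional to capacity, capped by capacity
  raw <- cap * pairs / sum(cap)
  alloc <- pmin(floor(raw), cap)
  while (sum(alloc) < pairs) {
    room <- cap - alloc
    frac <- ifelse(room > 0, raw - alloc, -Inf)
    i <- which.max(frac)
    alloc[i] <- alloc[i] + 1L
  }
  withSeed(seed, {
    trainIds <- character(0); valIds <- character(0)
    perCohort <- data.frame(cohort = names(byC), trainPairs = as.integer(alloc),
                            stringsAsFactors = FALSE)
    for (co in names(byC)) {
      d <- byC[[co]]
      k <- alloc[[co]]
      if (k == 0) next
      ca <- sampleIdx(d$sample_id[d$status == "case"], k)
      ct <- sampleIdx(d$sample_id[d$status == "control"], k)
      kv <- floor(validationFrac * k)
      valIds <- c(valIds, ca[seq_len(kv)], ct[seq_len(kv)])
      trainIds <- c(trainIds, ca[seq_len(k) > kv], ct[seq_len(k) > kv])
    }
    rest <- samples[!(samples$sample_id %in% c(trainIds, valIds)), , drop = FALSE]
    if (balancedHoldout) {
      if (nHoldout %% 2 != 0) stop("nHoldout must be even when balancedHoldout", call. = FALSE)
      hca <- rest$sample_id[rest$status == "case"]
      hct <- rest$sample_id[rest$status == "control"]
      if (min(length(hca), length(hct)) < nHoldout / 2)
        stop("infeasible balanced holdout: need ", nHoldout / 2,
             " of each status, have ", length(hca), " cases / ",
             length(hct), " controls", call. = FALSE)
      holdIds <- c(sampleIdx(hca, nHoldout / 2), sampleIdx(hct, nHoldout / 2))
    } else {
      if (nrow(rest) < nHoldout)
        stop("infeasible holdout: ", nHoldout, " requested, ",
             nrow(rest), " samples remain", call. = FALSE)
      holdIds <- sampleIdx(rest$sample_id, nHoldout)
    }
  })
  methods::new("SplitSpec", trainIds = trainIds, validationIds = valIds,
               holdoutIds = holdIds, perCohort = perCohort,
               seed = as.integer(seed))
}

#' Serialize / restore a SplitSpec as JSON
#'
#' @param split A `SplitSpec`.
#' @param path JSON path.
#' @return `readSplitSpec` returns a [SplitSpec-class]; `writeSplitSpec`
#'   returns `path` invisibly.
#' @export
writeSplitSpec <- function(split, path) {
  jsonlite::write_json(
    list(trainIds = split@trainIds, validationIds = split@validationIds,
         holdoutIds = split@holdoutIds, perCohort = split@perCohort,
         seed = split@seed),
    path, dataframe = "columns", auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeSplitSpec
#' @export
readSplitSpec <- function(path) {
  x <- jsonlite::fromJSON(path)
  methods::new("SplitSpec",
               trainIds = as.character(x$trainIds),
               validationIds = as.character(x$validationIds),
               holdoutIds = as.character(x$holdoutIds),
               perCohort = as.data.frame(x$perCohort),
               seed = as.integer(x$seed))
}
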