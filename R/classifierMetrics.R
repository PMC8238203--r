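# Accuracy (full and confidence-restricted), ROC/AUC, cost-based optimal
# operating point, prevalence-swept FDR/PPV, and baseline comparisons.

#' Percent correct of CV-based classification
#'
#' Prediction is case iff CV > 0 (a CV of exactly 0 predicts control, since
#' zero is not positive). `mode = "outer_quantile"` keeps the `frac/2` lowest
#' and `frac/2` highest CVs before scoring; `mode = "abs_cv"` keeps the top
#' `frac` by `|CV|`.
#'
#' @param cv Numeric CV vector in `[-0.5, 0.5]`.
#' @param labels 0/1 (or `"control"`/`"case"`) vector aligned with `cv`.
#' @param mode `"all"`, `"outer_quantile"` or `"abs_cv"`.
#' @param frac Fraction retained for the restricted modes, in (0, 1].
#' @return Percent correct (0-100).
#' @export
cvAccuracy <- function(cv, labels, mode = c("all", "outer_quantile", "abs_cv"),
                       frac = 1.0) {
  mode <- match.arg(mode)
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  y <- if (is.character(labels) || is.factor(labels))
    as.numeric(as.character(labels) == "case") else as.numeric(labels)
  keep <- switch(mode,
    all = seq_along(cv),
    outer_quantile = {
      k <- max(1L, floor(frac / 2 * length(cv)))
      ord <- order(cv)
      c(ord[seq_len(k)], ord[seq(length(cv) - k + 1L, length(cv))])
    },
    abs_cv = {
      k <- max(1L, floor(frac * length(cv)))
      order(abs(cv), decreasing = TRUE)[seq_len(k)]
    })
  pred <- as.numeric(cv[keep] > 0)
  100 * mean(pred == y[keep])
}

#' ROC curve and AUC from scores in [0, 1]
#'
#' The curve sweeps the threshold over the unique scores; AUC is the
#' trapezoid area, which equals the Mann-Whitney U statistic divided by
#' (P * N).
#'
#' @param scores Numeric scores (higher = more case-like), e.g. CV + 0.5.
#' @param labels 0/1 (or `"control"`/`"case"`) vector.
#' @return `list(thresholds, fpr, tpr, auc)` with `fpr`/`tpr` non-decreasing.
#' @export
rocCurve <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.numeric(as.character(labels) == "case") else as.numeric(labels)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # cumulative counts at each unique threshold (prediction: score >= thr)
  grp <- cumsum(!duplicated(ss))
  tpAll <- cumsum(ys); fpAll <- cumsum(1 - ys)
  last <- c(which(diff(grp) != 0), length(grp))
  tp <- c(0, tpAll[last]); fp <- c(0, fpAll[last])
  fpr <- fp / N; tpr <- tp / P
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

#' Cost-slope optimal operating point on a ROC curve
#'
#' The slope is `S = (Cost(P|N) - Cost(N|N)) / (Cost(N|P) - Cost(P|P)) * N/P`;
#' the operating point is the first ROC point touched by a line of slope S
#' moved down-and-right from (FPR 0, TPR 1), i.e. the point maximizing
#' `TPR - S * FPR` (smallest FPR on ties). The returned threshold realizes
#' that point under the rule "predict case iff score >= threshold".
#'
#' @param roc Output of [rocCurve()].
#' @param costs `list(cPN, cNN, cNP, cPP)`: costs of predicting P for a true
#'   N, N for N, N for P, P for P. Requires `cNP > cPP` and `cPN > cNN`.
#' @param P,N True case and control counts.
#' @return `list(S, threshold, fpr, tpr)`.
#' @export
optimalOperatingPoint <- function(roc, costs = list(cPN = 1, cNN = 0, cNP = 1, cPP = 0),
                                  P, N) {
  if (costs$cNP <= costs$cPP || costs$cPN <= costs$cNN)
    stop("misclassification costs must exceed correct-classification costs", call. = FALSE)
  if (length(roc$fpr) < 2) stop("degenerate ROC (single point)", call. = FALSE)
  S <- (costs$cPN - costs$cNN) / (costs$cNP - costs$cPP) * N / P
  score <- roc$tpr - S * roc$fpr
  i <- which(score == max(score))
  i <- i[which.min(roc$fpr[i])]
  list(S = S, threshold = roc$thresholds[i], fpr = roc$fpr[i], tpr = roc$tpr[i])
}

#' FDR, PPV, sensitivity and specificity across a prevalence sweep
#'
#' The holdout confusion rates are analytically reweighted to each target
#' prevalence (deterministic; a resampling mode is available for
#' cross-checks): at prevalence p, `TP = p * TPR`, `FP = (1 - p) * FPR`, etc.
#' `PPV + FDR = 1` identically.
#'
#' @param cv CV vector of a (typically prevalence-0.5) holdout.
#' @param labels 0/1 labels aligned with `cv`.
#' @param prevalence Numeric grid in (0, 1), default `seq(0.05, 0.5, 0.05)`.
#' @param thresholdMode `"fixed_zero"` (CV threshold 0) or `"oop"` (cost-slope
#'   optimum recomputed at each prevalence with `N/P = (1-p)/p`).
#' @param costs Cost list as in [optimalOperatingPoint()].
#' @param resample Optionally resample (with replacement, under `seed`) to
#'   each prevalence instead of analytic reweighting.
#' @param seed Seed for the resampling mode.
#' @return `data.frame` with one row per grid point.
#' @export
prevalenceMetrics <- function(cv, labels, prevalence = seq(0.05, 0.5, 0.05),
                              thresholdMode = c("fixed_zero", "oop"),
                              costs = list(cPN = 1, cNN = 0, cNP = 1, cPP = 0),
                              resample = FALSE, seed = 1) {
  thresholdMode <- match.arg(thresholdMode)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence grid must lie in (0, 1)", call. = FALSE)
  y <- if (is.character(labels) || is.factor(labels))
    as.numeric(as.character(labels) == "case") else as.numeric(labels)
  scores <- cv + 0.5
  roc <- rocCurve(scores, y)
  out <- lapply(prevalence, function(p) {
    thr <- if (thresholdMode == "fixed_zero") 0.5 else
      optimalOperatingPoint(roc, costs, P = p, N = 1 - p)$threshold
    if (resample) {
      n <- length(y)
      idx <- withSeed(childSeed(seed, "prev", round(p * 1000)), {
        ca <- which(y == 1); ct <- which(y == 0)
        c(sample(ca, round(p * n), replace = TRUE),
          sample(ct, n - round(p * n), replace = TRUE))
      })
      pr <- as.numeric(scores[idx] >= thr); yy <- y[idx]
      tp <- sum(pr & yy); fp <- sum(pr & !yy)
      fn <- sum(!pr & yy); tn <- sum(!pr & !yy)
    } else {
      pred <- as.numeric(scores >= thr)
      tprE <- sum(pred & y) / sum(y)
      fprE <- sum(pred & !y) / sum(!y)
      tp <- p * tprE; fn <- p * (1 - tprE)
      fp <- (1 - p) * fprE; tn <- (1 - p) * (1 - fprE)
    }
    fdr <- if (tp + fp > 0) fp / (fp + tp) else 0
    data.frame(prevalence = p, threshold = thr, fdr = fdr, ppv = 1 - fdr,
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  })
  do.call(rbind, out)
}

#' Ridge-stabilized logistic-regression baseline
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a ridge of 1e-6 on the coefficients (guards against complete
#' separation); prediction threshold 0.5.
#'
#' @param x Training feature matrix.
#' @param y Training 0/1 labels.
#' @param xNew Holdout feature matrix.
#' @param yNew Optional holdout labels, for accuracy.
#' @param maxIter IRLS iteration cap (default 100).
#' @return `list(coefficients, predictions, probabilities, accuracy)`.
#' @export
logisticBaseline <- function(x, y, xNew, yNew = NULL, maxIter = 100) {
  X <- cbind(1, as.matrix(x))
  y <- as.numeric(y)
  beta <- rep(0, ncol(X))
  ridge <- 1e-6
  for (it in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wgt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * wgt, X) + diag(ridge, ncol(X))
    g <- crossprod(X, y - mu) - ridge * beta
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-10) break
    if (it == maxIter) stop("IRLS did not converge in ", maxIter, " iterations",
                            call. = FALSE)
  }
  pNew <- as.vector(1 / (1 + exp(-(cbind(1, as.matrix(xNew)) %*% beta))))
  pred <- as.numeric(pNew >= 0.5)
  acc <- if (!is.null(yNew)) 100 * mean(pred == as.numeric(yNew)) else NA_real_
  list(coefficients = as.vector(beta), predictions = pred,
       probabilities = pNew, accuracy = acc)
}

#' McNemar comparison of two prediction vectors
#'
#' `b` counts samples A classifies correctly and B wrongly, `c` the reverse.
#' The p-value is the exact two-sided binomial test of `b` successes in
#' `b + c` trials at rate 0.5; the continuity-corrected chi-square variant is
#' also returned.
#'
#' @param predA,predB 0/1 prediction vectors.
#' @param labels True 0/1 labels.
#' @return `list(b, c, pExact, pChisq)`.
#' @export
mcnemarTest <- function(predA, predB, labels) {
  okA <- predA == labels; okB <- predB == labels
  b <- sum(okA & !okB); cc <- sum(!okA & okB)
  if (b + cc == 0) {
    warning("no discordant pairs; p = 1")
    return(list(b = b, c = cc, pExact = 1, pChisq = 1))
  }
  k <- min(b, cc)
  pEx <- min(1, 2 * stats::pbinom(k, b + cc, 0.5))
  chi <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, pExact = pEx,
       pChisq = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Chance accuracy of uniform guessing over K classes
#'
#' @param nClasses Number of classes.
#' @return Percent (e.g. ~4% for 24 cohorts).
#' @export
chanceAccuracy <- function(nClasses) 100 / nClasses
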