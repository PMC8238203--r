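# Feed-forward pattern-recognition network (tanh hidden layers, softmax
# output) trained by scaled conjugate gradient (SCG) with a cross-entropy +
# weight-decay performance and validation-based early stopping. The trainer
# is full-batch and deterministic given (config seed, data).

#' Build a scaled SNP feature matrix and label vector
#'
#' Feature cells are genotype codes \{0, 1, 2\} (missing calls mapped to 0,
#' the sparse-default rule); each feature is affinely mapped to `[-1, 1]`
#' using the training-set minimum and maximum. Constant features map to 0.
#' When a stored scaling is applied to new data, values outside the training
#' range are clipped to `[-1, 1]`.
#'
#' @param store A `GenotypeStore`.
#' @param ids Sample ids/indices (rows of the result).
#' @param featureLoci Ordered locus keys to use as features.
#' @param scaling Optional scaling (`list(lo, hi)`) fitted on a training set;
#'   default: fit on `ids`.
#' @return `list(x, y, scaling, nImputed, nClipped)`: `x` is samples x
#'   features in `[-1, 1]`, `y` is 0 = control / 1 = case.
#' @export
buildFeatureMatrix <- function(store, ids, featureLoci, scaling = NULL) {
  stopIfEmpty(ids, "sample id list")
  miss <- setdiff(featureLoci, locusKeys(store))
  if (length(miss)) stop("feature loci absent from store: ",
                         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  codes <- t(denseCodes(store, loci = featureLoci, ids = ids))
  nImputed <- sum(codes < 0)
  codes[codes < 0] <- 0L
  if (is.null(scaling)) {
    scaling <- list(lo = apply(codes, 2, min), hi = apply(codes, 2, max))
  }
  x <- applyFeatureScaling(codes, scaling)
  info <- sampleInfo(store)[ids, , drop = FALSE]
  list(x = x$x, y = as.numeric(info$status == "case"), scaling = scaling,
       nImputed = nImputed, nClipped = x$nClipped)
}

#' @rdname buildFeatureMatrix
#' @param codes Samples-by-features numeric matrix of genotype codes.
#' @export
applyFeatureScaling <- function(codes, scaling) {
  lo <- scaling$lo; hi <- scaling$hi
  span <- hi - lo
  x <- sweep(codes, 2, lo)
  x <- sweep(x, 2, ifelse(span > 0, span / 2, 1), "/") - 1
  x[, span == 0] <- 0
  nClipped <- sum(x < -1 | x > 1)
  x[x > 1] <- 1; x[x < -1] <- -1
  list(x = x, nClipped = nClipped)
}

# --- weight handling ---------------------------------------------------------

# Layers are list(W = in x out matrix, b = length-out vector).
layerShapes <- function(nIn, hidden, nOut) {
  sizes <- c(nIn, hidden, nOut)
  lapply(seq_len(length(sizes) - 1L),
         function(l) c(sizes[l], sizes[l + 1L]))
}

#' Flatten network weights to a vector / restore them
#'
#' Used by the trainer and by finite-difference checks of the analytic
#' gradient.
#'
#' @param weights List of layers (`list(W, b)` each).
#' @return `flattenWeights`: numeric vector; `unflattenWeights`: the layer
#'   list matching `template`.
#' @export
flattenWeights <- function(weights) {
  unlist(lapply(weights, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

#' @rdname flattenWeights
#' @param w Flat numeric vector.
#' @param template Layer list giving the shapes.
#' @export
unflattenWeights <- function(w, template) {
  pos <- 0L
  lapply(template, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(w[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- w[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
}

# Nguyen-Widrow-style scaled uniform initialization (hidden layers get their
# rows rescaled to magnitude 0.7 * H^(1/nIn); output layer small uniform).
initWeights <- function(nIn, hidden, nOut, seed) {
  withSeed(seed, {
    shapes <- layerShapes(nIn, hidden, nOut)
    nL <- length(shapes)
    lapply(seq_len(nL), function(l) {
      d <- shapes[[l]]
      W <- matrix(stats::runif(prod(d), -0.5, 0.5), d[1], d[2])
      b <- stats::runif(d[2], -0.5, 0.5)
      if (l < nL) {
        beta <- 0.7 * d[2]^(1 / d[1])
        nrm <- sqrt(colSums(W^2))
        W <- sweep(W, 2, ifelse(nrm > 0, beta / nrm, 1), "*")
        b <- beta * b * 2
      } else {
        W <- W * 0.1; b <- b * 0.1
      }
      list(W = W, b = b)
    })
  })
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

netForward <- function(weights, x) {
  acts <- vector("list", length(weights))
  a <- x
  nL <- length(weights)
  for (l in seq_len(nL)) {
    z <- a %*% weights[[l]]$W
    z <- sweep(z, 2, weights[[l]]$b, "+")
    a <- if (l < nL) tanh(z) else softmaxRows(z)
    acts[[l]] <- a
  }
  acts
}

#' Performance value and exact gradient of the network
#'
#' Performance is `(1 - reg) * mean cross-entropy + reg * mean(w^2)` with the
#' mean squared-weight penalty taken over weight entries only (biases are
#' excluded). The gradient is exact backpropagation of that performance,
#' returned flat in the [flattenWeights()] order.
#'
#' @param weights Layer list (or a [TrainedNet-class], whose weights are used).
#' @param x Samples-by-features matrix (already scaled).
#' @param t One-hot label matrix (samples x classes), or a 0/1 vector for the
#'   two-class case (column order: control, case).
#' @param reg Regularization ratio in `[0, 1)`.
#' @return `list(perf, grad, ce)`.
#' @export
lossAndGradient <- function(weights, x, t, reg = 0.1) {
  if (methods::is(weights, "TrainedNet")) weights <- weights@weights
  if (is.null(dim(t))) t <- cbind(control = 1 - t, case = t)
  n <- nrow(x)
  acts <- netForward(weights, x)
  nL <- length(weights)
  y <- acts[[nL]]
  if (!all(is.finite(y))) stop("non-finite activations", call. = FALSE)
  ce <- -sum(t * log(pmax(y, 1e-300))) / n
  nw <- sum(vapply(weights, function(l) length(l$W), 1))
  penalty <- sum(vapply(weights, function(l) sum(l$W^2), 1)) / nw
  perf <- (1 - reg) * ce + reg * penalty
  grads <- vector("list", nL)
  dz <- (y - t) / n
  for (l in rev(seq_len(nL))) {
    aPrev <- if (l == 1L) x else acts[[l - 1L]]
    gW <- (1 - reg) * crossprod(aPrev, dz) + reg * 2 * weights[[l]]$W / nw
    gb <- (1 - reg) * colSums(dz)
    grads[[l]] <- list(W = gW, b = gb)
    if (l > 1L) {
      da <- dz %*% Matrix::t(weights[[l]]$W)
      dz <- da * (1 - acts[[l - 1L]]^2)
    }
  }
  list(perf = perf, grad = flattenWeights(grads), ce = ce)
}

toOneHot <- function(y) {
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    t <- stats::model.matrix(~ f - 1)
    colnames(t) <- levels(f)
    list(t = t, classes = levels(f))
  } else {
    list(t = cbind(control = 1 - y, case = y), classes = c("control", "case"))
  }
}

#' Train a pattern-recognition network by scaled conjugate gradient
#'
#' Moller-style SCG: conjugate directions with curvature estimated by a
#' forward difference of the gradient (step `wtSigma / |direction|`), the
#' scale parameter lambda adapted by the comparison parameter, and a restart
#' to steepest descent every W iterations (W = number of weights). One SCG
#' iteration is one epoch. Training stops at `maxEpochs`, when the gradient
#' norm falls below `minGrad`, or after `maxFails` consecutive epochs of
#' rising validation performance; the returned weights are those of the best
#' validation epoch (final weights when no validation set is used).
#'
#' @param x,y Training features (scaled) and labels (0/1 vector, or a
#'   factor/character vector for K-class problems).
#' @param xv,yv Validation features/labels; may be `NULL` only when
#'   `config@maxFails` is infinite.
#' @param config A [NetConfig-class].
#' @param featureLoci,scaling Optional metadata stored on the result.
#' @return A [TrainedNet-class].
#' @export
trainPatternNet <- function(x, y, xv = NULL, yv = NULL, config = netConfig(),
                            featureLoci = character(0), scaling = list()) {
  oh <- toOneHot(y)
  if (length(oh$classes) < 2 || length(unique(max.col(oh$t))) < 2)
    stop("training labels must contain at least 2 classes", call. = FALSE)
  useVal <- is.finite(config@maxFails)
  if (useVal && (is.null(xv) || nrow(xv) == 0))
    stop("validation set is empty while maxFails early stopping is active", call. = FALSE)
  tv <- if (!is.null(xv)) {
    if (is.factor(y) || is.character(y)) {
      f <- factor(yv, levels = oh$classes)
      m <- stats::model.matrix(~ f - 1); colnames(m) <- oh$classes; m
    } else cbind(control = 1 - yv, case = yv)
  } else NULL

  weights <- initWeights(ncol(x), config@hidden, length(oh$classes), config@seed)
  w <- flattenWeights(weights)
  template <- weights
  N <- length(w)
  fg <- function(wv) lossAndGradient(unflattenWeights(wv, template), x, oh$t, config@reg)
  fOnly <- function(wv) fg(wv)$perf
  vPerf <- function(wv) {
    if (is.null(tv)) return(NA_real_)
    lossAndGradient(unflattenWeights(wv, template), xv, tv, config@reg)$perf
  }

  cur <- fg(w)
  fCur <- cur$perf
  r <- -cur$grad
  p <- r
  success <- TRUE
  lambda <- config@lambda0
  lambdaBar <- 0
  delta <- 0
  kIter <- 1L
  fails <- 0L
  bestW <- w
  bestV <- vPerf(w)
  stopReason <- "max_epochs"
  hist <- vector("list", config@maxEpochs)
  nEpochs <- 0L

  for (epoch in seq_len(config@maxEpochs)) {
    gradNorm <- sqrt(sum(r^2))
    if (gradNorm < config@minGrad) { stopReason <- "min_grad"; break }
    p2 <- sum(p^2)
    if (p2 == 0 || !is.finite(p2)) { p <- r; p2 <- sum(p^2); if (p2 == 0) { stopReason <- "min_grad"; break } }
    if (success) {
      sigmaK <- config@wtSigma / sqrt(p2)
      gPlus <- fg(w + sigmaK * p)$grad
      s <- (gPlus - (-r)) / sigmaK
      delta <- sum(p * s)
      if (!is.finite(delta)) { p <- r; delta <- sum(p^2) }  # reset on bad curvature
    }
    delta <- delta + (lambda - lambdaBar) * p2
    if (delta <= 0) {
      lambdaBar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdaBar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    fNew <- fOnly(w + alpha * p)
    Delta <- 2 * delta * (fCur - fNew) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      fCur <- fNew
      gNew <- fg(w)$grad
      rNew <- -gNew
      lambdaBar <- 0
      success <- TRUE
      if (kIter %% N == 0) {
        p <- rNew
      } else {
        beta <- (sum(rNew^2) - sum(rNew * r)) / mu
        p <- rNew + beta * p
      }
      r <- rNew
      if (Delta >= 0.75) lambda <- max(lambda / 4, 1e-15)
      kIter <- kIter + 1L
    } else {
      lambdaBar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) lambda <- min(lambda + delta * (1 - Delta) / p2, 1e15)
    if (!is.finite(lambda)) lambda <- 1e15

    vp <- vPerf(w)
    nEpochs <- epoch
    hist[[epoch]] <- c(train = fCur, validation = vp, gradNorm = gradNorm)
    if (useVal) {
      if (!is.na(vp) && (is.na(bestV) || vp < bestV)) {
        bestV <- vp; bestW <- w; fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config@maxFails) { stopReason <- "max_fails"; break }
      }
    }
  }
  finalW <- if (useVal) bestW else w
  histDf <- as.data.frame(do.call(rbind, hist[seq_len(nEpochs)]))
  if (nEpochs == 0L) histDf <- data.frame(train = numeric(0), validation = numeric(0),
                                          gradNorm = numeric(0))
  methods::new("TrainedNet",
               weights = unflattenWeights(finalW, template),
               featureLoci = as.character(featureLoci),
               scaling = scaling, classes = oh$classes, config = config,
               history = histDf, stopReason = stopReason)
}

#' Convenience wrapper: build features from a store and train
#'
#' @param store A `GenotypeStore`.
#' @param trainIds,valIds Sample ids for training and validation.
#' @param featureLoci Ordered locus keys used as features.
#' @param config A [NetConfig-class].
#' @param labels Optional label vector/factor overriding case/control status
#'   (e.g. cohort identity for a K-class network).
#' @return A [TrainedNet-class] carrying the feature list and scaling.
#' @export
trainClassifier <- function(store, trainIds, valIds, featureLoci,
                            config = netConfig(), labels = NULL) {
  tr <- buildFeatureMatrix(store, trainIds, featureLoci)
  va <- buildFeatureMatrix(store, valIds, featureLoci, scaling = tr$scaling)
  yTr <- tr$y; yVa <- va$y
  if (!is.null(labels)) {
    names(labels) <- rownames(sampleInfo(store))
    yTr <- as.character(labels[trainIds]); yVa <- as.character(labels[valIds])
  }
  trainPatternNet(tr$x, yTr, va$x, yVa, config,
                  featureLoci = featureLoci, scaling = tr$scaling)
}

#' Classifier values (CV) of a trained network
#'
#' `CV = P(case) - 0.5`, so each value lies in `[-0.5, +0.5]` with -0.5 the
#' control label and +0.5 the case label. `predictProb` exposes the
#' `[0, 1]`-normalized `P(class)` matrix (used for ROC curves). Applying the
#' network never changes its weights; repeated application is bit-identical.
#'
#' @param net A [TrainedNet-class].
#' @param features Samples-by-features matrix scaled with the net's stored
#'   scaling (see [buildFeatureMatrix()]).
#' @return `predictCv`: numeric vector of CVs; `predictProb`: probability
#'   matrix with class columns; `predictClass`: character vector.
#' @export
predictCv <- function(net, features) {
  p <- predictProb(net, features)
  if (!"case" %in% colnames(p))
    stop("CV is defined for case/control networks only", call. = FALSE)
  unname(p[, "case"] - 0.5)
}

#' @rdname predictCv
#' @export
predictProb <- function(net, features) {
  if (ncol(features) != nrow(net@weights[[1]]$W))
    stop("feature count mismatch: net expects ", nrow(net@weights[[1]]$W),
         ", got ", ncol(features), call. = FALSE)
  acts <- netForward(net@weights, features)
  p <- acts[[length(acts)]]
  colnames(p) <- net@classes
  p
}

#' @rdname predictCv
#' @export
predictClass <- function(net, features) {
  p <- predictProb(net, features)
  net@classes[max.col(p, ties.method = "first")]
}

#' Serialize / restore a TrainedNet as JSON
#'
#' @param net A `TrainedNet`.
#' @param path JSON path.
#' @return `readTrainedNet` returns the restored [TrainedNet-class].
#' @export
writeTrainedNet <- function(net, path) {
  cfg <- net@config
  jsonlite::write_json(list(
    layers = lapply(net@weights, function(l)
      list(W = l$W, b = l$b)),
    featureLoci = net@featureLoci,
    scaling = net@scaling, classes = net@classes,
    config = list(hidden = cfg@hidden, maxEpochs = cfg@maxEpochs,
                  minGrad = cfg@minGrad, maxFails = cfg@maxFails,
                  wtSigma = cfg@wtSigma, lambda0 = cfg@lambda0,
                  reg = cfg@reg, seed = cfg@seed),
    history = net@history, stopReason = net@stopReason),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTrainedNet
#' @export
readTrainedNet <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  weights <- lapply(x$layers, function(l)
    list(W = matrix(unlist(l$W), nrow = length(l$W), byrow = TRUE),
         b = as.numeric(l$b)))
  cfg <- do.call(netConfig, x$config)
  methods::new("TrainedNet", weights = weights,
               featureLoci = as.character(x$featureLoci),
               scaling = lapply(x$scaling, as.numeric),
               classes = as.character(x$classes), config = cfg,
               history = as.data.frame(x$history),
               stopReason = x$stopReason)
}
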