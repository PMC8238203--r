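blobData <- function(n, sep = 6, seed = 2, d = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(d * n, -sep / 2), ncol = d),
               matrix(stats::rnorm(d * n, sep / 2), ncol = d))
    y <- rep(c(0, 1), each = n)
    idx <- sample(2 * n)
    list(x = x[idx, ], y = y[idx])
  })
}

test_that("feature scaling maps codes to [-1, 1] with clipping", {
  store <- tinyStore()
  fm <- buildFeatureMatrix(store, paste0("s", 1:5), locusKeys(store))
  # locus 1 column holds codes {0,1,2} -> {-1, 0, 1}
  expect_equal(sort(unique(fm$x[, 1])), c(-1, 0, 1))
  # all-zero locus stays all zero
  expect_true(all(fm$x[, 4] == 0))
  # missing code in locus 3 imputed to 0 before scaling
  expect_equal(fm$nImputed, 1)
  # values outside the training range are clipped
  sc <- list(lo = c(0), hi = c(1))
  out <- applyFeatureScaling(matrix(c(0, 1, 2), 3, 1), sc)
  expect_equal(as.vector(out$x), c(-1, 1, 1))
  expect_equal(out$nClipped, 1)
  expect_error(buildFeatureMatrix(store, character(0), locusKeys(store)), "non-empty")
  expect_error(buildFeatureMatrix(store, "s1", "9:9:Z"), "absent")
})

test_that("performance at zero weights is ln 2 and reg = 0 gives plain CE", {
  set.seed(5)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c(0, 1), 20)
  w <- netsnp:::initWeights(3, c(4), 2, seed = 9)
  w0 <- lapply(w, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(lossAndGradient(w0, x, y, reg = 0)$perf, log(2), tolerance = 1e-12)
  lg <- lossAndGradient(w, x, y, reg = 0)
  expect_equal(lg$perf, lg$ce)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  for (shape in list(c(4, 3), c(5), c(6, 4, 2))) {
    x <- matrix(rnorm(25 * 5), 25, 5)
    y <- rbinom(25, 1, 0.5); y[1:2] <- c(0, 1)
    w <- netsnp:::initWeights(5, shape, 2, seed = 17)
    fw <- flattenWeights(w)
    g <- lossAndGradient(w, x, y, 0.1)$grad
    gFd <- vapply(seq_along(fw), function(k) {
      e1 <- fw; e1[k] <- e1[k] + 1e-6
      e0 <- fw; e0[k] <- e0[k] - 1e-6
      (lossAndGradient(unflattenWeights(e1, w), x, y, 0.1)$perf -
         lossAndGradient(unflattenWeights(e0, w), x, y, 0.1)$perf) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - gFd) / pmax(abs(gFd), 1e-4)), 1e-5)
  }
})

test_that("SCG solves a separable problem and is honest on permuted labels", {
  d <- blobData(200)
  cfg <- netConfig(hidden = c(10, 5), seed = 4)
  net <- trainPatternNet(d$x[1:300, ], d$y[1:300], d$x[301:340, ], d$y[301:340], cfg)
  cv <- predictCv(net, d$x[341:400, ])
  expect_equal(cvAccuracy(cv, d$y[341:400]), 100)
  # permuted labels: holdout accuracy within 3 binomial sd of 50%
  yPerm <- withr::with_seed(8, sample(d$y))
  netP <- trainPatternNet(d$x[1:300, ], yPerm[1:300], d$x[301:340, ], yPerm[301:340], cfg)
  accP <- cvAccuracy(predictCv(netP, d$x[341:400, ]), yPerm[341:400])
  expect_lt(abs(accP - 50), 300 * sqrt(0.25 / 60))
})

test_that("training is deterministic and stops as configured", {
  d <- blobData(60, sep = 2, seed = 3)
  cfg <- netConfig(hidden = c(5), maxEpochs = 40, seed = 6)
  n1 <- trainPatternNet(d$x[1:80, ], d$y[1:80], d$x[81:100, ], d$y[81:100], cfg)
  n2 <- trainPatternNet(d$x[1:80, ], d$y[1:80], d$x[81:100, ], d$y[81:100], cfg)
  expect_identical(flattenWeights(n1@weights), flattenWeights(n2@weights))
  # with early stopping disabled and minGrad = 0, exactly maxEpochs run
  cfgAll <- netConfig(hidden = c(5), maxEpochs = 30, minGrad = 0,
                      maxFails = Inf, seed = 6)
  nAll <- trainPatternNet(d$x[1:80, ], d$y[1:80], config = cfgAll)
  expect_equal(nrow(nAll@history), 30)
  expect_identical(nAll@stopReason, "max_epochs")
  # training loss is non-increasing in >= 95% of epoch transitions
  tr <- nAll@history$train
  expect_gte(mean(diff(tr) <= 1e-12), 0.95)
  expect_error(trainPatternNet(d$x[1:80, ], rep(0, 80), d$x[81:100, ], d$y[81:100], cfg),
               "2 classes")
  expect_error(trainPatternNet(d$x[1:80, ], d$y[1:80], NULL, NULL, cfg),
               "validation")
})

test_that("CV is P(case) - 0.5, bounded, and frozen after training", {
  d <- blobData(50, seed = 9)
  cfg <- netConfig(hidden = c(4), maxEpochs = 30, seed = 2)
  net <- trainPatternNet(d$x[1:60, ], d$y[1:60], d$x[61:80, ], d$y[61:80], cfg)
  cv <- predictCv(net, d$x[81:100, ])
  pr <- predictProb(net, d$x[81:100, ])
  expect_true(all(cv >= -0.5 & cv <= 0.5))
  expect_equal(cv + 0.5, unname(pr[, "case"]))
  expect_identical(cv, predictCv(net, d$x[81:100, ]))
  # zeroed output layer gives CV = 0 for every input
  net0 <- net
  nL <- length(net0@weights)
  net0@weights[[nL]]$W <- net0@weights[[nL]]$W * 0
  net0@weights[[nL]]$b <- net0@weights[[nL]]$b * 0
  expect_true(all(predictCv(net0, d$x[81:100, ]) == 0))
  expect_error(predictCv(net, d$x[81:100, 1, drop = FALSE]), "mismatch")
})

test_that("K-class softmax head learns a 3-class problem above chance", {
  withr::with_seed(21, {
    n <- 90
    x <- rbind(matrix(rnorm(2 * n, -4), ncol = 2), matrix(rnorm(2 * n, 0), ncol = 2),
               matrix(rnorm(2 * n, 4), ncol = 2))
    y <- rep(c("a", "b", "c"), each = n)
    idx <- sample(3 * n)
    x <- x[idx, ]; y <- y[idx]
  })
  cfg <- netConfig(hidden = c(8), maxEpochs = 120, seed = 5)
  net <- trainPatternNet(x[1:200, ], y[1:200], x[201:230, ], y[201:230], cfg)
  acc <- 100 * mean(predictClass(net, x[231:270, ]) == y[231:270])
  expect_gt(acc, chanceAccuracy(3) + 20)
  expect_error(predictCv(net, x[231:270, ]), "case/control")
})

test_that("trained networks survive a JSON round trip", {
  d <- blobData(40, seed = 13)
  cfg <- netConfig(hidden = c(4), maxEpochs = 20, seed = 3)
  net <- trainPatternNet(d$x[1:60, ], d$y[1:60], d$x[61:80, ], d$y[61:80], cfg,
                         featureLoci = paste0("f", 1:2),
                         scaling = list(lo = c(0, 0), hi = c(2, 2)))
  f <- tempfile(fileext = ".json")
  writeTrainedNet(net, f)
  back <- readTrainedNet(f)
  expect_equal(predictCv(back, d$x[61:80, ]), predictCv(net, d$x[61:80, ]))
  expect_identical(back@featureLoci, net@featureLoci)
})
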