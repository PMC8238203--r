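test_that("accuracy modes score the expected subsets with the zero-tie rule", {
  expect_equal(cvAccuracy(c(0.4, -0.4), c(1, 0)), 100)
  # all-zero CVs predict control
  expect_equal(cvAccuracy(rep(0, 10), c(rep(0, 7), rep(1, 3))), 70)
  # 8 symmetric CVs, outer quantile frac 0.25 -> exactly the 2 most extreme kept
  cv <- c(-0.4, -0.3, -0.2, -0.1, 0.1, 0.2, 0.3, 0.4)
  y <- c(0, 0, 1, 1, 0, 0, 1, 1)  # only the extremes are classified correctly
  expect_equal(cvAccuracy(cv, y, "outer_quantile", 0.25), 100)
  expect_equal(cvAccuracy(cv, y, "all"), 50)
  # top-|CV| mode keeps the most confident fraction
  expect_equal(cvAccuracy(cv, y, "abs_cv", 0.25), 100)
  expect_error(cvAccuracy(cv, y, frac = 0), "frac")
  # accuracy(all) equals the confusion-matrix identity at threshold 0
  set.seed(2)
  cvr <- runif(200, -0.5, 0.5); yr <- rbinom(200, 1, 0.5)
  pred <- as.numeric(cvr > 0)
  fp <- sum(pred & !yr); fn <- sum(!pred & yr)
  expect_equal(cvAccuracy(cvr, yr), 100 * (1 - (fp + fn) / 200))
})

test_that("ROC equals the rank-sum oracle and is transform-invariant", {
  expect_equal(rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  set.seed(9)
  for (i in 1:20) {
    n <- 60
    s <- runif(n); y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
    auc <- rocCurve(s, y)$auc
    u <- sum(rank(s)[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2
    expect_equal(auc, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-10)
    expect_equal(rocCurve(qlogis(s / 1.0001 + 1e-5), y)$auc, auc, tolerance = 1e-10)
  }
  expect_error(rocCurve(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- runif(300); y <- rbinom(300, 1, 0.4)
  expect_equal(rocCurve(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("chance-level scores give AUC near 0.5", {
  set.seed(3)
  y <- rbinom(2000, 1, 0.5); s <- runif(2000)
  P <- sum(y); N <- sum(!y)
  sdAuc <- sqrt((P + N + 1) / (12 * P * N))
  expect_lt(abs(rocCurve(s, y)$auc - 0.5), 3 * sdAuc)
})

test_that("cost-slope OOP matches the exhaustive expected-cost oracle", {
  # slope formula
  roc <- rocCurve(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  oop <- optimalOperatingPoint(roc, list(cPN = 1, cNN = 0, cNP = 1, cPP = 0),
                               P = 10, N = 10)
  expect_equal(oop$S, 1)
  oop2 <- optimalOperatingPoint(roc, list(cPN = 2, cNN = 0, cNP = 1, cPP = 0),
                                P = 10, N = 20)
  expect_equal(oop2$S, 4)
  expect_error(optimalOperatingPoint(roc, list(cPN = 1, cNN = 2, cNP = 1, cPP = 0),
                                     10, 10), "costs")
  expectedCost <- function(thr, s, y, costs, P, N) {
    pred <- s >= thr
    (costs$cPN * sum(pred & y == 0) + costs$cNP * sum(!pred & y == 1) +
       costs$cPP * sum(pred & y == 1) + costs$cNN * sum(!pred & y == 0))
  }
  set.seed(4)
  for (i in 1:50) {
    n <- 40
    s <- round(runif(n), 2); y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
    costs <- list(cPN = runif(1, 0.5, 3), cNN = 0, cNP = runif(1, 0.5, 3), cPP = 0)
    roc <- rocCurve(s, y)
    oop <- optimalOperatingPoint(roc, costs, P = sum(y), N = sum(!y))
    allCosts <- vapply(roc$thresholds, expectedCost, numeric(1),
                       s = s, y = y, costs = costs, P = sum(y), N = sum(!y))
    expect_equal(expectedCost(oop$threshold, s, y, costs, sum(y), sum(!y)),
                 min(allCosts), tolerance = 1e-12)
  }
})

test_that("prevalence sweep keeps PPV + FDR = 1 and respects base rates", {
  # perfect classifier: FDR 0 at every prevalence
  cv <- c(rep(0.4, 50), rep(-0.4, 50)); y <- rep(c(1, 0), each = 50)
  pm <- prevalenceMetrics(cv, y)
  expect_true(all(pm$fdr == 0))
  expect_equal(pm$ppv + pm$fdr, rep(1, nrow(pm)))
  # uninformative classifier: PPV tracks prevalence
  set.seed(6)
  cvU <- runif(4000, -0.5, 0.5); yU <- rbinom(4000, 1, 0.5)
  pmU <- prevalenceMetrics(cvU, yU)
  expect_lt(max(abs(pmU$ppv - pmU$prevalence)), 0.05)
  expect_error(prevalenceMetrics(cv, y, prevalence = c(0, 0.5)), "grid")
  # OOP thresholds never cost more than the fixed-zero threshold
  set.seed(7)
  cvC <- runif(500, -0.5, 0.5) + 0.2 * rbinom(500, 1, 0.5)
  yC <- as.numeric(cvC + runif(500, -0.3, 0.3) > 0.1)
  if (length(unique(yC)) == 2) {
    for (p in c(0.1, 0.3)) {
      a <- prevalenceMetrics(cvC, yC, p, "fixed_zero")
      b <- prevalenceMetrics(cvC, yC, p, "oop")
      costOf <- function(r) p * (1 - r$sensitivity) + (1 - p) * (1 - r$specificity)
      expect_lte(costOf(b), costOf(a) + 1e-12)
    }
  }
  # resampling mode approximates the analytic reweighting
  pmR <- prevalenceMetrics(cvU, yU, 0.2, resample = TRUE, seed = 3)
  pmA <- prevalenceMetrics(cvU, yU, 0.2)
  expect_lt(abs(pmR$ppv - pmA$ppv), 0.1)
})

test_that("logistic baseline matches glm and handles edge cases", {
  set.seed(11)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- rbinom(200, 1, plogis(x %*% c(1, -0.5, 0.2)))
  fit <- logisticBaseline(x, y, x, y)
  ref <- stats::glm(y ~ x, family = binomial())
  expect_equal(fit$coefficients, unname(coef(ref)), tolerance = 1e-4)
  # separable toy data: ridge keeps IRLS finite and accuracy perfect
  xs <- matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1)
  ys <- rep(c(0, 1), each = 50)
  sep <- logisticBaseline(xs, ys, xs, ys)
  expect_equal(sep$accuracy, 100)
  # constant features predict the majority class
  xc <- matrix(1, 100, 2)
  yc <- c(rep(1, 70), rep(0, 30))
  maj <- logisticBaseline(xc, yc, xc, yc)
  expect_true(all(maj$predictions == 1))
})

test_that("McNemar test reduces to the exact binomial on discordant pairs", {
  y <- rep(0, 30)
  a <- rep(0, 30); b <- rep(0, 30)
  a[1:10] <- 1; b[11:30] <- 1  # b = 20 (A right, B wrong reversed) ...
  mc <- mcnemarTest(a, b, y)
  expect_equal(mc$b + mc$c, 30)
  expect_equal(mc$pExact, 2 * pbinom(min(mc$b, mc$c), 30, 0.5))
  # b = c gives p = 1 exactly
  a2 <- c(rep(1, 5), rep(0, 5)); b2 <- c(rep(0, 5), rep(1, 5))
  expect_equal(mcnemarTest(a2, b2, rep(0, 10))$pExact, 1)
  expect_warning(same <- mcnemarTest(a, a, y), "discordant")
  expect_equal(same$pExact, 1)
  # continuity-corrected chi-square variant matches stats::mcnemar.test
  tab <- matrix(c(5, mc$b, mc$c, 5), 2)
  expect_equal(mc$pChisq, stats::mcnemar.test(tab, correct = TRUE)$p.value)
})
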