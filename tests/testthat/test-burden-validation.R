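test_that("burden counts sum dosage with optional |mCVt| weights", {
  store <- tinyStore()
  sets <- list(protective = c("1:100:T"), risk = c("1:200:G", "2:300:A"))
  bu <- burdenCounts(store, paste0("s", 1:5), sets)
  # s1: protective dosage 0; risk 2 + 0
  expect_equal(bu$protectiveCount, c(0, 0, 1, 2, 0))
  expect_equal(bu$riskCount, c(2, 2, 3, 1, 2))  # missing counted as 0
  # unit weights: weighted sums equal counts
  expect_equal(bu$weightedProtective, bu$protectiveCount)
  expect_equal(bu$weightedRisk, bu$riskCount)
  # hand-worked weighting: dosages (1,2,0) x |mCVt| (0.1,0.2,0.3) -> 0.5
  st2 <- GenotypeStore(rbind(c(1), c(2), c(0)),
                       data.frame(chr = "1", pos = 1:3, ref = "A", alt = "T"),
                       data.frame(sample_id = "a", cohort = "X",
                                  status = "case", age = 70))
  w <- stats::setNames(c(0.1, 0.2, 0.3), locusKeys(st2))
  bu2 <- burdenCounts(st2, "a", list(risk = locusKeys(st2)), weights = w,
                      weighting = "cvt")
  expect_equal(bu2$weightedRisk, 0.5)
  # carrier-indicator mode caps each locus at 1
  buC <- burdenCounts(store, paste0("s", 1:5), sets, carrierIndicator = TRUE)
  expect_equal(buC$riskCount, c(1, 1, 2, 1, 1))
  expect_error(burdenCounts(store, "s1", list(risk = "9:9:Z")), "absent")
  expect_error(burdenCounts(st2, "a", list(risk = locusKeys(st2)),
                            weighting = "cvt"), "weight")
})

test_that("the slope test matches lm()/anova() and behaves analytically", {
  # exact fit: y = 2x
  x <- 1:10
  fit <- glmSlopeTest(x, 2 * x)
  expect_equal(fit$beta, 2)
  expect_lt(fit$p, 1e-200)
  # oracle: closed form against lm + anova on random instances
  set.seed(19)
  for (i in 1:10) {
    xr <- rnorm(40); yr <- 1 + 0.5 * xr + rnorm(40)
    f <- glmSlopeTest(xr, yr)
    ref <- stats::lm(yr ~ xr)
    expect_equal(f$beta, unname(coef(ref)[2]), tolerance = 1e-10)
    a <- stats::anova(ref)
    expect_equal(f$Fstat, a$`F value`[1], tolerance = 1e-10)
    expect_equal(f$p, a$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(f$Fstat, unname(summary(ref)$coefficients[2, "t value"]^2),
                 tolerance = 1e-10)
    # anti-symmetry: negating y flips beta, leaves F and p unchanged
    g <- glmSlopeTest(xr, -yr)
    expect_equal(g$beta, -f$beta)
    expect_equal(g$Fstat, f$Fstat)
    expect_equal(g$p, f$p)
  }
  expect_error(glmSlopeTest(rep(1, 10), rnorm(10)), "constant")
  expect_error(glmSlopeTest(1:2, 1:2), "at least 3")
})

test_that("slope-test p-values are uniform under independence", {
  set.seed(23)
  ps <- vapply(1:1000, function(i) glmSlopeTest(rnorm(20), rnorm(20))$p,
               numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("validation report recovers configured phenotype links", {
  ch <- cachedFixture("ageCohort", function()
    generateCohort(synthSpec(nSamples = 4000, nSnps = 300, seed = 12)))
  pl <- ch$manifest$planted
  sets <- list(protective = pl$key[pl$tag == "protective"],
               risk = pl$key[pl$tag == "risk"])
  w <- stats::setNames(abs(log(pl$odds)), pl$key)
  rep <- validationReport(ch$store, sets, weights = w)
  get <- function(pred, resp) rep[rep$predictor == pred & rep$response == resp, ]
  # risk burden lowers age of diagnosis; protective burden raises it
  expect_lt(get("riskCount", "age")$beta, 0)
  expect_lt(get("riskCount", "age")$p, 0.01)
  expect_gt(get("protectiveCount", "age")$beta, 0)
  # Braak runs the other way
  expect_gt(get("riskCount", "braak")$beta, 0)
  expect_lt(get("riskCount", "braak")$p, 0.01)
  expect_lt(get("protectiveCount", "braak")$beta, 0)
  expect_equal(get("riskCount", "age")$df2, get("riskCount", "age")$n - 2)
  # permuting the burden across individuals severs the correlation
  info <- ch$samples
  iCase <- info$sample_id[info$status == "case"]
  bu <- burdenCounts(ch$store, iCase, sets)
  hits <- vapply(1:5, function(s) {
    perm <- withr::with_seed(s, sample(bu$riskCount))
    glmSlopeTest(perm, info$age[match(iCase, info$sample_id)])$p > 0.05
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("missing Braak values drop those rows with a warning", {
  store <- tinyStore()  # no braak column
  sets <- list(protective = "1:100:T", risk = character(0))
  expect_warning(rep <- validationReport(store, sets), "Braak rows omitted")
  expect_true(all(rep$response == "age"))
})
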