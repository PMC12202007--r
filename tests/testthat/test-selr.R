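test_that("LD statistics match hand-computed values", {
  # perfect LD: only AB and ab haplotypes
  a <- c(1, 1, 1, 0, 0, 0)
  expect_equal(ldStats(a, a), list(r2 = 1, d_prime = 1))
  # exact independence at 0.5/0.5
  hA <- c(1, 1, 0, 0)
  hB <- c(1, 0, 1, 0)
  expect_equal(ldStats(hA, hB), list(r2 = 0, d_prime = 0))
  # counts (AB, Ab, aB, ab) = (4, 1, 1, 4)
  A <- rep(c(1, 0), c(5, 5))
  B <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  ld <- ldStats(A, B)
  expect_equal(ld$r2, 0.36)
  expect_equal(ld$d_prime, 0.6)
  expect_error(ldStats(rep(1, 5), c(1, 0, 1, 0, 1)), "monomorphic")
})

test_that("pair featurization is pure and ordered", {
  f <- pairFeatures(0.1, 0.4, dist = 1000, r2 = 0.5, d_prime = 0.9)
  expect_identical(colnames(f), selrFeatureNames())
  expect_equal(f$min_maf, 0.1)
  expect_equal(f$delta_maf, 0.3)
  expect_equal(f$log10_dist, 3)
  expect_equal(f$`min_maf:r2`, f$min_maf * f$r2)
  expect_equal(f$`log10_dist:d_prime`, f$log10_dist * f$d_prime)
  expect_identical(f, pairFeatures(0.1, 0.4, 1000, 0.5, 0.9))
  expect_error(pairFeatures(0.1, 0.4, dist = 0, r2 = 0.5, d_prime = 0.9),
               ">= 1")
})

test_that("training recovers the generative coefficients", {
  sim <- simulateSelrPairs(20000, seed = 5)
  m <- trainSelr(sim$features, sim$labels, phaser = "synthetic")
  truth <- c("(Intercept)" = sim$intercept, selrTrueCoef())
  z <- abs(m@coefficients - truth) / m@stdErrors
  expect_lt(max(z), 3)
  expect_identical(m@nPairs, 20000L)
  expect_error(trainSelr(sim$features, rep(0L, 20000)), "single class")
  expect_error(trainSelr(sim$features[1:30, ], sim$labels[1:30]), "50")
})

test_that("a prevalence shift moves the intercept, not the slope signs", {
  lo <- simulateSelrPairs(20000, seed = 6, prevalence = 0.037)
  hi <- simulateSelrPairs(20000, seed = 6, prevalence = 0.15)
  mLo <- trainSelr(lo$features, lo$labels)
  mHi <- trainSelr(hi$features, hi$labels)
  expect_gt(mHi@coefficients[["(Intercept)"]],
            mLo@coefficients[["(Intercept)"]])
  big <- c("log10_dist", "min_maf", "r2", "d_prime")
  expect_identical(sign(mHi@coefficients[big]), sign(mLo@coefficients[big]))
})

test_that("predictions are clamped, monotone, and discriminative", {
  m0 <- new("SelrModel",
            coefficients = setNames(numeric(16),
                                    c("(Intercept)", selrFeatureNames())),
            stdErrors = setNames(numeric(16),
                                 c("(Intercept)", selrFeatureNames())),
            nPairs = 100L, phaser = "null")
  f <- pairFeatures(0.1, 0.2, 500, 0.4, 0.8)
  expect_equal(predictPi(m0, f), 0.5)   # logistic(0) clamped at 0.5

  sim <- simulateSelrPairs(20000, seed = 5)
  m <- trainSelr(sim$features, sim$labels)
  # increasing r2 alone must lower the predicted error rate
  fLo <- pairFeatures(0.2, 0.1, 2000, r2 = 0.1, d_prime = 0.5)
  fHi <- pairFeatures(0.2, 0.1, 2000, r2 = 0.9, d_prime = 0.5)
  expect_lt(predictPi(m, fHi), predictPi(m, fLo))
  # and increasing distance alone must raise it
  fNear <- pairFeatures(0.2, 0.1, 100, r2 = 0.4, d_prime = 0.5)
  fFar <- pairFeatures(0.2, 0.1, 50000, r2 = 0.4, d_prime = 0.5)
  expect_gt(predictPi(m, fFar), predictPi(m, fNear))
  # held-out discrimination at realistic (~3.7%) error prevalence
  test <- simulateSelrPairs(20000, seed = 6)
  expect_gt(aucScore(predictPi(m, test$features), test$labels), 0.8)
  expect_true(all(predictPi(m, test$features) >= 1e-6))
  expect_true(all(predictPi(m, test$features) <= 0.5))
})

test_that("models persist as plain text and round-trip", {
  sim <- simulateSelrPairs(5000, seed = 8)
  m <- trainSelr(sim$features, sim$labels, phaser = "synthetic")
  path <- tempfile(fileext = ".json")
  writeSelrModel(m, path)
  back <- readSelrModel(path)
  expect_equal(back@coefficients, m@coefficients)
  expect_equal(back@stdErrors, m@stdErrors)
  expect_identical(back@nPairs, m@nPairs)
  expect_identical(back@phaser, m@phaser)
  expect_equal(predictPi(back, sim$features), predictPi(m, sim$features))
})
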