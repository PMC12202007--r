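test_that("site emissions follow the phase/parity convention", {
  expect_equal(siteEmission(10, 5, phase = 0, p = 0.5), 252 * 0.5^10)
  expect_equal(siteEmission(1, 1, phase = 0, p = 0.7), 0.7)
  expect_equal(siteEmission(1, 1, phase = 0, p = 0.7, parity = "odd"), 0.3)
  expect_equal(siteEmission(1, 1, phase = 1, p = 0.7), 0.3)
  expect_error(siteEmission(1, 1, phase = 0, p = 1.2), "inside")
})

test_that("degenerate genes reduce to closed forms", {
  g1 <- GeneObservation("g", pos = 1, totalCount = 10, altCount = 7,
                        phase = 0)
  expect_equal(marginalLikelihood(g1, 0.7), dbinom(7, 10, 0.7))

  # zero switching error: phased product of binomials
  g2 <- GeneObservation("g", pos = c(1, 501), totalCount = c(10, 5),
                        altCount = c(7, 4), phase = c(0, 0), pi = 0)
  expect_equal(marginalLikelihood(g2, 0.7),
               dbinom(7, 10, 0.7) * dbinom(4, 5, 0.7))

  # pi = 0.5: non-anchor sites become independent equal mixtures
  g3 <- GeneObservation("g", pos = c(1, 501, 1001),
                        totalCount = c(10, 20, 15), altCount = c(7, 14, 9),
                        phase = c(0, 1, 0), pi = 0.5)
  p <- 0.6
  mix <- function(X, N) (dbinom(X, N, p) + dbinom(X, N, 1 - p)) / 2
  anchor <- dbinom(14, 20, 1 - p)       # anchor has phase 1
  expect_equal(marginalLikelihood(g3, p), anchor * mix(7, 10) * mix(9, 15),
               tolerance = 1e-12)
})

test_that("forward recursion equals brute-force phasing enumeration", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    g <- randGene(n)
    p <- runif(1, 0.1, 0.9)
    expected <- bruteLik(totalCounts(g), altCounts(g), predictedPhase(g),
                         switchRates(g), p)
    expect_equal(marginalLikelihood(g, p), expected, tolerance = 1e-12)
    expect_equal(enumLikelihood(g, p), expected, tolerance = 1e-12)
  }
})

test_that("likelihood is exchangeable under chromosome relabeling", {
  set.seed(72)
  for (rep in 1:20) {
    g <- randGene(sample(1:5, 1))
    p <- runif(1, 0.1, 0.9)
    expect_equal(logMarginalLikelihood(g, p),
                 logMarginalLikelihood(mirrorGene(g), 1 - p),
                 tolerance = 1e-10)
  }
})

test_that("likelihood does not depend on the processing direction", {
  set.seed(73)
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    g <- randGene(n)
    # reflect the gene: reverse site order and pair rates; the parity
    # chain is undirected so the likelihood must be identical
    gr <- GeneObservation("g", pos = max(sitePositions(g)) + 1L -
                            rev(sitePositions(g)),
                          totalCount = rev(totalCounts(g)),
                          altCount = rev(altCounts(g)),
                          phase = rev(predictedPhase(g)),
                          pi = rev(switchRates(g)))
    p <- runif(1, 0.1, 0.9)
    expect_equal(logMarginalLikelihood(g, p), logMarginalLikelihood(gr, p),
                 tolerance = 1e-10)
  }
})

test_that("log-space recursion matches linear space and survives depth", {
  set.seed(74)
  g <- randGene(4)
  for (p in c(0.2, 0.5, 0.8)) {
    expect_equal(exp(logMarginalLikelihood(g, p)), marginalLikelihood(g, p),
                 tolerance = 1e-10)
  }
  # deep counts underflow linear space but stay finite in log space
  deep <- GeneObservation("g", pos = c(1, 501, 1001),
                          totalCount = rep(5000L, 3),
                          altCount = c(2400L, 2700L, 2500L),
                          phase = c(0L, 1L, 0L), pi = c(0.05, 0.05))
  ll <- logMarginalLikelihood(deep, 0.3)
  expect_true(is.finite(ll))
  expect_lt(ll, log(1e-300))
})

test_that("anchor is the highest-coverage site with ties to the left", {
  # two sites tie at max coverage; a global phase flip relabels the
  # chromosomes, so L(p) of the flipped gene equals L(1-p) of the
  # original, while flipping only the non-anchor site genuinely changes
  # the relative phasing and hence the likelihood
  g <- function(ph) GeneObservation("g", pos = c(1, 501),
                                    totalCount = c(9, 9),
                                    altCount = c(7, 2), phase = ph,
                                    pi = 0.1)
  l00 <- marginalLikelihood(g(c(0, 0)), 0.7)
  l11 <- marginalLikelihood(g(c(1, 1)), 0.3)
  l01 <- marginalLikelihood(g(c(0, 1)), 0.7)
  expect_equal(l00, l11, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(l00, l01, tolerance = 1e-6)))
  # tie case agrees with the enumeration oracle (anchor = first site)
  expect_equal(marginalLikelihood(g(c(0, 1)), 0.65),
               bruteLik(c(9, 9), c(7, 2), c(0, 1), 0.1, 0.65),
               tolerance = 1e-12)
})
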