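test_that("posterior normalizes and is symmetric for balanced genes", {
  g <- GeneObservation("g", pos = c(1, 501, 1001),
                       totalCount = c(20, 20, 20), altCount = c(10, 10, 10),
                       phase = c(0, 1, 0), pi = 0.1)
  post <- posteriorTheta(g)
  expect_true(validObject(post))
  dx <- diff(post@logTheta)
  d <- post@density
  expect_equal(sum((d[-1] + d[-length(d)]) * dx / 2), 1, tolerance = 1e-8)
  expect_equal(log2Theta(post), 0, tolerance = 1e-6)
  expect_equal(meanLog2Theta(post), 0, tolerance = 1e-6)
})

test_that("single-site posterior matches a dense quadrature oracle", {
  g <- GeneObservation("g", pos = 1, totalCount = 20, altCount = 15,
                       phase = 0)
  post <- posteriorTheta(g, asePrior(sigma = 10))
  # independent oracle: direct quadrature of dbinom * prior on a dense
  # grid in log(theta)
  lt <- seq(-log(128), log(128), length.out = 100001)
  p <- 1 / (1 + exp(-lt))
  dens <- dbinom(15, 20, p) * dnorm(lt, 0, 10)
  dens <- dens / sum(dens)
  cdf <- cumsum(dens)
  med <- lt[which.min(abs(cdf - 0.5))]
  expect_equal(log2Theta(post), med / log(2), tolerance = 1e-3)
  expect_gt(thetaMedian(post), 2.5)    # p-hat 0.75 -> theta near 3
  expect_lt(thetaMedian(post), 3.5)
})

test_that("mirroring the counts mirrors the posterior", {
  set.seed(81)
  g <- randGene(4)
  pg <- posteriorTheta(g, defaultPi = 0.05)
  pm <- posteriorTheta(mirrorGene(g), defaultPi = 0.05)
  expect_equal(log2Theta(pg), -log2Theta(pm), tolerance = 1e-6)
  expect_equal(meanLog2Theta(pg), -meanLog2Theta(pm), tolerance = 1e-6)
  expect_equal(aseMagnitude(pg), aseMagnitude(pm), tolerance = 1e-8)
  ci_g <- credInt(pg)
  ci_m <- credInt(pm)
  expect_equal(ci_g[["lower"]], 1 / ci_m[["upper"]], tolerance = 1e-4)
})

test_that("summaries are stable under grid refinement", {
  set.seed(82)
  g <- randGene(3)
  a <- posteriorTheta(g, K = 1001, defaultPi = 0.05)
  b <- posteriorTheta(g, K = 2001, defaultPi = 0.05)
  expect_equal(log2Theta(a), log2Theta(b), tolerance = 1e-4)
  expect_equal(meanLog2Theta(a), meanLog2Theta(b), tolerance = 1e-4)
  expect_equal(aseMagnitude(a), aseMagnitude(b), tolerance = 1e-4)
})

test_that("latent-pi posterior handles degenerate and point-mass priors", {
  g1 <- GeneObservation("g", pos = 1, totalCount = 20, altCount = 14,
                        phase = 0)
  expect_equal(log2Theta(posteriorThetaLatentPi(g1)),
               log2Theta(posteriorTheta(g1)), tolerance = 1e-10)

  set.seed(83)
  g <- randGene(4)
  # Beta prior concentrated at pi = 0.05 (mean 0.1 of the rescaled beta)
  sharp <- asePrior(piShape1 = 2e6, piShape2 = 1.8e7)
  pLat <- posteriorThetaLatentPi(g, sharp)
  switchRates(g) <- rep(0.05, 3)
  pFix <- posteriorTheta(g)
  expect_equal(log2Theta(pLat), log2Theta(pFix), tolerance = 1e-4)
  expect_equal(aseMagnitude(pLat), aseMagnitude(pFix), tolerance = 1e-4)
})

test_that("uniform latent-pi posterior matches a 2-D brute-force oracle", {
  g <- GeneObservation("g", pos = c(1, 501, 1001),
                       totalCount = c(12, 9, 15), altCount = c(9, 2, 11),
                       phase = c(0, 1, 0))
  K <- 201
  post <- posteriorThetaLatentPi(g, K = K, J = 41)
  # oracle: enumerate the 4 parity assignments of the two non-anchor
  # sites; with pi ~ Uniform(0, 0.5) the path weight integrates in
  # closed form: int pi^k (1-pi)^(2-k) * 2 dpi over [0, 0.5] for k
  # disagreeing pairs out of 2
  wInt <- c(7 / 12, 1 / 6, 1 / 12)     # k = 0, 1, 2
  lt <- seq(-log(128), log(128), length.out = K)
  p <- 1 / (1 + exp(-lt))
  N <- totalCounts(g); X <- altCounts(g); ph <- predictedPhase(g)
  anchor <- which.max(N)
  free <- setdiff(1:3, anchor)
  lik <- 0
  for (a in 0:1) for (b in 0:1) {
    par <- integer(3)
    par[free] <- c(a, b)
    k <- sum(par[1:2] != par[2:3])
    emit <- 1
    for (i in 1:3) {
      eff <- if (par[i] == 1L) 1L - ph[i] else ph[i]
      q <- if (eff == 0L) p else 1 - p
      emit <- emit * dbinom(X[i], N[i], q)
    }
    lik <- lik + wInt[k + 1] * emit
  }
  dens <- lik * dnorm(lt, 0, 1)
  dx <- lt[2] - lt[1]
  dens <- dens / (sum((dens[-1] + dens[-K]) / 2) * dx)
  expect_equal(max(abs(post@density - dens)), 0, tolerance = 1e-6)
})

test_that("latent-pi inference is not sharper than knowing the true rate", {
  set.seed(84)
  widths <- replicate(25, {
    coh <- simulateGene(simConfig(nGenes = 1, nHets = 6, depth = 15,
                                  theta = 0.6, switchRate = 0.05,
                                  seed = sample.int(1e6, 1)))
    g <- coh$gene
    lat <- posteriorThetaLatentPi(g)
    switchRates(g) <- rep(0.05, 5)
    fix <- posteriorTheta(g)
    c(lat = unname(diff(log(credInt(lat)))),
      fix = unname(diff(log(credInt(fix)))))
  })
  expect_gte(mean(widths["lat", ]), mean(widths["fix", ]) - 1e-6)
})

test_that("null p-values respect the plus-one estimator bounds", {
  strong <- GeneObservation("g", pos = 1, totalCount = 1000, altCount = 980,
                            phase = 0)
  expect_equal(nullPvalue(strong, B = 100, seed = 5), 1 / 101)
  flat <- GeneObservation("g", pos = 1, totalCount = 10000, altCount = 5000,
                          phase = 0)
  expect_equal(nullPvalue(flat, B = 100, seed = 5), 1)
  expect_error(nullPvalue(strong, B = 50, seed = 1), ">= 100")
})

test_that("BH adjustment and extreme-gene selection follow conventions", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhFdr(c(0.1, 0)), "0, 1")
  expect_identical(bhFdr(numeric(0)), numeric(0))

  res <- data.frame(gene_id = paste0("g", 1:4),
                    abs_log2_theta = c(0.1, 0.5, 1.0, 4.0),
                    fdr = c(0.01, 0.01, 0.01, 0.01))
  expect_identical(selectExtremeAse(res), "g4")
  res$fdr <- rep(0.5, 4)
  expect_identical(selectExtremeAse(res), character(0))
  one <- data.frame(gene_id = "g1", abs_log2_theta = 2, fdr = 0.001)
  expect_identical(selectExtremeAse(one), "g1")
})

test_that("fitAse returns one tidy row per usable gene, reproducibly", {
  set.seed(85)
  coh <- simulateCohort(simConfig(nGenes = 3, nHets = 4, depth = 15,
                                  theta = 0.5, switchRate = 0.05,
                                  seed = 11))
  genes <- coh$genes
  empty <- GeneObservation("empty", pos = integer(0),
                           totalCount = integer(0), altCount = integer(0),
                           phase = integer(0), pi = numeric(0))
  r1 <- fitAse(c(genes, list(empty)), B = 100, seed = 7)
  r2 <- fitAse(c(genes, list(empty)), B = 100, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 6)
  expect_equal(attr(r1, "nEmpty"), 1)
  expect_true(all(r1$pvalue > 0 & r1$pvalue <= 1))
  expect_true(all(r1$fdr >= r1$pvalue - 1e-12))
  expect_identical(r1$ase_call, r1$fdr < 0.05)
  expect_equal(r1$abs_log2_theta, abs(r1$log2_theta))
  # gene order must not change per-gene results
  r3 <- fitAse(rev(genes), B = 100, seed = 7)
  m <- match(r1$gene_id[1:6], r3$gene_id)
  expect_equal(r3$pvalue[m], r1$pvalue)
})
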