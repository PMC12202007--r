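# Quadrature posterior over the ASE effect size theta = p/(1-p).
#
# The posterior is evaluated on a fixed grid in log(theta), symmetric
# about 0 and wide enough to cover effect sizes from 1/128 to 128, and
# trapezoid-normalized. All summaries (mean, median, equal-tailed credible
# interval) are computed from the grid by linear interpolation of the CDF.

.DEFAULT_K <- 1001L
.LOG_THETA_MAX <- log(128)

.thetaGrid <- function(K = .DEFAULT_K, maxLog = .LOG_THETA_MAX) {
  seq(-maxLog, maxLog, length.out = K)
}

# replace NA pair rates by the default assumed rate
.fillPi <- function(pi, defaultPi) {
  pi[is.na(pi)] <- defaultPi
  pi
}

# normalize a log-posterior on the grid and compute summaries
.gridPosterior <- function(lt, logpost, alpha) {
  K <- length(lt)
  d <- exp(logpost - max(logpost))
  z <- .trapz(lt, d)
  d <- d / z
  dx <- diff(lt)
  cdf <- c(0, cumsum((d[-1L] + d[-K]) * dx / 2))
  cdf <- cdf / cdf[K]
  qfun <- function(q) {
    i <- findInterval(q, cdf, all.inside = TRUE)
    lo <- cdf[i]; hi <- cdf[i + 1L]
    w <- if (hi > lo) (q - lo) / (hi - lo) else 0.5
    lt[i] + w * (lt[i + 1L] - lt[i])
  }
  meanLog <- .trapz(lt, d * lt)
  meanAbs <- .trapz(lt, d * abs(lt))
  med <- qfun(0.5)
  ciL <- qfun(alpha / 2)
  ciU <- qfun(1 - alpha / 2)
  new("ThetaPosterior", logTheta = lt, density = d,
      meanLog2 = meanLog / log(2), meanAbsLog2 = meanAbs / log(2),
      medianLog2 = med / log(2),
      ciLower = exp(ciL), ciUpper = exp(ciU), alpha = alpha)
}

#' Posterior distribution of the gene-level ASE effect size
#'
#' Combines the Normal(0, sigma^2) prior on log(theta) with the
#' phasing-marginal likelihood of the gene's allelic counts (see
#' [marginalLikelihood()]) on a K-point grid in log(theta), and returns the
#' normalized posterior with its summaries. Pair switching-error rates are
#' taken from the gene; NA rates are replaced by `defaultPi`.
#'
#' `posteriorThetaLatentPi` instead treats the switching-error rate as a
#' single latent scalar shared by all of the gene's site pairs, with a
#' Beta prior rescaled to [0, 0.5] (Uniform by default), and integrates it
#' out by Gauss-Legendre quadrature; the gene's own `pi` values are
#' ignored.
#'
#' @param gene a [GeneObservation-class] with n >= 1 sites and at least one
#'   read.
#' @param prior an [AsePrior-class]; default Normal(0, 1) on log(theta).
#' @param K grid size (default 1001).
#' @param defaultPi assumed switching-error rate substituted for NA pair
#'   rates (default 0.05).
#' @param alpha credible level is 1 - alpha (default 0.05).
#' @param J number of quadrature nodes for the latent switching-error rate.
#' @return A [ThetaPosterior-class].
#' @examples
#' g <- GeneObservation("g", pos = 1, totalCount = 20, altCount = 15,
#'                      phase = 0)
#' post <- posteriorTheta(g, asePrior(sigma = 10))
#' thetaMedian(post)   # near 3: p-hat = 0.75, theta = p/(1-p)
#' @export
posteriorTheta <- function(gene, prior = asePrior(), K = .DEFAULT_K,
                           defaultPi = 0.05, alpha = 0.05) {
  stopifnot(is(gene, "GeneObservation"), is(prior, "AsePrior"))
  if (nSites(gene) == 0L) stop("gene has no sites")
  if (sum(totalCounts(gene)) == 0L) stop("no reads: all total counts are zero")
  lt <- .thetaGrid(K)
  p <- plogis(lt)                       # theta/(1+theta)
  pi <- .fillPi(switchRates(gene), defaultPi)
  ll <- .logLikGrid(altCounts(gene), totalCounts(gene),
                    predictedPhase(gene), pi, p)
  .gridPosterior(lt, ll + dnorm(lt, 0, prior@sigma, log = TRUE), alpha)
}

#' @rdname posteriorTheta
#' @export
posteriorThetaLatentPi <- function(gene, prior = asePrior(), K = .DEFAULT_K,
                                   J = 25L, alpha = 0.05) {
  stopifnot(is(gene, "GeneObservation"), is(prior, "AsePrior"))
  if (nSites(gene) == 0L) stop("gene has no sites")
  if (sum(totalCounts(gene)) == 0L) stop("no reads: all total counts are zero")
  lt <- .thetaGrid(K)
  p <- plogis(lt)
  X <- altCounts(gene); N <- totalCounts(gene); phase <- predictedPhase(gene)
  n <- nSites(gene)
  if (n == 1L) {
    ll <- .logLikGrid(X, N, phase, numeric(0), p)
  } else {
    # integrate over the prior's quantile function: with u ~ Uniform(0,1)
    # and pi = F^{-1}(u), the integral of L(pi) dPrior(pi) becomes the
    # integral of L(F^{-1}(u)) du, which Gauss-Legendre handles well even
    # for sharply concentrated priors
    gl <- pracma::gaussLegendre(J, 0, 1)
    piNodes <- 0.5 * stats::qbeta(gl$x, prior@piShape1, prior@piShape2)
    logw <- log(gl$w)
    mat <- vapply(seq_len(J), function(j) {
      .logLikGrid(X, N, phase, rep(piNodes[j], n - 1L), p) + logw[j]
    }, numeric(K))
    m <- apply(mat, 1L, max)
    ll <- m + log(rowSums(exp(mat - m)))
  }
  .gridPosterior(lt, ll + dnorm(lt, 0, prior@sigma, log = TRUE), alpha)
}

#' Accessors for ThetaPosterior
#'
#' @param x a [ThetaPosterior-class].
#' @return `thetaMedian` the posterior median of theta; `log2Theta` the
#'   posterior median of log2(theta); `meanLog2Theta` the posterior mean of
#'   log2(theta); `aseMagnitude` the posterior mean of |log2(theta)|;
#'   `credInt` the equal-tailed credible interval on the theta scale
#'   (length-2 vector).
#' @name ThetaPosterior-accessors
#' @aliases thetaMedian log2Theta meanLog2Theta aseMagnitude credInt
NULL

#' @rdname ThetaPosterior-accessors
#' @export
setMethod("thetaMedian", "ThetaPosterior", function(x) 2^x@medianLog2)

#' @rdname ThetaPosterior-accessors
#' @export
setMethod("log2Theta", "ThetaPosterior", function(x) x@medianLog2)

#' @rdname ThetaPosterior-accessors
#' @export
setMethod("meanLog2Theta", "ThetaPosterior", function(x) x@meanLog2)

#' @rdname ThetaPosterior-accessors
#' @export
setMethod("credInt", "ThetaPosterior",
          function(x) c(lower = x@ciLower, upper = x@ciUpper))

#' @rdname ThetaPosterior-accessors
#' @export
setMethod("aseMagnitude", "ThetaPosterior", function(x) x@meanAbsLog2)

setMethod("show", "ThetaPosterior", function(object) {
  cat("ThetaPosterior on ", length(object@logTheta), "-point grid, ",
      "log2(theta) in [", sprintf("%.2f", object@logTheta[1] / log(2)),
      ", ", sprintf("%.2f",
                    object@logTheta[length(object@logTheta)] / log(2)),
      "]\n", sep = "")
  cat(sprintf("  median log2(theta) = %.4f (theta = %.4f)\n",
              object@medianLog2, 2^object@medianLog2))
  cat(sprintf("  mean   log2(theta) = %.4f\n", object@meanLog2))
  cat(sprintf("  ASE magnitude E|log2(theta)| = %.4f\n", object@meanAbsLog2))
  cat(sprintf("  %g%% CI on theta: [%.4f, %.4f]\n",
              100 * (1 - object@alpha), object@ciLower, object@ciUpper))
  invisible(NULL)
})

# ---- fast scoring used by null simulation and benchmarking ---------------

# Precomputed emission lookup for one gene shape: for every distinct
# total count N we tabulate dbinom(x, N, q) for x = 0..N over the p grid
# and its mirror, rescaled per column to a maximum of 1 so the linear
# recursion cannot overflow (per-gene constants cancel in normalization),
# so scoring a new count vector reduces to indexing.
.emissionCache <- function(N, p) {
  tabs <- new.env(parent = emptyenv())
  for (Nu in unique(N)) {
    x <- 0:Nu
    # K x (N+1): column x+1 holds dbinom(x, N, p_k) over the grid
    tp <- outer(p, x, function(pp, xx) dbinom(xx, Nu, pp, log = TRUE))
    tq <- outer(1 - p, x, function(pp, xx) dbinom(xx, Nu, pp, log = TRUE))
    sc <- pmax(apply(tp, 2L, max), apply(tq, 2L, max))
    tp <- exp(sweep(tp, 2L, sc))
    tq <- exp(sweep(tq, 2L, sc))
    assign(as.character(Nu), list(p = tp, q = tq), envir = tabs)
  }
  tabs
}

# linear-space directional segment over scaled emissions
.segmentLin <- function(Ee, Eo, pi, r, idx) {
  aE <- rep(1, nrow(Ee))
  aO <- rep(0, nrow(Ee))
  prev <- r
  for (j in idx) {
    pr <- pi[min(prev, j)]
    nE <- ((1 - pr) * aE + pr * aO) * Ee[, j]
    nO <- (pr * aE + (1 - pr) * aO) * Eo[, j]
    aE <- nE
    aO <- nO
    prev <- j
  }
  aE + aO
}

# posterior mean ASE magnitude E|log2 theta| for one count/phase vector,
# using cached emission tables; lt and the linear prior weights precomputed by the caller
.scoreFromCache <- function(cache, N, X, phase, pi, lt, priorLin) {
  n <- length(N)
  K <- length(lt)
  if (length(unique(N)) == 1L) {
    # common case (uniform depth): one lookup per parity
    tab <- get(as.character(N[1L]), envir = cache)
    Ee <- tab$p[, X + 1L, drop = FALSE]
    Eo <- tab$q[, X + 1L, drop = FALSE]
    sw <- which(phase == 1L)
    if (length(sw)) {
      Ee[, sw] <- tab$q[, X[sw] + 1L]
      Eo[, sw] <- tab$p[, X[sw] + 1L]
    }
  } else {
    Ee <- matrix(0, K, n)
    Eo <- matrix(0, K, n)
    for (i in seq_len(n)) {
      tab <- get(as.character(N[i]), envir = cache)
      if (phase[i] == 0L) {
        Ee[, i] <- tab$p[, X[i] + 1L]
        Eo[, i] <- tab$q[, X[i] + 1L]
      } else {
        Ee[, i] <- tab$q[, X[i] + 1L]
        Eo[, i] <- tab$p[, X[i] + 1L]
      }
    }
  }
  r <- .refSite(N)
  v <- Ee[, r]
  if (r < n) v <- v * .segmentLin(Ee, Eo, pi, r, seq(r + 1L, n))
  if (r > 1L) v <- v * .segmentLin(Ee, Eo, pi, r, seq(r - 1L, 1L))
  d <- v * priorLin
  .trapz(lt, d * abs(lt)) / .trapz(lt, d) / log(2)
}

#' ASE detection score of a gene
#'
#' The statistic used for ranking genes and for null-simulation p-values:
#' the posterior mean ASE magnitude E|log2(theta)|. Unlike the absolute
#' value of the posterior mean, the mean of the absolute value does not
#' cancel when phasing uncertainty splits the posterior into mirrored
#' modes at +/-|log2(theta)|, which is exactly the situation the parity
#' HMM is built for.
#'
#' @inheritParams posteriorTheta
#' @return A single non-negative number.
#' @export
aseScore <- function(gene, prior = asePrior(), K = .DEFAULT_K,
                     defaultPi = 0.05) {
  aseMagnitude(posteriorTheta(gene, prior, K, defaultPi))
}

#' Null-simulation p-value for a gene's ASE score
#'
#' Tests the null hypothesis theta = 1 (no ASE) by parametric simulation:
#' B replicate genes are generated with the observed gene's site count,
#' depths, predicted-phase structure and switching-error rates, but with
#' balanced expression (p = 0.5) and freshly drawn true phases corrupted by
#' switch errors at the gene's pair rates. The statistic is the posterior
#' mean ASE magnitude E|log2(theta)|; the p-value uses the plus-one estimator
#' (1 + #null >= observed) / (B + 1), so it is never exactly zero.
#'
#' @inheritParams posteriorTheta
#' @param B number of null replicates (>= 100).
#' @param seed integer seed for the replicate stream.
#' @return A p-value in (0, 1].
#' @export
nullPvalue <- function(gene, prior = asePrior(), B = 1000L,
                       seed = 1L, K = .DEFAULT_K, defaultPi = 0.05) {
  stopifnot(is(gene, "GeneObservation"))
  if (B < 100L) stop("B must be >= 100 for a stable tail estimate")
  n <- nSites(gene)
  if (n == 0L) stop("gene has no sites")
  N <- totalCounts(gene)
  pi <- .fillPi(switchRates(gene), defaultPi)
  lt <- .thetaGrid(K)
  p <- plogis(lt)
  priorLin <- dnorm(lt, 0, prior@sigma)
  cache <- .emissionCache(N, p)
  tObs <- .scoreFromCache(cache, N, altCounts(gene), predictedPhase(gene),
                          pi, lt, priorLin)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    X <- rbinom(n, N, 0.5)
    truePhase <- rbinom(n, 1L, 0.5)
    predPhase <- .corruptPhase(truePhase, pi)
    tb <- .scoreFromCache(cache, N, X, predPhase, pi, lt, priorLin)
    if (tb >= tObs) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Adjusted values of the same length.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhFdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Select genes with extreme ASE
#'
#' A gene is flagged as extreme when its FDR-adjusted p-value is below
#' `fdrLevel` and its ASE magnitude |log2(theta)| is at or above the
#' `magnitudeQuantile` empirical quantile (linear interpolation, type 7)
#' of the magnitudes of all genes in `results`.
#'
#' @param results a results data frame as returned by [fitAse()], with
#'   columns `gene_id`, `abs_log2_theta` and `fdr`.
#' @param fdrLevel FDR significance threshold (default 0.05).
#' @param magnitudeQuantile quantile of |log2(theta)| that defines
#'   "extreme" (default 0.75, the top quartile).
#' @return Character vector of selected gene ids.
#' @export
selectExtremeAse <- function(results, fdrLevel = 0.05,
                             magnitudeQuantile = 0.75) {
  stopifnot(nrow(results) > 0L)
  cut <- quantile(results$abs_log2_theta, magnitudeQuantile,
                  names = FALSE, type = 7)
  sel <- results$fdr < fdrLevel & results$abs_log2_theta >= cut
  results$gene_id[sel]
}

#' Fit the ASE model to a set of genes
#'
#' Runs [posteriorTheta()] (or [posteriorThetaLatentPi()]) on every gene,
#' optionally computes null-simulation p-values, applies
#' Benjamini-Hochberg FDR correction across genes and returns one tidy row
#' per gene. Genes with zero sites are dropped (reported via the
#' `"nEmpty"` attribute).
#'
#' @param genes list of [GeneObservation-class] objects.
#' @param prior an [AsePrior-class].
#' @param K posterior grid size.
#' @param defaultPi assumed switching-error rate for NA pair rates.
#' @param latentPi marginalize a shared latent switching-error rate
#'   instead of using per-pair values.
#' @param B null replicates per gene for p-values; set `B = 0` to skip
#'   p-values (pvalue/fdr/ase_call become NA).
#' @param fdrLevel FDR threshold for the binary ASE call.
#' @param seed integer seed; per-gene replicate streams are derived from it
#'   so results do not depend on gene order.
#' @param alpha credible level is 1 - alpha.
#' @return data.frame with columns gene_id, n_hets, total_reads,
#'   theta_median, log2_theta, abs_log2_theta, ci_lower, ci_upper, pvalue,
#'   fdr, ase_call.
#' @export
fitAse <- function(genes, prior = asePrior(), K = .DEFAULT_K,
                   defaultPi = 0.05, latentPi = FALSE, B = 1000L,
                   fdrLevel = 0.05, seed = 1L, alpha = 0.05) {
  if (is(genes, "GeneObservation")) genes <- list(genes)
  keep <- vapply(genes, nSites, integer(1)) > 0L
  nEmpty <- sum(!keep)
  genes <- genes[keep]
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    post <- if (latentPi) {
      posteriorThetaLatentPi(g, prior, K, alpha = alpha)
    } else {
      posteriorTheta(g, prior, K, defaultPi, alpha)
    }
    pv <- NA_real_
    if (B > 0L) {
      pv <- nullPvalue(g, prior, B = B, K = K, defaultPi = defaultPi,
                       seed = .geneSeed(seed, geneId(g)))
    }
    ci <- credInt(post)
    data.frame(gene_id = geneId(g), n_hets = nSites(g),
               total_reads = sum(totalCounts(g)),
               theta_median = thetaMedian(post),
               log2_theta = log2Theta(post),
               abs_log2_theta = abs(log2Theta(post)),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               pvalue = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (B > 0L && nrow(out) > 0L) {
    out$fdr <- bhFdr(out$pvalue)
    out$ase_call <- out$fdr < fdrLevel
  } else {
    out$fdr <- NA_real_
    out$ase_call <- NA
  }
  attr(out, "nEmpty") <- nEmpty
  out
}

# stable per-gene seed derived from the global seed and the gene id,
# independent of gene ordering; kept below 2^31
.geneSeed <- function(seed, id) {
  h <- sum(utf8ToInt(id) * (seq_along(utf8ToInt(id)) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}
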