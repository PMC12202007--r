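# Even/odd switching-error parity HMM.
#
# Relative phasing is anchored at the highest-coverage site r, which is
# assumed to carry its predicted phase. Every other site is in one of two
# latent states: "even" (an even number of switching errors separates it
# from r, so its predicted phase is effectively correct) or "odd" (the
# predicted phase is effectively flipped). Between adjacent sites i, i+1
# the parity flips with probability pi_i and is retained with 1 - pi_i.
# Summing the binomial emission likelihood over all 2^(n-1) parity vectors
# is done by a forward recursion running outward from r in both directions,
# in O(n) time with two states.

# trapezoid integral on an arbitrary grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# pairwise log-sum-exp that tolerates -Inf in either argument
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  ok <- is.finite(m)
  d <- abs(a - b)
  m[ok] <- m[ok] + log1p(exp(-d[ok]))
  m
}

# index of the anchor site: highest coverage, ties to the lowest position
.refSite <- function(N) which.max(N)

# binomial success probability for the alt count at one site:
# effective phase 0 (alt on maternal) -> p, effective phase 1 -> 1 - p
.siteProb <- function(phase, p, odd = FALSE) {
  eff <- if (odd) 1L - phase else phase
  if (eff == 0L) p else 1 - p
}

# log emission matrices over a vector of p values: K x n each
.emissionLog <- function(X, N, phase, p) {
  n <- length(X)
  K <- length(p)
  Ee <- matrix(0, K, n)
  Eo <- matrix(0, K, n)
  for (i in seq_len(n)) {
    qe <- .siteProb(phase[i], p)
    Ee[, i] <- dbinom(X[i], N[i], qe, log = TRUE)
    Eo[, i] <- dbinom(X[i], N[i], 1 - qe, log = TRUE)
  }
  list(even = Ee, odd = Eo)
}

# one directional segment of the log-space forward recursion; returns the
# length-K log sum over parity paths of the segment, anchored even at r
.segmentLog <- function(Ee, Eo, pi, r, idx) {
  K <- nrow(Ee)
  laE <- rep(0, K)
  laO <- rep(-Inf, K)
  prev <- r
  for (j in idx) {
    pr <- pi[min(prev, j)]          # pair rate between prev and j
    lstay <- log1p(-pr)
    lflip <- log(pr)
    nE <- .lse2(laE + lstay, laO + lflip) + Ee[, j]
    nO <- .lse2(laE + lflip, laO + lstay) + Eo[, j]
    laE <- nE
    laO <- nO
    prev <- j
  }
  .lse2(laE, laO)
}

# length-K log marginal likelihood over a grid of p values
.logLikGrid <- function(X, N, phase, pi, p) {
  n <- length(X)
  if (any(is.na(pi)))
    stop("switching-error rates contain NA; supply them or a default")
  if (any(pi < 0 | pi > 0.5))
    stop("switching-error rates must lie in [0, 0.5]")
  E <- .emissionLog(X, N, phase, p)
  r <- .refSite(N)
  out <- E$even[, r]
  if (r < n)
    out <- out + .segmentLog(E$even, E$odd, pi, r, seq(r + 1L, n))
  if (r > 1L)
    out <- out + .segmentLog(E$even, E$odd, pi, r, seq(r - 1L, 1L))
  out
}

#' Binomial emission probability of one site's alternate-allele count
#'
#' Probability of observing `altCount` alternate-allele reads out of
#' `totalCount` at a site with predicted phase `phase`, given the maternal
#' expression proportion `p` and the parity state of the site. With parity
#' "even" the predicted phase is taken at face value; with parity "odd" it
#' is flipped. Effective phase 0 places the alternate allele on the
#' maternal copy, so the binomial success probability is `p`; effective
#' phase 1 gives `1 - p`.
#'
#' @param totalCount,altCount read counts N, X at the site.
#' @param phase predicted phase (0 or 1).
#' @param p maternal expression proportion, in (0, 1); may be a vector.
#' @param parity "even" or "odd".
#' @param log return the log probability.
#' @return Binomial pmf value(s), one per element of `p`.
#' @examples
#' siteEmission(10, 5, phase = 0, p = 0.5)          # 252 * 0.5^10
#' siteEmission(1, 1, phase = 0, p = 0.7)           # 0.7
#' siteEmission(1, 1, phase = 0, p = 0.7, parity = "odd")  # 0.3
#' @export
siteEmission <- function(totalCount, altCount, phase, p,
                         parity = c("even", "odd"), log = FALSE) {
  parity <- match.arg(parity)
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1)")
  q <- .siteProb(as.integer(phase), p, odd = identical(parity, "odd"))
  dbinom(altCount, totalCount, q, log = log)
}

#' Marginal likelihood of a gene's counts over all phasings
#'
#' Computes, for a fixed maternal expression proportion `p`, the likelihood
#' of the gene's allelic counts summed over every possible true phasing of
#' its sites, weighting each phasing by its switching-error path
#' probability. The sum over the 2^(n-1) phasings is performed in O(n) by
#' the even/odd parity forward recursion anchored at the highest-coverage
#' site (ties broken toward the lowest position), whose predicted phase is
#' taken as given.
#'
#' `marginalLikelihood` works in linear space and can underflow for very
#' deep counts; [logMarginalLikelihood()] is the log-space version used by
#' all inference code.
#'
#' @param gene a [GeneObservation-class] with n >= 1 sites and non-NA
#'   switching-error rates.
#' @param p maternal expression proportion in (0, 1) (scalar for
#'   `marginalLikelihood`; vectorized for `logMarginalLikelihood`).
#' @return The marginal likelihood (or its natural log).
#' @examples
#' g <- GeneObservation("g", pos = c(1, 501), totalCount = c(10, 5),
#'                      altCount = c(7, 4), phase = c(0, 0), pi = 0)
#' marginalLikelihood(g, 0.7)          # == dbinom(7,10,.7) * dbinom(4,5,.7)
#' @export
marginalLikelihood <- function(gene, p) {
  stopifnot(is(gene, "GeneObservation"), length(p) == 1L)
  if (nSites(gene) == 0L) stop("gene has no sites")
  if (p <= 0 || p >= 1) stop("p must lie strictly inside (0, 1)")
  exp(logMarginalLikelihood(gene, p))
}

#' @rdname marginalLikelihood
#' @export
logMarginalLikelihood <- function(gene, p) {
  stopifnot(is(gene, "GeneObservation"))
  if (nSites(gene) == 0L) stop("gene has no sites")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  .logLikGrid(altCounts(gene), totalCounts(gene), predictedPhase(gene),
              switchRates(gene), p)
}

# brute-force reference: enumerate all 2^(n-1) parity assignments of the
# non-anchor sites (kept in the package so that tests and examples can use
# a single, independently-coded oracle)
#' Brute-force phasing enumeration (reference implementation)
#'
#' Computes the same marginal likelihood as [marginalLikelihood()] by
#' explicit enumeration of all 2^(n-1) parity assignments. Exponential in
#' n; intended for validation on small genes only.
#'
#' @inheritParams marginalLikelihood
#' @return The marginal likelihood.
#' @export
enumLikelihood <- function(gene, p) {
  stopifnot(is(gene, "GeneObservation"), length(p) == 1L)
  n <- nSites(gene)
  if (n == 0L) stop("gene has no sites")
  X <- altCounts(gene); N <- totalCounts(gene)
  phase <- predictedPhase(gene); pi <- switchRates(gene)
  r <- .refSite(N)
  others <- setdiff(seq_len(n), r)
  total <- 0
  for (mask in seq_len(2^length(others)) - 1L) {
    parity <- integer(n)                 # 0 = even, 1 = odd; anchor even
    if (length(others))
      parity[others] <- bitwAnd(bitwShiftR(mask, seq_along(others) - 1L), 1L)
    trans <- 1
    for (i in seq_len(n - 1L)) {
      pr <- pi[i]
      trans <- trans * if (parity[i] == parity[i + 1L]) 1 - pr else pr
    }
    emit <- 1
    for (i in seq_len(n)) {
      q <- .siteProb(phase[i], p, odd = parity[i] == 1L)
      emit <- emit * dbinom(X[i], N[i], q)
    }
    total <- total + trans * emit
  }
  total
}
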