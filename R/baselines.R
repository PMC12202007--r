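# Comparison methods: single-site and phased-sum estimators of allelic
# imbalance. Each returns an estimated allelic ratio and an exact
# two-sided binomial test against 0.5 (minlike convention, as implemented
# by stats::binom.test); the ROC score is -log10(p).

.baselineRow <- function(gene, method, x, n) {
  pv <- binom.test(x, n, p = 0.5)$p.value
  data.frame(gene_id = geneId(gene), method = method,
             statistic = x / n, pvalue = pv,
             score = -log10(pv), stringsAsFactors = FALSE)
}

#' Baseline ASE estimators
#'
#' `majorSite` tests only the highest-coverage site of the gene (ties
#' broken toward the lowest position) with an exact two-sided binomial
#' test against 0.5. `naiveSum` aggregates counts across all sites taking
#' the predicted phasing at face value: the haplotype-1 count is the sum
#' of X_i at sites with predicted phase 0 and N_i - X_i at sites with
#' phase 1; phasing errors therefore sum incorrect counts. `pseudoPhase`
#' assigns the larger allelic count at every site to haplotype 1 (ties go
#' to the alternate allele), which inflates type-I error under the null
#' and is provided for comparison only.
#'
#' @param gene a [GeneObservation-class] with n >= 1 sites.
#' @return One-row data.frame: gene_id, method, statistic (estimated
#'   allelic ratio), pvalue, score (-log10 p).
#' @examples
#' g <- GeneObservation("g", pos = c(1, 501), totalCount = c(10, 10),
#'                      altCount = c(7, 6), phase = c(0, 0))
#' naiveSum(g)   # aggregate 13 of 20 on haplotype 1
#' @export
majorSite <- function(gene) {
  stopifnot(is(gene, "GeneObservation"))
  if (nSites(gene) == 0L) stop("gene has no sites")
  i <- .refSite(totalCounts(gene))
  .baselineRow(gene, "majorsite", altCounts(gene)[i], totalCounts(gene)[i])
}

#' @rdname majorSite
#' @export
naiveSum <- function(gene) {
  stopifnot(is(gene, "GeneObservation"))
  if (nSites(gene) == 0L) stop("gene has no sites")
  X <- altCounts(gene); N <- totalCounts(gene); ph <- predictedPhase(gene)
  h1 <- sum(ifelse(ph == 0L, X, N - X))
  .baselineRow(gene, "naivesum", h1, sum(N))
}

#' @rdname majorSite
#' @export
pseudoPhase <- function(gene) {
  stopifnot(is(gene, "GeneObservation"))
  if (nSites(gene) == 0L) stop("gene has no sites")
  X <- altCounts(gene); N <- totalCounts(gene)
  h1 <- sum(pmax(X, N - X))
  .baselineRow(gene, "pseudo", h1, sum(N))
}
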