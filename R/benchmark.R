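# ROC/AUC benchmarking of the Bayesian estimator against the baselines on
# simulated cohorts.

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney U divided by n_pos * n_neg; ties count one half.
#'
#' @param scores numeric scores, larger = more ASE.
#' @param labels binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8, 0.3), c(1, 0, 1))   # 0.5
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# score one cohort with one method; shares the per-depth emission caches
# across genes for the Bayesian scorer
.scoreCohort <- function(genes, method, prior, K, assumedPi) {
  if (method %in% c("bayes", "bayes-latent")) {
    lt <- .thetaGrid(K)
    p <- plogis(lt)
    priorLin <- dnorm(lt, 0, prior@sigma)
    allN <- unique(unlist(lapply(genes, totalCounts)))
    cache <- .emissionCache(allN, p)
    vapply(genes, function(g) {
      n <- nSites(g)
      if (method == "bayes-latent" && n > 1L)
        return(aseMagnitude(posteriorThetaLatentPi(g, prior, K)))
      pi <- .fillPi(switchRates(g), assumedPi)
      .scoreFromCache(cache, totalCounts(g), altCounts(g),
                      predictedPhase(g), pi, lt, priorLin)
    }, numeric(1))
  } else {
    fn <- switch(method, naivesum = naiveSum, majorsite = majorSite,
                 pseudo = pseudoPhase,
                 stop("unknown method: ", method))
    vapply(genes, function(g) fn(g)$score, numeric(1))
  }
}

# nominal-level type-I error from baseline p-values on the null class
.type1 <- function(genes, labels, method, level = 0.05) {
  if (!method %in% c("naivesum", "majorsite", "pseudo")) return(NA_real_)
  fn <- switch(method, naivesum = naiveSum, majorsite = majorSite,
               pseudo = pseudoPhase)
  nulls <- genes[labels == 0L]
  mean(vapply(nulls, function(g) fn(g)$pvalue, numeric(1)) < level)
}

#' Run the simulation benchmark
#'
#' For every simulator configuration and method, simulates a labeled
#' cohort (positives at the configured theta, nulls at theta = 1), scores
#' every gene and computes the rank-based AUC. The Bayesian method
#' (`"bayes"`) is scored by the posterior mean ASE magnitude E|log2(theta)|
#' with the assumed switching-error rate `assumedPi`; `"bayes-latent"`
#' marginalizes a shared latent rate; baselines are scored by -log10 of
#' their exact binomial p-value, whose null-class rejection rate at the
#' 0.05 level is also reported.
#'
#' @param configs list of [SimConfig-class] objects (or a single one).
#' @param methods character vector from "bayes", "bayes-latent",
#'   "naivesum", "majorsite", "pseudo".
#' @param prior an [AsePrior-class] for the Bayesian scorer.
#' @param K posterior grid size.
#' @param assumedPi switching-error rate assumed by the Bayesian scorer
#'   (default 0.05).
#' @param oddSwitch use [simulateOddSwitchCohort()] instead of
#'   [simulateCohort()].
#' @return Tidy data.frame: method, theta, depth, n_hets, switch_rate,
#'   auc, type1_error, n_genes, seed.
#' @export
runBenchmark <- function(configs, methods = c("bayes", "naivesum",
                                              "majorsite"),
                         prior = asePrior(), K = .DEFAULT_K,
                         assumedPi = 0.05, oddSwitch = FALSE) {
  if (is(configs, "SimConfig")) configs <- list(configs)
  rows <- list()
  for (cfg in configs) {
    coh <- if (oddSwitch) simulateOddSwitchCohort(cfg) else
      simulateCohort(cfg)
    for (m in methods) {
      sc <- .scoreCohort(coh$genes, m, prior, K, assumedPi)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, theta = cfg@theta, depth = cfg@depth,
        n_hets = cfg@nHets, switch_rate = cfg@switchRate,
        auc = aucScore(sc, coh$labels),
        type1_error = .type1(coh$genes, coh$labels, m),
        n_genes = cfg@nGenes, seed = cfg@seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
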