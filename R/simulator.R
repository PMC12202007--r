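# Synthetic gene generator with switching-error-corrupted phasing.
#
# Counts are binomial: each site's alternate allele lands on the maternal
# haplotype with probability 1/2 (true phase), and the alternate read
# count is Binomial(N, p) or Binomial(N, 1-p) accordingly, with
# p = theta/(1+theta). The predicted phasing handed to estimators is the
# true phasing corrupted by a parity-switch process: each adjacent pair
# carries a switch error with the configured probability, and a switch
# flips the predicted phase of every downstream site.

#' Simulator configuration
#'
#' @param nGenes genes per class.
#' @param nHets heterozygous sites per gene (default 10).
#' @param depth reads per site, or the Poisson mean when
#'   `depthModel = "poisson"`.
#' @param theta true effect size (odds); 1 means no ASE.
#' @param switchRate per-adjacent-pair switching-error probability.
#' @param seed integer RNG seed.
#' @param depthModel "fixed" (default) or "poisson".
#' @param spacing synthetic inter-site spacing in bp (default 500).
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(nGenes = 100, depth = 10, theta = 0.5,
#'                  switchRate = 0.05, seed = 7)
#' @export
simConfig <- function(nGenes = 1000L, nHets = 10L, depth = 10,
                      theta = 1, switchRate = 0.05, seed = 1L,
                      depthModel = c("fixed", "poisson"), spacing = 500) {
  new("SimConfig", nGenes = as.integer(nGenes), nHets = as.integer(nHets),
      depth = as.numeric(depth), theta = as.numeric(theta),
      switchRate = as.numeric(switchRate), seed = as.integer(seed),
      depthModel = match.arg(depthModel), spacing = as.numeric(spacing))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nGenes, " genes/class, ", object@nHets,
      " hets/gene, depth ", object@depth, " (", object@depthModel,
      "), theta ", object@theta, ", switch rate ", object@switchRate,
      ", seed ", object@seed, "\n", sep = "")
  invisible(NULL)
})

# corrupt a true phase vector with per-pair switch indicators drawn at
# `rates`; a switch flips all downstream predicted phases
.corruptPhase <- function(truePhase, rates) {
  n <- length(truePhase)
  if (n <= 1L) {
    out <- truePhase
    attr(out, "switches") <- integer(0)
    return(out)
  }
  s <- rbinom(n - 1L, 1L, rates)
  parity <- c(0L, cumsum(s) %% 2L)
  out <- bitwXor(truePhase, parity)
  attr(out, "switches") <- which(s == 1L)
  out
}

# one gene under the generative model; assumes RNG state is set
.simGeneOnce <- function(cfg, id) {
  n <- cfg@nHets
  p <- cfg@theta / (1 + cfg@theta)
  N <- switch(cfg@depthModel,
              fixed = rep(as.integer(round(cfg@depth)), n),
              poisson = pmax(1L, stats::rpois(n, cfg@depth)))
  truePhase <- rbinom(n, 1L, 0.5)
  q <- ifelse(truePhase == 0L, p, 1 - p)   # phase 0: alt on maternal
  X <- rbinom(n, N, q)
  predPhase <- .corruptPhase(truePhase, cfg@switchRate)
  switches <- attr(predPhase, "switches")
  attributes(predPhase) <- NULL
  gene <- GeneObservation(id, pos = seq_len(n) * cfg@spacing,
                          totalCount = N, altCount = X, phase = predPhase,
                          pi = if (n > 1L) rep(NA_real_, n - 1L) else numeric(0))
  truth <- data.frame(gene_id = id, theta = cfg@theta,
                      n_switches = length(switches),
                      switch_positions = paste(switches, collapse = ","),
                      true_phase = paste(truePhase, collapse = ""),
                      stringsAsFactors = FALSE)
  list(gene = gene, truth = truth)
}

#' Simulate one gene with known ASE and corrupted phasing
#'
#' @param cfg a [SimConfig-class]; its seed initializes the RNG.
#' @param id gene identifier.
#' @return list with elements `gene` (a [GeneObservation-class] whose
#'   switching-error rates are NA, i.e. unknown to the estimator) and
#'   `truth` (one-row data.frame: theta, switch positions, true phases).
#' @export
simulateGene <- function(cfg, id = "sim_gene") {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  .simGeneOnce(cfg, id)
}

#' Simulate a labeled two-class cohort
#'
#' Generates `nGenes` ASE-positive genes at the configured theta and
#' `nGenes` null genes at theta = 1, with identical depth, site count and
#' switching-error rate. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SimConfig-class]; `cfg@theta` is the positive-class effect
#'   size.
#' @return list with `genes` (list of [GeneObservation-class]), `labels`
#'   (1 = ASE positive, 0 = null) and `truth` (data.frame).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  nullCfg <- cfg
  nullCfg@theta <- 1
  out <- vector("list", 2L * cfg@nGenes)
  labels <- integer(2L * cfg@nGenes)
  truths <- vector("list", 2L * cfg@nGenes)
  for (i in seq_len(cfg@nGenes)) {
    r <- .simGeneOnce(cfg, sprintf("pos_%05d", i))
    out[[i]] <- r$gene; truths[[i]] <- r$truth; labels[i] <- 1L
  }
  for (i in seq_len(cfg@nGenes)) {
    r <- .simGeneOnce(nullCfg, sprintf("neg_%05d", i))
    out[[cfg@nGenes + i]] <- r$gene
    truths[[cfg@nGenes + i]] <- r$truth
    labels[cfg@nGenes + i] <- 0L
  }
  list(genes = out, labels = labels, truth = do.call(rbind, truths))
}

# per-pair rate q such that, conditional on an odd total number of
# switches among nPairs pairs, the marginal per-pair switch frequency
# equals `target`
.oddCalibratedRate <- function(target, nPairs) {
  if (nPairs < 1L) stop("odd-switch cohorts need at least one site pair")
  f <- function(q) {
    pOdd <- (1 - (1 - 2 * q)^nPairs) / 2
    if (pOdd <= 0) return(-target)
    pEvenRest <- (1 + (1 - 2 * q)^(nPairs - 1L)) / 2
    q * pEvenRest / pOdd - target
  }
  uniroot(f, c(1e-9, 0.5), tol = 1e-12)$root
}

#' Simulate a cohort in which every gene carries an odd switch count
#'
#' Rejection-samples the switch pattern of each gene until the total
#' number of switch errors is odd, mimicking the worst case in which the
#' predicted phasing can never be globally correct. The per-pair switch
#' probability is calibrated so that the marginal per-pair switch
#' frequency, conditional on oddness, equals `cfg@switchRate`.
#'
#' @inheritParams simulateCohort
#' @return As [simulateCohort()].
#' @export
simulateOddSwitchCohort <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  if (cfg@nHets < 2L)
    stop("odd-switch simulation requires nHets >= 2 (no pairs exist)")
  q <- .oddCalibratedRate(cfg@switchRate, cfg@nHets - 1L)
  set.seed(cfg@seed)
  drawOne <- function(cc, id) {
    repeat {
      r <- .simGeneOnce(cc, id)
      if (r$truth$n_switches %% 2L == 1L) return(r)
    }
  }
  posCfg <- cfg; posCfg@switchRate <- q
  nullCfg <- posCfg; nullCfg@theta <- 1
  out <- vector("list", 2L * cfg@nGenes)
  labels <- integer(2L * cfg@nGenes)
  truths <- vector("list", 2L * cfg@nGenes)
  for (i in seq_len(cfg@nGenes)) {
    r <- drawOne(posCfg, sprintf("pos_%05d", i))
    out[[i]] <- r$gene; truths[[i]] <- r$truth; labels[i] <- 1L
  }
  for (i in seq_len(cfg@nGenes)) {
    r <- drawOne(nullCfg, sprintf("neg_%05d", i))
    out[[cfg@nGenes + i]] <- r$gene
    truths[[cfg@nGenes + i]] <- r$truth
    labels[cfg@nGenes + i] <- 0L
  }
  list(genes = out, labels = labels, truth = do.call(rbind, truths))
}
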