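#' @import methods
#' @importFrom stats dbinom rbinom runif dnorm dbeta binom.test glm
#'   binomial plogis quantile p.adjust uniroot setNames coef vcov ks.test
#' @importFrom utils read.delim write.table packageVersion head combn
NULL

#' GeneObservation: allelic counts at the heterozygous sites of one gene
#'
#' Container for the per-gene data consumed by the ASE model: the ordered
#' exonic heterozygous SNPs of a single gene, with total and alternate-allele
#' read counts, the phaser-predicted phase of each site, and the
#' switching-error rate of each adjacent site pair.
#'
#' @slot geneId single gene identifier.
#' @slot chrom chromosome name (one per site; all identical).
#' @slot pos 1-based genomic positions, strictly increasing.
#' @slot ref,alt single-nucleotide reference and alternate alleles.
#' @slot totalCount total reads overlapping each site (N_i).
#' @slot altCount reads carrying the alternate allele (X_i), 0 <= X_i <= N_i.
#' @slot phase predicted phase of each site: 0 when the alternate allele is
#'   on the first haplotype, 1 when on the second.
#' @slot pi switching-error rate between adjacent sites i and i+1, length
#'   n-1, each in [0, 0.5]; NA means "unknown" and is replaced by the
#'   model's default (or marginalized) at fit time.
#'
#' @seealso [GeneObservation()] for the user constructor,
#'   [marginalLikelihood()], [posteriorTheta()].
#' @exportClass GeneObservation
setClass("GeneObservation",
  representation(
    geneId     = "character",
    chrom      = "character",
    pos        = "integer",
    ref        = "character",
    alt        = "character",
    totalCount = "integer",
    altCount   = "integer",
    phase      = "integer",
    pi         = "numeric"
  )
)

setValidity("GeneObservation", function(object) {
  n <- length(object@pos)
  msg <- character()
  lens <- c(length(object@chrom), length(object@ref), length(object@alt),
            length(object@totalCount), length(object@altCount),
            length(object@phase))
  if (length(object@geneId) != 1L)
    msg <- c(msg, "geneId must be a single string")
  if (any(lens != n))
    msg <- c(msg, "per-site slots must all have the same length")
  if (n > 0) {
    if (any(object@pos < 1L))
      msg <- c(msg, "positions must be >= 1")
    if (length(unique(object@chrom)) > 1L)
      msg <- c(msg, "all sites must be on one chromosome")
    if (is.unsorted(object@pos, strictly = TRUE))
      msg <- c(msg, "sites must be strictly increasing in position")
    if (any(object@totalCount < 0L) || any(object@altCount < 0L) ||
        any(object@altCount > object@totalCount, na.rm = TRUE))
      msg <- c(msg, "counts must satisfy 0 <= altCount <= totalCount")
    if (any(object@ref == object@alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (!all(object@phase %in% c(0L, 1L)))
      msg <- c(msg, "phase must be 0 or 1 at every site")
  }
  if (length(object@pi) != max(n - 1L, 0L))
    msg <- c(msg, "pi must have length n - 1")
  bad <- !is.na(object@pi) & (object@pi < 0 | object@pi > 0.5)
  if (any(bad))
    msg <- c(msg, "switching-error rates must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' ThetaPosterior: discretized posterior of the ASE effect size
#'
#' Posterior distribution of log(theta), theta = p/(1-p) the odds of the
#' maternal expression proportion, on a fixed grid symmetric about 0.
#' The density is trapezoid-normalized to integrate to 1 over the grid.
#'
#' @slot logTheta grid of K strictly increasing points in natural-log theta.
#' @slot density non-negative density values at the grid points.
#' @slot meanLog2,medianLog2 posterior mean and median of log2(theta).
#' @slot meanAbsLog2 posterior mean ASE magnitude E|log2(theta)|, the
#'   detection statistic.
#' @slot ciLower,ciUpper equal-tailed credible interval on the theta scale.
#' @slot alpha 1 - alpha is the credible level.
#' @exportClass ThetaPosterior
setClass("ThetaPosterior",
  representation(
    logTheta  = "numeric",
    density   = "numeric",
    meanLog2  = "numeric",
    meanAbsLog2 = "numeric",
    medianLog2 = "numeric",
    ciLower   = "numeric",
    ciUpper   = "numeric",
    alpha     = "numeric"
  )
)

setValidity("ThetaPosterior", function(object) {
  msg <- character()
  g <- object@logTheta
  d <- object@density
  if (length(g) != length(d))
    msg <- c(msg, "grid and density lengths differ")
  if (is.unsorted(g, strictly = TRUE))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(d < 0))
    msg <- c(msg, "density must be non-negative")
  z <- .trapz(g, d)
  if (abs(z - 1) > 1e-8)
    msg <- c(msg, sprintf("density integrates to %.10f, not 1", z))
  med <- 2^object@medianLog2
  if (med < object@ciLower - 1e-9 || med > object@ciUpper + 1e-9)
    msg <- c(msg, "median must lie inside the credible interval")
  if (length(msg)) msg else TRUE
})

#' AsePrior: prior specification for the ASE model
#'
#' The prior on log(theta) is Normal(0, sigma^2). When the switching-error
#' rate is treated as a latent variable shared across a gene's site pairs,
#' its prior is a Beta(piShape1, piShape2) distribution rescaled to the
#' interval [0, 0.5]; the default (1, 1) is Uniform(0, 0.5).
#'
#' @slot sigma prior standard deviation of log(theta), > 0.
#' @slot piShape1,piShape2 Beta shape parameters of the latent
#'   switching-error-rate prior on [0, 0.5].
#' @exportClass AsePrior
setClass("AsePrior",
  representation(sigma = "numeric", piShape1 = "numeric",
                 piShape2 = "numeric")
)

setValidity("AsePrior", function(object) {
  msg <- character()
  if (length(object@sigma) != 1L || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (object@piShape1 <= 0 || object@piShape2 <= 0)
    msg <- c(msg, "Beta shape parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' SelrModel: logistic regression predictor of switching-error rates
#'
#' Fitted coefficients of the switching-error logistic regressor over the
#' five base pair features (minimum MAF, differential MAF, log10 inter-SNP
#' distance, LD r-squared and D-prime) and their ten pairwise interaction
#' products, together with standard errors and fit metadata.
#'
#' @slot coefficients named numeric of length 16 (intercept + 15 features).
#' @slot stdErrors standard errors of the coefficients (same names).
#' @slot nPairs number of site pairs used in the fit.
#' @slot phaser free-text name of the phasing tool the model was trained
#'   against.
#' @exportClass SelrModel
setClass("SelrModel",
  representation(
    coefficients = "numeric",
    stdErrors    = "numeric",
    nPairs       = "integer",
    phaser       = "character"
  )
)

setValidity("SelrModel", function(object) {
  want <- c("(Intercept)", selrFeatureNames())
  if (!identical(names(object@coefficients), want))
    return("coefficients must be named (Intercept) + the 15 frozen features")
  if (length(object@stdErrors) != length(object@coefficients))
    return("stdErrors must match coefficients in length")
  TRUE
})

#' SimConfig: settings of the synthetic gene simulator
#'
#' @slot nGenes genes per simulated class.
#' @slot nHets heterozygous sites per gene.
#' @slot depth reads per site (mean when depthModel = "poisson").
#' @slot theta true ASE effect size (odds); 1 = no ASE.
#' @slot switchRate per-adjacent-pair probability of a phasing switch error.
#' @slot seed RNG seed.
#' @slot depthModel "fixed" or "poisson".
#' @slot spacing inter-site spacing in bp for the synthetic positions.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nGenes = "integer", nHets = "integer", depth = "numeric",
    theta = "numeric", switchRate = "numeric", seed = "integer",
    depthModel = "character", spacing = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nHets < 1L) msg <- c(msg, "nHets must be >= 1")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@theta <= 0) msg <- c(msg, "theta must be positive")
  if (object@switchRate < 0 || object@switchRate > 0.5)
    msg <- c(msg, "switchRate must lie in [0, 0.5]")
  if (!object@depthModel %in% c("fixed", "poisson"))
    msg <- c(msg, "depthModel must be 'fixed' or 'poisson'")
  if (object@spacing < 1) msg <- c(msg, "spacing must be >= 1 bp")
  if (length(msg)) msg else TRUE
})
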