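#' Construct a GeneObservation
#'
#' Assembles the per-gene input of the ASE model: ordered heterozygous
#' sites with allelic read counts, predicted phases and (optionally) the
#' switching-error rate of each adjacent site pair. Sites are sorted by
#' position on construction.
#'
#' @param geneId single gene identifier.
#' @param pos 1-based positions of the n heterozygous sites.
#' @param totalCount,altCount per-site total and alternate-allele read
#'   counts (N_i, X_i).
#' @param phase predicted phase per site: 0 = alternate allele on the first
#'   haplotype, 1 = on the second.
#' @param pi switching-error rates of the n-1 adjacent pairs, each in
#'   [0, 0.5]; a single value is recycled; NA (default) marks the rate as
#'   unknown so that fitting functions substitute their default or
#'   marginalize it.
#' @param chrom chromosome name (recycled).
#' @param ref,alt single-nucleotide alleles (recycled placeholders by
#'   default; allele identity does not enter the likelihood).
#' @return A [GeneObservation-class] object.
#' @examples
#' g <- GeneObservation("geneA", pos = c(100, 600, 1100),
#'                      totalCount = c(10, 20, 15), altCount = c(3, 12, 8),
#'                      phase = c(0, 1, 0), pi = 0.05)
#' nSites(g)
#' @export
GeneObservation <- function(geneId, pos, totalCount, altCount, phase,
                            pi = NA_real_, chrom = "chr1",
                            ref = "A", alt = "G") {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  ord <- order(pos)
  if (n > 1L && length(pi) == 1L) pi <- rep(pi, n - 1L)
  if (n == 1L && length(pi) == 1L && is.na(pi[1L])) pi <- numeric(0)
  new("GeneObservation",
      geneId = as.character(geneId),
      chrom = chrom[ord],
      pos = as.integer(pos)[ord],
      ref = ref[ord], alt = alt[ord],
      totalCount = as.integer(totalCount)[ord],
      altCount = as.integer(altCount)[ord],
      phase = as.integer(phase)[ord],
      pi = as.numeric(pi))
}

#' Accessors for GeneObservation
#'
#' @param x a [GeneObservation-class].
#' @param value replacement switching-error rates (length n-1, in [0, 0.5]).
#' @return `geneId` the gene identifier; `nSites` the number of
#'   heterozygous sites; `sitePositions`, `totalCounts`, `altCounts`,
#'   `predictedPhase` the per-site vectors; `switchRates` the n-1 adjacent
#'   pair switching-error rates.
#' @name GeneObservation-accessors
#' @aliases geneId nSites sitePositions totalCounts altCounts
#'   predictedPhase switchRates switchRates<-
NULL

#' @rdname GeneObservation-accessors
#' @export
setMethod("geneId", "GeneObservation", function(x) x@geneId)

#' @rdname GeneObservation-accessors
#' @export
setMethod("nSites", "GeneObservation", function(x) length(x@pos))

#' @rdname GeneObservation-accessors
#' @export
setMethod("sitePositions", "GeneObservation", function(x) x@pos)

#' @rdname GeneObservation-accessors
#' @export
setMethod("totalCounts", "GeneObservation", function(x) x@totalCount)

#' @rdname GeneObservation-accessors
#' @export
setMethod("altCounts", "GeneObservation", function(x) x@altCount)

#' @rdname GeneObservation-accessors
#' @export
setMethod("predictedPhase", "GeneObservation", function(x) x@phase)

#' @rdname GeneObservation-accessors
#' @export
setMethod("switchRates", "GeneObservation", function(x) x@pi)

#' @rdname GeneObservation-accessors
#' @export
setReplaceMethod("switchRates", "GeneObservation", function(x, value) {
  x@pi <- as.numeric(value)
  validObject(x)
  x
})

setMethod("show", "GeneObservation", function(object) {
  n <- nSites(object)
  cat("GeneObservation '", object@geneId, "': ", n, " het site",
      if (n != 1L) "s", "\n", sep = "")
  if (n > 0L) {
    cat("  chrom ", object@chrom[1L], ", pos ", object@pos[1L], "..",
        object@pos[n], "\n", sep = "")
    cat("  reads: total ", sum(object@totalCount), ", alt fraction ",
        sprintf("%.3f", sum(object@altCount) / max(1L, sum(object@totalCount))),
        "\n", sep = "")
    pi <- object@pi
    if (length(pi) && all(is.na(pi))) {
      cat("  switching-error rates: unknown (model default applies)\n")
    } else if (length(pi)) {
      cat("  switching-error rates: ",
          paste(sprintf("%.3g", pi), collapse = " "), "\n", sep = "")
    }
  }
  invisible(NULL)
})

#' Prior specification for ASE inference
#'
#' @param sigma prior standard deviation of log(theta); default 1.
#' @param piShape1,piShape2 Beta shape parameters of the latent
#'   switching-error-rate prior, rescaled to [0, 0.5]; the default (1, 1)
#'   is Uniform(0, 0.5).
#' @return An [AsePrior-class] object.
#' @examples
#' asePrior()               # Normal(0, 1) on log theta, Uniform latent pi
#' asePrior(sigma = 10)     # nearly flat effect-size prior
#' @export
asePrior <- function(sigma = 1, piShape1 = 1, piShape2 = 1) {
  new("AsePrior", sigma = as.numeric(sigma),
      piShape1 = as.numeric(piShape1), piShape2 = as.numeric(piShape2))
}

setMethod("show", "AsePrior", function(object) {
  cat("AsePrior: log(theta) ~ Normal(0, ", object@sigma, "^2); ",
      "latent pi ~ Beta(", object@piShape1, ", ", object@piShape2,
      ") on [0, 0.5]\n", sep = "")
  invisible(NULL)
})
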