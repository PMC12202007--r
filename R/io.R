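# Readers and writers for the formats the tool touches (phased VCF,
# per-site count TSV, results TSV), plus the site-thinning and
# count-level quality filters applied before model fitting.

# When sites are dropped from a gene, the switching-error rate of a newly
# adjacent pair is the probability of an ODD number of switches along the
# removed stretch of the original parity chain:
#   pi' = (1 - prod(1 - 2 pi_j)) / 2  over the merged pairs j.
# NA rates propagate to NA.
.combinePi <- function(pi, keepIdx) {
  k <- sort(keepIdx)
  if (length(k) <= 1L) return(numeric(0))
  vapply(seq_len(length(k) - 1L), function(j) {
    span <- seq(k[j], k[j + 1L] - 1L)
    (1 - prod(1 - 2 * pi[span])) / 2
  }, numeric(1))
}

# rebuild a GeneObservation from a subset of its site indices
.subsetGene <- function(gene, keepIdx) {
  k <- sort(keepIdx)
  new("GeneObservation", geneId = gene@geneId,
      chrom = gene@chrom[k], pos = gene@pos[k],
      ref = gene@ref[k], alt = gene@alt[k],
      totalCount = gene@totalCount[k], altCount = gene@altCount[k],
      phase = gene@phase[k], pi = .combinePi(gene@pi, k))
}

#' Thin heterozygous sites to at least one read length apart
#'
#' Reads spanning two nearby sites would be double-counted when allelic
#' counts are summed, so sites closer than `readLength` are thinned:
#' sites are visited greedily in order of decreasing total count (ties
#' toward the lower position) and a site is retained only if no
#' already-retained site lies within `readLength - 1` bp. Distances are
#' genomic; the switching-error rates of newly adjacent pairs are
#' recombined along the removed stretch (odd-parity composition).
#'
#' The result is independent of the input ordering and the operation is
#' idempotent.
#'
#' @param gene a [GeneObservation-class].
#' @param readLength positive integer read length in bp.
#' @return The thinned [GeneObservation-class].
#' @examples
#' g <- GeneObservation("g", pos = c(100, 150, 400),
#'                      totalCount = c(10, 30, 5), altCount = c(5, 15, 2),
#'                      phase = c(0, 0, 0))
#' sitePositions(thinSites(g, 100))   # 150 and 400 survive
#' @export
thinSites <- function(gene, readLength) {
  stopifnot(is(gene, "GeneObservation"), readLength >= 1)
  n <- nSites(gene)
  if (n <= 1L) return(gene)
  ord <- order(-gene@totalCount, gene@pos)
  keep <- integer(0)
  for (i in ord) {
    if (!any(abs(gene@pos[keep] - gene@pos[i]) < readLength))
      keep <- c(keep, i)
  }
  .subsetGene(gene, keep)
}

#' Count-level genotyping-error and depth filter
#'
#' A heterozygous genotype with zero reads on one allele at high depth is
#' more plausibly a genotyping error than mono-allelic expression, so
#' sites that are fully mono-allelic (X = 0 or X = N) at depth
#' N >= `maxMonoallelicDepth` are removed, as are sites below `minDepth`.
#' Both thresholds are configurable and the filter can be disabled with
#' `maxMonoallelicDepth = Inf`. A gene whose sites are all removed is
#' returned with n = 0 and should be excluded downstream.
#'
#' @param gene a [GeneObservation-class].
#' @param minDepth minimum total count to keep a site (default 1).
#' @param maxMonoallelicDepth depth at or above which a mono-allelic site
#'   is treated as a genotyping error (default 20).
#' @return The filtered [GeneObservation-class].
#' @export
filterGenotypingErrors <- function(gene, minDepth = 1,
                                   maxMonoallelicDepth = 20) {
  stopifnot(is(gene, "GeneObservation"), minDepth >= 0,
            maxMonoallelicDepth >= 0)
  N <- gene@totalCount
  X <- gene@altCount
  mono <- (X == 0L | X == N) & N >= maxMonoallelicDepth
  keep <- which(!mono & N >= minDepth)
  .subsetGene(gene, keep)
}

# ---- gene annotation map -------------------------------------------------

#' Read a gene annotation map
#'
#' Accepts a BED file (0-based half-open; requires the rtracklayer
#' package) or a TSV with columns `gene_id chrom start end` where
#' [start, end) is half-open on 1-based coordinates. Returns a named
#' GRanges of gene intervals.
#'
#' @param path file path ending in `.bed` or a TSV.
#' @return A [GenomicRanges::GRanges] with gene ids as names.
#' @export
readGeneMap <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading BED requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    names(gr) <- S4Vectors::mcols(gr)$name
    return(gr)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% colnames(df)))
    stop("gene map TSV must have columns: ", paste(need, collapse = " "))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end - 1L))
  names(gr) <- df$gene_id
  gr
}

# ---- phased VCF ----------------------------------------------------------

#' Extract phased heterozygous SNVs from a VCF
#'
#' Reads the GT field of `sample` and keeps biallelic SNV records that
#' are heterozygous. Phased genotypes map to the package's phase
#' convention: GT "1|0" (alternate allele on the first haplotype) gives
#' phase 0, "0|1" gives phase 1. Unphased heterozygotes ("0/1", "1/0")
#' are retained but flagged with `phased = FALSE` and a NA phase — they
#' are never silently phased. Records with malformed GT are skipped and
#' counted in the `"nSkipped"` attribute.
#'
#' @param vcfPath path to a VCF 4.x file.
#' @param sample sample name present in the VCF.
#' @param genes gene annotation as a named GRanges (see [readGeneMap()]);
#'   sites are assigned to every gene they overlap.
#' @return data.frame with columns gene_id, chrom, pos, ref, alt, phase,
#'   phased; attributes `nSkipped` (malformed GT) and `nUnphased`.
#' @export
readPhasedVcf <- function(vcfPath, sample, genes) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  hdrSamples <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
  if (!sample %in% hdrSamples)
    stop("sample '", sample, "' not found in VCF (has: ",
         paste(hdrSamples, collapse = ", "), ")")
  gt <- VariantAnnotation::geno(vcf)$GT[, sample]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altList <- rr$ALT
  biallelic <- lengths(altList) == 1L
  alt <- rep(NA_character_, length(rr))
  alt[biallelic] <- as.character(unlist(altList[biallelic]))
  snv <- biallelic & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L
  hetPhased <- gt %in% c("0|1", "1|0")
  hetUnphased <- gt %in% c("0/1", "1/0")
  wellFormed <- grepl("^[0-9.]+[|/][0-9.]+$", gt)
  nSkipped <- sum(!wellFormed)
  if (nSkipped > 0L)
    warning(nSkipped, " record(s) with malformed GT skipped")
  keep <- snv & (hetPhased | hetUnphased)
  rrk <- rr[keep]
  phase <- ifelse(gt[keep] == "1|0", 0L, ifelse(gt[keep] == "0|1", 1L,
                                                NA_integer_))
  hits <- GenomicRanges::findOverlaps(rrk, genes)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene_id = names(genes)[si],
    chrom = as.character(GenomicRanges::seqnames(rrk))[qi],
    pos = GenomicRanges::start(rrk)[qi],
    ref = ref[keep][qi],
    alt = alt[keep][qi],
    phase = phase[qi],
    phased = !is.na(phase[qi]),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nSkipped") <- nSkipped
  attr(out, "nUnphased") <- sum(hetUnphased & snv)
  out
}

# ---- counts TSV ----------------------------------------------------------

#' Read and write per-site allelic count tables
#'
#' The counts TSV has a header line and columns
#' `gene_id chrom pos ref alt totalCount altCount phase` plus an optional
#' `pi` column holding the switching-error rate of the pair formed with
#' the next site of the same gene (the value on a gene's last row is
#' ignored and written as NA).
#'
#' @param path file path.
#' @param genes for `writeGeneCounts`, a list of
#'   [GeneObservation-class] objects.
#' @return `readGeneCounts` returns a named list of
#'   [GeneObservation-class]; `writeGeneCounts` returns `path` invisibly.
#' @export
readGeneCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "pos", "ref", "alt", "totalCount",
            "altCount", "phase")
  if (!all(need %in% colnames(df)))
    stop("counts TSV must have columns: ", paste(need, collapse = " "))
  hasPi <- "pi" %in% colnames(df)
  ids <- unique(df$gene_id)
  out <- lapply(ids, function(id) {
    d <- df[df$gene_id == id, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    n <- nrow(d)
    pi <- if (n > 1L) {
      if (hasPi) as.numeric(d$pi[-n]) else rep(NA_real_, n - 1L)
    } else numeric(0)
    new("GeneObservation", geneId = id, chrom = as.character(d$chrom),
        pos = as.integer(d$pos), ref = as.character(d$ref),
        alt = as.character(d$alt), totalCount = as.integer(d$totalCount),
        altCount = as.integer(d$altCount), phase = as.integer(d$phase),
        pi = pi)
  })
  names(out) <- ids
  out
}

#' @rdname readGeneCounts
#' @export
writeGeneCounts <- function(genes, path) {
  if (is(genes, "GeneObservation")) genes <- list(genes)
  rows <- lapply(genes, function(g) {
    n <- nSites(g)
    data.frame(gene_id = geneId(g), chrom = g@chrom, pos = g@pos,
               ref = g@ref, alt = g@alt, totalCount = g@totalCount,
               altCount = g@altCount, phase = g@phase,
               pi = if (n > 1L) c(g@pi, NA_real_) else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- results TSV ---------------------------------------------------------

.RESULT_COLS <- c("gene_id", "n_hets", "total_reads", "theta_median",
                  "log2_theta", "abs_log2_theta", "ci_lower", "ci_upper",
                  "pvalue", "fdr", "ase_call")

#' Read and write per-gene result tables
#'
#' Results are written tab-separated in a deterministic column order with
#' numeric columns at 12 significant digits, so a write-then-read
#' round trip preserves values to at least 10 significant digits.
#'
#' @param results a results data.frame from [fitAse()].
#' @param path file path.
#' @return `readResultsTsv` returns the data.frame; `writeResultsTsv`
#'   returns `path` invisibly.
#' @export
writeResultsTsv <- function(results, path) {
  if (!all(.RESULT_COLS %in% colnames(results)))
    stop("results must have columns: ", paste(.RESULT_COLS, collapse = " "))
  df <- results[, .RESULT_COLS, drop = FALSE]
  for (cl in .RESULT_COLS) {
    if (is.double(df[[cl]]))
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA, sprintf("%.12g", df[[cl]]))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(.RESULT_COLS %in% colnames(df)))
    stop("not a results TSV: ", path)
  df
}
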