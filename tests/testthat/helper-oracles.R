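# Independent oracles and fixture builders, coded from the model
# definition only (no package internals).

# Brute-force marginal likelihood: enumerate every parity assignment of
# the non-anchor sites explicitly. The anchor is the highest-coverage
# site (ties to the lowest position, i.e. first index after sorting) and
# is fixed at even parity. A site at even parity keeps its predicted
# phase, at odd parity flips it; phase 0 puts the alternate allele on the
# maternal copy (success probability p).
bruteLik <- function(N, X, phase, pi, p) {
  n <- length(N)
  anchor <- which(N == max(N))[1L]
  free <- setdiff(seq_len(n), anchor)
  grid <- if (length(free)) {
    as.matrix(expand.grid(rep(list(0:1), length(free))))
  } else {
    matrix(0L, 1L, 0L)
  }
  total <- 0
  for (row in seq_len(nrow(grid))) {
    par <- integer(n)
    par[free] <- grid[row, ]
    w <- 1
    for (i in seq_len(n - 1L))
      w <- w * ifelse(par[i] == par[i + 1L], 1 - pi[i], pi[i])
    for (i in seq_len(n)) {
      eff <- if (par[i] == 1L) 1L - phase[i] else phase[i]
      q <- if (eff == 0L) p else 1 - p
      w <- w * dbinom(X[i], N[i], q)
    }
    total <- total + w
  }
  total
}

# random gene with valid counts/phases/rates
randGene <- function(n, maxN = 30, id = "g") {
  N <- sample(2:maxN, n, replace = TRUE)
  p <- runif(1, 0.15, 0.85)
  GeneObservation(id, pos = seq_len(n) * 500L, totalCount = N,
                  altCount = rbinom(n, N, p), phase = rbinom(n, 1L, 0.5),
                  pi = if (n > 1L) runif(n - 1L, 0, 0.5) else numeric(0))
}

# mirrored gene: swap alt and ref counts at every site
mirrorGene <- function(g) {
  GeneObservation(geneId(g), pos = sitePositions(g),
                  totalCount = totalCounts(g),
                  altCount = totalCounts(g) - altCounts(g),
                  phase = predictedPhase(g),
                  pi = if (nSites(g) > 1L) switchRates(g) else numeric(0))
}

# minimal phased VCF fixture with one sample
writeVcfFixture <- function(path, sample = "NA00001") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    "chr1\t1000\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "chr1\t2000\t.\tC\tT\t.\tPASS\t.\tGT\t1|0",
    "chr1\t3000\t.\tG\tA\t.\tPASS\t.\tGT\t1|1",   # hom alt: excluded
    "chr1\t4000\t.\tT\tC\t.\tPASS\t.\tGT\t0/1",   # unphased: flagged
    "chr1\t5000\t.\tA\tAT\t.\tPASS\t.\tGT\t0|1",  # indel: excluded
    "chr1\t6000\t.\tG\tC\t.\tPASS\t.\tGT\t0|1"
  )
  writeLines(lines, path)
  path
}
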