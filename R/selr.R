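# Switching-error logistic regressor (SELR): predicts the probability
# that an adjacent SNP pair is phased incorrectly by a statistical phaser,
# from allele-frequency, distance and linkage-disequilibrium features.

.SELR_BASE <- c("min_maf", "delta_maf", "log10_dist", "r2", "d_prime")

#' Frozen SELR feature names
#'
#' The five base features followed by their ten pairwise interaction
#' products, in the fixed order used throughout the package.
#'
#' @return Character vector of 15 feature names.
#' @export
selrFeatureNames <- function() {
  pairs <- utils::combn(.SELR_BASE, 2L)
  c(.SELR_BASE, paste(pairs[1L, ], pairs[2L, ], sep = ":"))
}

#' Linkage-disequilibrium statistics for a site pair
#'
#' Computes r-squared and D-prime from the phased haplotypes of a
#' reference panel. `hapA` and `hapB` are 0/1 vectors over the same m
#' haplotypes (1 = the allele whose frequency is measured).
#' D = p_AB - p_A p_B; r2 = D^2 / (p_A(1-p_A) p_B(1-p_B)); D' = |D|/D_max
#' with D_max = min(p_A(1-p_B), (1-p_A)p_B) when D > 0 and
#' min(p_A p_B, (1-p_A)(1-p_B)) when D < 0; D = 0 gives D' = 0.
#'
#' @param hapA,hapB binary allele indicators over m >= 2 haplotypes.
#' @return Named list with `r2` and `d_prime`.
#' @examples
#' a <- rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 1)
#' b <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)   # counts (AB,Ab,aB,ab)=(4,1,1,4)
#' ldStats(a, b)                           # r2 = 0.36, D' = 0.6
#' @export
ldStats <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB), length(hapA) >= 2L)
  pA <- mean(hapA)
  pB <- mean(hapB)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("undefined LD: site is monomorphic in the panel")
  pAB <- mean(hapA == 1 & hapB == 1)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  if (D == 0) {
    dp <- 0
  } else {
    dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
      min(pA * pB, (1 - pA) * (1 - pB))
    dp <- abs(D) / dmax
  }
  list(r2 = r2, d_prime = dp)
}

#' Feature vector of an adjacent SNP pair
#'
#' Builds the 15 SELR features: minimum MAF of the pair, absolute MAF
#' difference, log10 inter-SNP distance, LD r2 and D-prime, plus all ten
#' pairwise products, in the frozen order of [selrFeatureNames()]. All
#' arguments are vectorized over pairs.
#'
#' @param maf1,maf2 minor-allele frequencies of the two SNPs, in [0, 0.5].
#' @param dist inter-SNP distance in bp (>= 1).
#' @param r2,d_prime LD statistics of the pair, e.g. from [ldStats()].
#' @return data.frame with 15 columns named as [selrFeatureNames()].
#' @examples
#' pairFeatures(0.1, 0.4, dist = 1000, r2 = 0.5, d_prime = 0.9)
#' @export
pairFeatures <- function(maf1, maf2, dist, r2, d_prime) {
  if (any(dist < 1)) stop("inter-SNP distance must be >= 1 bp")
  base <- data.frame(min_maf = pmin(maf1, maf2),
                     delta_maf = abs(maf1 - maf2),
                     log10_dist = log10(dist),
                     r2 = r2, d_prime = d_prime)
  pairs <- utils::combn(.SELR_BASE, 2L)
  for (k in seq_len(ncol(pairs))) {
    nm <- paste(pairs[1L, k], pairs[2L, k], sep = ":")
    base[[nm]] <- base[[pairs[1L, k]]] * base[[pairs[2L, k]]]
  }
  base
}

#' Train the switching-error logistic regressor
#'
#' Maximum-likelihood logistic regression (no regularization) of binary
#' switch-error labels on the 15 SELR features. Deterministic given the
#' data.
#'
#' @param features data.frame with the columns of [selrFeatureNames()],
#'   e.g. from [pairFeatures()].
#' @param labels binary vector: 1 = the pair was phased incorrectly.
#' @param phaser free-text name of the phaser the labels came from.
#' @return A fitted [SelrModel-class].
#' @export
trainSelr <- function(features, labels, phaser = "unspecified") {
  want <- selrFeatureNames()
  if (!all(want %in% colnames(features)))
    stop("features must contain the 15 SELR columns")
  if (nrow(features) < 50L)
    stop("need at least 50 pairs to fit SELR")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; cannot fit")
  # fit against the design matrix directly: ':' in the frozen feature
  # names would be parsed as a formula interaction otherwise
  X <- as.matrix(features[, want, drop = FALSE])
  fit <- glm(labels ~ X, family = binomial())
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  names(cf) <- c("(Intercept)", want)
  names(se) <- names(cf)
  new("SelrModel", coefficients = cf, stdErrors = se,
      nPairs = nrow(features), phaser = as.character(phaser))
}

#' Predict per-pair switching-error rates
#'
#' Inverse-logit of the fitted linear predictor, clamped to
#' [1e-6, 0.5] so that the values are valid transition probabilities for
#' the parity HMM.
#'
#' @param model a fitted [SelrModel-class].
#' @param features data.frame of SELR features, as for [trainSelr()].
#' @return Numeric vector of predicted rates in [1e-6, 0.5].
#' @export
predictPi <- function(model, features) {
  stopifnot(is(model, "SelrModel"))
  want <- selrFeatureNames()
  if (!all(want %in% colnames(features)))
    stop("features must contain the 15 SELR columns")
  X <- cbind(1, as.matrix(features[, want, drop = FALSE]))
  eta <- drop(X %*% model@coefficients)
  pmin(pmax(plogis(eta), 1e-6), 0.5)
}

setMethod("show", "SelrModel", function(object) {
  cat("SelrModel fitted on ", object@nPairs, " pairs (phaser: ",
      object@phaser, ")\n", sep = "")
  cf <- object@coefficients
  top <- head(cf[order(-abs(cf))], 6L)
  cat("  largest coefficients:\n")
  for (nm in names(top))
    cat(sprintf("    %-22s %+.4f\n", nm, top[[nm]]))
  invisible(NULL)
})

#' Read and write SELR models as plain text
#'
#' Models are persisted as a small JSON file holding the feature names,
#' coefficients, standard errors and fit metadata; portable and diffable.
#'
#' @param model a [SelrModel-class].
#' @param path file path.
#' @return `readSelrModel` returns a [SelrModel-class];
#'   `writeSelrModel` returns `path` invisibly.
#' @export
writeSelrModel <- function(model, path) {
  stopifnot(is(model, "SelrModel"))
  obj <- list(format = "selr-model-v1",
              phaser = model@phaser,
              n_pairs = model@nPairs,
              features = names(model@coefficients),
              coefficients = unname(model@coefficients),
              std_errors = unname(model@stdErrors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSelrModel
#' @export
readSelrModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "selr-model-v1"))
    stop("not a SELR model file: ", path)
  new("SelrModel",
      coefficients = setNames(obj$coefficients, obj$features),
      stdErrors = setNames(obj$std_errors, obj$features),
      nPairs = as.integer(obj$n_pairs), phaser = obj$phaser)
}

# ---- synthetic training-data generator ----------------------------------

#' Default generative coefficients of the synthetic SELR generator
#'
#' Encodes the documented qualitative trends of statistical-phasing
#' switch errors: error probability rises with inter-SNP distance and
#' falls with minor-allele frequency and with LD strength. The overall
#' coefficient scale is calibrated so that the generative (oracle) model
#' discriminates error from non-error pairs at AUC ~ 0.84, the level
#' reported for switching-error prediction on gold-standard phasing
#' truth data; the intercept is calibrated by [simulateSelrPairs()] to
#' hit the requested error prevalence.
#'
#' @return Named numeric over the 15 SELR features (no intercept).
#' @export
selrTrueCoef <- function() {
  cf <- setNames(numeric(15), selrFeatureNames())
  cf["log10_dist"] <- 1.05
  cf["min_maf"] <- -5.9
  cf["delta_maf"] <- 1.2
  cf["r2"] <- -1.75
  cf["d_prime"] <- -1.4
  cf["min_maf:r2"] <- 2.3
  cf["log10_dist:d_prime"] <- -0.35
  cf
}

#' Simulate labeled SNP-pair training data for SELR
#'
#' Draws pair features from simple population-genetic ranges (MAFs
#' uniform on [0.005, 0.5], distances log-uniform between 10 bp and
#' 100 kb, D-prime Beta-distributed with r2 <= D'^2) and labels each pair
#' as a switch error from a logistic model with coefficients `coefs`. The
#' intercept is calibrated numerically so the expected error prevalence
#' equals `prevalence` (default 3.7%).
#'
#' @param n number of pairs.
#' @param seed integer RNG seed.
#' @param coefs named generative coefficients (default [selrTrueCoef()]).
#' @param prevalence target mean error rate.
#' @return list with `features` (data.frame), `labels` (0/1 vector),
#'   `intercept` (calibrated value) and `eta` (true linear predictor).
#' @export
simulateSelrPairs <- function(n, seed = 1L, coefs = selrTrueCoef(),
                              prevalence = 0.037) {
  set.seed(seed)
  maf1 <- runif(n, 0.005, 0.5)
  maf2 <- runif(n, 0.005, 0.5)
  dist <- 10^runif(n, 1, 5)
  dp <- stats::rbeta(n, 1.5, 1.5)
  r2 <- dp^2 * stats::rbeta(n, 2, 1)
  feats <- pairFeatures(maf1, maf2, dist, r2, dp)
  X <- as.matrix(feats[, selrFeatureNames()])
  eta0 <- drop(X %*% coefs[selrFeatureNames()])
  b0 <- uniroot(function(b) mean(plogis(eta0 + b)) - prevalence,
                c(-30, 10), tol = 1e-10)$root
  eta <- eta0 + b0
  labels <- rbinom(n, 1L, plogis(eta))
  list(features = feats, labels = labels, intercept = b0, eta = eta)
}
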