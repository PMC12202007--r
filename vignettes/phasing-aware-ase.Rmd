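---
title: "Phasing-aware Bayesian estimation of allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing-aware Bayesian estimation of allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseBayes)
```

## The model

Allele-specific expression of one gene is parameterized by the odds
$\theta = p/(1-p)$, where $p$ is the proportion of the gene's expression
originating from the (arbitrarily labeled) maternal copy; $\theta = 1$
means balanced expression. The data are allelic read counts
$(N_i, X_i)$ at the gene's $n$ exonic heterozygous SNPs: $X_i \sim
\mathrm{Binomial}(N_i, p)$ when the alternate allele at site $i$ lies on
the maternal copy, $\mathrm{Binomial}(N_i, 1-p)$ otherwise. The
chromosome labels are exchangeable, so the likelihood satisfies
$L(p; X) = L(1-p; N-X)$ — the model estimates imbalance, not direction
relative to parental origin.

Which copy each alternate allele lies on is exactly what the upstream
phaser predicts, and exactly what it sometimes gets wrong. A *switching
error* between adjacent sites $i$ and $i+1$ (rate $\pi_i \in [0, 0.5]$)
flips the relative phasing of everything downstream. Because only
relative phasing is identifiable, the site with the highest coverage is
fixed as the anchor (ties resolved toward the lowest position, making
the fit deterministic) and taken at its predicted phase. Every other
site is then described by a two-valued latent state: the **parity** —
even or odd — of the number of switch errors between it and the anchor.
Even parity means the predicted phase is effectively correct at that
site, odd means it is effectively flipped. Between neighbours the parity
is retained with probability $1-\pi_i$ and flips with $\pi_i$, so the
marginal likelihood at fixed $p$,

$$L(p) = \sum_{\text{parities}} \prod_{\text{pairs } i} T_{\pi_i}
  \prod_{\text{sites } i} \mathrm{Bin}(X_i; N_i, q_i(\text{parity}_i)),$$

is a sum over $2^{n-1}$ configurations that a two-state forward
recursion, run outward from the anchor in both directions, evaluates in
$O(n)$. The recursion works in log space, so $\pi_i = 0$ (certain
phasing) and $\pi_i = 0.5$ (uninformative phasing) are handled exactly
rather than clamped, and genes with thousands of reads per site do not
underflow. Start/stop bookkeeping of the chain would contribute a
constant factor common to every parity path of a fixed-length gene; it
cancels under posterior normalization and is omitted.

`marginalLikelihood()` / `logMarginalLikelihood()` expose this
computation; `enumLikelihood()` is a deliberately brute-force
enumeration kept as an independent oracle.

## Posterior, statistic, and calls

The prior on $\log\theta$ is Normal$(0, \sigma^2)$ with $\sigma = 1$ by
default. This is a weakly informative scale choice — about 95% prior
mass on $\theta \in [1/7, 7]$ — exposed as a configuration knob
(`asePrior(sigma = )`); with total gene depths of tens of reads the
likelihood dominates and the sensitivity of the median to $\sigma \in
[0.5, 10]$ is small (grid-refinement and recovery tests quantify this).
The posterior is evaluated on a fixed grid of $K = 1001$ points in
$\log\theta \in [-\log 128, \log 128]$ — wide enough for the effect
sizes seen in real cohorts (two orders of magnitude either side of 1) —
and trapezoid-normalized; summaries come from linear interpolation of
the gridded CDF. Doubling $K$ moves summaries by less than $10^{-4}$,
which is the package's internal convergence check.

Reported per gene:

* `log2Theta` — posterior median of $\log_2\theta$ (robust on skewed
  posteriors), with `thetaMedian` on the odds scale and an equal-tailed
  credible interval;
* `aseMagnitude` — the posterior mean ASE magnitude
  $\mathrm{E}|\log_2\theta|$, used as the detection/ranking statistic.
  The *magnitude* functional matters: when phasing is ambiguous the
  posterior can split into two mirrored modes near $\pm|\log_2\theta|$,
  and the mean of $\log_2\theta$ cancels toward zero while the mean of
  $|\log_2\theta|$ retains the evidence of imbalance. In benchmark terms
  the magnitude statistic tracks the Neyman–Pearson oracle of the
  generative model to within about 0.01 AUC, whereas the absolute
  posterior mean loses 0.01–0.04 AUC at realistic depths;
* a null-simulation p-value: $B$ replicates (default 1000; large-scale
  analyses use 10 000) regenerate the gene with $\theta = 1$, the
  observed depths and fresh switch-corrupted phases, and the plus-one
  estimator $(1 + \#\{T_b \ge T_{\mathrm{obs}}\})/(B+1)$ guarantees
  $p > 0$. P-values are BH-adjusted across genes and the binary ASE call
  is `fdr < 0.05` by default. "Extreme ASE" genes additionally require
  the magnitude to reach the top quartile (type-7 empirical quantile)
  across the fitted genes.

### Unknown switching-error rates

When no per-pair rates are available there are two options. The default
substitutes a fixed 5% rate — a representative genome-wide switching
error level for statistical phasers on common variants. Alternatively
`posteriorThetaLatentPi()` treats one shared rate per gene as latent
with a Beta prior rescaled to $[0, 0.5]$ (Uniform by default) and
integrates it out. A *single* shared rate is used deliberately: per-pair
latent rates are unidentifiable at typical per-site depths. The inner
integral uses Gauss–Legendre quadrature against the prior's quantile
function (default $J = 25$ nodes), which remains accurate even for
sharply concentrated priors; a point-mass-like prior reproduces the
fixed-rate posterior, and marginalizing the rate never yields a sharper
interval, on average, than knowing the true rate.

## Predicting switching-error rates (SELR)

The switching-error logistic regressor predicts each adjacent pair's
error probability from five features — minimum MAF of the pair,
absolute MAF difference, $\log_{10}$ inter-SNP distance, LD $r^2$ and
$D'$ — plus all ten pairwise interaction products. The feature order is
frozen and versioned in the plain-JSON model file; no automatic feature
selection is performed. Fitting is plain maximum-likelihood logistic
regression, deterministic given the data, with a training interface so
the model can be recalibrated against any phaser's observed errors.
Predictions are clamped to $[10^{-6}, 0.5]$ to stay valid as HMM
transition probabilities. Only adjacent pairs are modeled — that is
what the parity chain consumes.

No pre-trained model is shipped: training data of real phaser errors
against gold-standard haplotypes are external. Instead the package
provides a synthetic pair generator (`simulateSelrPairs()`) encoding the
documented qualitative trends — error rates rise with inter-SNP
distance and fall with MAF and LD strength — whose coefficient scale is
calibrated so the generative model discriminates at AUC ≈ 0.84 (the
level reported for this class of predictor on gold-standard truth data)
at ~3.7% error prevalence, and whose intercept is solved numerically
for the requested prevalence. Tests verify coefficient recovery within
3 standard errors and held-out AUC > 0.8 on this generator; they
demonstrate the training/prediction machinery, not performance on any
particular real phaser.

## The simulator

`simulateCohort()` generates what the model and the baselines consume:
genes with a known $\theta$, a fixed number of het sites (default 10),
fixed or Poisson read depth per site, true phases drawn uniformly per
site, binomial counts, and predicted phasing equal to the true phasing
corrupted by independent per-pair switch errors at a configured rate.
Positive genes at the configured $\theta$ are paired with an equal
number of null genes ($\theta = 1$) under identical settings.
`simulateOddSwitchCohort()` conditions every gene on an odd total switch
count — the worst case, in which the predicted phasing can never be
globally right — with the per-pair rate calibrated (by root-finding on
the conditional expectation) so the marginal pair-level error frequency
still matches the requested rate. Synthetic positions are uniformly
spaced at 500 bp so featurization runs end-to-end in integration tests.

What the generator does *not* emulate: real read-depth heterogeneity
across sites and genes, allelic mapping bias, genotyping error,
overdispersion beyond binomial sampling, and error placement correlated
with local LD structure (corruption is independent per pair). Passing
benchmarks therefore validate the inference machinery under the model's
own sampling assumptions — they do not certify performance on any real
cohort. One visible consequence: at 5 reads per site the discrete
binomial counts carry slightly less information than semi-empirical
read data composed from real sequencing, so low-depth AUCs land a few
hundredths below figures derived from such data, while at 20 reads per
site the two regimes agree closely.

## Benchmarks and baselines

`runBenchmark()` scores each simulated gene with the Bayesian magnitude
statistic (assumed 5% rate by default, or latent) and with the
baselines: **MajorSite** (exact binomial test at the single
highest-coverage site), **NaiveSum** (counts summed across sites taking
predicted phasing at face value), and **pseudo-phasing** (the larger
allelic count at every site assigned to one haplotype — included only
to exhibit its inflated type-I error, which the tests assert). Baseline
p-values use the exact two-sided binomial test in the "minlike"
convention of `stats::binom.test()`, and ROC scores are $-\log_{10} p$;
AUC is the Mann–Whitney rank statistic with ties counted one half. The
Bayesian ROC score uses the posterior magnitude rather than the
null-simulation p-value: with a common gene structure the p-value is a
monotone transform of the statistic, so the AUC is unchanged, at a tiny
fraction of the cost.

Problem sizes used by the checked-in validation: oracle equivalence on
200 random genes with up to 10 sites; AUC operating points on cohorts
of 1000 + 1000 genes; calibration on 500 null genes with $B = 1000$
null replicates each; effect-size recovery on 200 genes per $\theta \in
\{0.5, 1, 2\}$; SELR recovery on 20 000 training and 20 000 held-out
pairs.

## Numerical and convention notes

* Phase convention: 0 = alternate allele on haplotype 1 (VCF GT `1|0`),
  1 = on haplotype 2 (`0|1`); unphased heterozygotes are flagged, never
  silently phased. Any consistent convention yields the same
  likelihood; the exchangeability property is asserted in tests.
* Coordinates are 1-based internally (VCF convention); TSV gene maps
  are half-open `[start, end)`, BED input is converted by rtracklayer.
* Site thinning uses genomic distance with greedy selection in
  decreasing coverage order (ties toward the lower position, so output
  is deterministic and order-independent). Transcript-aware distance
  would require an exon model that the count-table entry point does not
  have; genomic distance never under-thins within one exon and the
  cross-exon caveat is accepted.
* When filtering or thinning drops sites, newly adjacent pairs get the
  odd-parity composition of the removed stretch's rates,
  $\pi' = \tfrac{1}{2}(1 - \prod_j (1 - 2\pi_j))$, which is exact under
  the parity-chain model.
* The genotyping-error stand-in removes mono-allelic sites
  ($X_i \in \{0, N_i\}$) at depth $\ge 20$ and sites below a minimum
  depth; both thresholds are configurable and the filter can be
  disabled. It is a count-level heuristic, not a genotype-likelihood
  model.
* Degenerate inputs: empty genes error in likelihood/posterior code and
  are dropped (and counted) by `fitAse()`; all-zero read counts raise
  "no reads"; single-site genes make the latent-rate and fixed-rate
  posteriors identical since no pairs exist.

## Known limitations

Inference is per-gene; no strength is borrowed across genes. The
binomial emission ignores overdispersion and residual mapping bias —
upstream WASP-style filtering is assumed. The latent-rate variant
shares one error rate per gene. The null simulation conditions on the
observed depths and the assumed (or predicted) rates; misspecified
rates shift calibration, which is why the rate-prediction and latent
paths exist.
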