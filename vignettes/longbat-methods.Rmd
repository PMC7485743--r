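---
title: "Methods behind longbat: selection, expression and the longevity signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind longbat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(longbat)
```

`longbat` chains five analyses that together contrast a long-lived
and a short-lived species pair: a genome-wide Ka/Ks selection scan,
count-based expression analysis, per-gene variance partitioning, GO
term-level testing, and an anti-/pro-longevity signature test with a
subsampling null. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical and design decisions taken
where the methodology left genuine latitude. Every quantitative claim
made here is one the test suite or the acceptance script computes.

## Pairwise Ka/Ks by NG86 counting

For a pair of aligned coding sequences, codons containing gaps,
ambiguity or a stop in either sequence are excluded. For each
remaining codon, the synonymous site count is the sum over its three
positions of the fraction of the three single-nucleotide mutants that
preserve the amino acid; mutants creating stops count as
nonsynonymous, and `N = 3 - S` per codon. Site counts are summed per
sequence and averaged between the two sequences. Substitutions
between differing codons are classified by averaging synonymous /
nonsynonymous step counts over all orderings of the differing
positions, excluding mutational paths that pass through a stop codon
(if every path is blocked, all are used — the standard counting
convention). The proportions `ps = Sd/S` and `pn = Nd/N` are corrected
for multiple hits with the Jukes–Cantor transform
`d = -(3/4) log(1 - (4/3) p)`, undefined at `p >= 3/4`; saturated
genes are flagged and excluded from multiple-testing adjustment, as
is ω for genes with `Ks = 0`.

Positive selection is scored by a one-sided Fisher exact test on the
2×2 table `[[round(Nd), round(N - Nd)], [round(Sd), round(S - Sd)]]`
— the counting estimator does not define this table uniquely, and
rounding to integers is our recorded choice since the exact test
needs counts. Purifying selection uses the opposite tail with its own
BH adjustment. A gene is called positively selected iff ω > 1, its
FDR is below `kaks_fdr` (default 0.05) and it carries no filter flag;
the filters are a minimum compared length (`min_len_bp = 100`) and a
minimum ratio of compared length to total alignment columns
(`min_coverage = 0.8`; "coverage" is not defined more precisely by
the underlying protocol, so the compared-fraction reading is ours).

This counting estimator deliberately replaces maximum-likelihood and
model-averaged Ka/Ks estimators: it is closed-form, exactly
reproducible, and its every intermediate (S, N, Sd, Nd) is verified
in the test suite against brute-force enumeration over all 61×61
stop-free codon pairs. The cost is the usual NG86 bias under
transition/transversion asymmetry, which the simulator below does
not generate.

## Synthetic data

The generator is first-class, tested code: all validation runs on
data whose ground truth is known.

**Codon pairs.** A stop-free ancestral sequence is evolved
independently into two descendants. Single-nucleotide changes are
proposed uniformly; nonsynonymous proposals are accepted with
probability `min(ω, 1)`, synonymous with `min(1/ω, 1)`, stops are
rejected, and the proposal count is calibrated so the expected
accepted divergence matches the requested substitutions per site.
Because proposals are uniform, this matches the mutation model NG86
assumes, and the realized Ka/Ks ratio approaches the requested ω (a
few percent low, because stop-adjacent nonsynonymous sites can never
fix). The recovery tests require the median estimate over 50
simulated 10,000-codon genes to sit within ±20 % of ω for
ω ∈ {0.1, 1, 2} at divergence 0.2. With ω = 0 every accepted change
is synonymous, so the descendant proteins are identical — though
pathway averaging across codons hit in both lineages can still count
fractional nonsynonymous steps, which is a property of NG86 counting,
not of the simulator.

**Counts.** The study design is two species × 8 individuals, sex
alternating F/M within species so the crossed design stays balanced
at small n. Latent per-sample log2 expression is
`baseline + species + sex + residual`. The species and sex
contributions are fixed half-offsets of magnitude
`sd_total * sqrt(frac/2)`: with a 2-level factor, this scaling makes
the implied random-effect variance component equal `frac * sd_total²`
— precisely the estimand of the variance-partition module — while on
zero-residual data the ANOVA sum-of-squares decomposition equals the
requested species:sex ratio exactly. Counts are Poisson around
`library_size · 2^y / Σ 2^y` (negative binomial optional through a
dispersion parameter; the residual component already models
biological noise on the log scale, so Poisson is the default).
Baselines are drawn log-normal in the packaged fixture, giving the
strong shared abundance gradient (hence high sample-sample rank
correlations) that real transcriptomes show. One compositional caveat
matters for fixture design: expression is relative, so a shift shared
by all genes in one species cancels in the within-sample
normalization. Planted species effects must therefore sit against a
stable background, and the fixture plants balanced up/down sets.

**Annotation and lists.** Random terms draw uniform gene subsets
within a size range; planted terms are written exactly as given. Gene
lists are plain text, one id per line.

## Expression analysis

Genes whose counts sum to zero within species A *and* within species
B are removed ("expressed in neither" read literally as the AND rule;
the OR reading is available as `filter_rule = "or"`). Library sizes
are the column sums of the filtered matrix.

TMM factors follow the reference trimmed-mean-of-M-values estimator:
the reference sample minimizes the distance of its 75th-percentile
count fraction from the mean; M and A values are computed over
doubly-nonzero genes after library scaling; M is trimmed 30 % from
each tail and A 5 % from each tail; the factor is 2 to the weighted
mean of surviving M-values with inverse asymptotic binomial variance
weights, and factors are rescaled to zero log-mean. The test suite
pins this to `edgeR::calcNormFactors` at 1e-10 — edgeR is the
independent reference there, never the implementation. One subtlety:
the precision weights depend on absolute depth, so the weighted
factor is only approximately invariant to rescaling a single sample's
counts (about 1e-3 in log2 units in the tests); `do_weighting =
FALSE` gives the plain trimmed mean, which is exactly invariant.
Normalized expression is `log2(count / (lib · factor) · 1e6 +
pseudocount)` with pseudocount 1, so zero counts map to zero.

Sample-sample Spearman correlations (Pearson on midranks) are split
into intraspecific (2 × C(8,2) = 56) and interspecific (64)
coefficients. These sets are unpaired and of unequal size, so they
are compared with a rank-sum test rather than a signed-rank test.

Differential expression is a per-gene two-sided Wilcoxon rank-sum
test on normalized values between species — at 8 vs 8 without ties
this is exact, with minimal achievable two-sided p of
`2 / choose(16, 8) ≈ 1.6e-4` — followed by BH adjustment. The DEG
threshold defaults to FDR < 0.05, with the stricter 0.01 variant
available through `de_fdr` (both thresholds are in circulation for
this kind of analysis; 0.05 is our default because the downstream
modules consume the broader set). A rank test trades power against a
negative-binomial model for freedom from distributional assumptions
and exactness at this sample size.

## Variance partitioning

Per gene, `y = μ + u_species + v_sex + ε` with independent zero-mean
random effects for both 2-level factors, estimated by REML: the
residual variance is profiled out and the two variance ratios are
optimized under nonnegativity box constraints (relative tolerance
1e-8 of the optimizer, at most 500 iterations, method-of-moments
starting values). Reported are the variance fractions
`σ²_k / (σ²_species + σ²_sex + σ²_resid)`, which are shift- and
scale-invariant. Two degenerate rules keep the estimator total:
constant input returns fractions (0, 0, 1), and an (essentially)
perfect two-factor fit — where the REML criterion is unbounded in the
ratios — returns the ANOVA decomposition with zero residual. On
balanced designs with interior solutions REML coincides with the
truncated ANOVA method-of-moments estimator, and the tests verify
both that identity (1e-4) and agreement with lme4's REML.

A gene enters the screened set iff its species fraction is at least
`varfrac_threshold = 0.8` (inclusive — "at least 80 %"); direction
is the sign of the species mean difference of normalized expression
(the same scale the model was fitted on), with exact ties excluded
under a warning. Worth stating plainly: with one species contrast
(1 degree of freedom) the species component is intrinsically noisy
at n = 8 + 8 — the balanced-ANOVA oracle itself has a mean absolute
fraction error of about 0.17 at true fractions near 0.5 — so the
screen is reliable only far from the threshold, which is exactly how
it is used (planted 0.95 vs 0.1 fixtures separate cleanly).

## Ontology

Over-representation per term is an upper-tail hypergeometric test of
the overlap between a direction's screened genes and the term's genes
within the expressed background, BH-adjusted over the tested terms;
terms overlapping the foreground by fewer than `min_overlap = 3`
genes are not tested. No term-graph propagation is applied — the
annotation is taken as given. The top `n_top_terms = 20` terms across
both directions (deduplicated, each keeping its best FDR) are carried
into the term-level stage: per term, the per-gene species means
(mean of normalized log2 expression across each species' samples —
the natural paired summary, since the protocol does not dictate one)
form a paired vector tested with one-tailed signed-rank tests in both
directions, BH-adjusted per direction; the significant direction, if
any, is called. A term significant in both directions (impossible for
one-tailed pairs at reasonable n) would be called `none` with a
warning.

## Longevity signature

The anti-longevity list is tested with alternative "less" (lower in
the long-lived species, which is species A by the sample-metadata
convention), the pro-longevity list with "greater"; list genes
missing from the expression table are dropped with a message, and
fewer than two usable genes is an error. The null distribution draws
B = 1000 uniform same-size subsets from the background — by default
the variance-screened set, mirroring the "subsample from the
genetically distinct genes" construction; whether the real lists
were confined to that set is not stated by the protocol, so the
background is configurable. The 95 % highest density interval of the
null p-values is the acceptance region, and the observed p is
significant iff strictly outside it. Because the screened background
mixes strong up- and down-regulated genes, the null p-values are
broadly spread and the HDI is wide; an extreme observed p (the
planted anti-list reaches p ≈ 2⁻¹⁹ territory) falls far below its
lower bound.

## Statistical primitives and numerical choices

All tests are implemented in the package; base R and edgeR/lme4
appear only as oracles in the test suite.

- **Signed-rank**: zeros dropped before ranking (Wilcoxon's original
  convention). For n ≤ 25 the null of W⁺ is computed by a
  generating-function convolution over doubled midranks — integer
  arithmetic that equals full sign-pattern enumeration exactly, ties
  included — otherwise a tie-corrected normal approximation without
  continuity correction. The switchover is fixed, not data-driven,
  for cross-platform reproducibility.
- **Rank-sum**: exact by subset-sum counting when the pooled size is
  ≤ 20 and tie-free; otherwise tie-corrected normal approximation.
- **Fisher 2×2**: exact hypergeometric tails; the two-sided p sums
  tables with probability ≤ observed × (1 + 1e-7).
- **χ² 2×2**: Pearson statistic, df 1, no continuity correction
  (the correction convention is not dictated; uncorrected is the
  common default at these counts).
- **BH**: step-up `min monotone of p·m/i`, NA-tolerant, order
  preserved.
- **KS**: sup-distance of ECDFs with the asymptotic Kolmogorov
  p-value.
- **HDI**: the shortest contiguous window of the sorted sample
  containing `ceiling(mass · n)` points, no density smoothing; width
  ties (within a few ulps, to make the rule deterministic under
  floating point) break toward the smallest lower bound.
- Exact discrete p-values are *super-uniform* by construction, so
  calibration checks against U(0,1) are one-sided in the
  anti-conservative direction; a two-sided test would reject on
  discreteness alone.

## Orchestration and reproducibility

`run_pipeline()` executes the stages in order, writes each table as
TSV with lexicographically sorted ids, and emits a `summary.json`
(validated against a versioned schema) with reals rounded to six
decimals; identical configuration and seed give byte-identical
output. The master seed is expanded into independent per-stage
streams by hashing the stage label, so adding a stage cannot perturb
another stage's draws.

## Problem sizes

The packaged study conditions are two species × 8 individuals and
800 genes (5 positively selected at ω = 3 against an ω = 0.1
background at divergence 0.2; 100 genes at species fraction 0.95,
half up in each species, 30 forming the planted term; a 19-gene
anti-longevity list planted 1 log2 unit lower in the long-lived
species with residual sd 0.5; a 28-gene pro-longevity list with no
effect; library sizes around 3 million). Recovery experiments in the
tests use 500 genes per stratum for variance fractions, 50 × 10,000
codons per ω for selection, 1,000 terms and 100 replicates for the
null error-control checks — sizes chosen to give stable Monte-Carlo
estimates for each property.

## What passing tests do and do not show

The generator emulates the study design's structure: balanced
two-species sampling, crossed sex, log-scale variance components,
Poisson counting noise, uniform-mutation codon evolution. It does not
emulate codon-usage bias, transition/transversion asymmetry,
site-rate heterogeneity, count overdispersion beyond the optional NB,
batch effects, or annotation incompleteness. Passing recovery tests
therefore validate the implementation and its statistical
calibration, not robustness of the scientific conclusions to those
real-data complications. Known limitations worth restating: NG86 is
biased under asymmetric mutation; the rank-sum DE test discards
count-level information; the 2-level variance screen is noisy near
its threshold; and the subsampling null inherits the composition of
whatever background it is given.
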