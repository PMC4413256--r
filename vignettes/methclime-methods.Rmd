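---
title: "Models and methods behind methclime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methclime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(methclime)
```

methclime analyses natural variation in plant DNA methylomes measured at
two growth temperatures in a structured panel of inbred accessions. This
vignette explains the statistical models the package implements, the
choices made where the methodology was genuinely open, and what the
simulation-based tests do and do not establish.

## The data model

The primary input is the bisulfite "cytosine report": per accession and
growth environment, one row per cytosine with chromosome, 1-based
position, strand, sequence context (CG, CHG or CHH — the three plant
methylation contexts, maintained by distinct pathways) and methylated /
total read counts. The package treats each cytosine individually (no
symmetric-CpG strand merging) and never smooths counts: all aggregation
is count-weighted, so the level of any region is `sum(meth)/sum(total)`
over its covered cytosines. A no-op smoothing hook (`site_levels()`
feeding every aggregator) marks the place where kernel smoothing could be
inserted; we found raw count-weighted windows sufficient because every
downstream statistic operates on windows of at least 100 bp.

Genome-wide context averages are *unweighted* means of per-site levels at
covered sites by default; whether coverage weighting is preferable is not
determinable from first principles (deep sites are more precise but
coverage correlates with genomic features), so both are available
(`weighted = TRUE`) and the default is declared rather than argued.
The minimum coverage for a site level to be defined defaults to 1 and is
exposed everywhere.

Bisulfite conversion error is estimated from the chloroplast genome,
which is unmethylated, as `1 - sum(meth)/sum(total)` over chloroplast
cytosines; the simulator applies the complementary error symmetrically
(an unmethylated cytosine is read methylated with probability
`e = 0.0041` by default, i.e. 99.59% conversion efficiency, and a
methylated one escapes conversion at the same rate).

## Windows, variable windows and GBM genes

Local methylation is summarized in 200 bp sliding windows centered every
100 bp (half-overlapping tiling from position 1; partial windows at the
chromosome end are dropped). Upstream of association testing, windows
with missing data in any accession are removed and the remainder ranked
by across-accession variance; the most variable `top_n` are retained.
Ties in variance are broken by genomic order, earlier coordinate first —
an arbitrary but deterministic rule.

A gene is classified as gene-body methylated (GBM) when its mean CG level
across accessions is at least 0.05 while CHG (and, by default, CHH) stays
below 0.05; genes above the non-CG cutoffs are "TE-like" and excluded.
The CHH condition is on by default because genuine gene-body methylation
is a CG-only signature; disabling it (`use_chh = FALSE`) reproduces the
two-cutoff variant.

## Differential methylation

Between two samples (two temperatures within an accession, or mutant vs
wild type), counts are summed in non-overlapping 100 bp tiles and each
tile tested with a two-sided Fisher exact test on the 2x2 table of
(methylated, unmethylated) totals, Benjamini–Hochberg adjusted over the
tested tiles. A window is reported when `q <= 0.05` and the absolute
level difference reaches 0.3. We read the conventional "minimum fold
change of 0.3" of methylation DMR callers as an absolute difference —
that is the "difference" semantics of the tool lineage this reproduces —
and provide `semantics = "ratio"` for the literal fold-change reading.
Fisher's exact test is the appropriate per-window test because each
comparison involves exactly two samples without replicates; a
dispersion-aware model would require replicates the design does not have.

Temperature DMRs are called per accession (16C minus 10C orientation) and
summarized two ways: per-accession gain/loss counts, and a consensus set
of windows called in at least `k` accessions (`k = 1` by default; the
merging rule behind published per-accession counts is not uniquely
defined, so `k` is exposed). Pathway-dependent DMRs (e.g. CMT2- or
DCL3-dependent) are the loss-in-mutant windows of a mutant vs wild-type
comparison. Interval overlap uses 1-based closed intervals; the distance
between touching intervals is 0, so "within 500 bp" includes a DMR ending
exactly 500 bp from a feature edge.

TE-family enrichment among "variable" TEs permutes the variable label
over all TEs, flags a family as over-represented when its observed count
exceeds the 95th null percentile (and exceeds its expectation), and
reports the add-one empirical p-value `(r + 1)/(n_perm + 1)`.

## Kinship-corrected association

GWAS uses the standard single-variance-component linear mixed model
`y = x b + Z u + e`, `u ~ N(0, sg^2 K)` with an identity-by-state kinship
`K` (fraction of shared alleles, pairwise-complete). The variance ratio
is estimated once per phenotype on the null model by maximum likelihood
on the eigenbasis of `K` and reused for every SNP (the usual
two-step approximation), each SNP then tested by generalized least
squares with a Wald t-test; `exact = TRUE` re-estimates the ratio per
SNP. We chose the Wald test over a likelihood ratio because it is
deterministic, fast, and the two are asymptotically equivalent at these
sample sizes; calibration is verified by simulation (type-I error at
alpha = 0.05 within [0.035, 0.065] under a structured null, genomic
control lambda within [0.9, 1.1]). Missing genotypes are mean-imputed
per SNP and a 5% MAF filter is applied by default; both choices are
exposed because the upstream conventions vary.

The stepwise scan adds the most significant SNP as a fixed cofactor and
rescans until nothing passes the per-scan Bonferroni threshold
(`0.05 / n_snps`). Cofactors are excluded from subsequent testing; a SNP
collinear with the cofactors is skipped with `p = NA`. This recovers
repulsion-phase linked pairs — two adjacent SNPs whose non-reference
alleles never co-occur — because conditioning on the first reveals the
second, the behavior the major-locus simulation plants deliberately.

Cis/trans labelling uses a 100 kb window around the phenotype's genomic
anchor for GWAS summaries and 50 kb for variance-component relatedness
partitioning: the two distances come from different parts of the
methodology this package follows and are deliberately kept as separate
configurables rather than harmonized.

Structure correction for genotype-class displays subtracts the BLUP of
the random genetic value: `y - u_hat` with
`u_hat = U diag(d/(d + delta)) U' (y - mu)` on the eigenbasis of `K`.
When the genetic variance estimate is zero the phenotype is returned
unchanged.

## F2 QTL mapping

The Haley–Knott scan works on an F2 intercross with fully informative
markers. At each grid position (4 cM step), genotype probabilities are
obtained by conditioning on both flanking markers through the F2
genotype Markov chain under the Haldane (no-interference) map function;
the phenotype is regressed on the expected additive and dominance
dosages, and `LOD = (n/2) log10(RSS0/RSS1)`. The genome-wide 5%
threshold is the 95th percentile of max-LOD over 1000 phenotype
permutations; a 1.5-LOD support interval is reported. The included cross
simulator generates gametes marker-to-marker with Haldane recombination,
so planted QTL have known positions for recovery tests. Haplotype
inference from bisulfite reads is out of scope; synthetic crosses carry
known genotypes.

## Two-environment variance decomposition

The core decomposition models the N x 2 phenotype matrix (accessions by
environments) as

    Y = 1 mu' + U_cmt2 + U_cis + U_trans + psi

with each `U_k ~ MVN(0, C_k, R_k)` matrix-normal — a 2x2 trait covariance
`C_k` across environments and a fixed accession relatedness `R_k` — and
`psi ~ MVN(0, Sigma, I)`. Relatedness matrices are standardized-genotype
cross-products over declared SNP sets (cis: within 50 kb of the
phenotype anchor; major locus: its region; trans: all remaining SNPs),
rescaled to mean diagonal 1.

Each 2x2 covariance is parameterized as `a^2 J + diag(b1^2, b2^2)`: a
shared (environment-persistent) component plus environment-specific
ones. The shared/specific decomposition of a free-form covariance is not
unique; this parameterization makes the split identifiable at the cost
of constraining the cross-environment covariance to be non-negative,
which is the biologically expected sign for all four effects here. The
fractions reported are: environment — the sample-size-weighted variance
of the fitted environment means; for each random effect, `a^2` (shared)
and `mean(b1^2, b2^2)` (interaction); noise — the residual total;
normalized to sum to one.

Fitting is by maximum likelihood (not REML) on the observed cells of
`vec(Y)` (environment slow, accession fast), with the environment means
profiled out by GLS and the 12 variance parameters optimized by L-BFGS-B
with analytic gradients (`dV/da = 2a J (x) R` etc.). Up to 10 restarts
are attempted — the first from an equal-split heuristic, the rest from
log-uniform draws on [1e-3, 1] times the phenotypic variance — stopping
at the first convergence; non-converged fits are flagged and refused by
the partitioner. Convergence uses the optimizer's default relative
tolerance (`factr = 1e7`) with a gradient tolerance of 1e-5 and a cap of
500 iterations per restart. A tiny ridge (1e-10) guards the Cholesky
factorization near the boundary. Correctness is anchored by an oracle
test: for N <= 8 the objective equals a dense 2N x 2N multivariate-normal
log-density built without any Kronecker shortcut, to 1e-8, including
with missing cells.

Accessions measured in one environment only contribute their observed
cell; nothing is imputed.

## Population genetics and environment of origin

Hudson's Fst estimator is computed per site from sample allele
frequencies with the standard finite-sample corrections, and combined
across sites as a ratio of averages (the average-of-ratios variant is
also reported but never used as the genome value, since it weights
uninformative sites equally). Sites monomorphic in both populations are
excluded.

Additive genetic variance is estimated by Haseman–Elston regression of
pairwise phenotype cross-products on kinship. Because the phenotype is
mean-centered within the analysis group, the kinship must be Gower
double-centered to be the covariance regressor of the centered data, and
is rescaled to mean diagonal 1 so the slope is the additive variance on
the observable per-individual scale; with a raw IBS regressor the slope
is substantially attenuated whenever kinship has row structure (we
measured roughly a three-fold attenuation in a two-population panel).
The regression includes an intercept and the slope is floored at zero.

Qst follows the subtraction construction: overall additive variance from
all accessions, within-population variances from each population with
kinship computed on the subsample (keeping the IBS normalization
internal to the group), `sigma2_w` their `n_k - 1`-weighted average,
`sigma2_B = max(0, overall - within)`, and
`Qst = sigma2_B / (sigma2_B + 2 sigma2_w)`. The weighting is one of
several defensible conventions; it is isolated in
`qst_from_variances()` so the combination rule is testable in closed
form (`sigma2_B = sigma2_w` gives exactly 1/3).

Climate tables report pairwise-complete Pearson and Spearman
correlations of per-accession methylation averages against
environment-of-origin variables, with the two-sided Spearman p. SNP-set
enrichment in genomic regions draws frequency-matched null sets (allele
frequency bins of width 0.02, uniform fallback when a bin cannot be
matched, logged) and reports `observed/mean(null)` with the add-one
empirical p. Derived-allele polarity is taken as an input column when
needed; outgroup inference is out of scope. The north/south split
defaults to latitude 60 and is configurable.

Expression contrasts normalize each sample by its effective library size
(median over genes), compare per-accession class-mean expression between
regions by Wilcoxon rank-sum for GBM and non-GBM genes, and additionally
report each accession's GBM-mean expression normalized by its non-GBM
mean, which removes sample-level confounders by construction.

## The simulator and what the tests show

Every analysis stage is exercised against
synthetic data with known truth. The generator produces: two
subpopulations of inbred 0/1 genotypes under the Balding–Nichols model,
calibrated so realized Hudson Fst matches a target (0.187 by default,
the panel-scale estimate for the system this emulates); a repulsion-phase
major-locus pair with region-specific allele frequencies; non-overlapping
gene/TE annotations with a family table and a 2.7% "variable" TE subset;
and per-cytosine counts whose latent methylation probability is a
logistic function of additive logit-scale contributions — baseline by
feature type and context, major-locus and cis SNP effects on TE CHH
sites, a polygenic latitude-correlated liability on CG gene-body sites,
a genome-wide CHH temperature response, and stronger responses inside
variable TEs. Observed counts are Binomial with the conversion-error
mixture `p(1-e) + (1-p)e` at Poisson depth; the chloroplast contig is
simulated with `p = 0`.

No generative model for methylation exists in the source methodology;
the logistic-additive construction was chosen as the simplest link that
keeps probabilities in (0, 1) with unbounded effect sizes, and all
distributional choices here are stand-ins. Two calibrations are solved
rather than hard-coded: the Balding–Nichols divergence equals the Fst
target (accurate to a few hundredths), and the 16C logit shift is found
by root-solving so the genome-wide mean CHH level is 14% higher at 16C
*including* the planted temperature-DMR gains and losses — a fixed
`log(1.14)` shift under-delivers because the logistic saturates at
high-methylation TE sites.

The simulator deliberately omits: linkage disequilibrium decay (SNPs are
exchangeable within a chromosome apart from the planted pair),
read-level artefacts (mapping bias, PCR duplicates), realistic cytosine
spacing (sites are placed on a jittered grid, densely in features), and
any coupling between expression and temperature. Passing tests therefore
establish that the estimators recover the structures they target at
realistic effect sizes and sample sizes — not that real methylomes
satisfy the generative assumptions.

Problem sizes in the test suite are the package's own choices to keep a
full run fast while preserving power: variance-component recovery uses
N = 300 accessions and 25 phenotypes; GWAS calibration 2000 SNPs at
n = 150; Qst–Fst contrasts 50 replicate panels of 100 accessions; the F2
scan the classic n = 113 with 1000 permutation thresholds; the
end-to-end demo 24–60 accessions over a 0.4–2 Mb genome. The
h2-recovery check for Haseman–Elston uses a panmictic kinship: under a
strong two-population structure the single-realization HE slope is
heavily right-skewed (the population-split eigenvector contributes a
single chi-square degree of freedom), so median-recovery is a property
of the estimator only when the kinship spectrum is non-degenerate; the
structured case is covered by the Qst contrast tests instead.

## Known limitations

* Exactly two environments; the Kronecker machinery is written for
  E = 2 and does not generalize as-is.
* No standard errors on variance fractions; the fitter reports the ML
  point estimate and its convergence state.
* The shared-plus-specific covariance parameterization cannot represent
  negative cross-environment covariance; a free-form PSD `C` with
  post-hoc decomposition would, at the cost of an unidentifiable split.
* Per-window Fisher DMR calling ignores biological replication and
  within-window dependence between cytosines.
* The cis window (50 kb / 100 kb) is a hard cutoff, not an LD-aware
  boundary.
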