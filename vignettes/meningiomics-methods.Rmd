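---
title: "Methods: integrated analysis of primary atypical meningioma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated analysis of primary atypical meningioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(meningiomics)
```

This vignette documents the statistical models behind each stage of the
package, the parameters that matter, what the synthetic cohort does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Somatic variant filtering

Tumour/normal variant calls are consumed as a table (the callers
themselves are out of scope) and passed through a cascade of ten
quality filters. Every filter is evaluated on every record — there is no
short-circuiting — so the verdict is order-independent and the full
failure list is available for audit. The somatic score is built from
the two genotype log10-likelihood triplets as the phred-scaled
probability of genotype agreement under a flat prior,
$-10\log_{10}\sum_g P(g\mid T)P(g\mid N)$, capped at 255 (likelihoods
cited without an explicit formula are completed by this standard
construction). Tunables, with defaults chosen where only a qualitative
rule is stated: mutation-cluster window 100 bp (conventional for
clustered-artifact removal; the cluster rule flags runs of size > 2
within one sample), strand-bias cap phred 60, MQ0 cap 4 reads. The
homopolymer rule is disjunctive — a run of ≥ 10 bp either overlapping
the ±5 bp window around the site or starting immediately to its right —
because the source rule is phrased as a disjunction; both readings are
implemented as a union.

Consequence terms are ranked by a fixed severity ladder (transcript
ablation down to in-frame indels); a variant is deleterious iff its top
term is on the ladder. A plain missense term is *not* deleterious —
only the damaging-annotated form (`missense_damaging`) is, mirroring
"predicted deleterious/damaging".

## Clonality

For a mutation with VAF $f$ at tumour copy number $c$ and purity $p$,
the effective copies are $D = pc + 2(1-p)$, the mutated-copy
multiplicity $m$ is $f D / p$ rounded and clamped to $[1, c]$, and the
cancer cell fraction is $fD/(pm)$, clamped to $[0, 1.05]$. The
round-and-clamp multiplicity is the minimal completion of a rule stated
without one; the 1.05 ceiling keeps binomial sampling noise from
truncating genuinely clonal mutations at exactly 1.

## Copy-number instability

Event classification works on one arm at a time (segments spanning a
centromere are split first). With $f$ the covered arm fraction: large
if $f > 1/3$ (strict — a segment at exactly one third is focal), focal
if $1/10 < f \le 1/3$. Loss/gain additionally require logR below −0.1 /
above 0.1 *and* mean heterozygous-SNP BAF deviation ≥ 0.05; any
intensity-qualifying segment failing the BAF test is classed `none`
(the BAF false-positive correction). Copy-neutral LOH is $f > 1/3$,
$|{\rm logR}| \le 0.1$, BAF deviation ≥ 0.05 — the cn-LOH logR bound is
read as the interval $[-0.1, 0.1]$ (the source states an evidently
typoed "between 0.1 and 0.1").

PGA is the percentage of genomic base pairs in loss or gain segments,
overlaps counted once; cn-LOH is excluded by definition ("loss or gain
base pairs") with an `include_cn_loh` option for sensitivity analysis.
PGA is computed over the configured arm table, which covers autosomes
only by default. CNV-high/low uses a strict inequality against the
cohort mean (or the fixed 4.8% reference).

Purity estimation inverts the expected het-SNP BAF under single-copy
loss: with admixture-diluted BAF $(1-p)/(2-p)$, the deviation from ½ is
$d$ and $\hat p = 4d/(1+2d)$, computed as an SNP-count-weighted mean
over loss segments with ≥ 10 informative SNPs. This closed form stands
in for the cited qpure estimator, which describes the same principle.

Gene-level association maps each gene to the length-weighted mean logR
of overlapping segments (the summarization is unstated in the source;
length weighting is the neutral choice), then applies a two-sided
rank-sum test. Because group logR values are heavily tied, small
samples use an exact permutation enumeration of the rank-sum statistic
rather than the normal approximation.

## Differential testing (shared engine)

All assays share one moderated two-group test: per feature, an additive
linear model `value ~ grade (+ stratum)`; residual variances $s^2$ on
$d$ df are shrunk toward a prior, $\tilde s^2 = (d_0 s_0^2 + d s^2) /
(d_0 + d)$, with $(d_0, s_0^2)$ estimated by method of moments on
$\log s^2$ (matching the classical empirical-Bayes construction; the
unit tests cross-check t-statistics and hyperparameters against
limma's eBayes). The moderated t has $d_0 + d$ df; p-values are BH
adjusted with significance at adjusted p < 0.05. Stratification by NF2
status is realized as the additive two-factor model rather than
separate per-stratum fits — the combination rule was unstated, and the
additive model keeps one coefficient with maximal df. At $d_0 = 0$ the
statistic reduces to the ordinary equal-variance t; at $d_0 = \infty$
to the fully pooled prior (both verified numerically).

Expression is quantile normalized (ties share their mean quantile) and
batch-adjusted by per-feature location/scale alignment: batch means to
the grand mean, batch SDs to the pooled SD. This is a deliberate
simplification of ComBat without empirical-Bayes shrinkage across
features; it exactly undoes the additive batch shifts the synthetic
cohort plants, but will under-perform full ComBat on small batches of
real arrays. The signature is the adjusted-p < 0.05 set; PCA runs on
the centred, unit-scaled signature submatrix and grade separation is
summarized by the mean silhouette width on the first two components.
The random-forest grade classifier uses the top 25 genes by adjusted p
and reports out-of-bag error; ntree defaults to 5,000, with smaller
values used in tests and the pipeline default (the OOB estimate is
stable well below that for cohorts of this size).

## miRNA networks

Counts are normalized to $\log_2({\rm RPM} + 1)$; the pseudocount of 1
(unstated in the source) anchors zero counts at zero and is recorded
here. 5p/3p strands are distinct features and library totals are
per-sample sums. Regulatory edges require all three of: Spearman
$\rho < 0$, raw p < 0.05, and support in at least 3 of the 6 target
databases — raw p is used for edge significance because the rule is
stated that way; an FDR option exists. The per-miRNA negative-vs-
positive target counts are compared by a paired Wilcoxon signed-rank
test. The 14q32 cluster analysis takes a band interval and flags
members as CNV-driven when their expression is lower in band-loss
samples (one-sided rank-sum p < 0.05).

## Methylation

QC removes sites with missing values, SNP-overlapping probes, sex
chromosomes, and sites failing detection (p > 0.05) in ≥ 50% of
samples, reporting counts per reason. Differential testing runs on
M-values ($\log_2 \beta/(1-\beta)$, β clipped to [0.01, 0.99]) for
variance stabilization, while the effect gate is on the β scale:
called iff adjusted p < 0.05 *and* |Δ median β| > 0.1. This M-value/
β-gate split is a documented divergence from testing β directly; the
dual threshold is unchanged.

Consensus clustering subsamples 80% of samples per iteration,
clusters with average linkage on $1 - r$ (Pearson), cuts at k, and
accumulates co-clustering frequencies normalized by co-sampling counts;
final labels come from clustering the consensus matrix itself. The
reference protocol uses 1,000 iterations; the package default follows
it, and the test suite and pipeline default run 30–200 iterations,
which on the planted cohorts of 12–16 samples already yields a
near-binary consensus matrix. Robustness to large-scale events is
assessed by masking chromosomes and reporting the adjusted Rand index
against the unmasked labels.

The per-sample hypermethylation burden is the fraction of QC-passing
sites with β exceeding the reference-group median by more than 0.1 — a
per-sample analogue of the group-level differential-site count, needed
for correlating with PGA. Regulatory-domain enrichment re-implements
the basal-plus-extension rule (5 kb upstream, 1 kb downstream of the
TSS, extended to the nearest neighbouring basal domain up to 1 Mb,
never shrinking the basal domain; extensions are computed against
pre-extension basal coordinates so the result is order-independent)
and tests gene-set hits with the hypergeometric tail.

## Enhancers

Peaks whose midpoint lies within 2,000 bp of a TSS are excluded
entirely from stitching (full exclusion, the behaviour of recent ROSE
versions; an option could re-admit them to ranking only). Remaining
peaks merge at gaps ≤ 12,500 bp. Super-enhancer calling ranks regions
ascending by input-subtracted signal (signal = max(0, ChIP − input)),
scales both axes to [0, 1], and cuts at the first consecutive segment
whose slope reaches 1 — the scaled diagonal. "Reaches" (≥, not >) is
the deliberate convention: with two regions of unequal signal the
single segment has slope exactly 1 and the larger region is flagged,
and on exactly linear curves the cutoff sits at the first point; a
strict inequality would leave both cases with no cutoff. Differential
binding reuses the moderated engine on $\log_2({\rm signal}+1)$ — a
simplification of DiffBind's count model chosen to keep one
differential engine across assays (a negative-binomial option is noted
as future work). A region-gene pair is concordant iff both the region
and its nearest gene (by TSS-to-centre distance; the assignment rule
was unstated) are significant at adjusted p < 0.05 with equal fold-
change signs. Broad H3K27me3 domains are analyzed on fixed 10 kb bins
(the multiscale decomposition of the original peak caller is not
reproduced), with the global shift summarized as the fraction of
significant bins with positive fold change.

## The synthetic cohort

`generate_cohort()` writes a complete input bundle reproducibly from
(config, seed). It emulates: two grades with grade-linked instability
(CNV-high fractions default 0.7 atypical / 0.15 benign; CNV-high
samples carry chr14q, chr1p and 2–3 further arm events on top of the
chr22q loss every NF2 sample gets — PGA ≈ 12–16% versus ≈ 1–3%);
admixture-diluted BAFs (purity uniform on [0.5, 0.9], binomial reads at
depth 500); driver subgroups with clean hotspot variants plus failing
artifacts; Gaussian log2 expression (SD 0.5) with 100 planted
grade-DE genes at |logFC| 2, EZH2 up, an additive +1 batch shift on
the second batch; negative-binomial miRNA counts (size 10) with the
28-member 14q32 cluster down (logFC −1) in 14q-loss samples, let-7
members down in atypical and anti-correlated with EZH2, and target
genes coupled to realized miRNA abundances so planted edges survive
sampling noise; two methylation clusters with 200 planted sites whose
hypermethylation scales with CNV burden (full strength in NF2/SMARCB1
samples, which are hypermethylated despite genomic stability);
log-normal enhancer signal with 15 planted super-enhancers (×10
multiplier) and 20 grade-differential regions placed beside planted DE
genes; and a genome-wide +0.5 log2 H3K27me3 shift in atypical samples.

It deliberately does not emulate: read-level data, linkage
disequilibrium, probe chemistry (type I/II designs, BMIQ), spatial
autocorrelation of methylation, realistic inter-gene correlation
structure, or subclonal architecture. Passing tests on this cohort
therefore demonstrate that each stage implements its stated rule and
recovers planted structure at realistic effect sizes and sample sizes
— not that the pipeline's power estimates transfer to real arrays or
sequencing data.

The toy genome is 22 autosomes × 130 Mb with a 60 Mb p arm — the
arm-fraction rules only need arm boundaries, so a reduced genome keeps
fixtures small without changing any decision rule.

## Numerical choices and degenerate inputs

Posterior normalization in the somatic score subtracts the maximum
log-likelihood before exponentiating; a zero agreement probability maps
to the 255 cap. The trigamma inverse for the variance prior uses
Newton iteration with the standard asymptotic fallbacks; when the
log-variance spread is below its sampling noise the prior df is
infinite and all features share $s_0^2$. Zero-variance features are
excluded (miRNA DE) or survive via shrinkage (expression). β values
are clipped at 0.01/0.99 before the logit. All-equal enhancer signals
yield no super-enhancers with a warning. Constant PGA makes the
hypermethylation correlation NA with a warning. Ties in ranking break
to the first occurrence (nearest-gene assignment, top-gene selection
by adjusted then raw p).

## Known limitations

The batch adjustment is location/scale only; the enrichment operation
ignores probe density biases that the hosted GREAT service models; the
consensus-cluster k is user-chosen (per-k summaries are reported but no
automatic k selection is performed); the differential-binding model is
Gaussian on log counts rather than negative-binomial; and the clonality
model assumes a single tumour clone per mutation (no mixture
deconvolution).
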