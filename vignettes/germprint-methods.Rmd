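---
title: "Methods and design notes for germprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for germprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

germprint is a post-variant-calling toolkit for germplasm collections:
it starts from a multi-sample VCF of biallelic SNP genotypes (or from
its own cohort simulator) and carries the data through quality control,
diversity and differentiation statistics, population-structure
inference, and the design of a compact SNP fingerprinting panel with
identity-probability metrics and checksummed barcode payloads. This
vignette documents the statistical models, the tunable parameters, the
numerical choices, and the places where the design was genuinely open.

## The genotype data model

Everything operates on a `genotype_matrix`: an `n x L` integer matrix of
alternate-allele dosages (0, 1, 2, `NA` for missing) plus per-locus
metadata (chromosome, 1-based bp position, ref/alt single bases).
Coordinates follow the VCF convention; all physical distances are bp
differences of these positions. Strand is never flipped and only the GT
field is consumed: depth- or quality-based genotype masking is assumed
to have happened upstream in the caller. Multi-allelic, indel and
symbolic records are dropped on read and counted in a drop log, so that
dropped plus retained records always reconcile with the input line
count.

Every filtering stage returns an `attrition_report`, an ordered ledger
of (stage, removed, retained) with the telescoping invariant
`retained[k] = retained[k-1] - removed[k]` enforced at construction.

## Quality control

Stages run in a fixed order: sample missingness, then site missingness,
then the Hardy-Weinberg exact test, then minor allele frequency, then
windowed LD pruning, then the inbreeding-coefficient outlier screen and
the relatedness screen. The order matters (the HWE test is computed on
the post-missingness matrix) and is part of the tested contract. All
thresholds are strict as conventionally printed: `>` for missingness
ceilings, `<` for the HWE p-value and MAF floors. Defaults: `mind` 0.2,
`geno` 0.05, `hwe_p` 1e-5, `maf_min` 0.05, pruning 50-SNP windows, 5-SNP
step, r-squared 0.5, F outliers at 3 standard deviations, duplicate
flags at IBS >= 0.98 or PI_HAT > 0.98.

The HWE test is the two-sided conditional exact test: heterozygote
counts compatible with the observed allele counts are enumerated with
probability proportional to the multinomial coefficient times
`2^n_het`, and the p-value sums all configurations no more probable
than the observed one (no mid-p). It is applied cohort-wide even though
the cohort is structured — the Wahlund effect inflates rejections, a
deliberate, conservative reproduction of common practice that the
filter's very low default threshold (1e-5) largely absorbs.

The inbreeding coefficient uses the method-of-moments form
`F = (obs_hom - exp_hom) / (n_called - exp_hom)` with the
`2n/(2n-1)` small-sample correction inside `exp_hom`, matching common
tooling. The outlier screen is single-pass: mean and standard deviation
are computed once, with no iterative re-screening, so a pair of gross
outliers inflates the standard deviation and makes the screen slightly
conservative — the planted-defect tests document exactly this behaviour.

LD pruning slides a window of `window` currently retained SNPs along
each chromosome, advancing by `step`. Within a window, offending pairs
(r-squared above the ceiling, computed as the squared Pearson
correlation of dosages over mutually called samples) are resolved from
the strongest pair down; the member with the lower MAF is removed, with
ties broken toward the later (chrom, pos). The tie-break is a design
choice (the rule preserves informativeness and is deterministic); a
brute-force single-window oracle in the test suite pins the behaviour.
Pairs with undefined correlation (zero variance, < 2 shared calls) are
treated as not prunable.

PI_HAT is the PLINK-style method-of-moments estimate: observed counts
of IBS states 0/1/2 over a pair's shared loci are equated to their
expectations under IBD 0/1/2 given cohort allele frequencies, and the
component estimates are clamped to [0, 1] and renormalised. The
per-locus IBS-state expectations are averaged over loci rather than
recomputed per pair's exact overlap (missingness is assumed independent
of genotype); no finite-sample allele-count corrections are applied.
This is accurate to a few hundredths for unrelated pairs, which is all
the duplicate screen needs. Pairs with fewer than `min_overlap`
(default 100) shared calls are reported low-confidence and never
flagged.

## Diversity statistics

Per locus: `maf = min(p, 1-p)`; plug-in expected heterozygosity
`He = 2pq`; observed heterozygote fraction `Ho`; polymorphic
information content `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` (maximum 0.375
at MAF 0.5); per-site nucleotide diversity `2pq * n/(n-1)` with `n` the
called allele count. He deliberately carries no small-sample
correction so that the unbiased correction appears exactly once, in the
nucleotide-diversity estimator. Genome-wide nucleotide diversity per bp
divides the summed per-site values by a total reference length. Whether
that denominator should be the full or the callable genome is an open
convention; germprint defaults to the full length (the sum of
chromosome lengths for simulated cohorts, the span of observed
positions for VCF input) and makes it configurable.

Pairwise differentiation uses the Weir–Cockerham (1984) variance
components `a`, `b`, `c` per locus — including the heterozygosity
terms — and the weighted ratio-of-sums estimator
`sum(a) / sum(a + b + c)`. Loci where either population has fewer than
two called samples, or where the components are undefined, are skipped
and counted. An independently coded scalar implementation of the same
component formulas serves as the test oracle (agreement to 1e-12).

The LD-decay profile computes pairwise r-squared for intra-chromosomal
pairs within a distance cap (seeded subsampling above a pair budget,
default 2e6 pairs), bins by distance, and finds the half-decay and
r-squared = 0.1 crossings by linear interpolation between bin
midpoints. A curve that starts below a level, or never reaches it,
yields `NaN`. Under locus independence the profile is flat near
`1/(n-1)` — the expected r-squared of two independent vectors — which
the tests verify; decay statistics on such data are meaningless, and
the `NaN` convention makes that explicit.

## Population structure

PCA centres each locus by `2p` and scales by `sqrt(2p(1-p))`
(drift-variance scaling), mean-imputes missing entries (zero after
centring), drops monomorphic loci, and takes the singular value
decomposition. Explained fractions are eigenvalue shares over all
components, so they are non-increasing and sum to at most 1. All
assertions about PCA geometry in the tests are sign-invariant, since
component signs are arbitrary.

Admixture follows the binomial likelihood
`g_ij ~ Binomial(2, theta_ij)`, `theta = Q F`, over missing-masked
entries, maximised by EM with closed-form updates of the ancestry
proportions `Q` and cluster allele frequencies `F`. Cluster frequencies
are clipped to `[1e-6, 1 - 1e-6]` each iteration to keep the likelihood
finite. Plain EM is provably monotone but crawls near the optimum, so
the C++ core accelerates it with SQUAREM (SqS3) steps, safeguarded: an
accelerated proposal is accepted only when its log-likelihood does not
fall below the plain double-EM step it replaces, so the reported trace
is non-decreasing — the EM monotonicity property remains a tested
invariant. Defaults: tolerance 1e-6 on the log-likelihood gain, 2,000
iterations, 5 seeded restarts keeping the best likelihood. EM rather
than quasi-Newton block relaxation is a deliberate simplicity/robustness
trade: slower per fit, but monotone and easy to verify.

Cross-validation over K masks a random fold of called genotype entries,
refits, and scores the masked entries by mean binomial deviance against
`2 * theta_hat`; the best K minimises the average over folds (default
5). Two numerical choices matter here. First, fold fits floor the
cluster frequencies at `1/(2n)` (one-allele smoothing) instead of 1e-6:
without it, a handful of held-out genotypes at near-fixed fitted
frequencies contribute unbounded deviance, and that tail grows with K,
systematically biasing selection toward small K. Second, fold fits use
a looser tolerance and a single restart — ranking K does not need the
final digits of the likelihood. These CV fits never replace the final
fit, which is refitted at the selected K with full settings. This
scheme mirrors the cited genotype-masking cross-validation in spirit
but does not numerically reproduce any external tool's CV values.

Cluster assignment labels a sample with its maximum-Q cluster when that
proportion reaches 0.70 (inclusive), and `"admixed"` otherwise; a
stricter inclusive 0.99 threshold flags near-pure representatives.
k-means in PCA space (20 seeded restarts, best inertia) with mean
silhouette widths provides an independent check of cluster robustness.
Relatedness is summarised as a 1 - IBS distance matrix and a UPGMA
(average-linkage) tree whose node heights are half the merge distance,
hence ultrametric (tested to 1e-10); ties are resolved
deterministically by sorting labels lexicographically before
agglomeration.

## The fingerprinting panel

Candidates must be biallelic with per-locus missingness at most 5%,
MAF > 0.25, PIC > 0.25 and heterozygote informativeness
P(AB) > 0.30. P(AB) is interpreted as the observed heterozygote
fraction — the quantity a genotype heatmap displays — with expected
`2pq` available as a config alternative. "Approximately even
distribution" across chromosomes is operationalised as round-robin
quotas (8 or 7 per chromosome for 150 over 20) with availability-based
redistribution: chromosomes that cannot fill their quota hand the
remainder to those with the largest candidate surplus. Within a
chromosome, selection is greedy in decreasing PIC (ties: higher MAF,
then earlier position), accepting a candidate only if its r-squared
with every already selected locus on that chromosome stays below 0.2
and its spacing is at least 1 Mb. The 1 Mb floor is a design default —
physical spacing is rarely quantified in panel descriptions — and is
configurable. Greedy rather than exhaustive optimisation is deliberate:
exact selection is combinatorial, and the test suite measures the
greedy gap against a brute-force oracle on a small fixture instead of
assuming it away. Whether panel candidates should come from the
0.5-pruned analysis set or from a stricter genome-wide 0.2 pruning is
left to the caller; the default draws candidates from the curated
matrix and enforces the 0.2 ceiling pairwise within the panel.

Identity probabilities per locus use the standard biallelic forms
`PI = p^4 + q^4 + (2pq)^2` and
`PIsib = 0.25 + 0.5 s2 + 0.5 s2^2 - 0.25 s4` (`s2 = p^2 + q^2`,
`s4 = p^4 + q^4`); cumulative values are products over loci accumulated
in log space. A locus fixed at frequency 0 or 1 contributes 1 and
triggers a warning. Note the theoretical floor: with every locus at
MAF 0.5, a 150-locus panel cannot push PI below `0.375^150 ~ 1.3e-64`;
published cumulative PI values far below that floor cannot come from
this formula under locus independence, whereas the sibling formula at
the same frequencies reproduces published sibling values closely. The
package reports the standard formulas and leaves such discrepancies to
the reader.

Barcode payloads are versioned and checksummed:
`GP1|<panel-hash>|<sample>|<IUPAC genotype string>|<CRC32>`. Homozygotes
are the base, heterozygotes the two-base IUPAC code, missing is `N`.
The CRC-32 (IEEE polynomial) is implemented in R; decoding verifies the
checksum, and rasterising the payload as a QR image is intentionally
out of contract — any external QR encoder can render the string.

## The cohort simulator

`cohort_model()` + `simulate_cohort()` generate the study conditions the
pipeline assumes: 64 diploid samples, 20 chromosomes, three ancestral
populations under the Balding–Nichols model (population frequency
`f_kj ~ Beta` with mean `p_j` and variance `F_k p_j (1-p_j)`; ancestral
`p_j` uniform on [0.05, 0.95], a flat folded spectrum), Dirichlet(0.1)
admixture giving both near-pure (Q >= 0.99) and strongly admixed
samples, and per-site/per-sample missingness around 1%. The default
drift parameters `F = (0.072, 0.024, 0.106)` solve
`(F_a + F_b)/2 = FST_ab` for pairwise targets 0.048, 0.065 and 0.089,
so the simulated differentiation spans the low-to-moderate range the
pipeline is meant to resolve; a `pop_sizes` option instead assigns
samples to pure population blocks for parameter-recovery experiments.

Linkage disequilibrium is imposed by a quantile-copying chain rather
than recombination graphs: within a chromosome each gamete carries a
latent uniform quantile that is copied from the previous locus with
probability `exp(-d / lambda)` and redrawn otherwise, and the allele is
the indicator `u < f_kj`. Copy survival over distance `D` is
`exp(-D / lambda)`, which is the haplotype correlation; genotype
r-squared therefore decays as `exp(-2D / lambda)` plus the `1/(n-1)`
sampling floor, so the half-decay distance of mean r-squared is about
`lambda * ln 2 / 2`. The default `lambda = 90 kb` was calibrated once,
before any downstream testing, so that the measured half-decay of the
default cohort sits near 39.4 kb. Ancestry switches along each gamete in
geometric segments (mean 100 loci by default) so admixed samples carry
ancestry LD; recovery experiments that emulate a pruned, unlinked
marker set use one-locus segments instead, since segment-level ancestry
variance otherwise dominates the comparison between realised and drawn
ancestry proportions.

Planted QC defects are first-class: two high-missingness samples
(defaults 0.5031 and 0.2843 overall missing fraction), one
excess-homozygosity and one excess-heterozygosity outlier (F about
+0.5 and -0.5), and a near-duplicate copy with 0.5% of calls flipped.
The F = +0.5 defect halves heterozygous calls (converting to 0 or 2
with equal probability, leaving the allele frequency unbiased in
expectation); the F = -0.5 defect converts homozygotes to heterozygotes
at locus-specific rates targeting `Ho = 1.5 He`.

What the simulator does **not** emulate: coalescent genealogies,
recombination hotspots, selection, allele-frequency ascertainment from
variant calling, genotyping error correlated with depth, and clonal or
polyembryonic pedigree structure. Passing recovery tests on these
cohorts therefore demonstrates the estimators' correctness under the
stated generative model, not their behaviour on any particular real
dataset.

## Problem sizes and replication choices

The recovery experiments run at desk scale, chosen as the smallest
sizes at which the quantities of interest are statistically stable:
differentiation recovery uses 20,000 unlinked loci with population
blocks of 19/25/16 samples (pairwise FST standard errors well below the
0.012 acceptance band); structure recovery uses 5,000 unlinked loci and
n = 60 with 10 seeded replicates for cross-validated K selection; the
end-to-end QC recovery uses a 64-sample, 10,000-locus cohort with the
default LD scale. One caveat is documented rather than hidden: at
pairwise FST near 0.05 and n = 60, entry-masking cross-validation has
no power to justify a third cluster when cluster membership is strongly
diluted by admixture — the K-selection experiment therefore uses
unadmixed population blocks of the stated sizes, while Q-recovery is
additionally asserted on the admixed cohort. On real panels with
hundreds of thousands of markers the final fit is cheap relative to
variant calling; the EM core scales linearly in samples x loci x K.

## Known limitations

- The admixture model assumes unlinked loci; feeding it unpruned data
  will overstate confidence in structure.
- The HWE screen ignores structure by design (documented above).
- PI_HAT omits finite-sample corrections; it is a duplicate screen, not
  a kinship estimator.
- Panel selection is greedy; the measured optimality gap on small
  fixtures is a few percent of total PIC, but no global bound is
  claimed.
- The simulator's LD is a first-order copying chain: adequate for decay
  profiles and pruning behaviour, not for haplotype-block realism.
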