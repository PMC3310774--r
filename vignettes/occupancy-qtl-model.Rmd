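---
title: "Modeling genotype effects on transcription factor occupancy in a pedigree"
author: "bindingQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genotype effects on transcription factor occupancy in a pedigree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindingQTL)
```

# The scientific problem

A DNA sequence variant that falls inside a transcription factor's
recognition sequence may change the factor's binding energy and hence its
*in vivo* occupancy, measurable as ChIP-seq tag density. Across a
multi-generation pedigree, occupancy at a binding site becomes a
quantitative trait: it can be regressed on SNP genotype, tested for
allelic imbalance within heterozygotes, and subjected to sib-pair linkage
analysis. The striking empirical finding this package is built around is
*buffering*: most variants in the recognition interface do **not**
measurably change occupancy, and whether a given change matters depends on
the site's overall strength and its local sequence context.

bindingQTL provides the full analysis chain for such a study — and,
because the real ChIP-seq and capture-resequencing data are not required,
a synthetic-study generator that emulates every data type the chain
consumes, with exact truth tables for validation.

# The generative model

## Pedigree and transmission

`threeGenPedigree()` builds the canonical 12-member family: four founders,
their two children (the second-generation couple), and six grandchildren.
`simulatePedigree()` drops eight distinguishable founder haplotype labels
through the pedigree, with recombination between adjacent sites following
Haldane's map function. Identity by descent (IBD) for each of the 15 sib
pairs at each site is computed directly from the labels — truth, not
inference — taking values 0, 0.5 or 1.

The simulated sites live on a single chromosome. A real binding-site
catalog spans the whole genome, so adjacent catalog entries are nearly
unlinked; to emulate that on one chromosome the default recombination
rate is `1e-6` Morgans/bp, placing adjacent 3 kb-spaced site windows about
0.3 cM apart. (The genome-average per-bp rate would put the entire
synthetic catalog inside 0.01 cM, making per-pair IBD a single
whole-catalog block, which defeats both linkage analysis and its
permutation null.) Optional IBD "uncertainty" noise exercises the
exclusion rule for uncertain IBD estimates (threshold 0.05).

## Sites, motifs and SNPs

Each site is a 134 bp window with a 14 bp motif core sampled from a PWM
frequency model at the window center, on a random strand, inside
background flanks. SNPs are planted uniformly over the window
(`snpRate` per site, default 0.21 as observed in B-lymphoblast CTCF
catalogs; a second SNP with probability 0.19). Each SNP's motif-relative,
strand-oriented position is recorded: core positions 0–13, the
protein-DNA contact region spanning 20 bp upstream through 10 bp
downstream of the core (44 bp in total; both extents are configurable
because only the total is empirically established).

The three shipped motif models (`exampleMotifModels()`) are **synthetic**
CTCF-like matrices constructed for simulation — a canonical model and two
variants standing in for the factor's multivalent binding modes. All
functions accept user-supplied matrices in the same tab-delimited format.

## The occupancy curve

Binding energetics enter through the PWM log-odds score $a$ of the core
with a given allele. Occupancy follows a saturating logistic

$$ p(a) = \frac{1}{1 + e^{-(a - a_0)/s}} $$

which expresses a *threshold* mechanism: far above the midpoint a site is
saturated and robust to perturbation; far below it is empty and equally
unresponsive; only scores near $a_0$ respond. Defaults: $a_0 = 14$ bits,
chosen at roughly the 40–45th percentile of the sampled-core score
distribution so that deciles 4–7 of fitted occupancy straddle the
midpoint, and $s = 0.8$ bits. The slope was set so that the threshold
phenomenology is actually expressed at the generator's count depths: with
a much gentler slope (e.g. $s = 2$) the negative binomial test detects
essentially every core SNP and the characteristic buffering patterns —
depleted effect rates at the strongest and weakest sites, and larger
allele deltas required at stronger sites — disappear. The underlying
mechanism is only posited as threshold-like by the empirical work, so the
curve and both parameters are explicit configuration, and any comparison
of simulated occupancy-decile curves to real data must note that the
logistic choice is the simulator's own.

Expected ChIP-seq counts for a member with haplotype scores $a_1, a_2$
are $\mu = \text{depth} \times \text{batch} \times (p(a_1) + p(a_2))/2$,
drawn negative binomial with size $\theta$ (defaults: depth 50 per
replicate, $\theta = 10$, two replicates with batch factors 1 and 0.9,
one sample carrying a single replicate, mirroring the real design). At
heterozygous SNPs, the sample's pooled reads are split binomially between
alleles in proportion to the two haplotype occupancies.

A SNP's truth label is *functional* when its relative occupancy
difference $|p(a_A) - p(a_B)| / \max(p)$ exceeds 0.2 — the label is the
simulator's contract, not an empirical quantity.

## Resequencing, conservation, mappability

Pileups are Poisson-coverage draws (default 50x) with a symmetric
base-calling error (default 1%), plus a Phred-like site quality computed
as the likelihood-ratio margin between the best and second-best biallelic
genotype. The conservation-like track adds Gaussian noise to the PWM
column information content (flanks: noise only). Its default noise sd of
1 bit — comparable to the 0–1.7 bit information range itself — was chosen
because per-nucleotide conservation is empirically a near-chance
predictor of functional regulatory variants; a low-noise track would
make conservation an unrealistically strong predictor.

The mappability filter re-implements the personalized-genome read
simulation: every 36-mer starting within ±147 bp of the site center is
generated once per allele haplotype and looked up in the corresponding
personalized chromosome by exact matching; sites with more than 10%
ambiguous reads, or with per-allele ambiguous fractions differing by more
than 0.05, are excluded. Exact matching (rather than mismatch-tolerant
alignment semantics) keeps the filter deterministic and fast;
`mappabilityFilter(maxMismatch=)` provides the tolerant mode for small
inputs.

# The analysis chain

## Motif scanning and allele deltas

`scanCatalog()` evaluates all models, both strands, and every offset
within ±15 bp of the window center, retaining the single best match by an
*exact* score p-value: the score distribution under the i.i.d. background
is computed by dynamic programming over per-position log-odds discretized
at $10^{-3}$ bits, and matches with $p \ge 10^{-2}$ are discarded. Ties
break by higher raw score, then smaller offset, then the + strand —
deterministic output. The allele delta is the absolute log-odds
difference between a SNP's two alleles at its motif column (0 outside the
motif), with the favored allele reported on the genome strand.

PWMs are built by flooring frequencies at a pseudo-frequency of 0.01 and
renormalizing before taking log2 odds; an additive pseudo-count is a
reasonable alternative the constructor does not implement, and the
flooring choice is documented here precisely because the upstream
convention is ambiguous.

## Genotyping

`callSnps()` calls biallelic genotypes with the study's filters: coverage
≥ 8, Phred-like site quality ≥ 30, heterozygotes require a minor-allele
read fraction ≥ 20% (below that the majority homozygote is called — the
convention of common pileup callers; discarding would be the
alternative), more than two alleles above a 10% noise floor drops the
site. `mendelianConsistent()` screens every parent–child trio in the
three-generation pedigree against the biallelic transmission table and
drops offending sites entirely.

## Association

`fitNbGenotype()` is a log-link negative binomial GLM of per-replicate
counts on additive genotype (copies of the alphabetically later allele)
plus a replicate term (`MASS::glm.nb`; when the dispersion diverges to
the Poisson limit on degenerate data the Poisson GLM is used, which is
the $\theta \to \infty$ limit of the same model). Where both collapsed
classes have ≥ 4 data points, the two dominant collapsings are also fit
and the AIC-minimal model reported. Wald significance uses a *t*
reference with residual degrees of freedom: with ~24 points and an
estimated dispersion, the normal reference is several-fold
anticonservative in the far tail, which matters directly for FDR
control. A likelihood-ratio option exists. A separate ordinary linear
fit supplies $r^2$; the fitted heterozygote signal comes from the chosen
model's prediction at the reference replicate. Model selection by AIC
inherits the selection bias of the published design: the selected-model
p-values are mildly anticonservative, so calibration studies in the test
suite use the additive-only fit.

Testability follows the published rules: coverage ≥ 8x in ≥ 6 samples,
≥ 4 data points in each of ≥ 2 genotype classes, ≥ 12 points overall,
mappability pass; multi-SNP windows prefer the SNP with more data
points, then contact-region membership, then lowest p (flagged
position-ambiguous). q-values are Storey's estimator (π₀ from a λ-grid
0.05–0.90 with spline smoothing; for fewer than 100 tests π₀ is fixed at
1, where the estimator is too unstable) or Benjamini–Hochberg.

## Allele-specific occupancy

A one-degree chi-squared test of the two allele read counts against
50:50, no continuity correction, on heterozygous records with ≥ 13
allele-assigned reads and non-differential allele mappability. The
deepest sample represents a site (ties: lexicographically first sample).
FDR presets of 0.1% and 0.005% match the thresholds used in practice.

## Linkage

`differentialSites()` is a bespoke per-site NB likelihood-ratio test of a
sample effect against a replicate-only null. Dispersion is pooled: a
method-of-moments estimate from replicate pairs per site, lowess-trended
against the mean, then moderated toward the global median (per-site
estimates carry almost no degrees of freedom, and a single extreme-mean
site would otherwise dominate the extrapolated trend). Counts are then
variance-stabilized with the NB asinh map
$2\sqrt{\theta}\,\mathrm{asinh}\sqrt{y/\theta}$, standardized per site to
mean 0 / sd 1, and replicate-averaged. Haseman–Elston regression is the
original squared-differences form — chosen deliberately over
higher-powered variants for robustness — pooling all 15 sib pairs across
all differential sites; significance comes from permuting whole per-site
IBD vectors onto squared-difference vectors (without replacement by
default; an option samples with replacement), which preserves the
correlation structure among pairs from the same family. The add-one
estimator bounds p below by $1/(n_{perm}+1)$.

## Buffering analyses

The substitution grid reports, per motif position and unordered allele
pair, the proportion of sites where that change associates with
occupancy (cells with < 3 observations suppressed). The decile curve
ranks sites by fitted heterozygote signal into ten equal-count bins
(stable-order tie-breaking) — under the threshold model it shows an
interior maximum with depleted extremes. Mutual information between
context base (4 categories; a consensus/non-consensus collapse is a
flag) and the affected/unaffected label is plug-in MI in bits, with a
label-permutation null (2,000 iterations by default; the add-one rule
applies) and Storey q-values across all position pairs; rows with fewer
than 5 SNPs are suppressed, and sites within a row are canonically
ordered so results are independent of input order given the seed. The
"bootstrap" wording for this null is ambiguous in the empirical
literature; label permutation is the implemented reading, and a true
case-resampling bootstrap is deliberately not the default. Clustering of
standardized occupancy uses Euclidean Ward (`ward.D2`) agglomeration cut
at k = 3; Ward is this package's choice for cluster stability, as no
linkage is established empirically.

## Predictor evaluation

ROC curves rank SNPs by descending score with tie-grouping (trapezoidal
integration), and the AUC provably equals the midrank Mann–Whitney U
normalized by $n_+ n_-$ — the test suite asserts both routes agree to
$10^{-12}$. PPV is reported over a cutoff grid with undefined points
suppressed. `comparePredictors()` compares the PWM allele delta with the
conservation-like score on the identical reference set (contact-region
SNPs), with a SNP-level bootstrap CI on the AUC difference.

# What the simulation does and does not show

The generator reproduces, at desk scale, the qualitative structure of
the real study: an excess of significant SNPs in the contact region with
the higher-occupancy allele usually the energetically favored one, an
interior-maximum decile curve, larger perturbations needed at stronger
sites among significant SNPs with no such trend among non-significant
ones, SNP-associated differential sites carrying a clearly more negative
aggregate HE slope than unassociated ones, and binding-energetics
predictors beating conservation. It does **not** emulate: linkage
disequilibrium beyond pedigree transmission, indels or structural
variants, co-factor motifs, GC or fragment-length biases in counts,
methylation, or any unexplained heritable component (so the
"unassociated" HE stratum is expected near slope 0 here, where the real
study retains residual heritability). Passing tests therefore validate
the machinery and its statistical calibration, not biological
completeness.

# Problem sizes and runtime choices

The packaged tests and the acceptance script use: 2,000 null and 2,000
mixed-effect sites with 24 data points each for calibration and
recovery; a 2,000-site single-SNP study for the decile, trend, contact
and linkage-strata analyses; 100 replicate 250-site catalogs for the
predictor comparison; 50 null runs at 200 permutations plus 10 planted
runs at 2,000 permutations for the MI analysis; and 4,999 permutations
for the determined-trait linkage p. These sizes give stable estimates of
every reported proportion at a few percent precision while keeping a
complete run in minutes on one CPU.
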