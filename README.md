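# bindingQTL

Quantitative genetics of transcription factor occupancy in a pedigree.

A DNA variant inside a transcription factor's recognition sequence can
change the factor's binding energy, and therefore its ChIP-seq occupancy
— but usually it does not: occupancy is extensively *buffered* by site
strength and local sequence context. bindingQTL implements the complete
analysis chain for dissecting this, built around CTCF-style data from a
three-generation family, together with a synthetic-study generator so
that every stage is testable with exact truth tables and no external
downloads.

The chain:

- **Synthetic study generator** — a 12-member, three-generation pedigree
  with Mendelian transmission, recombination and truth identity-by-descent
  (IBD); 134 bp binding-site windows carrying PWM-sampled 14 bp motif
  cores; SNPs planted uniformly; negative-binomially dispersed ChIP-seq
  counts whose mean follows a saturating logistic function
  `p(a) = 1/(1+exp(-(a-a0)/s))` of allele binding energy (PWM log-odds
  `a`); allele-partitioned reads at heterozygous sites; resequencing
  pileups with base-call error; a conservation-like track.
- **Motif engine** — PWM construction with pseudo-frequency 0.01,
  multivalent (three-model) scanning on both strands within ±15 bp of
  the window center with *exact* dynamic-programming score p-values
  (matches kept at p < 1e-2), motif-relative strand-oriented SNP
  positions (core 0–13, a 44 bp protein-DNA contact region), and allele
  log-odds deltas.
- **Signal** — sliding 150 bp / 20 bp tag-density tracks, global median
  normalization (qualifying-bin median fixed at 25), motif-window
  occupancy, and a personalized-genome read-simulation mappability
  filter (36-mers from ±147 bp, per-allele, exact matching).
- **Genotyping** — pileup SNP calling (coverage ≥ 8, quality ≥ 30, minor
  fraction ≥ 20%), pedigree-wide Mendelian-consistency screening,
  ancestral-allele polarization, truth concordance.
- **Association** — negative binomial GLM of occupancy on genotype
  (`occupancy ~ genotype + replicate`, log link) with additive and
  dominant codings selected by AIC, Wald *t* significance, Storey or
  Benjamini-Hochberg FDR, and the published testability rules.
- **Allele-specific occupancy** — chi-squared test of within-heterozygote
  read imbalance against 50:50 at ≥ 13x coverage.
- **Linkage** — a bespoke NB likelihood-ratio differential-occupancy
  test with pooled trended dispersion, asinh variance stabilization, and
  aggregate Haseman-Elston sib-pair regression (squared trait differences
  on IBD ∈ {0, 0.5, 1}) with a structure-preserving permutation null.
- **Buffering analyses** — per-substitution effect grids, occupancy-decile
  curves, perturbation-vs-strength trends, mutual-information context
  dependence with a resampling null, and Ward clustering of occupancy.
- **Predictor evaluation** — ROC/AUC (tie-grouped; provably equal to the
  normalized Mann-Whitney U) and PPV curves comparing the PWM allele
  delta against conservation.

## Worked example

Simulate a 150-site study and regress occupancy on genotype:

```r
library(bindingQTL)

cfg   <- simConfig(seed = 20, nSites = 150, snpRate = 1)
study <- simulateStudy(cfg)
study
#> OccupancyStudy: 150 sites, 178 SNPs, 12 members, 23 count columns
#>   functional SNPs (truth): 15 of 178

se     <- studyCounts(study)
snps   <- as.data.frame(studySnps(study))
g      <- studyTruth(study)$genotypes
cd     <- SummarizedExperiment::colData(se)
counts <- SummarizedExperiment::assay(se)
fits <- do.call(rbind, lapply(seq_len(nrow(snps)), function(r)
  fitNbGenotype(as.integer(counts[snps$siteIdx[r], ]),
                g[cd$sample, r], cd$replicate)))
ok <- fits$converged & !is.na(fits$p)
fits$q <- NA
fits$q[ok] <- estimateFdr(fits$p[ok], "storey")
hit <- which(!is.na(fits$q) & fits$q < 0.01)
head(cbind(snps[hit, c("snpId", "motifPosition", "deltaTruth", "effectLabel")],
           round(fits[hit, c("beta", "q")], 4)), 5)
#>     snpId motifPosition deltaTruth effectLabel    beta      q
#>  snp00001            10   5.832860  functional -1.6197 0.0003
#>  snp00011             7   4.087463  functional -0.7194 0.0018
#>  snp00012             4   2.169931  functional -1.9180 0.0000
#>  snp00047             5   4.754904  functional -3.8333 0.0000
#>  snp00086             9   5.108505  functional  1.3028 0.0000
```

Eight of 177 tested SNPs reach FDR 1%; every one sits inside the motif
core, carries a multi-bit allele log-odds delta, and was labeled
functional by the generator's truth model. `beta` is the log-scale
effect per copy of the B allele, so `snp00047` (delta 4.75 bits at core
position 5) loses occupancy with each B copy while `snp00086` gains it —
the sign pattern the motif energetics predict. Most of the other 163
core and contact-region SNPs change nothing: that is the buffering
phenomenon the package exists to quantify.

`runPipeline(cfg, "outdir")` chains every stage (mappability screen,
motif scan, genotype calling with Mendelian screening, association,
allele-specific tests, linkage, buffering, predictor evaluation) and
writes BED/VCF/TSV tables, a YAML config snapshot, a JSON-lines run log
and a summary ledger; identical configuration and seed reproduce every
output byte for byte.

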