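test_that("pedigree topology is validated with the offending member named", {
  ped <- threeGenPedigree()
  expect_equal(nrow(ped@members), 12)
  expect_equal(length(pedigreeSibs(ped)), 6)
  expect_equal(nrow(sibPairs(ped)), 15)

  bad <- ped@members
  bad$father[bad$id == "GM07"] <- "GM01"   # child wired to a founder
  expect_error(Pedigree(bad), "GM07")
  bad2 <- ped@members
  bad2$mother[bad2$id == "GM05"] <- NA     # one parent only
  expect_error(Pedigree(bad2), "GM05")
})

test_that("transmission produces valid IBD with whole-chromosome blocks at r=0", {
  ped <- threeGenPedigree()
  set.seed(1)
  sim <- simulatePedigree(ped, seq(1, 3e6, length.out = 200),
                          recombRate = 0)
  expect_true(all(sim$ibd %in% c(0, 0.5, 1)))
  # no recombination: each pair's IBD is one value across all sites
  expect_true(all(apply(sim$ibd, 2, function(v) length(unique(v))) == 1))

  # recomputing IBD from the haplotype labels reproduces the table
  hap <- sim$haplotypes
  pr <- sim$pairs
  for (k in seq_len(nrow(pr))) {
    re <- ((hap[pr$sib1[k], , 1] == hap[pr$sib2[k], , 1]) +
             (hap[pr$sib1[k], , 2] == hap[pr$sib2[k], , 2])) / 2
    expect_identical(unname(re), unname(sim$ibd[, k]))
  }
})

test_that("free recombination gives mean sib-pair IBD near one half", {
  set.seed(2)
  # sites far apart at an enormous map distance: independent transmissions
  sim <- simulatePedigree(threeGenPedigree(), seq(1, 1e10, length.out = 10000),
                          recombRate = 1e-4)
  m <- mean(sim$ibd)
  se <- sd(as.vector(sim$ibd)) / sqrt(length(sim$ibd))
  expect_lt(abs(m - 0.5), 3 * max(se, 0.35 / sqrt(10000)))
})

test_that("site catalog plants SNPs uniformly with strand-oriented truth", {
  pwm <- exampleMotifModels()[["canonical"]]
  set.seed(3)
  cat1 <- generateSites(simConfig(nSites = 100, snpRate = 1), pwm)
  expect_true(all(table(cat1$snps$siteIdx) >= 1))
  expect_equal(length(unique(cat1$snps$siteIdx)), 100)

  set.seed(4)
  cat2 <- generateSites(simConfig(nSites = 3500, snpRate = 1,
                                  multiSnpRate = 0.4), pwm)
  snps <- cat2$snps
  expect_gte(nrow(snps), 3500)
  phat <- mean(snps$inContact)
  p0 <- 44 / 134
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / nrow(snps)))

  # core SNPs carry per-allele scores; flank SNPs are silent by construction
  expect_true(all(snps$deltaTruth[!snps$inCore] == 0))
  expect_true(all(abs((snps$scoreB - snps$scoreA)[!snps$inCore]) < 1e-12))
  expect_warning(generateSites(simConfig(nSites = 5, snpRate = 0), pwm),
                 "without SNPs")
})

test_that("a degenerate PWM column yields uniform base sampling", {
  f <- exampleMotifModels()[["canonical"]]@freqs
  f[7, ] <- 0.25
  pwm <- buildPWM(f)
  set.seed(5)
  cat1 <- suppressWarnings(generateSites(simConfig(nSites = 2000, snpRate = 0), pwm))
  comp <- table(substr(mcols(cat1$sites)$coreSeq, 7, 7)) / 2000
  expect_true(all(abs(comp - 0.25) < 3 * sqrt(0.25 * 0.75 / 2000)))
})

test_that("generated genotypes are exactly Mendelian and recover founder frequency", {
  ped <- threeGenPedigree()
  set.seed(6)
  nSnp <- 6000
  sim <- simulatePedigree(ped, seq(1, 2e7, length.out = nSnp))
  founderAlleles <- bindingQTL:::sampleFounderAlleles(nSnp, 0.5)
  g <- bindingQTL:::genotypesFromHaplotypes(sim$haplotypes, founderAlleles,
                                            seq_len(nSnp))
  colnames(g) <- sprintf("s%d", seq_len(nSnp))
  mc <- mendelianConsistent(g, ped)
  expect_equal(nrow(mc$violations), 0)
  founders <- ped@members$id[is.na(ped@members$father)]
  fhat <- mean(g[founders, ]) / 2
  expect_lt(abs(fhat - 0.5), 3 * sqrt(0.5 * 0.5 / (8 * nSnp)))
})

test_that("counts follow the saturating occupancy model", {
  # silent SNP: both haplotypes score equally, allele fraction centers on 1/2
  cfg <- simConfig(seed = 9, nSites = 120, snpRate = 1, multiSnpRate = 0)
  study <- simulateStudy(cfg)
  snps <- studySnps(study)
  ac <- as.data.frame(studyAlleleCounts(study))
  silent <- snps$snpId[snps$deltaTruth == 0]
  acS <- ac[ac$snpId %in% silent & (ac$readsA + ac$readsB) > 0, ]
  tot <- sum(acS$readsA + acS$readsB)
  fB <- sum(acS$readsB) / tot
  expect_lt(abs(fB - 0.5), 4 * sqrt(0.25 / tot))

  # step-function limit: occupancy collapses to an indicator
  expect_equal(occupancyProbability(c(10, 20), a0 = 14, s = 0), c(0, 1))

  # NB moment check on 2000 null sites (variance = mu + mu^2/theta)
  set.seed(10)
  sims <- simulateGenotypeEffect(0, 2000, nSamples = 12, replicates = 1,
                                 depth = 50, theta = 10,
                                 batchFactors = c(a = 1))
  y <- unlist(lapply(sims, `[[`, "counts"))
  expect_lt(abs(var(y) / (50 + 50^2 / 10) - 1), 0.1)

  # monotonicity: expected count non-decreasing in the weaker allele score
  p <- occupancyProbability(seq(5, 25, 0.5), 14, 2)
  expect_true(all(diff(p) >= 0))
})

test_that("pileups reproduce genotypes when error-free", {
  cfg0 <- simConfig(seed = 12, nSites = 40, snpRate = 1, baseError = 0)
  study <- simulateStudy(cfg0)
  called <- callSnps(studyPileups(study))
  conc <- genotypeConcordance(called, studyTruth(study)$genotypes,
                              as.data.frame(studySnps(study)))
  expect_equal(conc$overall, 0)

  # base_error = 0.01 at depth 50: about half a read mismatches on average
  set.seed(13)
  cfg1 <- simConfig(seed = 13, nSites = 60, snpRate = 1, multiSnpRate = 0,
                    baseError = 0.01, pileupDepth = 50)
  st1 <- simulateStudy(cfg1)
  pu <- as.data.frame(studyPileups(st1))
  snps <- as.data.frame(studySnps(st1))
  g <- studyTruth(st1)$genotypes
  homRef <- pu[g[cbind(pu$sample, pu$snpId)] == 0, ]
  aIdx <- match(snps$alleleA[match(homRef$snpId, snps$snpId)],
                c("A", "C", "G", "T"))
  matches <- as.matrix(homRef[, c("nA", "nC", "nG", "nT")])[
    cbind(seq_len(nrow(homRef)), aIdx)]
  mism <- homRef$depth - matches
  expect_lt(abs(mean(mism) - 0.5), 3 * sd(mism) / sqrt(length(mism)))
})

test_that("conservation track mirrors information content", {
  pwm <- exampleMotifModels()[["canonical"]]
  set.seed(14)
  cat1 <- suppressWarnings(generateSites(simConfig(nSites = 30, snpRate = 0), pwm))
  cons <- emitConservation(cat1$sites, pwm, noiseSd = 0)
  ic <- pwmInformation(pwm)
  core <- 61:74
  st <- as.character(GenomicRanges::strand(cat1$sites))
  row1 <- cons[1, core]
  if (st[1] == "-") row1 <- rev(row1)
  expect_equal(order(row1), order(ic))
  expect_true(all(cons[, 1:60] == 0))   # flanks carry no signal at sd 0

  # a degenerate column scores zero information
  f <- pwm@freqs; f[3, ] <- 0.25
  pwmD <- buildPWM(f)
  expect_lt(pwmInformation(pwmD)[3], 1e-3)
})

test_that("the study generator is deterministic given its seed", {
  cfg <- simConfig(seed = 77, nSites = 15, snpRate = 1)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(SummarizedExperiment::assay(studyCounts(a)),
                   SummarizedExperiment::assay(studyCounts(b)))
  expect_identical(as.data.frame(studySnps(a)), as.data.frame(studySnps(b)))
  expect_identical(studyTruth(a)$ibd, studyTruth(b)$ibd)
})
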