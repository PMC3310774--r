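#' Simulation configuration constructor
#'
#' Collects every knob of the synthetic study generator with defaults that
#' mirror the study design being emulated: a 134 bp resequencing window per
#' site, 36 bp reads, two ChIP-seq replicates per sample with one sample
#' having a single replicate, mean depth 50 with negative binomial
#' dispersion theta = 10, SNPs at 21% of sites, genome-average recombination,
#' and a saturating (logistic) occupancy curve in PWM log-odds units.
#'
#' @param seed master seed; all stage substreams derive from it.
#' @param nSites number of binding sites.
#' @param windowBp resequencing window per site (default 134).
#' @param readLen read length in bp (default 36).
#' @param depth mean ChIP-seq reads per site per replicate (default 50).
#' @param dispersion negative binomial size parameter theta (default 10).
#' @param batchFactors per-replicate multiplicative scalars.
#' @param singleRepSample sample id with a single replicate (`NA` for none).
#' @param occMidpoint logistic occupancy midpoint a0, log-odds bits.
#' @param occSlope logistic occupancy slope s, log-odds bits.
#' @param snpRate per-site probability of carrying at least one SNP.
#' @param multiSnpRate probability a SNP-bearing site carries a second SNP.
#' @param recombRate recombination rate, Morgans per bp (default 1e-6:
#'   the single simulated chromosome stands in for a genome-wide site
#'   catalog, so adjacent site windows are placed about 0.3 cM apart).
#' @param pileupDepth mean resequencing coverage per SNP per sample.
#' @param baseError per-base sequencing error probability.
#' @param founderFreq allele-B frequency on founder haplotypes.
#' @param effectThreshold relative occupancy difference above which a SNP is
#'   truth-labeled functional (default 0.2).
#' @param ibdUncertainty upper bound of injected IBD uncertainty (default 0).
#' @param siteSpacing bp between site windows on the simulated chromosome.
#' @param conservationNoise sd of the Gaussian noise on the
#'   conservation-like track.
#' @param ancestralMissing probability the outgroup allele is unavailable.
#' @param contactUpstream,contactDownstream contact-region extents around
#'   the core motif (defaults 20 and 10 bp; 44 bp total with a 14 bp core).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nSites = 200L, windowBp = 134L,
                      readLen = 36L, depth = 50, dispersion = 10,
                      batchFactors = c(a = 1, b = 0.9),
                      singleRepSample = "GM12",
                      occMidpoint = 14, occSlope = 0.8,
                      snpRate = 0.21, multiSnpRate = 0.19,
                      recombRate = 1e-6, pileupDepth = 50,
                      baseError = 0.01, founderFreq = 0.5,
                      effectThreshold = 0.2, ibdUncertainty = 0,
                      siteSpacing = 3000L, conservationNoise = 1,
                      ancestralMissing = 0.05,
                      contactUpstream = 20L, contactDownstream = 10L) {
  params <- list(seed = as.integer(seed), nSites = as.integer(nSites),
                 windowBp = as.integer(windowBp), readLen = as.integer(readLen),
                 depth = depth, dispersion = dispersion,
                 batchFactors = batchFactors,
                 singleRepSample = singleRepSample,
                 occMidpoint = occMidpoint, occSlope = occSlope,
                 snpRate = snpRate, multiSnpRate = multiSnpRate,
                 recombRate = recombRate, pileupDepth = pileupDepth,
                 baseError = baseError, founderFreq = founderFreq,
                 effectThreshold = effectThreshold,
                 ibdUncertainty = ibdUncertainty,
                 siteSpacing = as.integer(siteSpacing),
                 conservationNoise = conservationNoise,
                 ancestralMissing = ancestralMissing,
                 contactUpstream = as.integer(contactUpstream),
                 contactDownstream = as.integer(contactDownstream))
  new("SimConfig", params = params)
}

# deterministic substream seed per named stage
subSeed <- function(seed, stage) {
  stages <- c(pedigree = 1L, sites = 2L, alleles = 3L, counts = 4L,
              pileups = 5L, conservation = 6L, mappability = 7L)
  (as.integer(seed) %% 2000000L) * 1000L + stages[[stage]]
}

#' Saturating occupancy curve
#'
#' Occupancy probability as a logistic function of a PWM log-odds score:
#' `1 / (1 + exp(-(a - a0) / s))`. This is the generator's threshold-like
#' binding model: sites far above the midpoint are saturated, sites far
#' below are empty, and only scores near `a0` respond to perturbation.
#'
#' @param score PWM log-odds score(s), bits.
#' @param a0 midpoint, bits.
#' @param s slope, bits.
#' @return occupancy in (0, 1).
#' @export
occupancyProbability <- function(score, a0, s) {
  if (s <= 0) return(as.numeric(score >= a0))
  1 / (1 + exp(-(score - a0) / s))
}

sampleFromRows <- function(freqs, n) {
  # one base per row per draw; returns n x width matrix of codes
  w <- nrow(freqs)
  m <- matrix(0L, n, w)
  for (j in seq_len(w))
    m[, j] <- sample.int(4L, n, replace = TRUE, prob = freqs[j, ])
  m
}

#' Generate a binding-site catalog with planted SNPs
#'
#' Each site is a `windowBp` window on a simulated chromosome carrying a
#' motif core sampled from the PWM frequency model at the window center
#' (on a random strand), embedded in background flanks. SNPs are planted
#' uniformly across the window at `snpRate`; a planted SNP's motif-relative
#' strand-oriented position, its per-allele PWM scores and its truth
#' functional/silent label (relative occupancy difference above
#' `effectThreshold`) are recorded.
#'
#' @param cfg a [SimConfig-class].
#' @param pwm the [PWM-class] used both to sample cores and to score alleles.
#' @return list with `sites` (a `GRanges` with window sequence, strand,
#'   core coordinates and base score in `mcols`) and `snps` (a `DataFrame`
#'   of SNP truth records). Emits a warning (not an error) when
#'   `snpRate = 0` leaves the catalog SNP-free.
#' @export
generateSites <- function(cfg, pwm) {
  p <- cfg@params
  w <- pwmWidth(pwm)
  n <- p$nSites
  win <- p$windowBp
  coreOff <- (win - w) %/% 2L            # 0-based window offset of core start
  gStart <- (seq_len(n) - 1L) * p$siteSpacing + 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  coreCodes <- sampleFromRows(pwm@freqs, n)
  baseScore <- numeric(n)
  for (j in seq_len(w))
    baseScore <- baseScore + pwm@logodds[j, coreCodes[, j]]
  bg <- pwm@background
  seqs <- character(n)
  for (i in seq_len(n)) {
    codes <- sample.int(4L, win, replace = TRUE, prob = bg)
    core <- coreCodes[i, ]
    if (strand[i] == "-") core <- rev(5L - core)
    codes[(coreOff + 1L):(coreOff + w)] <- core
    seqs[i] <- paste(DNA_BASES[codes], collapse = "")
  }
  siteId <- sprintf("site%05d", seq_len(n))
  sites <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = gStart, width = win),
    strand = strand,
    siteId = siteId,
    coreStart = gStart + coreOff,        # genome coords, 1-based
    coreSeq = apply(coreCodes, 1, function(cc)
      paste(DNA_BASES[cc], collapse = "")),
    baseScore = baseScore,
    windowSeq = seqs)

  hasSnp <- runif(n) < p$snpRate
  if (!any(hasSnp))
    warning("snpRate left the catalog without SNPs; ",
            "downstream association stages will have nothing to test")
  rec <- list()
  for (i in which(hasSnp)) {
    k <- 1L + as.integer(runif(1) < p$multiSnpRate)
    wp <- sample.int(win, k) - 1L        # 0-based window positions
    for (pos in wp) {
      refCode <- match(substr(mcols(sites)$windowSeq[i], pos + 1L, pos + 1L),
                       DNA_BASES)
      altCode <- sample(setdiff(1:4, refCode), 1L)
      rec[[length(rec) + 1L]] <- data.frame(
        siteIdx = i, windowPos = pos,
        genomePos = gStart[i] + pos,
        alleleA = DNA_BASES[refCode], alleleB = DNA_BASES[altCode],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rec) == 0L) {
    snps <- S4Vectors::DataFrame(
      snpId = character(0), siteId = character(0), siteIdx = integer(0),
      windowPos = integer(0), genomePos = integer(0),
      alleleA = character(0), alleleB = character(0))
    return(list(sites = sites, snps = snps))
  }
  snps <- do.call(rbind, rec)
  snps <- snps[order(snps$siteIdx, snps$windowPos), , drop = FALSE]
  snps$snpId <- sprintf("snp%05d", seq_len(nrow(snps)))
  snps$siteId <- siteId[snps$siteIdx]

  # strand-oriented motif-relative annotation and per-allele scores
  coreStartW <- coreOff                  # window coords, 0-based
  st <- as.character(GenomicRanges::strand(sites))[snps$siteIdx]
  mrp <- mapply(function(posW, s) {
    r <- motifRelativePosition(posW, coreStartW, s, width = w,
                               contactUpstream = p$contactUpstream,
                               contactDownstream = p$contactDownstream)
    c(r$position, r$inCore, r$inContact)
  }, snps$windowPos, st)
  snps$motifPosition <- as.integer(mrp[1, ])
  snps$inCore <- as.logical(mrp[2, ])
  snps$inContact <- as.logical(mrp[3, ])
  snps$motifColumn <- ifelse(snps$inCore, snps$motifPosition, NA_integer_)

  base0 <- mcols(sites)$baseScore[snps$siteIdx]
  dscore <- numeric(nrow(snps))
  for (r in seq_len(nrow(snps))) {
    if (!snps$inCore[r]) next
    cc <- snps$motifColumn[r] + 1L
    a <- snps$alleleA[r]; b <- snps$alleleB[r]
    if (st[r] == "-") {
      a <- DNA_BASES[5L - match(a, DNA_BASES)]
      b <- DNA_BASES[5L - match(b, DNA_BASES)]
    }
    dscore[r] <- pwm@logodds[cc, b] - pwm@logodds[cc, a]
  }
  snps$scoreA <- base0
  snps$scoreB <- base0 + dscore
  snps$deltaTruth <- abs(dscore)
  pA <- occupancyProbability(snps$scoreA, p$occMidpoint, p$occSlope)
  pB <- occupancyProbability(snps$scoreB, p$occMidpoint, p$occSlope)
  snps$occA <- pA
  snps$occB <- pB
  rel <- abs(pA - pB) / pmax(pA, pB)
  snps$effectLabel <- ifelse(rel > p$effectThreshold, "functional", "silent")

  # outgroup (ancestral) allele: usually the A allele, sometimes the B
  # allele (derived-increasing cases), occasionally missing
  u <- runif(nrow(snps))
  snps$outgroup <- ifelse(u < p$ancestralMissing, NA_character_,
                    ifelse(u < p$ancestralMissing + 0.25,
                           snps$alleleB, snps$alleleA))
  snps <- S4Vectors::DataFrame(
    snps[, c("snpId", "siteId", "siteIdx", "windowPos", "genomePos",
             "alleleA", "alleleB", "motifPosition", "motifColumn",
             "inCore", "inContact", "scoreA", "scoreB", "deltaTruth",
             "occA", "occB", "effectLabel", "outgroup")])
  list(sites = sites, snps = snps)
}

# founder haplotype alleles: 8 x nSnps logical, TRUE = carries allele B
sampleFounderAlleles <- function(nSnps, founderFreq) {
  matrix(runif(8L * nSnps) < founderFreq, nrow = 8L)
}

# member x snp genotype (copies of allele B) from haplotype labels
genotypesFromHaplotypes <- function(hap, founderAlleles, snpSiteIdx) {
  ids <- dimnames(hap)[[1]]
  g <- matrix(NA_integer_, length(ids), length(snpSiteIdx),
              dimnames = list(ids, NULL))
  for (m in seq_along(ids)) {
    l1 <- hap[m, snpSiteIdx, 1]
    l2 <- hap[m, snpSiteIdx, 2]
    idx <- seq_along(snpSiteIdx)
    g[m, ] <- founderAlleles[cbind(l1, idx)] + founderAlleles[cbind(l2, idx)]
  }
  g
}

# per-member, per-site haplotype scores given planted SNP effects
haplotypeScores <- function(hap, founderAlleles, sites, snps) {
  ids <- dimnames(hap)[[1]]
  nSites <- dim(hap)[2]
  base <- mcols(sites)$baseScore
  dscore <- snps$scoreB - snps$scoreA
  hs <- array(rep(base, each = length(ids)),
              dim = c(length(ids), nSites, 2), dimnames = dimnames(hap))
  core <- which(snps$inCore & dscore != 0)
  for (r in core) {
    si <- snps$siteIdx[r]
    for (h in 1:2) {
      carries <- founderAlleles[hap[, si, h], r]
      hs[, si, h] <- hs[, si, h] + carries * dscore[r]
    }
  }
  hs
}

#' Simulate ChIP-seq counts under the saturating occupancy model
#'
#' Each member's expected count at a site is
#' `depth * batch * (p(h1) + p(h2)) / 2` where `p(h)` is the logistic
#' occupancy of that haplotype's PWM score; counts are drawn negative
#' binomial with size `dispersion`. At heterozygous SNPs the sample's
#' pooled reads are partitioned binomially between alleles in proportion
#' to the two haplotype occupancies.
#'
#' @param sites,snps catalog from [generateSites()].
#' @param hap haplotype label array from [simulatePedigree()].
#' @param founderAlleles 8 x nSnps logical matrix (TRUE = allele B).
#' @param cfg a [SimConfig-class].
#' @return list with `counts` (a `SummarizedExperiment`), `alleleCounts`
#'   (`DataFrame`: snpId, sample, readsA, readsB), and `hapScores`.
#' @export
simulateCounts <- function(sites, snps, hap, founderAlleles, cfg) {
  p <- cfg@params
  if (p$dispersion <= 0) stop("dispersion (theta) must be > 0")
  ids <- dimnames(hap)[[1]]
  nSites <- dim(hap)[2]
  hs <- haplotypeScores(hap, founderAlleles, sites, snps)
  occ <- occupancyProbability(hs, p$occMidpoint, p$occSlope)
  siteMean <- (occ[, , 1] + occ[, , 2]) / 2   # members x sites

  reps <- names(p$batchFactors)
  cols <- expand.grid(sample = ids, replicate = reps,
                      stringsAsFactors = FALSE)
  cols <- cols[order(cols$sample, cols$replicate), ]
  if (!is.na(p$singleRepSample))
    cols <- cols[!(cols$sample == p$singleRepSample &
                     cols$replicate != reps[1]), ]
  mu <- matrix(0, nSites, nrow(cols))
  for (j in seq_len(nrow(cols)))
    mu[, j] <- p$depth * p$batchFactors[[cols$replicate[j]]] *
      siteMean[cols$sample[j], ]
  counts <- matrix(rnbinom(length(mu), size = p$dispersion, mu = mu),
                   nSites, nrow(cols))
  dimnames(counts) <- list(mcols(sites)$siteId,
                           paste(cols$sample, cols$replicate, sep = "."))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      sample = cols$sample, replicate = cols$replicate,
      batch = unlist(p$batchFactors[cols$replicate]),
      row.names = colnames(counts)))

  ac <- list()
  if (nrow(snps) > 0) {
    pooled <- t(rowsum(t(counts), cols$sample))  # sites x samples
    for (r in seq_len(nrow(snps))) {
      si <- snps$siteIdx[r]
      carr1 <- founderAlleles[hap[, si, 1], r]
      carr2 <- founderAlleles[hap[, si, 2], r]
      hets <- which(xor(carr1, carr2))
      for (m in hets) {
        sB <- hs[m, si, if (carr1[m]) 1 else 2]
        sA <- hs[m, si, if (carr1[m]) 2 else 1]
        pB <- occupancyProbability(sB, p$occMidpoint, p$occSlope)
        pA <- occupancyProbability(sA, p$occMidpoint, p$occSlope)
        tot <- pooled[si, ids[m]]
        rb <- rbinom(1, tot, if (pA + pB > 0) pB / (pA + pB) else 0.5)
        ac[[length(ac) + 1L]] <- data.frame(
          snpId = snps$snpId[r], siteId = snps$siteId[r], sample = ids[m],
          readsA = tot - rb, readsB = rb, stringsAsFactors = FALSE)
      }
    }
  }
  alleleCounts <- if (length(ac)) S4Vectors::DataFrame(do.call(rbind, ac))
                  else S4Vectors::DataFrame(snpId = character(0),
                                            siteId = character(0),
                                            sample = character(0),
                                            readsA = integer(0),
                                            readsB = integer(0))
  list(counts = se, alleleCounts = alleleCounts, hapScores = hs)
}

# Phred-like genotype/site quality from base counts under a symmetric
# error model: 10 * log10 likelihood ratio of best vs second-best of the
# three biallelic genotypes.
pileupQuality <- function(nA, nB, err) {
  ll <- cbind(AA = nA * log(1 - err) + nB * log(err / 3),
              AB = (nA + nB) * log(0.5 * (1 - err) + 0.5 * err / 3),
              BB = nB * log(1 - err) + nA * log(err / 3))
  srt <- t(apply(ll, 1, sort, decreasing = TRUE))
  10 * (srt[, 1] - srt[, 2]) / log(10)
}

#' Simulate resequencing pileups
#'
#' Per-SNP, per-sample base counts: coverage is Poisson(`pileupDepth`), each
#' read samples one of the member's two haplotype alleles and reports it
#' correctly with probability `1 - baseError` (otherwise a uniformly chosen
#' other base). A Phred-like site quality increasing with depth and allele
#' purity is attached.
#'
#' @param snps SNP catalog from [generateSites()].
#' @param genotypes member x SNP matrix of allele-B copy numbers.
#' @param cfg a [SimConfig-class].
#' @return `DataFrame` with snpId, sample, base counts `nA`,`nC`,`nG`,`nT`,
#'   `depth` and `quality`.
#' @export
simulatePileups <- function(snps, genotypes, cfg) {
  p <- cfg@params
  if (p$pileupDepth <= 0) stop("pileupDepth must be > 0")
  ids <- rownames(genotypes)
  nSnp <- nrow(snps)
  out <- vector("list", nSnp * length(ids))
  k <- 0L
  for (r in seq_len(nSnp)) {
    aCode <- match(snps$alleleA[r], DNA_BASES)
    bCode <- match(snps$alleleB[r], DNA_BASES)
    for (m in seq_along(ids)) {
      depth <- rpois(1, p$pileupDepth)
      cnt <- integer(4)
      if (depth > 0) {
        g <- genotypes[m, r]
        trueCodes <- sample(c(aCode, bCode), depth, replace = TRUE,
                            prob = c(2 - g, g) / 2)
        errs <- runif(depth) < p$baseError
        if (any(errs)) {
          trueCodes[errs] <- vapply(trueCodes[errs], function(tc)
            sample(setdiff(1:4, tc), 1L), integer(1))
        }
        cnt <- tabulate(trueCodes, 4L)
      }
      k <- k + 1L
      out[[k]] <- c(r, m, cnt, depth)
    }
  }
  tab <- do.call(rbind, out)
  df <- S4Vectors::DataFrame(
    snpId = snps$snpId[tab[, 1]], sample = ids[tab[, 2]],
    nA = tab[, 3], nC = tab[, 4], nG = tab[, 5], nT = tab[, 6],
    depth = tab[, 7])
  # quality against the site's two declared alleles
  aIdx <- match(snps$alleleA[tab[, 1]], DNA_BASES)
  bIdx <- match(snps$alleleB[tab[, 1]], DNA_BASES)
  cnts <- as.matrix(tab[, 3:6])
  nAallele <- cnts[cbind(seq_len(nrow(cnts)), aIdx)]
  nBallele <- cnts[cbind(seq_len(nrow(cnts)), bIdx)]
  df$quality <- ifelse(df$depth == 0, 0,
                       pileupQuality(nAallele, nBallele,
                                     max(p$baseError, 1e-4)))
  df
}

#' Conservation-like per-base track
#'
#' A stand-in for a phyloP-style score: core motif positions receive the
#' PWM column information content plus Gaussian noise, flank positions
#' noise only. Orientation follows each site's motif strand.
#'
#' @param sites site catalog from [generateSites()].
#' @param pwm the planted [PWM-class].
#' @param noiseSd Gaussian noise sd.
#' @param windowBp window width (must match the catalog).
#' @return matrix nSites x windowBp of scores.
#' @export
emitConservation <- function(sites, pwm, noiseSd = 1, windowBp = 134L) {
  ic <- pwmInformation(pwm)
  w <- length(ic)
  n <- length(sites)
  coreOff <- (windowBp - w) %/% 2L
  m <- matrix(rnorm(n * windowBp, 0, noiseSd), n, windowBp)
  st <- as.character(GenomicRanges::strand(sites))
  for (i in seq_len(n)) {
    cols <- if (st[i] == "+") ic else rev(ic)
    m[i, (coreOff + 1L):(coreOff + w)] <-
      m[i, (coreOff + 1L):(coreOff + w)] + cols
  }
  m
}

#' Simulate a complete synthetic occupancy study
#'
#' Runs every generator stage under named substreams of the master seed:
#' pedigree transmission with truth IBD, site/SNP catalog, founder allele
#' assignment, NB ChIP-seq counts with allele-partitioned reads,
#' resequencing pileups, and the conservation track.
#'
#' @param cfg a [SimConfig-class].
#' @param pwm the planted [PWM-class] (default [exampleMotifModels()]
#'   canonical model).
#' @param ped a [Pedigree-class] (default [threeGenPedigree()]).
#' @return an [OccupancyStudy-class].
#' @examples
#' study <- simulateStudy(simConfig(seed = 7, nSites = 30))
#' study
#' @export
simulateStudy <- function(cfg, pwm = NULL, ped = threeGenPedigree()) {
  p <- cfg@params
  if (is.null(pwm)) pwm <- exampleMotifModels()[["canonical"]]
  set.seed(subSeed(p$seed, "sites"))
  cat_ <- generateSites(cfg, pwm)
  sites <- cat_$sites; snps <- cat_$snps

  set.seed(subSeed(p$seed, "pedigree"))
  centers <- GenomicRanges::start(sites) + (p$windowBp %/% 2L)
  sim <- simulatePedigree(ped, centers, p$recombRate, p$ibdUncertainty)

  set.seed(subSeed(p$seed, "alleles"))
  founderAlleles <- sampleFounderAlleles(nrow(snps), p$founderFreq)
  genotypes <- genotypesFromHaplotypes(sim$haplotypes, founderAlleles,
                                       snps$siteIdx)
  colnames(genotypes) <- snps$snpId

  set.seed(subSeed(p$seed, "counts"))
  cts <- simulateCounts(sites, snps, sim$haplotypes, founderAlleles, cfg)

  set.seed(subSeed(p$seed, "pileups"))
  pileups <- simulatePileups(snps, genotypes, cfg)

  set.seed(subSeed(p$seed, "conservation"))
  conservation <- emitConservation(sites, pwm, p$conservationNoise,
                                   p$windowBp)
  if (nrow(snps) > 0)
    snps$conservation <- conservation[cbind(snps$siteIdx,
                                            snps$windowPos + 1L)]

  new("OccupancyStudy", pedigree = ped, sites = sites, snps = snps,
      counts = cts$counts, alleleCounts = cts$alleleCounts,
      pileups = pileups,
      truth = list(genotypes = genotypes, ibd = sim$ibd,
                   ibdUncertainty = sim$ibdUncertainty,
                   haplotypes = sim$haplotypes, pairs = sim$pairs,
                   founderAlleles = founderAlleles,
                   conservation = conservation,
                   hapScores = cts$hapScores),
      config = cfg, pwm = pwm)
}

#' Direct genotype-to-count benchmark generator
#'
#' A stripped-down generator for calibration and power studies of the
#' association test: per site, genotypes for `nSamples` members are drawn
#' binomially at minor allele frequency `maf` (redrawn until at least two
#' genotype classes have four or more data points, so every site is
#' testable), and counts for `replicates` replicates per sample follow
#' `mu = depth * batch * effect^(g/2)` with NB dispersion `theta`.
#' `effect = 1` gives pure null sites.
#'
#' @param nSitesEff,nSitesNull numbers of effect and null sites.
#' @param effect homozygote fold change (e.g. 2 for a 2-fold effect).
#' @param nSamples samples (default 12).
#' @param replicates replicates per sample (default 2).
#' @param depth mean count (default 50).
#' @param theta NB size (default 10).
#' @param batchFactors per-replicate scalars.
#' @param maf minor allele frequency (default 0.5).
#' @return list of per-site records: `counts`, `genotype` (per data point),
#'   `replicate`, `isEffect`.
#' @export
simulateGenotypeEffect <- function(nSitesEff, nSitesNull, effect = 2,
                                   nSamples = 12, replicates = 2,
                                   depth = 50, theta = 10,
                                   batchFactors = c(a = 1, b = 0.9),
                                   maf = 0.5) {
  nTot <- nSitesEff + nSitesNull
  isEffect <- rep(c(TRUE, FALSE), c(nSitesEff, nSitesNull))
  reps <- rep(names(batchFactors)[seq_len(replicates)], each = nSamples)
  lapply(seq_len(nTot), function(i) {
    repeat {
      g <- rbinom(nSamples, 2, maf)
      tabg <- tabulate(g + 1L, 3L)
      if (sum(tabg >= 2) >= 2 && sum(tabg) >= 6) break
    }
    gAll <- rep(g, replicates)
    fold <- if (isEffect[i]) effect else 1
    mu <- depth * unlist(batchFactors[reps]) * fold^(gAll / 2)
    list(counts = rnbinom(length(mu), size = theta, mu = mu),
         genotype = gAll, replicate = reps, isEffect = isEffect[i])
  })
}
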