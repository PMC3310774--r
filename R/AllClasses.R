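#' @import methods
#' @importFrom S4Vectors DataFrame metadata mcols
#' @importFrom stats rnbinom rbinom rpois runif rnorm sd median quantile
#'   pchisq pnorm lm coef anova p.adjust smooth.spline predict var
#'   setNames aggregate hclust cutree dist complete.cases
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix with log-odds scores
#'
#' A frequency model of a fixed-width motif together with its log-odds
#' (bits) representation against an i.i.d. background. Construct with
#' [buildPWM()]; slots are not meant to be set directly.
#'
#' @slot freqs numeric matrix, positions x bases (A,C,G,T); rows sum to 1
#'   after pseudo-frequency flooring and renormalization.
#' @slot logodds numeric matrix of the same shape, `log2(freq/background)`.
#' @slot background numeric length-4 base composition, sums to 1.
#' @slot pseudo pseudo-frequency floor applied during construction.
#' @slot modelId character label distinguishing motif model variants.
#' @exportClass PWM
setClass("PWM", representation(
  freqs = "matrix",
  logodds = "matrix",
  background = "numeric",
  pseudo = "numeric",
  modelId = "character"
))

setValidity("PWM", function(object) {
  f <- object@freqs
  if (!is.numeric(f) || ncol(f) != 4L || nrow(f) < 1L)
    return("freqs must be a numeric positions x 4 matrix with >= 1 row")
  if (!identical(colnames(f), DNA_BASES))
    return("freqs columns must be named A, C, G, T")
  if (any(f < 0)) return("negative frequencies")
  if (any(abs(rowSums(f) - 1) > 1e-9))
    return("freqs rows must sum to 1 within 1e-9")
  if (any(!is.finite(object@logodds)))
    return("logodds must be finite everywhere")
  if (abs(sum(object@background) - 1) > 1e-9 || length(object@background) != 4L)
    return("background must be 4 probabilities summing to 1")
  TRUE
})

setMethod("show", "PWM", function(object) {
  cat(sprintf("PWM model '%s': width %d, max score %.2f bits\n",
              object@modelId, nrow(object@freqs),
              sum(apply(object@logodds, 1, max))))
  cat("consensus:", paste(DNA_BASES[apply(object@freqs, 1, which.max)],
                          collapse = ""), "\n")
})

#' Three-generation pedigree
#'
#' Members of a three-generation pedigree: four founders, two
#' second-generation members (each the child of a distinct founder couple),
#' and their children. Construct with [threeGenPedigree()] or [Pedigree()].
#'
#' @slot members data.frame with columns `id`, `sex` ("M"/"F"), `father`,
#'   `mother` (member ids or `NA` for founders), `generation` (1-3).
#' @exportClass Pedigree
setClass("Pedigree", representation(members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  need <- c("id", "sex", "father", "mother", "generation")
  if (!all(need %in% names(m))) return("members lacks required columns")
  if (anyDuplicated(m$id)) return("duplicate member ids")
  for (i in seq_len(nrow(m))) {
    fa <- m$father[i]; mo <- m$mother[i]
    if (is.na(fa) != is.na(mo))
      return(sprintf("member %s has exactly one parent", m$id[i]))
    if (!is.na(fa) && !(fa %in% m$id))
      return(sprintf("member %s: unknown father %s", m$id[i], fa))
    if (!is.na(mo) && !(mo %in% m$id))
      return(sprintf("member %s: unknown mother %s", m$id[i], mo))
  }
  founders <- m$id[is.na(m$father)]
  if (length(founders) != 4L)
    return(sprintf("expected exactly 4 founders, found %d", length(founders)))
  gen2 <- m$id[!is.na(m$father) & m$father %in% founders]
  if (length(gen2) != 2L)
    return(sprintf("expected exactly 2 second-generation members, found: %s",
                   paste(gen2, collapse = ", ")))
  g2 <- m[m$id %in% gen2, ]
  if (!all(g2$father %in% founders & g2$mother %in% founders))
    return(sprintf("member %s must have two founder parents", g2$id[1]))
  kids <- m[!(m$id %in% c(founders, gen2)), ]
  if (nrow(kids) > 0 &&
      !(all(kids$father %in% gen2) && all(kids$mother %in% gen2)))
    return(sprintf("member %s is not a child of the second-generation couple",
                   kids$id[which(!(kids$father %in% gen2 &
                                     kids$mother %in% gen2))][1]))
  # acyclic by construction given the generational checks above
  TRUE
})

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree: %d members (%d founders, %d sibs in generation 3)\n",
              nrow(m), sum(is.na(m$father)), sum(m$generation == 3L)))
})

#' Simulation configuration
#'
#' All knobs of the synthetic study generator. Construct with [simConfig()],
#' which supplies study defaults and validates ranges.
#'
#' @slot params named list of generator parameters; see [simConfig()].
#' @exportClass SimConfig
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  probs <- c("snpRate", "multiSnpRate", "baseError", "founderFreq",
             "effectThreshold", "ibdUncertainty", "ancestralMissing")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      return(sprintf("%s must lie in [0, 1]", nm))
  if (p$depth <= 0 || p$dispersion <= 0 || p$pileupDepth <= 0)
    return("depth, dispersion and pileupDepth must be > 0")
  if (p$recombRate < 0) return("recombRate must be >= 0")
  if (p$windowBp < 14L) return("windowBp must cover the motif width")
  if (p$nSites < 1L) return("nSites must be >= 1")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat(sprintf(paste0("SimConfig: %d sites, window %d bp, depth %g, ",
                     "theta %g, occ midpoint %g / slope %g, seed %d\n"),
              p$nSites, p$windowBp, p$depth, p$dispersion,
              p$occMidpoint, p$occSlope, p$seed))
})

#' A complete synthetic occupancy study
#'
#' Holds everything one run of the generator produces: the pedigree with
#' truth haplotypes and identity-by-descent, the binding-site catalog, the
#' planted SNPs, ChIP-seq counts (a [SummarizedExperiment::SummarizedExperiment]),
#' allele-partitioned counts at heterozygous sites, resequencing pileups,
#' the conservation-like track, and the generating configuration.
#' Construct with [simulateStudy()].
#'
#' @slot pedigree a [Pedigree-class].
#' @slot sites `GRanges` of site windows with motif annotation in `mcols`.
#' @slot snps `DataFrame` of planted SNPs with truth annotation.
#' @slot counts `SummarizedExperiment`, sites x (sample, replicate) counts.
#' @slot alleleCounts `DataFrame` of allele-partitioned reads at het sites.
#' @slot pileups `DataFrame` of per-SNP per-sample resequencing base counts.
#' @slot truth list: `genotypes` (member x SNP), `ibd` (site x sib pair),
#'   `ibdUncertainty`, `haplotypes`, `pairs`, `conservation`.
#' @slot config the generating [SimConfig-class].
#' @slot pwm the [PWM-class] used to plant and score motifs.
#' @exportClass OccupancyStudy
setClass("OccupancyStudy", representation(
  pedigree = "Pedigree",
  sites = "ANY",
  snps = "ANY",
  counts = "ANY",
  alleleCounts = "ANY",
  pileups = "ANY",
  truth = "list",
  config = "SimConfig",
  pwm = "PWM"
))

setMethod("show", "OccupancyStudy", function(object) {
  cat(sprintf(paste0("OccupancyStudy: %d sites, %d SNPs, %d members, ",
                     "%d count columns\n"),
              length(object@sites), nrow(object@snps),
              nrow(object@pedigree@members), ncol(object@counts)))
  cat(sprintf("  functional SNPs (truth): %d of %d\n",
              sum(object@snps$effectLabel == "functional"),
              nrow(object@snps)))
})

#' @describeIn OccupancyStudy-class pedigree accessor
#' @param x an `OccupancyStudy`
#' @export
studyPedigree <- function(x) x@pedigree

#' @describeIn OccupancyStudy-class site catalog accessor
#' @export
studySites <- function(x) x@sites

#' @describeIn OccupancyStudy-class SNP table accessor
#' @export
studySnps <- function(x) x@snps

#' @describeIn OccupancyStudy-class count container accessor
#' @export
studyCounts <- function(x) x@counts

#' @describeIn OccupancyStudy-class allele-partitioned count accessor
#' @export
studyAlleleCounts <- function(x) x@alleleCounts

#' @describeIn OccupancyStudy-class pileup accessor
#' @export
studyPileups <- function(x) x@pileups

#' @describeIn OccupancyStudy-class truth-table accessor
#' @export
studyTruth <- function(x) x@truth

#' @describeIn OccupancyStudy-class configuration accessor
#' @export
studyConfig <- function(x) x@config
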