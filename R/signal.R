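#' Sliding-window tag density track
#'
#' Counts, for each bin of a sliding window (default 150 bp advanced in
#' 20 bp steps), the tags whose full read extent overlaps the window.
#' Coordinates are 0-based half-open.
#'
#' @param tags data.frame with `start`, `end` (0-based half-open read
#'   intervals).
#' @param window window width in bp (default 150).
#' @param step step width in bp (default 20).
#' @param extent optional c(start, end) genomic extent to bin; defaults to
#'   the smallest step-aligned extent covering all tags.
#' @return data.frame `start`, `count` with attributes `window`, `step`,
#'   `scale` (1 until normalized) and `normalized`.
#' @export
slidingDensity <- function(tags, window = 150, step = 20, extent = NULL) {
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  if (is.null(extent)) {
    if (nrow(tags) == 0) extent <- c(0, window)
    else extent <- c(step * floor((min(tags$start) - window + 1) / step),
                     max(tags$end))
  }
  starts <- seq(extent[1], max(extent[1], extent[2] - 1), by = step)
  if (nrow(tags) == 0) {
    cnt <- integer(length(starts))
  } else {
    bins <- IRanges::IRanges(start = starts + 1L, width = window)
    reads <- IRanges::IRanges(start = tags$start + 1L, end = tags$end)
    cnt <- IRanges::countOverlaps(bins, reads)
  }
  out <- data.frame(start = starts, count = as.numeric(cnt))
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "scale") <- 1
  attr(out, "normalized") <- FALSE
  out
}

#' Global linear normalization of density tracks
#'
#' One scale factor per sample: `target / median(counts of bins with count
#' > minReads)` over all of that sample's tracks, applied to every bin, so
#' that the qualifying-bin median becomes `target` (default 25).
#'
#' @param tracks a single track or list of tracks from [slidingDensity()]
#'   belonging to one sample.
#' @param target normalized value of the qualifying-bin median (default 25).
#' @param minReads qualification threshold (default 15, exclusive).
#' @return list with `tracks` (normalized) and `scale`.
#' @export
normalizeGlobal <- function(tracks, target = 25, minReads = 15) {
  single <- is.data.frame(tracks)
  if (single) tracks <- list(tracks)
  qual <- unlist(lapply(tracks, function(t) t$count[t$count > minReads]))
  if (length(qual) == 0)
    stop("normalization failure: no bins exceed minReads")
  scale <- target / median(qual)
  tracks <- lapply(tracks, function(t) {
    t$count <- t$count * scale
    attr(t, "scale") <- scale
    attr(t, "normalized") <- TRUE
    t
  })
  list(tracks = if (single) tracks[[1]] else tracks, scale = scale)
}

#' Site occupancy from a density track
#'
#' The maximum normalized bin value among bins overlapping the motif
#' interval -- the per-site quantitative occupancy phenotype.
#'
#' @param track a track from [slidingDensity()] (normalized or raw).
#' @param interval c(start, end), 0-based half-open motif interval.
#' @return maximum overlapping bin value.
#' @export
siteOccupancy <- function(track, interval) {
  window <- attr(track, "window")
  ov <- track$start < interval[2] & (track$start + window) > interval[1]
  if (!any(ov)) stop("interval lies outside the track extent")
  max(track$count[ov])
}

substituteAlleles <- function(genome, pos, alleles) {
  if (length(pos) == 0) return(genome)
  Biostrings::replaceLetterAt(genome, pos, paste(alleles, collapse = ""))
}

countReadHits <- function(reads, genome, maxMismatch = 0) {
  if (maxMismatch == 0) {
    pd <- Biostrings::PDict(reads)
    Biostrings::countPDict(pd, genome)
  } else {
    vapply(seq_along(reads), function(i)
      Biostrings::countPattern(reads[[i]], genome,
                               max.mismatch = maxMismatch), integer(1))
  }
}

#' Read-simulation mappability filter
#'
#' Emulates the personalized-genome mappability screen: every read-length
#' k-mer starting within `flank` bp of the site center is simulated once
#' per allele haplotype (all A alleles, then all B alleles substituted into
#' the genome), and a read is ambiguous when its sequence occurs at more
#' than one genomic locus of that haplotype genome. A site passes when the
#' larger per-allele ambiguous fraction is at most `maxAmbiguous` and the
#' two fractions do not differ by more than `alleleMargin` (differing
#' mappability between alleles would bias allele-specific read counts).
#'
#' @param genome reference chromosome as a `DNAString` or character.
#' @param center 1-based position of the site center.
#' @param snps data.frame with `pos` (1-based), `alleleA`, `alleleB` for
#'   the site's SNPs (may be empty).
#' @param readLen read length (default 36).
#' @param flank half-width of the simulated-read window (default 147).
#' @param maxAmbiguous maximum tolerated ambiguous fraction (default 0.1).
#' @param alleleMargin maximum tolerated |fracA - fracB| (default 0.05).
#' @param maxMismatch mismatches tolerated when matching reads back to the
#'   genome (default 0, exact matching; larger values are substantially
#'   slower and intended for small inputs).
#' @return one-row data.frame: `fracA`, `fracB`, `alleleDifferential`,
#'   `pass`. A window truncated at a contig end raises a warning.
#' @export
mappabilityFilter <- function(genome, center, snps = NULL, readLen = 36,
                              flank = 147, maxAmbiguous = 0.1,
                              alleleMargin = 0.05, maxMismatch = 0) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  L <- length(genome)
  from <- center - flank
  to <- center + flank
  if (from < 1 || to + readLen - 1 > L) {
    warning("read window truncated at contig bounds")
    from <- max(1, from)
    to <- min(to, L - readLen + 1)
  }
  starts <- from:to
  frac <- c(A = NA_real_, B = NA_real_)
  for (al in c("A", "B")) {
    g <- genome
    if (!is.null(snps) && nrow(snps) > 0)
      g <- substituteAlleles(g, snps$pos,
                             snps[[paste0("allele", al)]])
    reads <- Biostrings::DNAStringSet(
      vapply(starts, function(s)
        as.character(Biostrings::subseq(g, s, s + readLen - 1)),
        character(1)))
    hits <- countReadHits(reads, g, maxMismatch)
    frac[al] <- mean(hits > 1)
  }
  diffFlag <- abs(frac["A"] - frac["B"]) > alleleMargin
  data.frame(fracA = unname(frac["A"]), fracB = unname(frac["B"]),
             alleleDifferential = unname(diffFlag),
             pass = unname(max(frac) <= maxAmbiguous & !diffFlag))
}

#' Assemble the simulated chromosome
#'
#' Concatenates random background sequence with each site's window sequence
#' placed at its genomic coordinates, yielding the contig that the
#' mappability filter scans.
#'
#' @param sites `GRanges` site catalog from [generateSites()].
#' @param seed seed for the background fill.
#' @return a `DNAString`.
#' @export
studyGenome <- function(sites, seed = 0L) {
  set.seed(seed)
  L <- max(GenomicRanges::end(sites)) + 300L
  g <- sample(DNA_BASES, L, replace = TRUE)
  for (i in seq_along(sites)) {
    s <- GenomicRanges::start(sites)[i]
    seqi <- strsplit(mcols(sites)$windowSeq[i], "")[[1]]
    g[s:(s + length(seqi) - 1L)] <- seqi
  }
  Biostrings::DNAString(paste(g, collapse = ""))
}

#' Mappability screen over a site catalog
#'
#' Runs [mappabilityFilter()] at every site of a catalog against the
#' assembled study chromosome.
#'
#' @param sites site catalog (`GRanges`).
#' @param snps SNP table (needs `siteIdx`, `genomePos`, `alleleA`,
#'   `alleleB`).
#' @param genome `DNAString` from [studyGenome()].
#' @param readLen,flank,maxAmbiguous,alleleMargin as in
#'   [mappabilityFilter()] (exact matching only; the screen is the
#'   vectorized equivalent of the per-site filter).
#' @return data.frame keyed by `siteId` with the per-site report.
#' @export
mappabilityScreen <- function(sites, snps, genome, readLen = 36,
                              flank = 147, maxAmbiguous = 0.1,
                              alleleMargin = 0.05) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  L <- length(genome)
  centers <- GenomicRanges::start(sites) +
    (GenomicRanges::width(sites) %/% 2L)
  startsOf <- function(center) {
    from <- center - flank; to <- center + flank
    if (from < 1 || to + readLen - 1 > L) {
      warning("read window truncated at contig bounds")
      from <- max(1, from); to <- min(to, L - readLen + 1)
    }
    from:to
  }
  persGenome <- function(i, al) {
    sn <- snps[snps$siteIdx == i, , drop = FALSE]
    if (nrow(sn) == 0) return(genome)
    substituteAlleles(genome, sn$genomePos, sn[[paste0("allele", al)]])
  }
  # one read dictionary over all sites and alleles, then one scan per
  # personalized genome (PDict construction dominates per-site scanning)
  reads <- list(); slice <- list(); at <- 0L
  for (i in seq_along(sites)) {
    st <- startsOf(centers[i])
    for (al in c("A", "B")) {
      g <- persGenome(i, al)
      reads[[paste(i, al)]] <- Biostrings::extractAt(
        g, IRanges::IRanges(st, width = readLen))
      slice[[paste(i, al)]] <- at + seq_along(st)
      at <- at + length(st)
    }
  }
  pd <- Biostrings::PDict(do.call(c, unname(reads)))
  frac <- matrix(NA_real_, length(sites), 2, dimnames = list(NULL, c("A", "B")))
  for (i in seq_along(sites)) {
    for (al in c("A", "B")) {
      cnt <- Biostrings::countPDict(pd, persGenome(i, al))
      frac[i, al] <- mean(cnt[slice[[paste(i, al)]]] > 1)
    }
  }
  diffFlag <- abs(frac[, "A"] - frac[, "B"]) > alleleMargin
  data.frame(siteId = mcols(sites)$siteId,
             fracA = frac[, "A"], fracB = frac[, "B"],
             alleleDifferential = diffFlag,
             pass = pmax(frac[, "A"], frac[, "B"]) <= maxAmbiguous &
               !diffFlag)
}
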