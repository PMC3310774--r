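#' Build a position weight matrix
#'
#' Converts a position x base frequency matrix to a [PWM-class] by flooring
#' frequencies at a pseudo-frequency, renormalizing each position, and
#' taking log2 odds against the background composition. The pseudo-frequency
#' default of 0.01 keeps log-odds finite at zero-count cells.
#'
#' @param freqs numeric matrix, positions in rows, bases A,C,G,T in columns
#'   (column names optional but, if present, must be A,C,G,T in order).
#'   Each row must sum to 1 within 1e-6.
#' @param background length-4 base probabilities (default uniform).
#' @param pseudo pseudo-frequency floor (default 0.01).
#' @param modelId label for the motif model variant.
#' @return a validated [PWM-class] object.
#' @examples
#' pwm <- buildPWM(matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4))
#' pwm@logodds
#' @export
buildPWM <- function(freqs, background = rep(0.25, 4), pseudo = 0.01,
                     modelId = "canonical") {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4L)
    stop("freqs must have 4 columns (A, C, G, T)")
  if (any(freqs < 0)) stop("negative frequencies are not allowed")
  if (any(abs(rowSums(freqs) - 1) > 1e-6))
    stop("each position's frequencies must sum to 1 within 1e-6")
  colnames(freqs) <- DNA_BASES
  rownames(freqs) <- NULL
  f <- pmax(freqs, pseudo)
  f <- f / rowSums(f)
  lo <- log2(sweep(f, 2, background, "/"))
  new("PWM", freqs = f, logodds = lo, background = background,
      pseudo = pseudo, modelId = modelId)
}

#' @describeIn buildPWM motif width in bp
#' @param pwm a [PWM-class]
#' @export
pwmWidth <- function(pwm) nrow(pwm@freqs)

#' @describeIn buildPWM per-position information content in bits
#' @export
pwmInformation <- function(pwm) {
  f <- pwm@freqs
  rowSums(f * log2(sweep(f, 2, pwm@background, "/")))
}

seqToCodes <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (anyNA(codes)) stop("sequence contains non-ACGT characters")
  codes
}

complementCodes <- function(codes) 5L - codes

#' Score a sequence with a PWM
#'
#' Sum of per-position log2-odds for a sequence of exactly the motif width.
#'
#' @param pwm a [PWM-class].
#' @param seq character sequence of length `pwmWidth(pwm)`.
#' @return score in bits.
#' @export
scoreSeq <- function(pwm, seq) {
  codes <- seqToCodes(seq)
  if (length(codes) != pwmWidth(pwm))
    stop("sequence length must equal the motif width")
  sum(pwm@logodds[cbind(seq_along(codes), codes)])
}

# Discretized exact score distribution under the i.i.d. background.
# Returns integer bin values (origin) and tail probabilities so that
# tailAt(t) = Pr(discretized score >= t bins).
pwmScoreTail <- function(pwm, bin = 1e-3) {
  k <- round(pwm@logodds / bin)
  bg <- pwm@background
  p <- 1
  lo0 <- 0L
  for (i in seq_len(nrow(k))) {
    ki <- as.integer(k[i, ])
    newlo <- lo0 + min(ki)
    newlen <- length(p) + (max(ki) - min(ki))
    q <- numeric(newlen)
    for (b in 1:4) {
      off <- ki[b] - min(ki)
      idx <- seq_along(p) + off
      q[idx] <- q[idx] + p * bg[b]
    }
    p <- q
    lo0 <- newlo
  }
  tail <- rev(cumsum(rev(p)))
  list(lo0 = lo0, tail = tail, bin = bin)
}

tailLookup <- function(dist, score) {
  t <- round(score / dist$bin)
  i <- t - dist$lo0 + 1
  n <- length(dist$tail)
  ifelse(i <= 1, 1, ifelse(i > n, 0, dist$tail[pmax(i, 1)]))
}

#' Exact PWM score p-value
#'
#' Probability that a random background sequence of the motif width scores
#' at least `score`, computed by dynamic programming over the discretized
#' per-position score distribution (the full distribution is exact up to
#' the discretization of individual log-odds entries).
#'
#' @param pwm a [PWM-class].
#' @param score threshold score in bits.
#' @param bin discretization bin width in bits (default 1e-3).
#' @return p-value in \[0, 1\]. Thresholds below the minimum achievable
#'   score give 1; above the maximum, 0.
#' @export
scorePvalue <- function(pwm, score, bin = 1e-3) {
  as.numeric(tailLookup(pwmScoreTail(pwm, bin), score))
}

# Score every placement of a logodds matrix along integer-coded sequence.
# starts are 1-based indices into codes.
scorePlacements <- function(lo, codes, starts) {
  w <- nrow(lo)
  sc <- numeric(length(starts))
  for (j in seq_len(w))
    sc <- sc + lo[j, codes[starts + j - 1L]]
  sc
}

#' Scan a site for the best motif match
#'
#' Evaluates one or several PWM models at every offset within `radius` bp of
#' the window center, on both strands, and returns the single best match by
#' score p-value. Ties are broken by higher raw score, then smaller absolute
#' offset, then the + strand. Matches with p-value at or above `maxP`
#' (default 1e-2) are discarded.
#'
#' @param seq character site sequence.
#' @param pwms a [PWM-class] or list of PWMs (the multivalent model set).
#' @param center 1-based index of the window center within `seq`
#'   (default the middle base).
#' @param radius maximum offset of the motif midpoint from the center
#'   (default 15 bp).
#' @param maxP p-value retention threshold (default 1e-2).
#' @param bin score discretization for p-values.
#' @return one-row data.frame with `start` (1-based motif start in `seq`,
#'   genome orientation), `offset`, `strand`, `score`, `pvalue`, `model`,
#'   `width`; or a zero-row frame if no match passes `maxP`.
#' @export
scanSite <- function(seq, pwms, center = NULL, radius = 15, maxP = 1e-2,
                     bin = 1e-3) {
  if (is(pwms, "PWM")) pwms <- list(pwms)
  codes <- seqToCodes(seq)
  n <- length(codes)
  if (is.null(center)) center <- (n + 1L) %/% 2L
  hits <- list()
  for (pwm in pwms) {
    w <- pwmWidth(pwm)
    anchor <- center - ((w + 1L) %/% 2L) + 1L  # start placing midpoint at center
    offs <- (-radius):radius
    starts <- anchor + offs
    keep <- starts >= 1L & (starts + w - 1L) <= n
    if (!any(keep)) stop("sequence too short to cover center +/- radius + width")
    starts <- starts[keep]; offs <- offs[keep]
    dist <- pwmScoreTail(pwm, bin)
    lo <- pwm@logodds
    # reverse strand: reverse positions and complement bases
    loRC <- lo[rev(seq_len(w)), 4:1, drop = FALSE]
    colnames(loRC) <- DNA_BASES
    for (strand in c("+", "-")) {
      sc <- scorePlacements(if (strand == "+") lo else loRC, codes, starts)
      hits[[length(hits) + 1L]] <- data.frame(
        start = starts, offset = offs, strand = strand, score = sc,
        pvalue = as.numeric(tailLookup(dist, sc)), model = pwm@modelId,
        width = w, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  hits$pvalue <- pmax(hits$pvalue, .Machine$double.xmin)  # report < bin resolution
  ord <- order(hits$pvalue, -hits$score, abs(hits$offset),
               hits$strand != "+")
  best <- hits[ord[1L], , drop = FALSE]
  rownames(best) <- NULL
  if (best$pvalue >= maxP) return(best[0L, , drop = FALSE])
  best
}

#' Motif-relative, strand-oriented SNP position
#'
#' Indexes a SNP position against a motif match: core positions run 0 to
#' width-1 from the motif's 5' end on the motif strand; upstream flank
#' positions are negative. The protein-DNA contact region spans
#' `contactUpstream` bp 5' of the core through `contactDownstream` bp 3' of
#' it (defaults 20 and 10, giving a 44 bp region around a 14 bp core).
#'
#' @param snpPos position of the SNP (same coordinate system as `matchStart`).
#' @param matchStart leftmost (genome orientation) position of the match.
#' @param strand match strand, "+" or "-".
#' @param width motif width (default 14).
#' @param contactUpstream,contactDownstream contact-region extents.
#' @param oneBased compatibility flag: report core positions 1-14
#'   instead of 0-13.
#' @return list with `position`, `inCore`, `inContact`.
#' @export
motifRelativePosition <- function(snpPos, matchStart, strand, width = 14,
                                  contactUpstream = 20,
                                  contactDownstream = 10,
                                  oneBased = FALSE) {
  pos <- if (strand == "+") snpPos - matchStart
         else (matchStart + width - 1) - snpPos
  list(position = if (oneBased) pos + 1L else pos,
       inCore = pos >= 0 & pos <= width - 1,
       inContact = pos >= -contactUpstream &
                   pos <= width - 1 + contactDownstream)
}

#' Allele log-odds delta at a motif column
#'
#' The absolute difference in PWM log-odds between a SNP's two alleles at
#' the motif column it falls in, with the energetically favored allele.
#' SNPs outside the motif get delta 0 and no favored allele; exact ties get
#' no favored allele. Alleles are given on the genome strand and are
#' complemented internally for minus-strand matches; the favored allele is
#' reported back on the genome strand.
#'
#' @param pwm a [PWM-class].
#' @param motifColumn 0-based motif column of the SNP (e.g. from
#'   [motifRelativePosition()]), or `NA`/out-of-range for flank SNPs.
#' @param alleleA,alleleB the two alleles, genome strand.
#' @param strand match strand ("+" or "-").
#' @return list with `delta` (bits) and `favored` (allele or `NA`).
#' @export
alleleDelta <- function(pwm, motifColumn, alleleA, alleleB, strand = "+") {
  if (!(alleleA %in% DNA_BASES) || !(alleleB %in% DNA_BASES))
    stop("alleles must be one of A, C, G, T")
  w <- pwmWidth(pwm)
  if (is.na(motifColumn) || motifColumn < 0 || motifColumn > w - 1)
    return(list(delta = 0, favored = NA_character_))
  a <- alleleA; b <- alleleB
  if (strand == "-") {
    a <- DNA_BASES[5L - match(a, DNA_BASES)]
    b <- DNA_BASES[5L - match(b, DNA_BASES)]
  }
  loA <- pwm@logodds[motifColumn + 1L, a]
  loB <- pwm@logodds[motifColumn + 1L, b]
  delta <- abs(loA - loB)
  favored <- if (loA == loB) NA_character_
             else if (loA > loB) alleleA else alleleB
  list(delta = unname(delta), favored = favored)
}

#' Scan a site catalog for motif matches
#'
#' Applies [scanSite()] to every site window, returning at most one best
#' match per site.
#'
#' @param sites `GRanges` site catalog with window sequences in
#'   `mcols(sites)$windowSeq`.
#' @param pwms a [PWM-class] or list of PWMs.
#' @param ... passed to [scanSite()].
#' @return data.frame with one row per matched site: siteId, start
#'   (1-based within the window), offset, strand, score, pvalue, model,
#'   width.
#' @export
scanCatalog <- function(sites, pwms, ...) {
  out <- lapply(seq_along(sites), function(i) {
    m <- scanSite(mcols(sites)$windowSeq[i], pwms, ...)
    if (nrow(m) == 0) return(NULL)
    cbind(siteId = mcols(sites)$siteId[i], m)
  })
  do.call(rbind, out)
}

#' Annotate SNPs against observed motif matches
#'
#' For each SNP at a matched site, computes the observed strand-oriented
#' motif-relative position, contact-region membership, and the allele
#' log-odds delta under the matched model.
#'
#' @param snps SNP table (`snpId`, `siteId`, `windowPos`, alleles).
#' @param matches output of [scanCatalog()].
#' @param pwms the model list used for the scan (named by modelId).
#' @param contactUpstream,contactDownstream contact-region extents.
#' @return data.frame: snpId, siteId, matched, obsPosition, obsInCore,
#'   obsInContact, delta, favored, matchScore.
#' @export
snpMotifAnnotation <- function(snps, matches, pwms,
                               contactUpstream = 20,
                               contactDownstream = 10) {
  if (is(pwms, "PWM")) pwms <- setNames(list(pwms), pwms@modelId)
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, function(p) p@modelId, character(1))
  mi <- match(snps$siteId, matches$siteId)
  out <- data.frame(snpId = snps$snpId, siteId = snps$siteId,
                    matched = !is.na(mi),
                    obsPosition = NA_integer_, obsInCore = FALSE,
                    obsInContact = FALSE, delta = 0,
                    favored = NA_character_, matchScore = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in which(!is.na(mi))) {
    m <- matches[mi[r], ]
    pwm <- pwms[[m$model]]
    rel <- motifRelativePosition(snps$windowPos[r], m$start - 1L,
                                 m$strand, width = m$width,
                                 contactUpstream = contactUpstream,
                                 contactDownstream = contactDownstream)
    ad <- alleleDelta(pwm, if (rel$inCore) rel$position else NA,
                      snps$alleleA[r], snps$alleleB[r], m$strand)
    out$obsPosition[r] <- rel$position
    out$obsInCore[r] <- rel$inCore
    out$obsInContact[r] <- rel$inContact
    out$delta[r] <- ad$delta
    out$favored[r] <- ad$favored
    out$matchScore[r] <- m$score
  }
  out
}
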