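#' Select testable heterozygous allele-count records
#'
#' A record is testable when the sample is heterozygous at the SNP, total
#' allele-assigned reads reach `minCov` (default 13), and the site passes
#' the mappability screen without differential allele mappability.
#'
#' @param alleleCounts `DataFrame`/data.frame with snpId, siteId, sample,
#'   readsA, readsB.
#' @param genotypes member x SNP matrix of called genotypes.
#' @param mappability data.frame from [mappabilityScreen()] or `NULL`.
#' @param minCov minimum total reads (default 13).
#' @return data.frame of testable records.
#' @export
selectHetTestable <- function(alleleCounts, genotypes = NULL,
                              mappability = NULL, minCov = 13) {
  ac <- as.data.frame(alleleCounts)
  keep <- (ac$readsA + ac$readsB) >= minCov
  if (!is.null(genotypes)) {
    het <- mapply(function(s, m)
      s %in% colnames(genotypes) && !is.na(genotypes[m, s]) &&
        genotypes[m, s] == 1L,
      ac$snpId, ac$sample)
    keep <- keep & het
  }
  if (!is.null(mappability)) {
    mi <- match(ac$siteId, mappability$siteId)
    keep <- keep & !is.na(mi) & mappability$pass[mi] &
      !mappability$alleleDifferential[mi]
  }
  ac[keep, , drop = FALSE]
}

#' Chi-squared test of allelic imbalance
#'
#' One-degree-of-freedom chi-squared test of the two allele read counts
#' against a 50:50 null, without continuity correction:
#' `(a-e)^2/e + (b-e)^2/e` with `e = (a+b)/2`.
#'
#' @param readsA,readsB allele read counts (vectorized).
#' @return data.frame with `statistic` and `p`; records with zero total
#'   get `NA` (undefined, excluded by selection).
#' @export
alleleChisq <- function(readsA, readsB) {
  tot <- readsA + readsB
  e <- tot / 2
  stat <- ifelse(tot == 0, NA_real_,
                 (readsA - e)^2 / e + (readsB - e)^2 / e)
  data.frame(statistic = stat,
             p = ifelse(is.na(stat), NA_real_,
                        pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Representative sample per site
#'
#' Among a site's testable samples, the one with the most total reads;
#' ties go to the lexicographically first sample id.
#'
#' @param records testable records for one or more sites (needs siteId,
#'   sample, readsA, readsB).
#' @return logical vector flagging the representative record(s).
#' @export
representativeSample <- function(records) {
  rec <- as.data.frame(records)
  tot <- rec$readsA + rec$readsB
  flag <- logical(nrow(rec))
  for (sid in unique(rec$siteId)) {
    ix <- which(rec$siteId == sid)
    best <- ix[order(-tot[ix], rec$sample[ix])][1]
    flag[best] <- TRUE
  }
  flag
}

#' Allele-specific occupancy analysis
#'
#' Runs the chi-squared imbalance test on all testable heterozygous
#' records, attaches q-values, and flags the representative sample per
#' site.
#'
#' @inheritParams selectHetTestable
#' @param fdrMethod "storey" or "bh".
#' @return data.frame: record table with statistic, p, q, representative.
#' @export
runAlleleSpecific <- function(alleleCounts, genotypes = NULL,
                              mappability = NULL, minCov = 13,
                              fdrMethod = "storey") {
  rec <- selectHetTestable(alleleCounts, genotypes, mappability, minCov)
  if (nrow(rec) == 0) return(cbind(rec, statistic = numeric(0),
                                   p = numeric(0), q = numeric(0),
                                   representative = logical(0)))
  ts <- alleleChisq(rec$readsA, rec$readsB)
  rec$statistic <- ts$statistic
  rec$p <- ts$p
  rec$q <- estimateFdr(rec$p, fdrMethod)
  rec$representative <- representativeSample(rec)
  rec
}
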