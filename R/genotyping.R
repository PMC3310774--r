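#' Call SNPs from resequencing pileups
#'
#' Biallelic calling with the study's filters: the two alleles are the two
#' most abundant bases above a noise floor across pooled samples (more
#' than two such bases flags the site multi-allelic and drops it); a
#' sample's genotype is missing below `minCov` coverage; a heterozygote
#' requires the minor allele to carry at least `minMinorFrac` of that
#' sample's reads, otherwise the majority homozygote is called; sites with
#' Phred-like quality below `minQual` fail the quality filter. Genotypes
#' are coded as copies of the alphabetically later allele (allele B).
#'
#' @param pileups `DataFrame` from [simulatePileups()] (or same layout).
#' @param minCov minimum coverage for a genotype call (default 8).
#' @param minQual minimum site quality (default 30).
#' @param minMinorFrac minimum minor-allele read fraction for a
#'   heterozygote (default 0.2).
#' @param noiseFloor minimum pooled read fraction for a base to count as
#'   an allele (default 0.1).
#' @return list with `calls` (data.frame: snpId, alleleA, alleleB, quality,
#'   multiAllelic, qualityPass) and `genotypes` (member x SNP matrix of
#'   allele-B copies, `NA` = missing; only sites passing all site-level
#'   filters appear).
#' @export
callSnps <- function(pileups, minCov = 8, minQual = 30,
                     minMinorFrac = 0.2, noiseFloor = 0.1) {
  pu <- as.data.frame(pileups)
  ids <- sort(unique(pu$sample))
  snpIds <- unique(pu$snpId)
  calls <- list()
  geno <- list()
  for (s in snpIds) {
    rows <- pu[pu$snpId == s, , drop = FALSE]
    pooled <- colSums(rows[, c("nA", "nC", "nG", "nT")])
    names(pooled) <- DNA_BASES
    tot <- sum(pooled)
    above <- if (tot > 0) DNA_BASES[pooled / tot >= noiseFloor]
             else character(0)
    multi <- length(above) > 2
    if (multi || length(above) < 2) {
      calls[[s]] <- data.frame(snpId = s, alleleA = NA, alleleB = NA,
                               quality = 0, multiAllelic = multi,
                               qualityPass = FALSE)
      next
    }
    ab <- sort(above)              # A = earlier, B = later allele
    qual <- max(rows$quality)
    g <- rep(NA_integer_, length(ids))
    names(g) <- ids
    for (m in seq_len(nrow(rows))) {
      nA <- rows[[paste0("n", ab[1])]][m]
      nB <- rows[[paste0("n", ab[2])]][m]
      cov <- rows$depth[m]
      if (cov < minCov) next
      nmin <- min(nA, nB)
      if ((nA + nB) > 0 && nmin / (nA + nB) >= minMinorFrac) {
        g[rows$sample[m]] <- 1L
      } else {
        g[rows$sample[m]] <- if (nA >= nB) 0L else 2L
      }
    }
    calls[[s]] <- data.frame(snpId = s, alleleA = ab[1], alleleB = ab[2],
                             quality = qual, multiAllelic = FALSE,
                             qualityPass = qual >= minQual)
    geno[[s]] <- g
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  keep <- calls$snpId[!calls$multiAllelic & calls$qualityPass]
  genotypes <- if (length(keep))
    do.call(cbind, geno[keep]) else matrix(NA_integer_, length(ids), 0)
  colnames(genotypes) <- keep
  rownames(genotypes) <- ids
  list(calls = calls, genotypes = genotypes)
}

allelesFromGeno <- function(g) switch(as.character(g),
                                      "0" = 0L, "1" = c(0L, 1L), "2" = 1L)

trioPossible <- function(child, father, mother) {
  if (is.na(child)) return(TRUE)
  fa <- if (is.na(father)) c(0L, 1L) else allelesFromGeno(father)
  mo <- if (is.na(mother)) c(0L, 1L) else allelesFromGeno(mother)
  child %in% outer(fa, mo, "+")
}

#' Mendelian consistency screen
#'
#' Checks every parent-child trio in the pedigree at every SNP: the
#' child's genotype must be reachable by biallelic Mendelian transmission
#' from its parents' genotypes (missing genotypes are unconstrained).
#' Sites violating transmission in any trio are listed; the study-level
#' filter drops such sites entirely.
#'
#' @param genotypes member x SNP matrix of allele copies (0/1/2/`NA`).
#' @param ped a [Pedigree-class].
#' @return list with `pass` (logical per SNP) and `violations`
#'   (data.frame: snpId, child).
#' @export
mendelianConsistent <- function(genotypes, ped) {
  m <- ped@members
  kids <- m[!is.na(m$father), , drop = FALSE]
  snpIds <- colnames(genotypes)
  viol <- list()
  pass <- rep(TRUE, ncol(genotypes))
  names(pass) <- snpIds
  for (j in seq_len(ncol(genotypes))) {
    for (k in seq_len(nrow(kids))) {
      ok <- trioPossible(genotypes[kids$id[k], j],
                         genotypes[kids$father[k], j],
                         genotypes[kids$mother[k], j])
      if (!ok) {
        pass[j] <- FALSE
        viol[[length(viol) + 1L]] <- data.frame(snpId = snpIds[j],
                                                child = kids$id[k])
      }
    }
  }
  list(pass = pass,
       violations = if (length(viol)) do.call(rbind, viol)
                    else data.frame(snpId = character(0),
                                    child = character(0)))
}

#' Polarize a SNP by an outgroup allele
#'
#' If the outgroup allele matches one of the two alleles, the other is
#' derived; a missing outgroup or a third allele leaves the SNP
#' unpolarized.
#'
#' @param alleleA,alleleB the SNP's two alleles (vectors recycle).
#' @param outgroup outgroup (e.g. chimpanzee) allele or `NA`.
#' @return data.frame with `ancestral`, `derived` (both `NA` when
#'   unpolarized) and `polarized`.
#' @export
polarizeAncestral <- function(alleleA, alleleB, outgroup) {
  n <- max(length(alleleA), length(alleleB), length(outgroup))
  alleleA <- rep_len(alleleA, n); alleleB <- rep_len(alleleB, n)
  outgroup <- rep_len(outgroup, n)
  isA <- !is.na(outgroup) & outgroup == alleleA
  isB <- !is.na(outgroup) & outgroup == alleleB
  data.frame(
    ancestral = ifelse(isA, alleleA, ifelse(isB, alleleB, NA)),
    derived = ifelse(isA, alleleB, ifelse(isB, alleleA, NA)),
    polarized = isA | isB)
}

#' Genotype concordance against truth
#'
#' Discordance = mismatched non-missing genotype pairs / compared pairs,
#' overall and per sample, over the SNPs present in both sets. Allele
#' coding is reconciled: when the called allele pair matches the truth
#' pair but with A/B swapped, called genotypes are flipped before
#' comparison.
#'
#' @param called list from [callSnps()].
#' @param truthGenotypes member x SNP truth matrix (copies of truth B).
#' @param truthAlleles data.frame with `snpId`, `alleleA`, `alleleB`.
#' @return list with `overall` discordance, `perSample`, and `nCompared`.
#' @export
genotypeConcordance <- function(called, truthGenotypes, truthAlleles) {
  shared <- intersect(colnames(called$genotypes), colnames(truthGenotypes))
  if (length(shared) == 0) stop("no overlapping loci to compare")
  ids <- intersect(rownames(called$genotypes), rownames(truthGenotypes))
  g1 <- called$genotypes[ids, shared, drop = FALSE]
  g2 <- truthGenotypes[ids, shared, drop = FALSE]
  ci <- match(shared, called$calls$snpId)
  ti <- match(shared, truthAlleles$snpId)
  for (j in seq_along(shared)) {
    ca <- c(called$calls$alleleA[ci[j]], called$calls$alleleB[ci[j]])
    ta <- c(truthAlleles$alleleA[ti[j]], truthAlleles$alleleB[ti[j]])
    if (!setequal(ca, ta))
      g1[, j] <- NA_integer_       # different alleles: treat as missing
    else if (ca[2] != ta[2])
      g1[, j] <- 2L - g1[, j]      # same alleles, swapped A/B coding
  }
  cmp <- !is.na(g1) & !is.na(g2)
  mism <- cmp & (g1 != g2)
  perSample <- ifelse(rowSums(cmp) > 0, rowSums(mism) / rowSums(cmp), NA)
  list(overall = sum(mism) / sum(cmp), perSample = perSample,
       nCompared = sum(cmp))
}
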