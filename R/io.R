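#' Read a PWM frequency matrix
#'
#' Tab-delimited file, one row per motif position, header columns
#' `A C G T` (an optional leading position column is ignored).
#'
#' @param file path.
#' @param ... passed to [buildPWM()] (background, pseudo, modelId).
#' @return a [PWM-class].
#' @export
readPWM <- function(file, ...) {
  tab <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(DNA_BASES %in% names(tab)))
    stop("PWM file must have columns A, C, G, T")
  buildPWM(as.matrix(tab[, DNA_BASES]), ...)
}

#' Synthetic multivalent motif model set
#'
#' Loads the three synthetic CTCF-like 14 bp motif models shipped with the
#' package (a canonical model plus two variants emulating alternative
#' binding modes). These are synthetic stand-ins constructed for
#' simulation; real motif matrices can be supplied to every function that
#' takes a PWM.
#'
#' @return named list of three [PWM-class] objects.
#' @export
exampleMotifModels <- function() {
  files <- c(canonical = "pwm_canonical_synthetic.tsv",
             variant1 = "pwm_variant1_synthetic.tsv",
             variant2 = "pwm_variant2_synthetic.tsv")
  out <- lapply(names(files), function(nm)
    readPWM(system.file("extdata", files[[nm]], package = "bindingQTL",
                        mustWork = TRUE), modelId = nm))
  names(out) <- names(files)
  out
}

#' Write the site catalog as BED
#'
#' 0-based half-open intervals with the site id as name and the motif
#' strand.
#'
#' @param sites `GRanges` site catalog.
#' @param file output path.
#' @export
writeSitesBed <- function(sites, file) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                   chromStart = GenomicRanges::start(sites) - 1L,
                   chromEnd = GenomicRanges::end(sites),
                   name = mcols(sites)$siteId,
                   score = 0L,
                   strand = as.character(GenomicRanges::strand(sites)))
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Write SNP calls as a minimal VCF
#'
#' VCF v4-style columns with a GT field per sample, 1-based positions.
#' Genotypes 0/1/2 copies of the B (ALT) allele map to 0/0, 0/1, 1/1;
#' missing to ./.
#'
#' @param snps SNP table with `snpId`, `genomePos`, `alleleA`, `alleleB`.
#' @param genotypes member x SNP matrix (0/1/2/NA).
#' @param file output path.
#' @param chrom chromosome name.
#' @export
writeSnpVcf <- function(snps, genotypes, file, chrom = "chrS") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  gtStr <- c("0/0", "0/1", "1/1")
  for (r in seq_len(nrow(snps))) {
    g <- genotypes[, r]
    gt <- ifelse(is.na(g), "./.", gtStr[g + 1L])
    writeLines(paste(c(chrom, snps$genomePos[r], snps$snpId[r],
                       snps$alleleA[r], snps$alleleB[r], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(file)
}

#' Write a genotype TSV mirror
#'
#' Site-per-row table: chrom, 0-based start, end, snp id, alleles and one
#' genotype column per sample, with "00" indicating missing data.
#'
#' @inheritParams writeSnpVcf
#' @export
writeSnpTsv <- function(snps, genotypes, file, chrom = "chrS") {
  g <- t(genotypes)
  gchr <- matrix(as.character(g), nrow(g), ncol(g),
                 dimnames = dimnames(g))
  gchr[is.na(g)] <- "00"
  df <- data.frame(chrom = chrom,
                   chromStart = snps$genomePos - 1L,
                   chromEnd = snps$genomePos,
                   snpId = snps$snpId,
                   genotype = paste(snps$alleleB, snps$alleleA, sep = "/"),
                   gchr, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

writeTsv <- function(df, file) {
  write.table(as.data.frame(df), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
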