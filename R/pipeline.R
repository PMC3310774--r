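#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in dependency order -- study generation,
#' mappability screen, motif scan, genotyping with Mendelian screening,
#' genotype-occupancy association, allele-specific testing, aggregate
#' sib-pair linkage, buffering analyses, and predictor evaluation -- and
#' writes every stage's tables plus a run log and a summary ledger to
#' `outDir`. All randomness derives from the configuration seed, so two
#' runs with the same configuration produce byte-identical outputs.
#'
#' @param cfg a [SimConfig-class].
#' @param outDir output directory (created if missing).
#' @param pwms motif model list (default [exampleMotifModels()]).
#' @param stages character vector of stages to run; dependencies of a
#'   requested stage must be included or the run fails fast.
#' @param fdrLevel association significance level (default 0.01).
#' @param fdrLevelAS allele-specific significance level (default 0.001).
#' @param fdrMethod "storey" or "bh".
#' @param nBoot mutual-information resampling iterations (default 2000).
#' @param nPerm linkage permutations (default 1000).
#' @return invisibly, a list with every stage's in-memory results.
#' @export
runPipeline <- function(cfg, outDir, pwms = NULL,
                        stages = c("synth", "mappability", "scan",
                                   "genotype", "assoc", "allelic",
                                   "linkage", "buffering", "evaluate"),
                        fdrLevel = 0.01, fdrLevelAS = 0.001,
                        fdrMethod = "storey", nBoot = 2000, nPerm = 1000) {
  deps <- list(mappability = "synth", scan = "synth", genotype = "synth",
               assoc = c("synth", "scan", "genotype", "mappability"),
               allelic = c("synth", "genotype", "mappability"),
               linkage = c("synth", "assoc"),
               buffering = c("synth", "scan", "assoc"),
               evaluate = c("synth", "scan", "assoc"))
  for (s in stages) {
    missing <- setdiff(deps[[s]], stages)
    if (length(missing))
      stop(sprintf("stage '%s' requires stage(s): %s", s,
                   paste(missing, collapse = ", ")))
  }
  if (is.null(pwms)) pwms <- exampleMotifModels()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg@params
  logCon <- file(file.path(outDir, "run_log.jsonl"), "w")
  on.exit(close(logCon))
  logStage <- function(stage, ...) {
    writeLines(jsonlite::toJSON(c(list(stage = stage, seed = p$seed), ...),
                                auto_unbox = TRUE), logCon)
  }
  yaml::write_yaml(p, file.path(outDir, "config.yaml"))
  out <- list(config = cfg)

  halt <- function(stage, e)
    stop(sprintf("stage '%s' failed (seed %d): %s", stage, p$seed,
                 conditionMessage(e)), call. = FALSE)

  ## synth ------------------------------------------------------------
  study <- tryCatch(simulateStudy(cfg, pwms[["canonical"]]),
                    error = function(e) halt("synth", e))
  out$study <- study
  snps <- as.data.frame(studySnps(study))
  writeSitesBed(studySites(study), file.path(outDir, "sites.bed"))
  writeSnpVcf(snps, studyTruth(study)$genotypes,
              file.path(outDir, "snps_truth.vcf"))
  writeTsv(data.frame(siteId = rownames(
    SummarizedExperiment::assay(studyCounts(study))),
    SummarizedExperiment::assay(studyCounts(study)), check.names = FALSE),
    file.path(outDir, "counts.tsv"))
  writeTsv(data.frame(siteId = mcols(studySites(study))$siteId,
                      studyTruth(study)$ibd, check.names = FALSE),
           file.path(outDir, "truth_ibd.tsv"))
  writeTsv(studyPileups(study), file.path(outDir, "pileups.tsv"))
  logStage("synth", nSites = length(studySites(study)), nSnps = nrow(snps))

  ## mappability -------------------------------------------------------
  mapp <- NULL
  if ("mappability" %in% stages) {
    mapp <- tryCatch({
      set.seed(subSeed(p$seed, "mappability"))
      genome <- studyGenome(studySites(study), subSeed(p$seed, "mappability"))
      mappabilityScreen(studySites(study), snps, genome,
                        readLen = p$readLen)
    }, error = function(e) halt("mappability", e))
    writeTsv(mapp, file.path(outDir, "mappability.tsv"))
    logStage("mappability", nPass = sum(mapp$pass))
    out$mappability <- mapp
  }

  ## scan ---------------------------------------------------------------
  annot <- NULL
  if ("scan" %in% stages) {
    matches <- tryCatch(scanCatalog(studySites(study), pwms),
                        error = function(e) halt("scan", e))
    annot <- snpMotifAnnotation(snps, matches, pwms,
                                contactUpstream = p$contactUpstream,
                                contactDownstream = p$contactDownstream)
    writeTsv(matches, file.path(outDir, "motif_matches.tsv"))
    writeTsv(annot, file.path(outDir, "snp_annotation.tsv"))
    logStage("scan", nMatched = nrow(matches))
    out$matches <- matches; out$annotation <- annot
  }

  ## genotype -----------------------------------------------------------
  called <- NULL; coverage <- NULL
  if ("genotype" %in% stages) {
    res <- tryCatch({
      called <- callSnps(studyPileups(study))
      mend <- mendelianConsistent(called$genotypes, studyPedigree(study))
      called$genotypes <- called$genotypes[, mend$pass, drop = FALSE]
      pu <- as.data.frame(studyPileups(study))
      coverage <- matrix(0L, nrow(called$genotypes), nrow(snps),
                         dimnames = list(rownames(called$genotypes),
                                         snps$snpId))
      coverage[cbind(pu$sample, pu$snpId)] <- pu$depth
      conc <- genotypeConcordance(called, studyTruth(study)$genotypes, snps)
      list(called = called, mend = mend, coverage = coverage, conc = conc)
    }, error = function(e) halt("genotype", e))
    called <- res$called; coverage <- res$coverage
    writeSnpTsv(snps[snps$snpId %in% colnames(called$genotypes), ],
                called$genotypes[, , drop = FALSE],
                file.path(outDir, "genotypes.tsv"))
    logStage("genotype", nCalled = ncol(called$genotypes),
             discordance = res$conc$overall,
             mendelianFailures = nrow(res$mend$violations))
    out$genotyping <- res
  }

  ## assoc ----------------------------------------------------------------
  assocRes <- NULL; testable <- NULL
  if ("assoc" %in% stages) {
    assocRes <- tryCatch({
      nReps <- table(SummarizedExperiment::colData(studyCounts(study))$sample)
      nReps <- setNames(as.integer(nReps), names(nReps))
      testable <- selectTestable(
        snps, called$genotypes, coverage, nReps, mapp,
        contactFlag = annot$obsInContact)
      runAssociation(studyCounts(study), snps, called$genotypes,
                     testable, fdrMethod = fdrMethod)
    }, error = function(e) halt("assoc", e))
    writeTsv(assocRes, file.path(outDir, "association.tsv"))
    writeTsv(testable$exclusions, file.path(outDir, "assoc_exclusions.tsv"))
    out$association <- assocRes
    out$classification <- classifyResults(assocRes, annot, fdrLevel)
    logStage("assoc", nTested = nrow(assocRes),
             nSignificant = out$classification$nSignificant)
  }

  ## allelic ---------------------------------------------------------------
  if ("allelic" %in% stages) {
    asRes <- tryCatch(
      runAlleleSpecific(studyAlleleCounts(study), called$genotypes, mapp,
                        fdrMethod = fdrMethod),
      error = function(e) halt("allelic", e))
    writeTsv(asRes, file.path(outDir, "allele_specific.tsv"))
    logStage("allelic", nTested = nrow(asRes),
             nSignificant = sum(asRes$q < fdrLevelAS, na.rm = TRUE))
    out$alleleSpecific <- asRes
  }

  ## linkage ----------------------------------------------------------------
  if ("linkage" %in% stages) {
    linkRes <- tryCatch({
      set.seed(subSeed(p$seed, "mappability") + 11L)
      sibs <- pedigreeSibs(studyPedigree(study))
      ds <- differentialSites(studyCounts(study), samples = sibs)
      vst <- vstStandardize(studyCounts(study), ds$dispersion,
                            samples = sibs)
      diffIds <- ds$table$siteId[ds$table$differential]
      zz <- vst$z[rownames(vst$z) %in% diffIds, , drop = FALSE]
      siteIdx <- match(rownames(zz), mcols(studySites(study))$siteId)
      rec <- sibPairRecords(zz, studyTruth(study)$ibd,
                            studyTruth(study)$pairs, siteIdx,
                            studyTruth(study)$ibdUncertainty)
      sigSites <- assocRes$siteId[!is.na(assocRes$q) &
                                    assocRes$q < fdrLevel]
      strata <- list(associated = rec[rec$siteId %in% sigSites, ],
                     unassociated = rec[!(rec$siteId %in% sigSites), ])
      he <- lapply(strata, function(rr) {
        if (length(unique(rr$siteId)) < 2 ||
            length(unique(rr$ibd[!rr$excluded])) < 2) return(NULL)
        c(heRegress(rr), permutationPvalue(rr, nPerm)["p"])
      })
      list(differential = ds, records = rec, he = he)
    }, error = function(e) halt("linkage", e))
    writeTsv(linkRes$records, file.path(outDir, "sibpair_records.tsv"))
    logStage("linkage", nDifferential = sum(linkRes$differential$table$differential))
    out$linkage <- linkRes
  }

  ## buffering ---------------------------------------------------------------
  if ("buffering" %in% stages) {
    buf <- tryCatch({
      set.seed(subSeed(p$seed, "mappability") + 13L)
      ai <- match(assocRes$snpId, annot$snpId)
      sig <- !is.na(assocRes$q) & assocRes$q < fdrLevel
      si <- match(assocRes$snpId, snps$snpId)
      subTab <- substitutionTable(annot$obsPosition[ai],
                                  snps$alleleA[si], snps$alleleB[si], sig)
      dec <- if (nrow(assocRes) >= 10)
        decileCurve(assocRes$signalHet, sig) else NULL
      svp <- strengthVsPerturbation(annot$matchScore[ai],
                                    annot$delta[ai], sig)
      core <- annot$obsInCore[ai]
      mi <- if (sum(core) >= 5) {
        st <- studySites(study)
        coreSeqs <- mcols(st)$coreSeq[match(assocRes$siteId[core],
                                            mcols(st)$siteId)]
        sig5 <- !is.na(assocRes$q[core]) & assocRes$q[core] < 0.05
        mutualInfoContext(coreSeqs, annot$obsPosition[ai][core], sig5,
                          nBoot = nBoot)
      } else NULL
      list(substitution = subTab, decile = dec, strength = svp, mi = mi)
    }, error = function(e) halt("buffering", e))
    writeTsv(buf$substitution, file.path(outDir, "substitution_grid.tsv"))
    if (!is.null(buf$mi)) writeTsv(buf$mi, file.path(outDir, "mi_context.tsv"))
    logStage("buffering", nCells = nrow(buf$substitution))
    out$buffering <- buf
  }

  ## evaluate ------------------------------------------------------------------
  if ("evaluate" %in% stages) {
    evalRes <- tryCatch({
      set.seed(subSeed(p$seed, "mappability") + 17L)
      ai <- match(assocRes$snpId, annot$snpId)
      si <- match(assocRes$snpId, snps$snpId)
      ref <- annot$obsInContact[ai] & !is.na(assocRes$q)
      lab <- assocRes$q[ref] < fdrLevel
      if (length(unique(lab)) < 2) NULL
      else comparePredictors(snps$conservation[si][ref],
                             annot$delta[ai][ref], lab)
    }, error = function(e) halt("evaluate", e))
    if (!is.null(evalRes)) {
      ai <- match(assocRes$snpId, annot$snpId)
      si <- match(assocRes$snpId, snps$snpId)
      ref <- annot$obsInContact[ai] & !is.na(assocRes$q)
      roc <- rocAuc(annot$delta[ai][ref], assocRes$q[ref] < fdrLevel)$roc
      writeTsv(roc, file.path(outDir, "roc_delta.tsv"))
      jsonlite::write_json(
        list(aucDelta = evalRes$aucDelta,
             aucConservation = evalRes$aucConservation),
        file.path(outDir, "auc.json"), auto_unbox = TRUE, digits = NA)
      logStage("evaluate", aucDelta = evalRes$aucDelta,
               aucConservation = evalRes$aucConservation)
    }
    out$evaluation <- evalRes
  }

  ## summary ledger -------------------------------------------------------------
  ledger <- list(sitesSurveyed = length(studySites(study)),
                 sitesPolymorphic = length(unique(snps$siteId)),
                 snpsPlanted = nrow(snps))
  if (!is.null(assocRes)) {
    ledger$sitesTestable <- nrow(assocRes)
    ledger$sitesSignificant <- sum(!is.na(assocRes$q) &
                                     assocRes$q < fdrLevel)
  }
  jsonlite::write_json(ledger, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  out$ledger <- ledger
  invisible(out)
}

#' Validate pipeline file formats
#'
#' Checks BED files for 0-based half-open intervals (end > start) and
#' strand fields in +/-, VCF files for 1-based positions and well-formed
#' GT fields, and TSV files for a header and rectangular rows. Problems
#' are reported with file and line numbers.
#'
#' @param files character vector of paths (format inferred from
#'   extension).
#' @return data.frame: file, line, problem (zero rows = clean).
#' @export
validateIo <- function(files) {
  probs <- list()
  note <- function(f, l, msg)
    probs[[length(probs) + 1L]] <<- data.frame(file = f, line = l,
                                               problem = msg)
  for (f in files) {
    lines <- readLines(f)
    ext <- tolower(tools::file_ext(f))
    if (ext == "bed") {
      for (i in seq_along(lines)) {
        fl <- strsplit(lines[i], "\t")[[1]]
        if (length(fl) < 3) { note(f, i, "fewer than 3 BED fields"); next }
        st <- suppressWarnings(as.numeric(fl[2]))
        en <- suppressWarnings(as.numeric(fl[3]))
        if (is.na(st) || is.na(en)) note(f, i, "non-numeric coordinates")
        else {
          if (st < 0) note(f, i, "negative chromStart")
          if (en <= st) note(f, i, "chromEnd <= chromStart")
        }
        if (length(fl) >= 6 && !(fl[6] %in% c("+", "-")))
          note(f, i, "strand not +/-")
      }
    } else if (ext == "vcf") {
      body <- which(!startsWith(lines, "#"))
      for (i in body) {
        fl <- strsplit(lines[i], "\t")[[1]]
        if (length(fl) < 10) { note(f, i, "fewer than 10 VCF fields"); next }
        pos <- suppressWarnings(as.numeric(fl[2]))
        if (is.na(pos) || pos < 1) note(f, i, "POS must be >= 1")
        gts <- fl[10:length(fl)]
        bad <- !(gts %in% c("0/0", "0/1", "1/0", "1/1", "./."))
        if (any(bad)) note(f, i, "genotype outside {0/0,0/1,1/1,./.}")
      }
    } else {
      if (length(lines) == 0) { note(f, 1, "empty file"); next }
      ncols <- length(strsplit(lines[1], "\t")[[1]])
      if (ncols < 1 || !nzchar(lines[1])) note(f, 1, "missing header")
      for (i in seq_along(lines)[-1])
        if (length(strsplit(lines[i], "\t")[[1]]) != ncols)
          note(f, i, "ragged row")
    }
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(file = character(0), line = integer(0),
                  problem = character(0))
}
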