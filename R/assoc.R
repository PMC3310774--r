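#' Negative binomial regression of occupancy on genotype
#'
#' Fits a log-link NB GLM of per-replicate counts on genotype (coded
#' additively as copies of allele B) with a categorical replicate term for
#' batch effects. Where class sizes permit (>= 4 data points in both
#' collapsed classes), both dominant collapsings are also fitted
#' (heterozygote grouped with the AA or with the BB homozygote) and the
#' model minimizing AIC is reported. A separate ordinary linear fit on the
#' additive design supplies r-squared. Significance is the Wald test of
#' the genotype coefficient (likelihood-ratio available via `test`).
#'
#' @param counts non-negative integer counts, one per data point.
#' @param genotype allele-B copy number (0/1/2) per data point.
#' @param replicate replicate label per data point.
#' @param test "wald" (default) or "lrt".
#' @param models "auto" (default: additive plus dominant collapsings with
#'   AIC selection) or "additive" (no collapsing).
#' @return one-row data.frame: `beta` (log-scale effect of the chosen
#'   model's genotype term), `se`, `p`, `model`, AICs of the fitted
#'   models, `theta`, `r2`, `signalHet` (fitted heterozygote count at the
#'   reference replicate), `converged`.
#' @export
fitNbGenotype <- function(counts, genotype, replicate = NULL,
                          test = c("wald", "lrt"),
                          models = c("auto", "additive")) {
  test <- match.arg(test)
  models <- match.arg(models)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(unique(genotype)) < 2)   # monomorphic: nothing to regress on
    return(data.frame(beta = NA, se = NA, p = NA, model = NA,
                      aicAdditive = NA, aicDominantA = NA, aicDominantB = NA,
                      theta = NA, r2 = NA, signalHet = NA, converged = FALSE))
  df <- data.frame(y = counts, g = genotype)
  hasRep <- !is.null(replicate) && length(unique(replicate)) > 1
  if (hasRep) df$rep <- factor(replicate)
  form <- if (hasRep) y ~ g + rep else y ~ g
  form0 <- if (hasRep) y ~ rep else y ~ 1

  fit1 <- function(gcode) {
    d <- df; d$g <- gcode
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = d,
                                    control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit)) {
      # theta -> Inf (under-dispersed/constant data): Poisson limit
      fit <- tryCatch(stats::glm(form, data = d, family = stats::poisson()),
                      error = function(e) NULL)
      if (!is.null(fit)) fit$theta <- Inf
    }
    fit
  }
  codes <- list(additive = df$g)
  tab <- tabulate(df$g + 1L, 3L)
  if (models == "auto" && tab[2] > 0) {
    if (tab[1] + tab[2] >= 4 && tab[3] >= 4)
      codes$dominantA <- as.numeric(df$g == 2)     # het grouped with AA
    if (tab[2] + tab[3] >= 4 && tab[1] >= 4)
      codes$dominantB <- as.numeric(df$g >= 1)     # het grouped with BB
  }
  fits <- lapply(codes, fit1)
  ok <- !vapply(fits, is.null, logical(1))
  if (!ok[["additive"]])
    return(data.frame(beta = NA, se = NA, p = NA, model = NA,
                      aicAdditive = NA, aicDominantA = NA, aicDominantB = NA,
                      theta = NA, r2 = NA, signalHet = NA, converged = FALSE))
  aics <- vapply(names(codes), function(nm)
    if (ok[[nm]]) stats::AIC(fits[[nm]]) else NA_real_, numeric(1))
  chosen <- names(codes)[which.min(aics)]
  fit <- fits[[chosen]]
  cf <- summary(fit)$coefficients
  beta <- cf["g", 1]; se <- cf["g", 2]
  p <- if (test == "wald") {
    # t reference with residual df: the NB dispersion is estimated from
    # few points, so the normal reference is anticonservative in the tail
    2 * stats::pt(-abs(beta / se), df = max(fit$df.residual, 1))
  } else {
    d <- df; d$g <- codes[[chosen]]
    fit0 <- tryCatch(
      suppressWarnings(MASS::glm.nb(form0, data = d)),
      error = function(e) stats::glm(form0, data = d,
                                     family = stats::poisson()))
    pchisq(2 * (as.numeric(stats::logLik(fit)) -
                  as.numeric(stats::logLik(fit0))), 1, lower.tail = FALSE)
  }
  lmfit <- suppressWarnings(lm(form, data = df))
  r2 <- suppressWarnings(summary(lmfit)$r.squared)
  hetCode <- c(additive = 1, dominantA = 0, dominantB = 1)[[chosen]]
  signalHet <- exp(cf["(Intercept)", 1] + beta * hetCode)
  data.frame(beta = beta, se = se, p = p, model = chosen,
             aicAdditive = aics[["additive"]],
             aicDominantA = if ("dominantA" %in% names(aics))
               aics[["dominantA"]] else NA_real_,
             aicDominantB = if ("dominantB" %in% names(aics))
               aics[["dominantB"]] else NA_real_,
             theta = if (is.null(fit$theta)) NA_real_ else fit$theta,
             r2 = r2,
             signalHet = signalHet,
             converged = isTRUE(fit$converged) || !is.null(fit$theta),
             row.names = NULL)
}

#' False discovery rate estimation
#'
#' Storey q-values (pi0 estimated on a lambda grid 0.05-0.90 with spline
#' smoothing) or Benjamini-Hochberg step-up. Both are monotone in p.
#'
#' @param p p-values in \[0, 1\].
#' @param method "storey" or "bh".
#' @return q-values in the order of `p` (empty input gives empty output).
#' @export
estimateFdr <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (method == "bh") return(p.adjust(p, "BH"))
  n <- length(p)
  lambda <- seq(0.05, 0.90, 0.05)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (n < 100) 1 else {
    fit <- smooth.spline(lambda, pi0l, df = 3)
    min(max(predict(fit, max(lambda))$y, 0), 1)
  }
  if (pi0 <= 0) pi0 <- 1 / n  # degenerate: all p tiny
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- cummin(pi0 * n * p[o] / rank(p, ties.method = "max")[o])
  pmin(q, 1)
}

#' Select testable site/SNP combinations
#'
#' Applies the testability rules: site mappability pass, resequencing
#' coverage at least `minCov` in at least `minSamples` samples, at least
#' `minPerClass` data points in each of two or more genotype classes and
#' `minTotal` data points overall. Sites with several qualifying SNPs are
#' resolved by preferring the SNP with more data points, then one inside
#' the contact region; if several remain the association fit breaks the
#' tie by p-value and the site is flagged position-ambiguous.
#'
#' @param snps SNP table (`snpId`, `siteId`, `siteIdx`).
#' @param genotypes member x SNP matrix (`NA` = missing).
#' @param coverage member x SNP resequencing depth matrix.
#' @param nReplicates data points contributed per genotyped sample
#'   (member x nothing; a named vector of replicate counts per sample).
#' @param mappability data.frame from [mappabilityScreen()] or `NULL` to
#'   skip that filter.
#' @param contactFlag logical per SNP: inside the contact region
#'   (observed annotation).
#' @param minCov,minSamples,minPerClass,minTotal thresholds (8, 6, 4, 12).
#' @return list with `testable` (data.frame snpId, siteId, dataPoints,
#'   ambiguous) and `exclusions` (snpId, reason).
#' @export
selectTestable <- function(snps, genotypes, coverage, nReplicates,
                           mappability = NULL, contactFlag = NULL,
                           minCov = 8, minSamples = 6, minPerClass = 4,
                           minTotal = 12) {
  excl <- list()
  keep <- logical(nrow(snps))
  dataPoints <- integer(nrow(snps))
  for (r in seq_len(nrow(snps))) {
    id <- snps$snpId[r]
    if (!is.null(mappability)) {
      mp <- mappability$pass[mappability$siteId == snps$siteId[r]]
      if (length(mp) && !mp[1]) {
        excl[[length(excl) + 1L]] <- data.frame(snpId = id,
                                                reason = "mappability")
        next
      }
    }
    if (!(id %in% colnames(genotypes))) {
      excl[[length(excl) + 1L]] <- data.frame(snpId = id,
                                              reason = "not called")
      next
    }
    cov <- coverage[, id]
    if (sum(cov >= minCov) < minSamples) {
      excl[[length(excl) + 1L]] <- data.frame(snpId = id,
                                              reason = "coverage")
      next
    }
    g <- genotypes[, id]
    usable <- !is.na(g) & cov >= minCov
    pts <- nReplicates[rownames(genotypes)]
    clsPts <- vapply(0:2, function(k)
      sum(pts[usable & g == k]), numeric(1))
    if (sum(clsPts >= minPerClass) < 2) {
      excl[[length(excl) + 1L]] <-
        data.frame(snpId = id, reason = "genotype-class minimum")
      next
    }
    if (sum(clsPts) < minTotal) {
      excl[[length(excl) + 1L]] <- data.frame(snpId = id,
                                              reason = "data points")
      next
    }
    keep[r] <- TRUE
    dataPoints[r] <- sum(clsPts)
  }
  testable <- data.frame(snpId = snps$snpId[keep],
                         siteId = snps$siteId[keep],
                         dataPoints = dataPoints[keep],
                         ambiguous = rep(FALSE, sum(keep)),
                         stringsAsFactors = FALSE)
  if (!is.null(contactFlag))
    testable$inContact <- contactFlag[match(testable$snpId, snps$snpId)]
  # multi-SNP resolution: more data points, then contact region
  for (sid in unique(testable$siteId[duplicated(testable$siteId)])) {
    rows <- which(testable$siteId == sid)
    best <- rows[testable$dataPoints[rows] == max(testable$dataPoints[rows])]
    if (length(best) > 1 && !is.null(testable$inContact) &&
        any(testable$inContact[best]))
      best <- best[testable$inContact[best]]
    drop <- setdiff(rows, best)
    if (length(drop)) {
      excl <- c(excl, lapply(testable$snpId[drop], function(s)
        data.frame(snpId = s, reason = "multi-SNP window")))
      testable <- testable[-drop, , drop = FALSE]
    }
    rows <- which(testable$siteId == sid)
    if (length(rows) > 1) testable$ambiguous[rows] <- TRUE
  }
  list(testable = testable,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(snpId = character(0),
                                    reason = character(0)))
}

#' Run the genotype-occupancy association survey
#'
#' For every testable site/SNP, fits the NB genotype regression on the
#' per-replicate counts of genotyped samples, resolves remaining multi-SNP
#' ties by lowest p, attaches q-values, and derives the higher-occupancy
#' allele from the sign of the additive-coded effect.
#'
#' @param se `SummarizedExperiment` of counts (colData `sample`,
#'   `replicate`).
#' @param snps SNP table.
#' @param genotypes member x SNP called genotype matrix.
#' @param testable output of [selectTestable()].
#' @param fdrMethod "storey" or "bh".
#' @param test "wald" or "lrt".
#' @return data.frame of association results, one row per tested site.
#' @export
runAssociation <- function(se, snps, genotypes, testable,
                           fdrMethod = "storey", test = "wald") {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  tt <- testable$testable
  res <- list()
  for (r in seq_len(nrow(tt))) {
    id <- tt$snpId[r]
    sn <- snps[snps$snpId == id, ]
    g <- genotypes[, id]
    use <- cd$sample %in% rownames(genotypes)[!is.na(g)]
    y <- counts[sn$siteId, use]
    gv <- g[cd$sample[use]]
    fit <- fitNbGenotype(as.integer(y), gv, cd$replicate[use], test = test)
    res[[r]] <- cbind(snpId = id, siteId = tt$siteId[r],
                      ambiguous = tt$ambiguous[r], fit)
  }
  res <- do.call(rbind, res)
  # ambiguous multi-SNP sites: keep lowest p per site
  if (any(res$ambiguous)) {
    keep <- unlist(lapply(split(seq_len(nrow(res)), res$siteId),
                          function(ix) ix[which.min(res$p[ix])]))
    res <- res[sort(keep), , drop = FALSE]
  }
  conv <- res$converged & !is.na(res$p)
  res$q <- NA_real_
  res$q[conv] <- estimateFdr(res$p[conv], fdrMethod)
  res$higherOccAllele <- ifelse(is.na(res$beta), NA,
    ifelse(res$beta > 0,
           snps$alleleB[match(res$snpId, snps$snpId)],
           snps$alleleA[match(res$snpId, snps$snpId)]))
  rownames(res) <- NULL
  res
}

#' Summarize association results against motif annotation
#'
#' Counts significant SNPs inside and outside the protein-DNA contact
#' region, the fraction whose higher-occupancy allele is the
#' PWM-favored allele, and median q inside vs outside.
#'
#' @param results output of [runAssociation()].
#' @param annotation output of [snpMotifAnnotation()].
#' @param fdr significance threshold on q (default 0.01).
#' @return list of summary quantities.
#' @export
classifyResults <- function(results, annotation, fdr = 0.01) {
  ai <- match(results$snpId, annotation$snpId)
  inContact <- annotation$obsInContact[ai]
  favored <- annotation$favored[ai]
  sig <- !is.na(results$q) & results$q < fdr
  concord <- results$higherOccAllele == favored
  okf <- sig & inContact & !is.na(favored)
  list(nTested = nrow(results),
       nSignificant = sum(sig),
       nSigInContact = sum(sig & inContact, na.rm = TRUE),
       nSigOutside = sum(sig & !inContact, na.rm = TRUE),
       fracSigInContact = if (sum(sig)) mean(inContact[sig], na.rm = TRUE)
                          else NA_real_,
       concordanceFraction = if (any(okf)) mean(concord[okf], na.rm = TRUE)
                             else NA_real_,
       medianQInside = median(results$q[inContact & !is.na(results$q)]),
       medianQOutside = median(results$q[!inContact & !is.na(results$q)]))
}
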