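#' Differential-occupancy test across samples
#'
#' A per-site negative binomial likelihood-ratio test of a sample effect
#' against a replicate-only null, using a pooled trended dispersion: each
#' site's method-of-moments dispersion from replicate pairs is smoothed
#' against its mean by lowess, and the trended value is held fixed in both
#' fits. Sites without replicate information or with all-zero counts are
#' excluded with a reason.
#'
#' @param se `SummarizedExperiment` of counts with colData `sample` and
#'   `replicate`.
#' @param samples optional subset of sample ids to test across (e.g. the
#'   six grandchildren).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return list with `table` (siteId, statistic, df, p, padj,
#'   differential), `excluded` (siteId, reason), `dispersion` (per-site
#'   trended theta).
#' @export
differentialSites <- function(se, samples = NULL, alpha = 0.05) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  if (!is.null(samples)) {
    keep <- cd$sample %in% samples
    counts <- counts[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
  }
  smp <- factor(cd$sample)
  repl <- factor(cd$replicate)
  multiRep <- names(which(table(cd$sample) >= 2))
  excluded <- list()
  if (length(multiRep) == 0) {
    # no replicate pairs anywhere: no dispersion estimate is possible
    return(list(table = data.frame(), dispersion = numeric(0),
                excluded = data.frame(siteId = rownames(counts),
                                      reason = "no dispersion estimate")))
  }
  ok <- rowSums(counts) > 0
  for (sid in rownames(counts)[!ok])
    excluded[[length(excluded) + 1L]] <- data.frame(siteId = sid,
                                                    reason = "all zero")
  # method-of-moments per-site dispersion from within-sample replicates
  mu <- rowMeans(counts)
  withinVar <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    devs <- unlist(lapply(multiRep, function(s) {
      y <- counts[i, cd$sample == s]
      y - mean(y)
    }))
    nn <- length(devs) - length(multiRep)
    if (nn > 0) withinVar[i] <- sum(devs^2) / nn
  }
  if (all(is.na(withinVar))) {
    for (sid in rownames(counts)[ok])
      excluded[[length(excluded) + 1L]] <-
        data.frame(siteId = sid, reason = "no dispersion estimate")
    return(list(table = data.frame(), dispersion = numeric(0),
                excluded = do.call(rbind, excluded)))
  }
  # theta from var = mu + mu^2/theta, floored; lowess trend on mean
  rawTheta <- ifelse(withinVar > mu, mu^2 / (withinVar - mu), 1e4)
  rawTheta <- pmin(pmax(rawTheta, 0.05), 1e4)
  use <- ok & !is.na(rawTheta) & mu > 0
  trend <- stats::lowess(log(mu[use]), log(rawTheta[use]), f = 0.5)
  thetaTrend <- exp(stats::approx(trend$x, trend$y,
                                  xout = log(pmax(mu, 1e-8)),
                                  rule = 2, ties = mean)$y)
  # moderate toward the pooled median: per-site raw estimates carry almost
  # no degrees of freedom, and a single extreme-mean site would otherwise
  # dominate the trend where it is extrapolated
  thetaTrend <- exp((log(thetaTrend) + log(median(rawTheta[use]))) / 2)
  res <- list()
  hasRep <- nlevels(repl) > 1
  for (i in which(ok)) {
    th <- thetaTrend[i]
    y <- as.integer(counts[i, ])
    fam <- MASS::negative.binomial(theta = th)
    full <- tryCatch(stats::glm(y ~ smp + repl, family = fam),
                     error = function(e) NULL)
    null <- tryCatch(stats::glm(if (hasRep) y ~ repl else y ~ 1,
                                family = fam),
                     error = function(e) NULL)
    if (is.null(full) || is.null(null)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(siteId = rownames(counts)[i], reason = "fit failure")
      next
    }
    stat <- max(0, null$deviance - full$deviance)
    df <- null$df.residual - full$df.residual
    res[[length(res) + 1L]] <- data.frame(
      siteId = rownames(counts)[i], statistic = stat, df = df,
      p = pchisq(stat, df, lower.tail = FALSE))
  }
  tab <- do.call(rbind, res)
  tab$padj <- p.adjust(tab$p, "BH")
  tab$differential <- tab$padj < alpha
  list(table = tab, dispersion = setNames(thetaTrend, rownames(counts)),
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(siteId = character(0),
                                  reason = character(0)))
}

#' Variance-stabilize and standardize occupancy
#'
#' Applies the NB variance-stabilizing map
#' `2 * sqrt(theta) * asinh(sqrt(y / theta))` (inverse-hyperbolic-sine
#' family; variance approximately constant in the mean for
#' `var = mu + mu^2/theta`), then centers each site to mean 0 and sd 1
#' across columns, then averages replicates per sample. Sites with zero
#' variance are dropped with a reason.
#'
#' @param se `SummarizedExperiment` of counts.
#' @param theta per-site dispersion (scalar or named vector, e.g. from
#'   [differentialSites()]).
#' @param samples optional sample subset.
#' @return list with `z` (site x sample matrix of standardized,
#'   replicate-averaged traits), `standardized` (site x column matrix
#'   before averaging), `dropped` (siteId, reason).
#' @export
vstStandardize <- function(se, theta = 10, samples = NULL) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  if (!is.null(samples)) {
    keep <- cd$sample %in% samples
    counts <- counts[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
  }
  th <- if (length(theta) == 1) rep(theta, nrow(counts))
        else theta[rownames(counts)]
  v <- 2 * sqrt(th) * asinh(sqrt(sweep(counts, 1, th, "/")))
  sds <- apply(v, 1, sd)
  dropIds <- rownames(counts)[sds == 0 | is.na(sds)]
  dropped <- data.frame(siteId = dropIds,
                        reason = rep("zero variance", length(dropIds)))
  keepRow <- sds > 0 & !is.na(sds)
  v <- v[keepRow, , drop = FALSE]
  z <- t(scale(t(v)))
  zbar <- t(rowsum(t(z), cd$sample) / as.vector(table(cd$sample)))
  list(z = zbar, standardized = z, dropped = dropped)
}

#' Build sib-pair records for Haseman-Elston regression
#'
#' Squared differences of the standardized, replicate-averaged trait for
#' every sib pair at every site, joined with the truth IBD bin; records
#' whose IBD uncertainty exceeds `maxUncertainty` (default 0.05) are
#' excluded.
#'
#' @param z site x sample trait matrix (rownames = siteId).
#' @param ibd site x pair IBD matrix (siteIdx rows aligned with `siteIdx`).
#' @param pairs sib-pair table from [sibPairs()].
#' @param siteIdx row index into `ibd` for each row of `z`.
#' @param ibdUncertainty matrix like `ibd` (default all zero).
#' @param maxUncertainty exclusion threshold.
#' @return data.frame: siteId, pair, sqDiff, ibd, excluded.
#' @export
sibPairRecords <- function(z, ibd, pairs, siteIdx,
                           ibdUncertainty = NULL, maxUncertainty = 0.05) {
  out <- list()
  for (i in seq_len(nrow(z))) {
    for (k in seq_len(nrow(pairs))) {
      d <- z[i, pairs$sib1[k]] - z[i, pairs$sib2[k]]
      unc <- if (is.null(ibdUncertainty)) 0
             else ibdUncertainty[siteIdx[i], k]
      out[[length(out) + 1L]] <- data.frame(
        siteId = rownames(z)[i], pair = pairs$pair[k],
        sqDiff = d^2, ibd = ibd[siteIdx[i], k],
        excluded = unc > maxUncertainty)
    }
  }
  if (length(out) == 0)
    return(data.frame(siteId = character(0), pair = character(0),
                      sqDiff = numeric(0), ibd = numeric(0),
                      excluded = logical(0)))
  do.call(rbind, out)
}

#' Haseman-Elston regression
#'
#' Ordinary least squares of sib-pair squared trait differences on the
#' IBD bin, pooled across all sites and pairs. A negative slope indicates
#' heritable variation (pairs sharing more ancestry differ less).
#'
#' @param records data.frame from [sibPairRecords()] (excluded rows are
#'   dropped).
#' @return list with `slope`, `intercept`, `n`.
#' @export
heRegress <- function(records) {
  rec <- records[!records$excluded, , drop = FALSE]
  if (length(unique(rec$ibd)) < 2)
    stop("undefined slope: a single IBD bin is present")
  fit <- lm(sqDiff ~ ibd, data = rec)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = nrow(rec))
}

#' Permutation p-value for the Haseman-Elston slope
#'
#' Permutes whole per-site IBD vectors onto per-site squared-difference
#' vectors (keeping all pair values of a site together, preserving the
#' correlation structure among pairs), recomputes the slope, and reports
#' the one-sided add-one estimate
#' `p = (1 + #\{slope_perm <= slope_obs\}) / (nPerm + 1)` for the
#' heritability (negative-slope) direction.
#'
#' @param records data.frame from [sibPairRecords()].
#' @param nPerm number of permutations (warns below 100).
#' @param withReplacement sample site assignments with replacement
#'   instead of permuting (default FALSE).
#' @return list with `p`, `observed`, `permSlopes`.
#' @export
permutationPvalue <- function(records, nPerm = 1000,
                              withReplacement = FALSE) {
  if (nPerm < 100) warning("fewer than 100 permutations")
  sites <- unique(records$siteId)
  if (length(sites) < 2) stop("need >= 2 sites to permute")
  obs <- heRegress(records)$slope
  # site x pair matrices aligned by pair id; excluded records become NA
  pairsU <- unique(records$pair)
  sqMat <- matrix(NA_real_, length(sites), length(pairsU),
                  dimnames = list(sites, pairsU))
  ibdMat <- sqMat
  ok <- !records$excluded
  sqMat[cbind(match(records$siteId[ok], sites),
              match(records$pair[ok], pairsU))] <- records$sqDiff[ok]
  ibdMat[cbind(match(records$siteId[ok], sites),
               match(records$pair[ok], pairsU))] <- records$ibd[ok]
  slopeOf <- function(x, y) {
    use <- !is.na(x) & !is.na(y)
    x <- x[use]; y <- y[use]
    if (length(unique(x)) < 2) return(NA_real_)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  perm <- numeric(nPerm)
  n <- length(sites)
  for (b in seq_len(nPerm)) {
    idx <- if (withReplacement) sample(n, n, replace = TRUE) else sample(n)
    perm[b] <- slopeOf(as.vector(ibdMat[idx, ]), as.vector(sqMat))
  }
  list(p = (1 + sum(perm <= obs, na.rm = TRUE)) / (nPerm + 1),
       observed = obs, permSlopes = perm)
}
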