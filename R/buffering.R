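#' Per-substitution effect grid
#'
#' Tabulates, for each motif-relative position and unordered allele pair,
#' how many SNPs were observed and what proportion significantly affected
#' occupancy. Cells observed at fewer than `minObs` sites are suppressed.
#'
#' @param position motif-relative position per SNP.
#' @param alleleA,alleleB the SNP alleles per SNP.
#' @param significant logical per SNP (at the chosen FDR).
#' @param minObs minimum observations per cell (default 3).
#' @return data.frame: position, pair, nObserved, nSignificant,
#'   proportion; plus attribute `nTotal` (all analyzed SNPs, before cell
#'   suppression).
#' @export
substitutionTable <- function(position, alleleA, alleleB, significant,
                              minObs = 3) {
  pair <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "/"),
                 alleleA, alleleB)
  key <- paste(position, pair)
  agg <- aggregate(significant, by = list(key = key), FUN = function(v)
    c(n = length(v), sig = sum(v)))
  tab <- data.frame(key = agg$key,
                    nObserved = agg$x[, "n"],
                    nSignificant = agg$x[, "sig"])
  parts <- strsplit(tab$key, " ")
  tab$position <- as.integer(vapply(parts, `[`, character(1), 1))
  tab$pair <- vapply(parts, `[`, character(1), 2)
  tab$proportion <- tab$nSignificant / tab$nObserved
  nTotal <- length(position)
  tab <- tab[tab$nObserved >= minObs,
             c("position", "pair", "nObserved", "nSignificant",
               "proportion")]
  tab <- tab[order(tab$position, tab$pair), ]
  rownames(tab) <- NULL
  attr(tab, "nTotal") <- nTotal
  tab
}

#' Proportion of significant SNPs per occupancy decile
#'
#' Sites are ranked by the fitted heterozygote signal from the
#' association model and cut into equal-count deciles (ties and
#' remainders resolved by stable input order); the per-decile proportion
#' of significant SNPs traces the strength-dependent buffering curve.
#'
#' @param signalHet fitted heterozygote signal per site.
#' @param significant logical per site.
#' @param nBins number of bins (default 10).
#' @return data.frame: decile, n, nSignificant, proportion, meanSignal.
#' @export
decileCurve <- function(signalHet, significant, nBins = 10) {
  n <- length(signalHet)
  if (n < nBins) stop(sprintf("need >= %d sites for %d bins", nBins, nBins))
  ord <- order(signalHet)   # stable for ties
  sizes <- diff(round(seq(0, n, length.out = nBins + 1)))
  bin <- rep(seq_len(nBins), sizes)[order(ord)]
  out <- data.frame(decile = seq_len(nBins))
  out$n <- as.vector(table(bin))
  out$nSignificant <- vapply(seq_len(nBins), function(b)
    sum(significant[bin == b]), numeric(1))
  out$proportion <- out$nSignificant / out$n
  out$meanSignal <- vapply(seq_len(nBins), function(b)
    mean(signalHet[bin == b]), numeric(1))
  out
}

#' Perturbation magnitude vs motif strength
#'
#' Bins SNPs by the log-odds score of their site's motif match and
#' summarizes the allele log-odds delta among significant SNPs (mean and
#' sd per bin), with the parallel table for non-significant SNPs and a
#' linear trend test of delta on match score in each stratum.
#'
#' @param matchScore motif match score per SNP.
#' @param delta allele log-odds delta per SNP.
#' @param significant logical per SNP.
#' @param nBins number of equal-width score bins (default 6).
#' @return list with `significant` and `nonSignificant` bin tables
#'   (empty bins suppressed) and `trend`/`trendNonSig` (slope, p).
#' @export
strengthVsPerturbation <- function(matchScore, delta, significant,
                                   nBins = 6) {
  ok <- !is.na(matchScore) & !is.na(delta) & !is.na(significant)
  matchScore <- matchScore[ok]; delta <- delta[ok]
  significant <- significant[ok]
  if (length(matchScore) == 0) stop("no scored SNPs to bin")
  breaks <- seq(min(matchScore), max(matchScore), length.out = nBins + 1)
  breaks[1] <- breaks[1] - 1e-9
  binOf <- cut(matchScore, breaks, labels = FALSE)
  mkTab <- function(sel) {
    out <- lapply(seq_len(nBins), function(b) {
      v <- delta[sel & binOf == b]
      if (length(v) == 0) return(NULL)  # empty bin suppressed
      data.frame(bin = b, lower = breaks[b], n = length(v),
                 meanDelta = mean(v), sdDelta = sd(v))
    })
    do.call(rbind, out)
  }
  trendOf <- function(sel) {
    if (sum(sel) < 3 || length(unique(matchScore[sel])) < 2 ||
        var(delta[sel]) == 0)
      return(list(slope = 0, p = 1))
    fit <- summary(lm(delta[sel] ~ matchScore[sel]))
    list(slope = fit$coefficients[2, 1], p = fit$coefficients[2, 4])
  }
  list(significant = mkTab(significant),
       nonSignificant = mkTab(!significant),
       trend = trendOf(significant),
       trendNonSig = trendOf(!significant))
}

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Plug-in mutual information (bits)
#'
#' @param x,y categorical vectors of equal length.
#' @return MI in bits.
#' @export
miPlugin <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  -sum(plogp(px)) - sum(plogp(py)) + sum(plogp(p))
}

#' Mutual-information context dependence
#'
#' For SNPs at each core motif position k, measures the mutual information
#' between the base identity at every other core position j and whether
#' the SNP affects occupancy, with a resampling null: the affected flags
#' are permuted among the row's sites and
#' `p = (1 + #\{MI_null >= MI_obs\}) / (nBoot + 1)`; q-values are computed
#' across all pairs. Rows with fewer than `minRow` SNPs are suppressed.
#'
#' @param coreSeqs strand-oriented core sequences (width bp each).
#' @param snpPosition 0-based core position of each site's SNP.
#' @param affected logical per site.
#' @param nBoot resampling iterations (default 2000).
#' @param minRow minimum SNPs per row (default 5).
#' @param width motif width (default 14).
#' @param collapseConsensus if TRUE, context bases are collapsed to
#'   consensus/non-consensus using `consensus`.
#' @param consensus consensus sequence (required when collapsing).
#' @return data.frame: snpPosition (k), contextPosition (j), n, mi, p, q.
#' @export
mutualInfoContext <- function(coreSeqs, snpPosition, affected,
                              nBoot = 2000, minRow = 5, width = 14,
                              collapseConsensus = FALSE, consensus = NULL) {
  codes <- t(vapply(coreSeqs, function(s)
    match(strsplit(s, "")[[1]], DNA_BASES), integer(width)))
  if (collapseConsensus) {
    if (is.null(consensus)) stop("consensus required for collapsing")
    cc <- match(strsplit(consensus, "")[[1]], DNA_BASES)
    codes <- 1L + (codes != matrix(cc, nrow(codes), width, byrow = TRUE))
  }
  nCat <- if (collapseConsensus) 2L else 4L
  out <- list()
  for (k in 0:(width - 1)) {
    rows <- which(snpPosition == k)
    if (length(rows) < minRow) next
    # canonical within-row order: results do not depend on input order
    rows <- rows[order(coreSeqs[rows], affected[rows])]
    f <- as.numeric(affected[rows])
    n <- length(rows)
    n1 <- sum(f)
    if (n1 == 0 || n1 == n) next  # flag entropy zero: MI identically 0
    Fp <- matrix(0, n, nBoot)
    for (b in seq_len(nBoot)) Fp[, b] <- sample(f)
    hFlag <- -plogp(n1 / n) - plogp(1 - n1 / n)
    for (j in setdiff(0:(width - 1), k)) {
      cj <- codes[rows, j + 1]
      X <- matrix(0, nCat, n)
      X[cbind(cj, seq_len(n))] <- 1
      tot <- rowSums(X)
      hBase <- -sum(plogp(tot / n))
      miOf <- function(c1) {
        c0 <- tot - c1
        hJoint <- -(colSums(plogp(c1 / n)) + colSums(plogp(c0 / n)))
        hBase + hFlag - hJoint
      }
      miObs <- miOf(matrix(X %*% f, nCat, 1))
      miNull <- miOf(X %*% Fp)
      out[[length(out) + 1L]] <- data.frame(
        snpPosition = k, contextPosition = j, n = n, mi = miObs,
        p = (1 + sum(miNull >= miObs - 1e-12)) / (nBoot + 1))
    }
  }
  tab <- do.call(rbind, out)
  if (!is.null(tab) && nrow(tab) > 0) tab$q <- estimateFdr(tab$p, "storey")
  tab
}

#' Cluster site occupancy profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage) of standardized occupancy profiles, cut at `k` clusters, with
#' per-cluster mean intensity and significant-SNP proportion.
#'
#' @param z site x sample standardized occupancy matrix.
#' @param k number of clusters (default 3).
#' @param intensity optional per-site overall intensity (e.g. mean raw
#'   occupancy) summarized per cluster.
#' @param significant optional logical per site.
#' @return list with `labels` (named by siteId) and `summary`.
#' @export
clusterOccupancy <- function(z, k = 3, intensity = NULL,
                             significant = NULL) {
  if (k > nrow(z)) stop("k exceeds the number of sites")
  hc <- hclust(dist(z), method = "ward.D2")
  labels <- cutree(hc, k = k)
  summ <- data.frame(cluster = seq_len(k),
                     n = as.vector(table(factor(labels, levels = 1:k))))
  if (!is.null(intensity))
    summ$meanIntensity <- vapply(seq_len(k), function(c)
      mean(intensity[labels == c]), numeric(1))
  if (!is.null(significant))
    summ$fracSignificant <- vapply(seq_len(k), function(c)
      mean(significant[labels == c]), numeric(1))
  list(labels = setNames(labels, rownames(z)), summary = summ)
}
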