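#' ROC curve and AUC
#'
#' Ranks predictions by descending score with tie-grouping (tied scores
#' advance the curve diagonally, i.e. trapezoidal ROC) and integrates the
#' area under the curve; the AUC equals the Mann-Whitney U statistic
#' normalized by `nPos * nNeg`, with ties counting one half.
#'
#' @param score numeric predictions (higher = predicted more disruptive).
#' @param label logical or 0/1 outcome (TRUE = affected).
#' @return list with `roc` (data.frame cutoff, tpr, fpr) and `auc`.
#'   Single-class labels raise an error.
#' @export
rocAuc <- function(score, label) {
  label <- as.logical(label)
  nPos <- sum(label); nNeg <- sum(!label)
  if (nPos == 0 || nNeg == 0)
    stop("AUC undefined: both labels must be present")
  cuts <- sort(unique(score), decreasing = TRUE)
  tp <- vapply(cuts, function(c) sum(label & score >= c), numeric(1))
  fp <- vapply(cuts, function(c) sum(!label & score >= c), numeric(1))
  roc <- data.frame(cutoff = c(Inf, cuts), tpr = c(0, tp) / nPos,
                    fpr = c(0, fp) / nNeg)
  # trapezoidal integration over the tie-grouped curve
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Mann-Whitney normalized U (rank-based AUC)
#'
#' Independent rank-sum computation of the AUC used for cross-checking
#' the ROC integral: `U / (nPos * nNeg)` with midranks for ties.
#'
#' @inheritParams rocAuc
#' @return normalized U in \[0, 1\].
#' @export
aucMannWhitney <- function(score, label) {
  label <- as.logical(label)
  r <- rank(score)
  nPos <- sum(label); nNeg <- sum(!label)
  if (nPos == 0 || nNeg == 0) stop("both labels must be present")
  (sum(r[label]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Positive predictive value over a cutoff grid
#'
#' `PPV(c) = TP / (TP + FP)` among SNPs with score >= c. Cutoffs above
#' the maximum score (no predictions) are suppressed.
#'
#' @inheritParams rocAuc
#' @param cutoffs numeric cutoff grid (default: the observed scores).
#' @return data.frame: cutoff, nPredicted, ppv.
#' @export
ppvCurve <- function(score, label, cutoffs = NULL) {
  label <- as.logical(label)
  if (is.null(cutoffs)) cutoffs <- sort(unique(score))
  out <- lapply(cutoffs, function(c) {
    pred <- score >= c
    if (!any(pred)) return(NULL)  # undefined PPV: suppressed point
    data.frame(cutoff = c, nPredicted = sum(pred),
               ppv = sum(label & pred) / sum(pred))
  })
  do.call(rbind, out)
}

#' Compare two predictors on the same reference set
#'
#' AUCs of the allele log-odds delta and a conservation-like score on an
#' identical SNP reference set, with a bootstrap confidence interval on
#' the AUC difference (SNP-level resampling).
#'
#' @param conservation,delta scores per SNP (same length and order).
#' @param label logical outcome per SNP.
#' @param nBoot bootstrap replicates (default 200; 0 skips the CI).
#' @return list with `aucDelta`, `aucConservation`, `difference`, `ci`.
#' @export
comparePredictors <- function(conservation, delta, label, nBoot = 200) {
  if (length(conservation) != length(delta) ||
      length(delta) != length(label))
    stop("predictors and labels must cover the same SNP set")
  aucC <- rocAuc(conservation, label)$auc
  aucD <- rocAuc(delta, label)$auc
  ci <- NULL
  if (nBoot > 0) {
    n <- length(label)
    diffs <- vapply(seq_len(nBoot), function(b) {
      ix <- sample(n, n, replace = TRUE)
      if (length(unique(label[ix])) < 2) return(NA_real_)
      rocAuc(delta[ix], label[ix])$auc -
        rocAuc(conservation[ix], label[ix])$auc
    }, numeric(1))
    ci <- quantile(diffs, c(0.025, 0.975), na.rm = TRUE)
  }
  list(aucDelta = aucD, aucConservation = aucC,
       difference = aucD - aucC, ci = ci)
}
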