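# Independent oracles used across the suite. Each is deliberately naive
# (enumeration / brute force) and shares no code with the implementation.

# exact tail probability by enumerating all 4^w sequences
enumPvalue <- function(pwm, threshold) {
  lo <- pwm@logodds
  bg <- pwm@background
  w <- nrow(lo)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    sc <- sc + lo[j, grid[, j]]
    pr <- pr * bg[grid[, j]]
  }
  list(p = sum(pr[sc >= threshold]), scores = sc, probs = pr)
}

randomPWM <- function(w, concentrated = FALSE) {
  f <- matrix(stats::rgamma(4 * w, if (concentrated) 0.4 else 1), w, 4)
  f <- f / rowSums(f)
  buildPWM(f)
}

# naive per-bin overlap counting
bruteDensity <- function(tags, starts, window) {
  vapply(starts, function(b) {
    if (nrow(tags) == 0) return(0)
    sum(tags$start < b + window & tags$end > b)
  }, numeric(1))
}

# Punnett-square trio transmission oracle (0/1/2 copies of one allele)
trioOracleTable <- function() {
  gam <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  out <- expand.grid(father = 0:2, mother = 0:2, child = 0:2)
  out$possible <- mapply(function(f, m, c)
    c %in% (rep(gam[[as.character(f)]],
                each = length(gam[[as.character(m)]])) +
              gam[[as.character(m)]]),
    out$father, out$mother, out$child)
  out
}

# pairwise-comparison AUC oracle (slow O(n^2))
aucPairwise <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# hand plug-in MI for a 2x2 contingency table of counts
miHand2x2 <- function(n11, n12, n21, n22) {
  n <- n11 + n12 + n21 + n22
  p <- c(n11, n12, n21, n22) / n
  px <- c(p[1] + p[2], p[3] + p[4])
  py <- c(p[1] + p[3], p[2] + p[4])
  ent <- function(v) -sum(ifelse(v > 0, v * log2(v), 0))
  ent(px) + ent(py) - ent(p)
}

# tiny pileup row builder
pileupRow <- function(snpId, sample, nA = 0, nC = 0, nG = 0, nT = 0,
                      quality = 40) {
  S4Vectors::DataFrame(snpId = snpId, sample = sample, nA = nA, nC = nC,
                       nG = nG, nT = nT, depth = nA + nC + nG + nT,
                       quality = quality)
}
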