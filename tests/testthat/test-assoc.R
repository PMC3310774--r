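test_that("NB genotype regression handles degenerate and clean signals", {
  g <- rep(c(0, 1, 2, 0, 1, 2), each = 2)
  repl <- rep(c("a", "b"), 6)

  # identical counts across genotypes: no signal
  fit0 <- fitNbGenotype(rep(20L, 12), g, repl)
  expect_lt(abs(fit0$beta), 1e-6)
  expect_gt(fit0$p, 0.9)

  # a clear multiplicative effect recovers the right sign and magnitude
  set.seed(51)
  mu <- 50 * 2^(g / 2)
  y <- rnbinom(12, size = 50, mu = mu)
  fit1 <- fitNbGenotype(y, g, repl, models = "additive")
  expect_gt(fit1$beta, 0)
  expect_lt(fit1$p, 0.01)
  expect_equal(fit1$beta, log(2) / 2, tolerance = 0.35)
  expect_true(fit1$r2 >= 0 && fit1$r2 <= 1)
  expect_error(fitNbGenotype(c(-1, 2, 3), c(0, 1, 2)), "non-negative")
})

test_that("swapping allele labels negates beta and preserves p", {
  set.seed(52)
  g <- rep(c(0, 0, 0, 1, 1, 1, 2, 2, 2, 1, 0, 2), 2)
  repl <- rep(c("a", "b"), each = 12)
  y <- rnbinom(24, size = 10, mu = 50 * 1.5^(g / 2))
  f1 <- fitNbGenotype(y, g, repl, models = "additive")
  f2 <- fitNbGenotype(y, 2 - g, repl, models = "additive")
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
})

test_that("AIC prefers the dominant model on dominance-generated data", {
  set.seed(53)
  wins <- 0
  n <- 60
  for (i in seq_len(n)) {
    g <- rep(c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2), 2)
    mu <- 40 * ifelse(g >= 1, 2.5, 1)   # pure dominance of allele B
    y <- rnbinom(length(g), size = 10, mu = mu)
    fit <- fitNbGenotype(y, g, rep(c("a", "b"), each = 12))
    if (fit$model %in% c("dominantA", "dominantB")) wins <- wins + 1
  }
  expect_gt(wins / n, 0.5)
})

test_that("FDR estimation: BH by hand, Storey pi0 on null input, monotonicity", {
  expect_equal(estimateFdr(c(1, 1, 1), "bh"), c(1, 1, 1))
  expect_equal(estimateFdr(c(0.001, 0.02, 0.9), "bh"),
               c(0.003, 0.03, 0.9))
  expect_equal(estimateFdr(numeric(0)), numeric(0))
  expect_error(estimateFdr(c(0.5, 1.2)), "0, 1")

  set.seed(54)
  p <- runif(10000)
  q <- estimateFdr(p, "storey")
  # pi0-hat recoverable as q/BH ratio: near 1 on uniform p
  qbh <- estimateFdr(p, "bh")
  pi0 <- median(q / qbh, na.rm = TRUE)
  expect_gt(pi0, 0.9)
  expect_lte(pi0, 1.1)
  # monotone in p for both methods
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(diff(qbh[o]) >= -1e-12))
})

test_that("testability rules produce the stated exclusion reasons", {
  ids <- sprintf("GM%02d", 1:12)
  snps <- data.frame(snpId = c("s1", "s2", "s3"),
                     siteId = c("site1", "site2", "site3"),
                     siteIdx = 1:3)
  g <- matrix(NA_integer_, 12, 3, dimnames = list(ids, snps$snpId))
  g[, "s1"] <- c(rep(0L, 5), rep(1L, 4), rep(2L, 3))     # classes 5/4/3
  g[, "s2"] <- c(rep(0L, 10), 1L, 2L)                    # classes 10/1/1
  g[, "s3"] <- c(rep(0L, 6), rep(1L, 6))
  cov <- matrix(20L, 12, 3, dimnames = list(ids, snps$snpId))
  cov[6:12, "s3"] <- 0L                                  # coverage in 5 only
  nReps <- setNames(rep(2L, 12), ids)
  sel <- selectTestable(snps, g, cov, nReps)
  expect_equal(sel$testable$snpId, "s1")
  expect_equal(sel$exclusions$reason[sel$exclusions$snpId == "s2"],
               "genotype-class minimum")
  expect_equal(sel$exclusions$reason[sel$exclusions$snpId == "s3"],
               "coverage")

  # mappability failure short-circuits
  mp <- data.frame(siteId = "site1", pass = FALSE,
                   alleleDifferential = FALSE)
  sel2 <- selectTestable(snps, g, cov, nReps, mappability = mp)
  expect_equal(sel2$exclusions$reason[sel2$exclusions$snpId == "s1"],
               "mappability")
})

test_that("multi-SNP windows resolve by data points then contact region", {
  ids <- sprintf("GM%02d", 1:12)
  snps <- data.frame(snpId = c("a", "b"), siteId = "site1", siteIdx = 1L)
  g <- matrix(c(rep(0L, 4), rep(1L, 4), rep(2L, 4),
                rep(0L, 4), rep(1L, 4), rep(2L, 2), NA, NA), 12, 2,
              dimnames = list(ids, c("a", "b")))
  cov <- matrix(20L, 12, 2, dimnames = list(ids, c("a", "b")))
  nReps <- setNames(rep(2L, 12), ids)
  sel <- selectTestable(snps, g, cov, nReps,
                        contactFlag = c(FALSE, TRUE))
  # SNP a has more data points and wins despite b being in the contact region
  expect_equal(sel$testable$snpId, "a")
  expect_equal(sel$exclusions$reason[sel$exclusions$snpId == "b"],
               "multi-SNP window")

  # equal data points: the contact-region SNP wins
  g2 <- g; g2[, "b"] <- g[, "a"]
  sel2 <- selectTestable(snps, g2, cov, nReps,
                         contactFlag = c(FALSE, TRUE))
  expect_equal(sel2$testable$snpId, "b")
})

test_that("classification summarizes concordance against motif annotation", {
  results <- data.frame(snpId = c("a", "b", "c"), siteId = 1:3,
                        q = c(0.001, 0.5, 0.002),
                        higherOccAllele = c("G", "A", "T"),
                        beta = 1)
  annot <- data.frame(snpId = c("a", "b", "c"),
                      obsInContact = c(TRUE, TRUE, FALSE),
                      favored = c("G", "A", "C"))
  cls <- classifyResults(results, annot, fdr = 0.01)
  expect_equal(cls$nSignificant, 2)
  expect_equal(cls$nSigInContact, 1)
  expect_equal(cls$concordanceFraction, 1)  # only "a" is in-contact+favored
})
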