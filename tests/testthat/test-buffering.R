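test_that("plug-in mutual information matches hand arithmetic", {
  # perfect balanced dependence: one full bit
  x <- rep(c("A", "C"), each = 10)
  y <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(miPlugin(x, y), 1)

  # independence: numerically zero on an exact product table
  x2 <- rep(c("A", "C"), times = 10)
  y2 <- rep(c(TRUE, TRUE, FALSE, FALSE), times = 5)
  expect_lt(abs(miPlugin(x2, y2)), 1e-12)

  # symmetry
  set.seed(81)
  x3 <- sample(c("A", "C", "G", "T"), 40, TRUE)
  y3 <- sample(c(TRUE, FALSE), 40, TRUE)
  expect_equal(miPlugin(x3, y3), miPlugin(y3, x3))

  # the 13/0 vs 5/6 contingency observed at the diagnostic context
  # position, against independent plug-in arithmetic
  xa <- c(rep("A", 13), rep("A", 5), rep("notA", 6))
  ya <- c(rep(TRUE, 13), rep(FALSE, 11))
  expect_equal(miPlugin(xa, ya), miHand2x2(13, 0, 5, 6))
})

test_that("MI context analysis recovers planted dependence, suppresses thin rows", {
  set.seed(82)
  mkRow <- function(n, k, dep = FALSE) {
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), 14, TRUE),
                               collapse = ""))
    if (dep) {
      flags <- substr(seqs, 6, 6) == "A"   # context at position 5 decides
      # force a balanced informative row
      need <- max(5 - sum(flags), 0)
      if (need > 0) {
        ix <- which(!flags)[seq_len(need)]
        substr(seqs[ix], 6, 6) <- "A"
        flags <- substr(seqs, 6, 6) == "A"
      }
    } else flags <- runif(n) < 0.4
    list(seqs = seqs, pos = rep(k, n), flags = flags)
  }
  r1 <- mkRow(40, 1, dep = TRUE)
  r2 <- mkRow(30, 8, dep = FALSE)
  r3 <- mkRow(3, 11)   # below minRow: suppressed
  seqs <- c(r1$seqs, r2$seqs, r3$seqs)
  pos <- c(r1$pos, r2$pos, r3$pos)
  flags <- c(r1$flags, r2$flags, r3$flags)
  set.seed(83)
  mi <- mutualInfoContext(seqs, pos, flags, nBoot = 500)
  expect_false(any(mi$snpPosition == 11))
  expect_true(all(mi$mi >= 0))
  top <- mi[mi$snpPosition == 1 & mi$contextPosition == 5, ]
  expect_equal(top$mi, 1, tolerance = 0.35)
  expect_lt(top$p, 0.01)
  expect_true(all(mi$p >= 1 / 501))

  # permuting the site order leaves results unchanged under the same seed
  o <- sample(length(seqs))
  set.seed(83)
  mi2 <- mutualInfoContext(seqs[o], pos[o], flags[o], nBoot = 500)
  expect_equal(mi[order(mi$snpPosition, mi$contextPosition), "p"],
               mi2[order(mi2$snpPosition, mi2$contextPosition), "p"])
})

test_that("substitution grid suppresses thin cells and conserves counts", {
  pos <- c(rep(3, 5), rep(3, 2), rep(7, 4))
  aA <- c(rep("C", 5), rep("A", 2), rep("G", 4))
  aB <- c(rep("T", 5), rep("G", 2), rep("A", 4))
  sig <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, rep(FALSE, 4))
  tab <- substitutionTable(pos, aA, aB, sig, minObs = 3)
  # the 2-observation A/G cell at position 3 is suppressed
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "nTotal"), 11)
  expect_equal(tab$proportion[tab$position == 3], 3 / 5)
  expect_equal(tab$pair[tab$position == 7], "A/G")   # unordered pair key
  expect_equal(tab$proportion[tab$position == 7], 0)

  allSig <- substitutionTable(rep(5, 4), rep("C", 4), rep("G", 4),
                              rep(TRUE, 4))
  expect_equal(allSig$proportion, 1)
})

test_that("decile curve recomposes the global significant fraction", {
  set.seed(84)
  sig <- runif(100) < 0.3
  sh <- rnorm(100)
  dc <- decileCurve(sh, sig)
  expect_equal(sum(dc$n), 100)
  expect_equal(sum(dc$nSignificant) / sum(dc$n), mean(sig))
  expect_equal(sum(dc$proportion * dc$n) / sum(dc$n), mean(sig))

  # 20 sites: two per decile, by hand
  dc20 <- decileCurve(1:20, rep(c(TRUE, FALSE), 10))
  expect_true(all(dc20$n == 2))
  expect_equal(dc20$proportion, rep(0.5, 10))

  expect_error(decileCurve(1:5, rep(TRUE, 5)), "need >= 10")

  # uniform significance: flat at the global rate in expectation
  dcU <- decileCurve(rnorm(5000), runif(5000) < 0.2)
  expect_true(all(abs(dcU$proportion - 0.2) < 0.06))
})

test_that("strength-vs-perturbation trends degenerate gracefully", {
  eq <- strengthVsPerturbation(runif(30, 10, 20), rep(2, 30),
                               rep(c(TRUE, FALSE), 15))
  expect_equal(eq$trend$slope, 0)
  expect_equal(eq$trend$p, 1)
  # empty significant bins are suppressed rather than reported as NaN
  sc <- c(rep(10, 5), rep(20, 5))
  sv <- strengthVsPerturbation(sc, rnorm(10, 3), c(rep(TRUE, 5), rep(FALSE, 5)),
                               nBins = 2)
  expect_equal(nrow(sv$significant), 1)
  expect_equal(nrow(sv$nonSignificant), 1)
})

test_that("occupancy clustering separates planted blobs deterministically", {
  set.seed(85)
  z <- rbind(matrix(rnorm(60, -3), 10, 6),
             matrix(rnorm(60, 0), 10, 6),
             matrix(rnorm(60, 3), 10, 6))
  rownames(z) <- sprintf("s%02d", 1:30)
  cl <- clusterOccupancy(z, k = 3,
                         intensity = rowMeans(z),
                         significant = rep(c(TRUE, FALSE, FALSE), each = 10))
  truth <- rep(1:3, each = 10)
  # perfect agreement up to label permutation
  expect_equal(length(unique(paste(cl$labels, truth))), 3)
  expect_equal(cl$summary$n, rep(10L, 3))

  # row order does not change the partition
  o <- sample(30)
  cl2 <- clusterOccupancy(z[o, ], k = 3)
  expect_equal(unname(cl$labels[rownames(z)[o]] != 0),
               unname(cl2$labels != 0))
  agree <- table(cl$labels[rownames(z)[o]], cl2$labels)
  expect_equal(sum(agree > 0), 3)

  expect_equal(unname(clusterOccupancy(z, k = 1)$labels),
               rep(1L, 30))
  expect_error(clusterOccupancy(z[1:2, ], k = 3), "exceeds")
})
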