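mkRecords <- function(sq, ibd, sites = NULL, pairs = NULL) {
  n <- length(sq)
  if (is.null(sites)) sites <- sprintf("site%03d", seq_len(n))
  if (is.null(pairs)) pairs <- sprintf("p%03d", seq_len(n))
  data.frame(siteId = sites, pair = pairs, sqDiff = sq, ibd = ibd,
             excluded = FALSE)
}

test_that("Haseman-Elston regression on hand-solvable inputs", {
  rec <- mkRecords(c(4, 2, 0), c(0, 0.5, 1))
  fit <- heRegress(rec)
  expect_equal(fit$slope, -4)
  expect_equal(fit$intercept, 4)

  recC <- mkRecords(rep(3, 6), rep(c(0, 0.5, 1), 2))
  expect_equal(heRegress(recC)$slope, 0)

  expect_error(heRegress(mkRecords(c(1, 2), c(0.5, 0.5))), "single IBD bin")

  # invariance to record ordering
  set.seed(71)
  rec2 <- mkRecords(runif(30), sample(c(0, 0.5, 1), 30, TRUE))
  perm <- rec2[sample(30), ]
  expect_equal(heRegress(rec2)$slope, heRegress(perm)$slope)

  # excluded records (IBD uncertainty above threshold) are dropped
  rec3 <- rbind(mkRecords(c(4, 2, 0), c(0, 0.5, 1)),
                cbind(mkRecords(100, 1)[, 1:4], excluded = TRUE))
  expect_equal(heRegress(rec3)$slope, -4)
})

test_that("variance stabilization standardizes and flags degenerate sites", {
  set.seed(72)
  mu <- rep(c(10, 20, 40, 80, 100), each = 40)
  counts <- matrix(rnbinom(200 * 12, size = 10, mu = mu), 200, 12)
  counts[7, ] <- 5   # constant site
  rownames(counts) <- sprintf("site%03d", 1:200)
  colnames(counts) <- paste0(rep(sprintf("GM%02d", 1:6), each = 2),
                             ".", c("a", "b"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      sample = rep(sprintf("GM%02d", 1:6), each = 2),
      replicate = rep(c("a", "b"), 6), row.names = colnames(counts)))
  v <- vstStandardize(se, theta = 10)
  expect_true("site007" %in% v$dropped$siteId)
  expect_true(all(abs(rowMeans(v$standardized)) < 1e-9))
  sds <- apply(v$standardized, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-9))
  # replicates averaged afterwards: one column per sample
  expect_equal(ncol(v$z), 6)

  # stabilization: transformed variance varies < 2-fold across a 10x
  # range of means (before per-site standardization)
  th <- 10
  raw <- lapply(c(10, 20, 40, 80, 100), function(m)
    2 * sqrt(th) * asinh(sqrt(rnbinom(4000, size = th, mu = m) / th)))
  vr <- vapply(raw, var, numeric(1))
  expect_lt(max(vr) / min(vr), 2)
})

test_that("permutation p honors the add-one bound and the null is calibrated", {
  set.seed(73)
  # trait fully determined by shared inheritance: extreme permutation p
  ped <- threeGenPedigree()
  sim <- simulatePedigree(ped, seq(1, 3e7, length.out = 40),
                          recombRate = 3e-7)
  pairs <- sim$pairs
  sibs <- pedigreeSibs(ped)
  eff <- matrix(rnorm(8 * 40, sd = 2), 8, 40)
  trait <- sapply(seq_len(40), function(s)
    eff[sim$haplotypes[sibs, s, 1], s] + eff[sim$haplotypes[sibs, s, 2], s])
  rownames(trait) <- sibs
  rec <- do.call(rbind, lapply(seq_len(40), function(s) {
    d <- trait[pairs$sib1, s] - trait[pairs$sib2, s]
    mkRecords(d^2, sim$ibd[s, ], sites = sprintf("site%03d", s),
              pairs = pairs$pair)
  }))
  out <- permutationPvalue(rec, nPerm = 500)
  expect_lt(out$observed, 0)
  expect_gte(out$p, 1 / 501)
  expect_lte(out$p, 0.01)

  # no heritability: p roughly uniform over repeated datasets
  ps <- replicate(30, {
    simN <- simulatePedigree(ped, seq(1, 3e7, length.out = 12),
                             recombRate = 3e-7)
    tr <- matrix(rnorm(6 * 12), 6, 12, dimnames = list(sibs, NULL))
    recN <- do.call(rbind, lapply(seq_len(12), function(s) {
      d <- tr[pairs$sib1, s] - tr[pairs$sib2, s]
      mkRecords(d^2, simN$ibd[s, ], sites = sprintf("site%03d", s),
                pairs = pairs$pair)
    }))
    suppressWarnings(permutationPvalue(recN, nPerm = 99)$p)
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)

  expect_warning(permutationPvalue(rec, nPerm = 50), "100")
  expect_error(permutationPvalue(rec[rec$siteId == "site001", ], 100),
               ">= 2 sites")
})

test_that("differential site detection is calibrated and powered", {
  mkSe <- function(counts) {
    colnames(counts) <- paste0(rep(sprintf("GM%02d", 1:6), each = 2),
                               ".", c("a", "b"))
    rownames(counts) <- sprintf("site%03d", seq_len(nrow(counts)))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        sample = rep(sprintf("GM%02d", 1:6), each = 2),
        replicate = rep(c("a", "b"), 6), row.names = colnames(counts)))
  }
  set.seed(74)
  # null: discovery rate near the nominal level before adjustment
  y0 <- matrix(rnbinom(400 * 12, size = 10, mu = 50), 400, 12)
  ds0 <- differentialSites(mkSe(y0))
  expect_lt(mean(ds0$table$p < 0.05), 0.12)
  expect_equal(sum(ds0$table$differential), 0)

  # one sample shifted 4-fold: detected nearly always
  hits <- 0
  for (i in 1:25) {
    y1 <- matrix(rnbinom(20 * 12, size = 10, mu = 50), 20, 12)
    y1[1, 1:2] <- rnbinom(2, size = 10, mu = 200)
    ds1 <- differentialSites(mkSe(y1))
    if (ds1$table$differential[ds1$table$siteId == "site001"])
      hits <- hits + 1
  }
  expect_gte(hits / 25, 0.9)

  # all-zero rows and replicate-free designs are excluded with reasons
  y2 <- matrix(rnbinom(5 * 12, size = 10, mu = 50), 5, 12)
  y2[3, ] <- 0
  ds2 <- differentialSites(mkSe(y2))
  expect_true("site003" %in% ds2$excluded$siteId)

  cn <- sprintf("GM%02d.a", 1:6)
  y3 <- matrix(rnbinom(12, size = 10, mu = 50), 2, 6,
               dimnames = list(c("site001", "site002"), cn))
  se3 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = y3),
    colData = S4Vectors::DataFrame(sample = sprintf("GM%02d", 1:6),
                                   replicate = "a", row.names = cn))
  ds3 <- differentialSites(se3)
  expect_equal(unique(ds3$excluded$reason), "no dispersion estimate")
  expect_equal(nrow(ds3$table), 0)
})

test_that("sib-pair records exclude uncertain IBD", {
  z <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("s1", "s2"), pedigreeSibs(threeGenPedigree())))
  pairs <- sibPairs(threeGenPedigree())
  ibd <- matrix(0.5, 2, 15, dimnames = list(NULL, pairs$pair))
  unc <- ibd * 0
  unc[1, 3] <- 0.2
  rec <- sibPairRecords(z, ibd, pairs, 1:2, unc)
  expect_equal(sum(rec$excluded), 1)
  expect_equal(nrow(rec), 30)
})
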