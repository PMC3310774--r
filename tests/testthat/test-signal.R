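test_that("sliding density equals brute-force interval counting", {
  expect_error(slidingDensity(data.frame(start = 0, end = 36), window = 0),
               "window and step")

  # no tags: an all-zero track
  tr0 <- slidingDensity(data.frame(start = numeric(0), end = numeric(0)))
  expect_true(all(tr0$count == 0))

  # a single 36 bp tag: a run of identical bins, count 1
  tr1 <- slidingDensity(data.frame(start = 7, end = 43))
  nz <- tr1$count[tr1$count > 0]
  expect_true(all(nz == 1))
  expect_equal(length(nz), ceiling((150 + 36 - 1) / 20))
  expect_equal(tr1$count, bruteDensity(data.frame(start = 7, end = 43),
                                       tr1$start, 150))

  # three tags at known positions, then random property cases
  tg <- data.frame(start = c(0, 100, 110), end = c(36, 136, 146))
  tr3 <- slidingDensity(tg)
  expect_equal(tr3$count, bruteDensity(tg, tr3$start, 150))

  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    st <- sample(0:500, n, replace = TRUE)
    tg <- data.frame(start = st, end = st + 36)
    w <- sample(c(50, 150, 200), 1)
    sp <- sample(c(10, 20, 25), 1)
    tr <- slidingDensity(tg, window = w, step = sp)
    expect_equal(tr$count, bruteDensity(tg, tr$start, w))
  }
})

test_that("global normalization is one linear map fixing the qualifying median", {
  tr <- slidingDensity(data.frame(start = numeric(0), end = numeric(0)),
                       extent = c(0, 200))
  tr$count <- c(50, 50, 30, 10, 5, 50, 60, 40, 70, 45)
  nm <- normalizeGlobal(tr, target = 25, minReads = 15)
  expect_equal(nm$scale, 25 / 50)
  expect_equal(nm$tracks$count[3], 15)

  # qualifying median exactly at target: identity
  tr2 <- tr; tr2$count <- c(25, 25, 25, 1, 2, 25, 25, 25, 25, 25)
  expect_equal(normalizeGlobal(tr2)$scale, 1)

  # after scaling, the qualifying-bin median equals the target exactly
  qual <- tr$count > 15
  expect_equal(median(nm$tracks$count[qual]), 25)

  # ratios of any two bins are preserved
  r0 <- tr$count[1] / tr$count[3]
  expect_equal(nm$tracks$count[1] / nm$tracks$count[3], r0)

  tr3 <- tr; tr3$count <- rep(3, 10)
  expect_error(normalizeGlobal(tr3), "normalization failure")
})

test_that("site occupancy is the max over overlapping bins", {
  tr <- slidingDensity(data.frame(start = numeric(0), end = numeric(0)),
                       extent = c(0, 200))
  tr$count <- c(10, 25, 18, rep(0, 7))
  # bins start at 0,20,40..., window 150: the 14 bp interval overlaps all 3
  expect_equal(siteOccupancy(tr, c(45, 59)), 25)
  tr$count[] <- 0
  expect_equal(siteOccupancy(tr, c(45, 59)), 0)
  expect_error(siteOccupancy(tr, c(1e6, 1e6 + 14)), "outside")

  set.seed(22)
  for (i in 1:20) {
    tr$count <- rpois(10, 20)
    iv <- sort(sample(0:300, 2)); iv[2] <- iv[1] + 14
    ov <- which(tr$start < iv[2] & tr$start + 150 > iv[1])
    if (length(ov)) expect_equal(siteOccupancy(tr, iv), max(tr$count[ov]))
  }
})

test_that("mappability filter detects duplications and allele-differential k-mers", {
  set.seed(23)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  # unique random genome: nothing ambiguous
  g1 <- rnd(1200)
  r1 <- mappabilityFilter(g1, center = 600, flank = 50)
  expect_equal(r1$fracA, 0)
  expect_true(r1$pass)

  # the whole simulated-read window duplicated elsewhere: fully ambiguous
  seg <- rnd(200)   # covers center +/- flank plus the read length
  g2 <- paste0(rnd(200), seg, rnd(200), seg, rnd(200))
  r2 <- mappabilityFilter(g2, center = 300, flank = 50)
  expect_equal(r2$fracA, 1)
  expect_equal(r2$fracB, 1)
  expect_false(r2$pass)

  # allele B recreates a second locus that allele A does not match
  core <- rnd(120)
  coreB <- core
  substr(coreB, 60, 60) <- if (substr(core, 60, 60) == "A") "C" else "A"
  g3 <- paste0(rnd(150), core, rnd(150), coreB, rnd(150))
  snp <- data.frame(pos = 150 + 60,
                    alleleA = substr(core, 60, 60),
                    alleleB = substr(coreB, 60, 60))
  r3 <- mappabilityFilter(g3, center = 150 + 60, snps = snp, flank = 20)
  # exhaustive string-search oracle for the B haplotype
  gB <- g3
  substr(gB, 150 + 60, 150 + 60) <- snp$alleleB
  starts <- (150 + 60 - 20):(150 + 60 + 20)
  amb <- vapply(starts, function(s) {
    read <- substr(gB, s, s + 35)
    length(gregexpr(read, gB, fixed = TRUE)[[1]]) > 1
  }, logical(1))
  expect_equal(r3$fracB, mean(amb))
  expect_gt(r3$fracB, r3$fracA)
  expect_true(r3$alleleDifferential)
  expect_false(r3$pass)

  # symmetric in allele labels
  snpSwap <- data.frame(pos = snp$pos, alleleA = snp$alleleB,
                        alleleB = snp$alleleA)
  r4 <- mappabilityFilter(g3, center = 150 + 60, snps = snpSwap, flank = 20)
  expect_equal(r4$fracA, r3$fracB)
  expect_equal(r4$fracB, r3$fracA)

  expect_warning(mappabilityFilter(g1, center = 50, flank = 147),
                 "truncated")
})

test_that("the catalog screen reproduces the per-site filter", {
  cfg <- simConfig(seed = 31, nSites = 8, snpRate = 1)
  study <- simulateStudy(cfg)
  sites <- studySites(study)
  snps <- as.data.frame(studySnps(study))
  g <- studyGenome(sites, seed = 5)
  scr <- suppressWarnings(mappabilityScreen(sites, snps, g))
  centers <- GenomicRanges::start(sites) + 67L
  for (i in c(2, 5, 8)) {
    sn <- snps[snps$siteIdx == i, ]
    one <- mappabilityFilter(g, centers[i],
                             data.frame(pos = sn$genomePos,
                                        alleleA = sn$alleleA,
                                        alleleB = sn$alleleB))
    expect_equal(scr$fracA[i], one$fracA)
    expect_equal(scr$fracB[i], one$fracB)
  }
})
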