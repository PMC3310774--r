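#' Construct a pedigree
#'
#' @param members data.frame with columns `id`, `sex`, `father`, `mother`,
#'   `generation`.
#' @return a validated [Pedigree-class].
#' @export
Pedigree <- function(members) {
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  new("Pedigree", members = members)
}

#' Default 12-member three-generation pedigree
#'
#' Four founders (two grandparental couples), their two children who form
#' the second-generation couple, and six grandchildren -- the structure of
#' a classic CEPH-style family used for occupancy heritability studies.
#'
#' @param nChildren number of third-generation sibs (default 6).
#' @return a [Pedigree-class].
#' @examples
#' threeGenPedigree()
#' @export
threeGenPedigree <- function(nChildren = 6) {
  founders <- data.frame(
    id = c("GM01", "GM02", "GM03", "GM04"),
    sex = c("M", "F", "M", "F"),
    father = NA_character_, mother = NA_character_, generation = 1L)
  parents <- data.frame(
    id = c("GM05", "GM06"), sex = c("M", "F"),
    father = c("GM01", "GM03"), mother = c("GM02", "GM04"),
    generation = 2L)
  kids <- data.frame(
    id = sprintf("GM%02d", 6 + seq_len(nChildren)),
    sex = rep_len(c("M", "F"), nChildren),
    father = "GM05", mother = "GM06", generation = 3L)
  Pedigree(rbind(founders, parents, kids))
}

#' @describeIn threeGenPedigree member ids of the third-generation sibs
#' @param ped a [Pedigree-class]
#' @export
pedigreeSibs <- function(ped) {
  m <- ped@members
  m$id[m$generation == 3L]
}

#' @describeIn threeGenPedigree all unordered sib pairs (15 for 6 sibs)
#' @export
sibPairs <- function(ped) {
  sibs <- pedigreeSibs(ped)
  idx <- utils::combn(sibs, 2)
  data.frame(pair = paste(idx[1, ], idx[2, ], sep = ":"),
             sib1 = idx[1, ], sib2 = idx[2, ], stringsAsFactors = FALSE)
}

# One gamete: founder haplotype labels transmitted by `parent` at each site,
# with Haldane recombination between adjacent sites.
transmitGamete <- function(hapParent, sitePos, recombRate) {
  nSites <- length(sitePos)
  pick <- integer(nSites)
  pick[1] <- sample(1:2, 1)
  if (nSites > 1) {
    d <- diff(sitePos)
    theta <- 0.5 * (1 - exp(-2 * recombRate * d))
    sw <- runif(nSites - 1) < theta
    pick <- ((cumsum(c(pick[1] - 1L, sw))) %% 2L) + 1L
  }
  hapParent[cbind(pick, seq_len(nSites))]
}

#' Simulate pedigree transmission with truth identity-by-descent
#'
#' Drops founder haplotype labels through the pedigree with Haldane-model
#' recombination between adjacent sites, and computes per-site IBD for every
#' sib pair directly from the transmitted labels: IBD = (number of shared
#' parental labels) / 2, taking values 0, 0.5 or 1.
#'
#' @param ped a [Pedigree-class].
#' @param sitePos integer site positions in bp along one chromosome.
#' @param recombRate recombination rate in Morgans per bp (default 1e-8,
#'   the genome average). 0 forces whole-chromosome transmission blocks.
#' @param ibdUncertainty if > 0, an uncertainty value drawn uniformly on
#'   \[0, `ibdUncertainty`\] is attached to each IBD entry (emulating
#'   imperfect marker-based inference); 0 gives exact truth.
#' @return list with `haplotypes` (member x site x 2 array of founder
#'   haplotype labels 1-8; slice 1 paternal, 2 maternal), `ibd`
#'   (site x sib-pair matrix), `ibdUncertainty` (same shape), and
#'   `pairs` (the sib-pair table).
#' @export
simulatePedigree <- function(ped, sitePos, recombRate = 1e-8,
                             ibdUncertainty = 0) {
  stopifnot(validObject(ped))
  m <- ped@members
  nSites <- length(sitePos)
  ids <- m$id
  hap <- array(NA_integer_, dim = c(length(ids), nSites, 2),
               dimnames = list(ids, NULL, c("pat", "mat")))
  founders <- ids[is.na(m$father)]
  for (i in seq_along(founders)) {
    hap[founders[i], , 1] <- 2L * i - 1L
    hap[founders[i], , 2] <- 2L * i
  }
  # transmit in generation order so parents are resolved first
  for (g in 2:3) {
    for (id in ids[m$generation == g]) {
      fa <- m$father[m$id == id]; mo <- m$mother[m$id == id]
      hap[id, , 1] <- transmitGamete(rbind(hap[fa, , 1], hap[fa, , 2]),
                                     sitePos, recombRate)
      hap[id, , 2] <- transmitGamete(rbind(hap[mo, , 1], hap[mo, , 2]),
                                     sitePos, recombRate)
    }
  }
  pairs <- sibPairs(ped)
  ibd <- matrix(NA_real_, nSites, nrow(pairs),
                dimnames = list(NULL, pairs$pair))
  for (k in seq_len(nrow(pairs))) {
    s1 <- pairs$sib1[k]; s2 <- pairs$sib2[k]
    ibd[, k] <- ((hap[s1, , 1] == hap[s2, , 1]) +
                 (hap[s1, , 2] == hap[s2, , 2])) / 2
  }
  unc <- matrix(0, nSites, nrow(pairs), dimnames = dimnames(ibd))
  if (ibdUncertainty > 0)
    unc[] <- runif(length(unc), 0, ibdUncertainty)
  list(haplotypes = hap, ibd = ibd, ibdUncertainty = unc, pairs = pairs)
}
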