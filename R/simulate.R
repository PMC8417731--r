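# FW-RIL simulator: founder haplotypes, the double-cross pedigree with
# single-seed-descent selfing, and conversion to biallelic SNP genotypes.

#' Simulate founder SNP haplotypes
#'
#' Draws fully homozygous biallelic haplotypes for the four founders,
#' i.i.d. Bernoulli(0.5) per founder and marker, so every marker is expected
#' to segregate well above the usual minor-allele-frequency floor.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param seed optional integer seed (draws do not disturb the session RNG).
#' @param founderNames names for the four founders.
#' @return integer matrix, 4 founders x markers, alleles in {0, 1}.
#' @examples
#' ph <- simulateFounderHaplotypes(buildMap(1, 100, 5), seed = 1)
#' @export
simulateFounderHaplotypes <- function(map, seed = NULL,
                                      founderNames = paste0("P", 1:4)) {
  stopifnot(is(map, "GeneticMap"), length(founderNames) == 4L)
  m <- length(map@marker)
  withSeed(seed, {
    h <- matrix(rbinom(4L * m, 1L, 0.5), nrow = 4L,
                dimnames = list(founderNames, map@marker))
    storage.mode(h) <- "integer"
    h
  })
}

# One meiosis on a single chromosome: given two parental haplotype vectors of
# founder labels at marker positions `cm`, place crossovers as a Poisson
# process (rate 1 / 100 cM, no interference) and return the gamete.
.gameteChrom <- function(h1, h2, cm) {
  L <- max(cm)
  nxo <- if (L > 0) rpois(1L, L / 100) else 0L
  start <- sample.int(2L, 1L)
  if (nxo == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(runif(nxo, 0, L))
  k <- findInterval(cm, xo)
  ifelse((start + k) %% 2L == 1L, h1, h2)
}

# Whole-genome meiosis; `hap` is a 2 x markers matrix of founder labels.
.gamete <- function(hap, map) {
  out <- integer(ncol(hap))
  for (ch in unique(map@chrom)) {
    i <- which(map@chrom == ch)
    out[i] <- .gameteChrom(hap[1L, i], hap[2L, i], map@cm[i])
  }
  out
}

#' Simulate a four-way RIL population with founder-origin tracking
#'
#' Follows the study pedigree: two founder crosses (P1 x P2) and (P3 x P4),
#' their F1s crossed to form the four-way hybrid, then `nSelfingGenerations`
#' of single-seed-descent selfing. Meioses place crossovers as a Poisson
#' process along each chromosome (Haldane, no interference) and the founder
#' origin of every segment is tracked. Loci still heterozygous after selfing
#' are fixed to one haplotype chosen at random, so the returned lines are
#' fully homozygous.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param nLines number of lines (>= 1).
#' @param nSelfingGenerations selfing generations after the double cross
#'   (>= 1; default 5, one per field season of the emulated programme).
#' @param seed optional integer seed.
#' @param founderNames names for the four founders.
#' @return A \linkS4class{FounderGeno}.
#' @examples
#' fg <- simulateFWRIL(buildMap(1, 100, 11), nLines = 20, seed = 1)
#' table(founderCalls(fg))
#' @export
simulateFWRIL <- function(map, nLines, nSelfingGenerations = 5, seed = NULL,
                          founderNames = paste0("P", 1:4)) {
  stopifnot(is(map, "GeneticMap"))
  if (nLines < 1) stop("nLines must be >= 1")
  if (nSelfingGenerations < 1) stop("nSelfingGenerations must be >= 1")
  m <- length(map@marker)
  withSeed(seed, {
    geno <- matrix(NA_integer_, nrow = nLines, ncol = m,
                   dimnames = list(sprintf("L%03d", seq_len(nLines)),
                                   map@marker))
    f1a <- rbind(rep(1L, m), rep(2L, m))  # F1 of P1 x P2
    f1b <- rbind(rep(3L, m), rep(4L, m))  # F1 of P3 x P4
    chromIdx <- lapply(unique(map@chrom), function(ch)
      which(map@chrom == ch))
    for (l in seq_len(nLines)) {
      ind <- rbind(.gamete(f1a, map), .gamete(f1b, map))
      for (g in seq_len(nSelfingGenerations)) {
        ind <- rbind(.gamete(ind, map), .gamete(ind, map))
      }
      # residual heterozygosity: fix each chromosome to one haplotype
      # chosen at random, so perfectly linked loci stay consistent
      for (idx in chromIdx) {
        geno[l, idx] <- ind[sample.int(2L, 1L), idx]
      }
    }
    new("FounderGeno", geno = geno, map = map, founders = founderNames)
  })
}

#' Convert founder-coded genotypes to biallelic SNP genotypes
#'
#' Each line's allele at a marker is the allele carried by its founder of
#' origin; lines are homozygous, so the output is coded 0/1.
#'
#' @param founderGeno a \linkS4class{FounderGeno}.
#' @param parentalHaplotypes 4 x markers matrix of founder alleles in {0, 1}
#'   (see [simulateFounderHaplotypes()]); marker sets must match the map.
#' @return integer matrix, lines x markers, values in {0, 1}.
#' @examples
#' map <- buildMap(1, 50, 6)
#' fg <- simulateFWRIL(map, 10, seed = 2)
#' ph <- simulateFounderHaplotypes(map, seed = 3)
#' snp <- founderToSnp(fg, ph)
#' @export
founderToSnp <- function(founderGeno, parentalHaplotypes) {
  stopifnot(is(founderGeno, "FounderGeno"))
  geno <- founderGeno@geno
  if (!identical(colnames(parentalHaplotypes), colnames(geno)))
    stop("marker sets of genotypes and parental haplotypes do not match")
  if (any(!is.na(geno) & (geno < 1 | geno > 4)))
    stop("founder label outside 1..4")
  m <- ncol(geno)
  idx <- cbind(as.vector(geno), rep(seq_len(m), each = nrow(geno)))
  snp <- matrix(parentalHaplotypes[idx], nrow = nrow(geno),
                dimnames = dimnames(geno))
  storage.mode(snp) <- "integer"
  snp
}
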