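# Independent oracles and fixture builders shared across tests. These stay
# deliberately separate from the package's own code paths: the Markov chain
# enumerates the pedigree exactly, the ANOVA oracle uses sequential least
# squares, and the moment oracles come from e1071.

# Exact two-locus founder-change probability for the FW-RIL pedigree:
# gamete from F1(P1 x P2) paired with gamete from F1(P3 x P4), then nSelf
# generations of selfing, then per-locus random fixation of the residual
# heterozygosity. States are ordered diplotypes over the 16 two-locus
# founder haplotypes.
markovChangeProb <- function(d_cM, nSelf) {
  r <- 0.5 * (1 - exp(-0.02 * d_cM))
  haps <- expand.grid(a = 1:4, b = 1:4)
  H <- nrow(haps)
  gam <- array(0, c(H, H, H))
  for (i in 1:H) for (j in 1:H) {
    for (ca in 1:2) for (cb in 1:2) {
      a <- if (ca == 1) haps$a[i] else haps$a[j]
      b <- if (cb == 1) haps$b[i] else haps$b[j]
      k <- which(haps$a == a & haps$b == b)
      gam[i, j, k] <- gam[i, j, k] + 0.5 * (if (ca == cb) 1 - r else r)
    }
  }
  idx <- function(a, b) which(haps$a == a & haps$b == b)
  q1 <- gam[idx(1, 1), idx(2, 2), ]   # gamete of the P1xP2 F1
  q2 <- gam[idx(3, 3), idx(4, 4), ]   # gamete of the P3xP4 F1
  P <- outer(q1, q2)
  for (g in seq_len(nSelf)) {
    Pn <- matrix(0, H, H)
    for (i in 1:H) for (j in 1:H) {
      if (P[i, j] > 0) Pn <- Pn + P[i, j] * outer(gam[i, j, ], gam[i, j, ])
    }
    P <- Pn
  }
  # fixation picks one haplotype per chromosome, so the final two-locus
  # origins come from a single haplotype chosen at random
  ch <- 0
  for (i in 1:H) for (j in 1:H) {
    if (P[i, j] > 0) {
      d2 <- (haps$a[i] != haps$b[i]) + (haps$a[j] != haps$b[j])
      ch <- ch + P[i, j] * d2 / 2
    }
  }
  ch
}

# Sequential least-squares ANOVA oracle for a balanced single-environment
# split-block table (independent of the package's closed-form projections).
anovaOracleSingle <- function(pheno) {
  dat <- data.frame(y = pheno$value, G = factor(pheno$line),
                    D = factor(pheno$density), R = factor(pheno$rep))
  f <- y ~ R + D + R:D + G + D:G
  a <- anova(lm(terms(f, keep.order = TRUE), data = dat))
  ss <- c(a$`Sum Sq`)
  names(ss) <- c("R", "D", "RD", "G", "GD", "Residual")
  ss
}

# A balanced long phenotype table filled with arbitrary values.
makeBalancedPheno <- function(g, d, r, e = 1, values = NULL) {
  out <- expand.grid(rep = seq_len(r), density = paste0("D", seq_len(d)),
                     env = paste0("E", seq_len(e)),
                     line = sprintf("L%03d", seq_len(g)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- if (is.null(values)) rnorm(nrow(out)) else values
  out[, c("line", "env", "density", "rep", "value")]
}

# Detection records for the report module: (id, method, density, env) rows.
.detections <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[1], method = r[2], density = r[3], env = r[4],
               stringsAsFactors = FALSE)))
}

# A two-marker map at a given cM distance (dummy increasing bp).
twoMarkerMap <- function(d_cM) {
  new("GeneticMap", chrom = rep("Chr01", 2), marker = c("mA", "mB"),
      cm = c(0, d_cM), bp = c(1, 2 + round(d_cM * 1e6)))
}
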