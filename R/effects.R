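# Moment-based decomposition of a detected QTL's effects across densities:
# allele effects, density effects, allele-by-density interaction, the
# variance partition and the additive / additive-by-density PVE shares.

#' Assign allelic classes from founder posteriors
#'
#' Each line is assigned the founder with the largest posterior mass at the
#' evaluated position, provided that mass reaches `minProb`; otherwise the
#' line is excluded (NA).
#'
#' @param probsAtPeak lines x 4 matrix of founder posteriors at one position.
#' @param minProb assignment threshold (default 0.7).
#' @return integer vector of classes in 1..4 with NA for excluded lines;
#'   attribute `excluded` counts the exclusions.
#' @examples
#' assignAlleleClass(rbind(c(1, 0, 0, 0), c(0.4, 0.3, 0.2, 0.1)))
#' @export
assignAlleleClass <- function(probsAtPeak, minProb = 0.7) {
  stopifnot(ncol(probsAtPeak) == 4L)
  cls <- max.col(probsAtPeak, ties.method = "first")
  top <- probsAtPeak[cbind(seq_len(nrow(probsAtPeak)), cls)]
  cls[top < minProb] <- NA_integer_
  structure(as.integer(cls), excluded = sum(top < minProb),
            names = rownames(probsAtPeak))
}

#' Decompose phenotypes over allele classes and densities
#'
#' Moment decomposition of observations y_ijk (allele class i, density j,
#' replicate k): grand mean mu, allele effects G_i (class means minus mu),
#' density effects D_j, interactions GD_ij = mu_ij - mu - G_i - D_j, with
#' variance shares sigma2_G = sum_i f_i G_i^2, sigma2_D = (1/d) sum_j D_j^2,
#' sigma2_GD = sum_ij f_ij GD_ij^2 and sigma2_p the mean squared deviation
#' from mu. PVE_A and PVE_AD are the percent shares of sigma2_G and
#' sigma2_GD in sigma2_p. Frequencies are observed class proportions
#' (`equalFreq = TRUE` forces 1/g and 1/(g d)). On balanced data the
#' reconstruction mu + G_i + D_j + GD_ij = mu_ij is exact and
#' PVE_A + PVE_AD <= 100.
#'
#' @param y numeric observations.
#' @param cls allele class per observation (values in 1..4 or any labels;
#'   NA rows are dropped).
#' @param density density label per observation.
#' @param equalFreq use equal class frequencies instead of observed ones.
#' @return list of class `effectDecomposition`: mu, cellMeans, G, D, GD,
#'   fI, fIJ, sigma2_G, sigma2_D, sigma2_GD, sigma2_p, pveA, pveAD, g, d, n,
#'   balanced, undefined.
#' @examples
#' decomposeDensityEffects(c(1, 2, 3, 4), cls = c(1, 1, 2, 2),
#'                         density = c("D1", "D2", "D1", "D2"))
#' @export
decomposeDensityEffects <- function(y, cls, density, equalFreq = FALSE) {
  keep <- !is.na(y) & !is.na(cls) & !is.na(density)
  y <- y[keep]; cls <- cls[keep]; density <- density[keep]
  ci <- factor(cls); dj <- factor(density)
  g <- nlevels(ci); d <- nlevels(dj)
  if (g < 2L) stop("need at least 2 allele classes present")
  nIJ <- table(ci, dj)
  if (any(nIJ == 0)) {
    warning("empty class x density cell: weighted marginal means used")
    balanced <- FALSE
  } else balanced <- all(nIJ == nIJ[1])
  n <- length(y)
  mu <- mean(y)
  cellMeans <- tapply(y, list(ci, dj), mean)
  G <- c(tapply(y, ci, mean)) - mu
  D <- c(tapply(y, dj, mean)) - mu
  GD <- sweep(sweep(cellMeans, 1, G), 2, D) - mu
  fI <- if (equalFreq) rep(1 / g, g) else as.numeric(table(ci)) / n
  fIJ <- if (equalFreq) matrix(1 / (g * d), g, d)
         else unclass(nIJ) / n
  s2G <- sum(fI * G^2)
  s2D <- sum(D^2) / d
  s2GD <- sum(fIJ * GD^2, na.rm = TRUE)
  s2p <- mean((y - mu)^2)
  undefined <- s2p < .Machine$double.eps
  if (undefined) warning("constant phenotype: PVE shares undefined")
  structure(list(mu = mu, cellMeans = cellMeans, G = G, D = D, GD = GD,
                 fI = fI, fIJ = fIJ, sigma2_G = s2G, sigma2_D = s2D,
                 sigma2_GD = s2GD, sigma2_p = s2p,
                 pveA = if (undefined) NA_real_ else 100 * s2G / s2p,
                 pveAD = if (undefined) NA_real_ else 100 * s2GD / s2p,
                 g = g, d = d, n = n, balanced = balanced,
                 undefined = undefined),
            class = "effectDecomposition")
}

#' Per-environment QTL effect table
#'
#' For each named QTL and environment, lines are classified by founder at the
#' QTL peak, all replicate observations under both densities enter the
#' moment decomposition, and one row reports the four additive effects, the
#' allele-by-density interaction under each density (for two balanced
#' densities the second column is exactly the negative of the first, a
#' consequence of the zero-sum constraint), and the PVE shares. A `Total`
#' row per environment sums the PVE columns.
#'
#' @param calls named calls (rows of [nameQtl()] output; one decomposition
#'   per distinct `name`, peak taken from its highest-LOD row).
#' @param probs the \linkS4class{FounderProb} used for the scans.
#' @param pheno long phenotype data.frame covering both densities.
#' @param minProb class-assignment threshold passed to
#'   [assignAlleleClass()].
#' @return data.frame: env, qtl, add1..add4, add1_D1..add4_D1,
#'   add1_D2..add4_D2, pveA, pveAD (plus Total rows).
#' @export
perEnvironmentEffectTable <- function(calls, probs, pheno, minProb = 0.7) {
  stopifnot(is(probs, "FounderProb"), nrow(calls) > 0)
  dens <- sort(unique(pheno$density))
  envs <- sort(unique(pheno$env))
  lines <- lineNames(probs)
  rows <- list()
  for (ev in envs) {
    ph <- pheno[pheno$env == ev, ]
    tot <- c(0, 0)
    for (nm in unique(calls$name)) {
      sub <- calls[calls$name == nm, ]
      best <- sub[which.max(sub$lod), ]
      i <- which(probs@chrom == best$chrom)
      pk <- i[which.min(abs(probs@cm[i] - best$peak_cm))]
      cls <- assignAlleleClass(probs@prob[, pk, , drop = TRUE], minProb)
      ci <- cls[match(ph$line, lines)]
      dec <- decomposeDensityEffects(ph$value, ci, ph$density)
      present <- as.integer(levels(factor(ci[!is.na(ci)])))
      addFull <- setNames(rep(NA_real_, 4), 1:4)
      addFull[as.character(present)] <- dec$G
      gdFull <- matrix(NA_real_, 4, length(dens),
                       dimnames = list(1:4, dens))
      gdFull[as.character(present), colnames(dec$GD)] <- dec$GD
      row <- data.frame(env = ev, qtl = nm, t(addFull))
      names(row)[3:6] <- paste0("add", 1:4)
      for (dd in dens) {
        v <- gdFull[, dd]
        dfv <- data.frame(t(v))
        names(dfv) <- paste0("add", 1:4, "_", dd)
        row <- cbind(row, dfv)
      }
      row$pveA <- dec$pveA
      row$pveAD <- dec$pveAD
      rows[[length(rows) + 1L]] <- row
      tot <- tot + c(dec$pveA, dec$pveAD)
    }
    totRow <- rows[[length(rows)]]
    totRow[1, ] <- NA
    totRow$env <- ev; totRow$qtl <- "Total"
    totRow$pveA <- tot[1]; totRow$pveAD <- tot[2]
    rows[[length(rows) + 1L]] <- totRow
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
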