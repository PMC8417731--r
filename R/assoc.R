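# Single-marker association scan (the package's stand-in for multi-locus
# mixed-model GWAS machinery) and an LD-decay utility.

#' Single-marker association scan
#'
#' Per marker, the trait is regressed on the allele count of a biallelic
#' homozygous genotype; LOD = (n/2) log10(RSS0/RSS1), the effect is the
#' allele-substitution coefficient, and r2 = 100 (1 - RSS1/RSS0). Markers at
#' or below the minor-allele-frequency floor are dropped before testing;
#' monomorphic markers are skipped and counted. Records at or above the LOD
#' threshold are named `qn[RD]NN-<chrom>-<k>` with per-chromosome sequence
#' numbers in physical order.
#'
#' @param snp lines x markers matrix coded 0/1 (homozygous lines).
#' @param trait numeric trait, named by line (or ordered as rows).
#' @param map \linkS4class{GeneticMap} supplying chromosome and bp per
#'   marker.
#' @param mafMin minor-allele-frequency floor (markers kept require
#'   MAF > `mafMin`; default 0.05).
#' @param lodMin LOD threshold for reporting (default 3).
#' @param treatment,method labels carried into the records.
#' @param traitName "NN" or "RD" (controls the name stem).
#' @return data.frame of records: name, marker, chrom, bp, treatment,
#'   method, effect, lod, r2, maf. Attributes `nSkippedMonomorphic` and
#'   `nFilteredMAF` count the dropped markers.
#' @examples
#' map <- buildMap(1, 50, 6)
#' fg <- simulateFWRIL(map, 80, seed = 1)
#' snp <- founderToSnp(fg, simulateFounderHaplotypes(map, seed = 2))
#' y <- setNames(rnorm(80) + 2 * snp[, 3], rownames(snp))
#' markerScan(snp, y, map)
#' @export
markerScan <- function(snp, trait, map, mafMin = 0.05, lodMin = 3,
                       treatment = "", method = "SMA", traitName = "NN") {
  stopifnot(is(map, "GeneticMap"),
            identical(colnames(snp), map@marker))
  y <- .matchTrait(trait, rownames(snp))
  keep <- !is.na(y)
  y <- y[keep]; snp <- snp[keep, , drop = FALSE]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  freq <- colMeans(snp, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  mono <- maf == 0
  pass <- !mono & maf > mafMin
  rows <- list()
  for (j in which(pass)) {
    x <- snp[, j]
    ok <- !is.na(x)
    fit <- lm(y[ok] ~ x[ok])
    rss1 <- sum(resid(fit)^2)
    lod <- .lodFromRss(sum(ok), rss0, rss1)
    if (lod < lodMin) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker = map@marker[j], chrom = map@chrom[j], bp = map@bp[j],
      treatment = treatment, method = method,
      effect = unname(coef(fit)[2]), lod = lod,
      r2 = 100 * (1 - rss1 / rss0), maf = maf[j],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(name = character(0), marker = character(0),
                      chrom = character(0), bp = numeric(0),
                      treatment = character(0), method = character(0),
                      effect = numeric(0), lod = numeric(0),
                      r2 = numeric(0), maf = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(chromNumber(out$chrom), out$bp), , drop = FALSE]
    stem <- if (identical(traitName, "RD")) "qnRDNN" else "qnNN"
    seqno <- stats::ave(out$bp, out$chrom, FUN = seq_along)
    out <- cbind(name = sprintf("%s-%d-%d", stem, chromNumber(out$chrom),
                                seqno), out)
    rownames(out) <- NULL
  }
  attr(out, "nSkippedMonomorphic") <- sum(mono)
  attr(out, "nFilteredMAF") <- sum(!mono & !pass)
  out
}

#' Linkage-disequilibrium decay with physical distance
#'
#' Pairwise allele-indicator r2 between markers on the same chromosome
#' within `maxDist`, averaged in distance bins; the decay distance is the
#' physical distance at which the binned mean first drops below
#' `r2Threshold` (linearly interpolated between bin midpoints).
#'
#' @param snp lines x markers matrix coded 0/1.
#' @param map \linkS4class{GeneticMap} with bp positions.
#' @param r2Threshold decay threshold (default 0.1).
#' @param maxDist maximum pair distance in bp.
#' @param nBins number of distance bins (default 20).
#' @return list of class `ldResult`: bins (data.frame mid, meanR2, n),
#'   decayDistance (bp, NA when the curve never crosses the threshold).
#' @export
ldDecay <- function(snp, map, r2Threshold = 0.1, maxDist = 5e6,
                    nBins = 20) {
  stopifnot(identical(colnames(snp), map@marker))
  dist <- r2 <- numeric(0)
  for (ch in unique(map@chrom)) {
    i <- which(map@chrom == ch)
    poly <- i[apply(snp[, i, drop = FALSE], 2, function(x)
      length(unique(x[!is.na(x)])) > 1L)]
    if (length(poly) < 2L) next
    for (a in seq_len(length(poly) - 1L)) {
      for (b in (a + 1L):length(poly)) {
        d <- abs(map@bp[poly[b]] - map@bp[poly[a]])
        if (d > maxDist) next
        r <- suppressWarnings(cor(snp[, poly[a]], snp[, poly[b]],
                                  use = "complete.obs"))
        if (is.na(r)) next
        dist <- c(dist, d); r2 <- c(r2, r^2)
      }
    }
  }
  if (!length(dist)) stop("no marker pairs within maxDist")
  breaks <- seq(0, maxDist, length.out = nBins + 1L)
  bin <- cut(dist, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  meanR2 <- tapply(r2, bin, mean)
  nPer <- tapply(r2, bin, length)
  bins <- data.frame(mid = mids, meanR2 = as.numeric(meanR2),
                     n = as.integer(ifelse(is.na(nPer), 0L, nPer)))
  obs <- bins[!is.na(bins$meanR2), ]
  decay <- NA_real_
  below <- which(obs$meanR2 < r2Threshold)
  if (length(below)) {
    k <- below[1]
    if (k == 1L) decay <- obs$mid[1]
    else {
      x0 <- obs$mid[k - 1]; y0 <- obs$meanR2[k - 1]
      x1 <- obs$mid[k]; y1 <- obs$meanR2[k]
      decay <- x0 + (y0 - r2Threshold) / (y0 - y1) * (x1 - x0)
    }
  }
  structure(list(bins = bins, decayDistance = decay,
                 r2Threshold = r2Threshold), class = "ldResult")
}
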