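#' Build an evenly spaced genetic map
#'
#' Creates a map with `nMarkersPerChrom` markers evenly spaced from 0 to
#' `chromLengthCM` on each chromosome; physical positions are the genetic
#' positions scaled by `bpPerCM` and rounded to integers. With a single
#' marker per chromosome the marker sits at 0 cM.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLengthCM chromosome length in cM (>= 0); recycled over
#'   chromosomes.
#' @param nMarkersPerChrom markers per chromosome (>= 1); recycled.
#' @param bpPerCM physical scale in bp per cM (default 1e6, roughly the
#'   genome-wide soybean average).
#' @return A \linkS4class{GeneticMap}.
#' @examples
#' buildMap(1, 100, 26)       # 4 cM spacing
#' @export
buildMap <- function(nChrom, chromLengthCM = 100, nMarkersPerChrom = 26,
                     bpPerCM = 1e6) {
  if (nChrom < 1) stop("nChrom must be >= 1")
  len <- rep_len(chromLengthCM, nChrom)
  nm <- rep_len(as.integer(nMarkersPerChrom), nChrom)
  if (any(nm < 1)) stop("nMarkersPerChrom must be >= 1")
  if (any(len < 0)) stop("chromLengthCM must be >= 0")
  chrom <- marker <- character(0)
  cm <- bp <- numeric(0)
  for (i in seq_len(nChrom)) {
    ch <- sprintf("Chr%02d", i)
    pos <- if (nm[i] == 1L) 0 else seq(0, len[i], length.out = nm[i])
    chrom <- c(chrom, rep(ch, nm[i]))
    marker <- c(marker, sprintf("M%02d_%03d", i, seq_len(nm[i])))
    cm <- c(cm, pos)
    bp <- c(bp, round(pos * bpPerCM))
  }
  new("GeneticMap", chrom = chrom, marker = marker, cm = cm, bp = bp)
}
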