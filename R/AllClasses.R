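#' GeneticMap: marker positions along chromosomes
#'
#' Ordered marker table: chromosome id, marker id, genetic position (cM) and
#' optional physical position (bp). Genetic positions must be nondecreasing
#' within a chromosome and physical positions, when present, strictly
#' increasing.
#'
#' @slot chrom character, chromosome id per marker (grouped, in map order).
#' @slot marker character, unique marker ids.
#' @slot cm numeric, genetic position in centimorgans.
#' @slot bp numeric, physical position in base pairs (may be all NA).
#'
#' @seealso [buildMap()], [mapTable()]
#' @export
setClass("GeneticMap",
  representation(chrom = "character", marker = "character",
                 cm = "numeric", bp = "numeric"))

setValidity("GeneticMap", function(object) {
  n <- length(object@marker)
  if (length(object@chrom) != n || length(object@cm) != n ||
      length(object@bp) != n)
    return("chrom, marker, cm and bp must have equal length")
  if (n == 0L) return("map must contain at least one marker")
  if (anyDuplicated(object@marker)) return("marker ids must be unique")
  for (ch in unique(object@chrom)) {
    i <- object@chrom == ch
    if (is.unsorted(object@cm[i]))
      return(sprintf("cM positions not nondecreasing on %s", ch))
    b <- object@bp[i]
    if (!all(is.na(b)) && (anyNA(b) || any(diff(b) <= 0)))
      return(sprintf("bp positions must be strictly increasing on %s", ch))
  }
  TRUE
})

#' FounderGeno: founder-of-origin genotypes for a homozygous population
#'
#' Lines-by-markers matrix of founder labels in 1..4 (both haplotypes equal
#' after forced homozygosis, so a single label per line and marker), together
#' with the genetic map and founder names.
#'
#' @slot geno integer matrix, lines x markers, values in 1..4.
#' @slot map a [GeneticMap-class].
#' @slot founders character of length 4, founder names.
#'
#' @seealso [simulateFWRIL()], [founderToSnp()]
#' @export
setClass("FounderGeno",
  representation(geno = "matrix", map = "GeneticMap", founders = "character"))

setValidity("FounderGeno", function(object) {
  g <- object@geno
  if (ncol(g) != length(object@map@marker))
    return("geno column count does not match map")
  if (!identical(colnames(g), object@map@marker))
    return("geno colnames must equal map marker ids")
  if (length(object@founders) != 4L) return("exactly 4 founders required")
  v <- g[!is.na(g)]
  if (length(v) && (any(v < 1) || any(v > 4) || any(v != round(v))))
    return("founder labels must be integers in 1..4")
  TRUE
})

#' FounderProb: founder-origin posterior probabilities on an evaluation grid
#'
#' For each line and evaluation position (markers plus a regular cM grid), the
#' posterior probability that the local genome descends from each of the four
#' founders. Every probability vector sums to one.
#'
#' @slot prob numeric array, lines x positions x 4 founders.
#' @slot chrom character, chromosome per evaluation position.
#' @slot cm numeric, cM per evaluation position.
#' @slot atMarker logical, TRUE where the position is a mapped marker.
#' @slot onGrid logical, TRUE where the position belongs to the scan grid.
#' @slot marker character, marker id or NA for pure grid positions.
#' @slot map the [GeneticMap-class] the probabilities were computed on.
#'
#' @seealso [inferFounderProbs()], [imScan()]
#' @export
setClass("FounderProb",
  representation(prob = "array", chrom = "character", cm = "numeric",
                 atMarker = "logical", onGrid = "logical",
                 marker = "character", map = "GeneticMap"))

setValidity("FounderProb", function(object) {
  d <- dim(object@prob)
  if (length(d) != 3L || d[3] != 4L)
    return("prob must be a lines x positions x 4 array")
  if (d[2] != length(object@cm) || d[2] != length(object@chrom) ||
      d[2] != length(object@atMarker) || d[2] != length(object@onGrid) ||
      d[2] != length(object@marker))
    return("position annotations must match the prob array")
  s <- apply(object@prob, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-9)) return("posteriors must sum to 1")
  if (any(object@prob < -1e-12) || any(object@prob > 1 + 1e-12))
    return("posteriors must lie in [0, 1]")
  TRUE
})

#' ScanResult: genome-scan profile for one trait
#'
#' LOD profile over the evaluation grid together with per-position founder
#' effect estimates (sum-to-zero deviations), the null and full residual sums
#' of squares, and the percent variance explained at each position.
#'
#' @slot chrom character, chromosome per grid position.
#' @slot cm numeric, grid position in cM.
#' @slot lod numeric, LOD score (>= 0).
#' @slot pve numeric, percent phenotypic variance explained at the position.
#' @slot effects numeric matrix, positions x 4 founder-effect deviations.
#' @slot rss0 numeric, residual sum of squares of the null model per position.
#' @slot rss1 numeric, residual sum of squares of the founder model.
#' @slot n integer, number of lines scanned.
#' @slot trait character, trait label (e.g. "NN" or "RD").
#' @slot method character, "IM" or "ICIM".
#' @slot flagged logical, TRUE where the local design was degenerate.
#'
#' @seealso [imScan()], [icimScan()], [callQtl()]
#' @export
setClass("ScanResult",
  representation(chrom = "character", cm = "numeric", lod = "numeric",
                 pve = "numeric", effects = "matrix", rss0 = "numeric",
                 rss1 = "numeric", n = "integer", trait = "character",
                 method = "character", flagged = "logical"))

setValidity("ScanResult", function(object) {
  p <- length(object@cm)
  if (length(object@chrom) != p || length(object@lod) != p ||
      length(object@pve) != p || nrow(object@effects) != p ||
      length(object@rss1) != p || length(object@flagged) != p)
    return("per-position slots must have equal length")
  if (any(object@lod < -1e-9, na.rm = TRUE)) return("LOD must be >= 0")
  TRUE
})
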