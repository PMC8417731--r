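#' @rdname mapTable
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname accessors
#' @export
setGeneric("founderCalls", function(x) standardGeneric("founderCalls"))

#' @rdname accessors
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname accessors
#' @export
setGeneric("lineNames", function(x) standardGeneric("lineNames"))

#' @rdname accessors
#' @export
setGeneric("probArray", function(x) standardGeneric("probArray"))

#' @rdname accessors
#' @export
setGeneric("positionTable", function(x) standardGeneric("positionTable"))

#' @rdname scanTable
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' Marker table of a GeneticMap
#'
#' @param x a \linkS4class{GeneticMap} (or an object carrying one).
#' @return A data.frame with columns chrom, marker, cm, bp.
#' @examples
#' mapTable(buildMap(2, 100, 6))
#' @rdname mapTable
#' @export
setMethod("mapTable", "GeneticMap", function(x)
  data.frame(chrom = x@chrom, marker = x@marker, cm = x@cm, bp = x@bp,
             stringsAsFactors = FALSE))

#' @rdname mapTable
#' @export
setMethod("mapTable", "FounderGeno", function(x) mapTable(x@map))

#' Accessors for fourwayQTL containers
#'
#' Number of markers, chromosome names, founder names, line names, the
#' founder-label matrix of a \linkS4class{FounderGeno}, and the posterior
#' array / evaluation-position table of a \linkS4class{FounderProb}.
#'
#' @param x the container.
#' @return The corresponding component (see each method's class).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("nMarkers", "GeneticMap", function(x) length(x@marker))

#' @rdname accessors
#' @export
setMethod("nMarkers", "FounderGeno", function(x) nMarkers(x@map))

#' @rdname accessors
#' @export
setMethod("chromNames", "GeneticMap", function(x) unique(x@chrom))

#' @rdname accessors
#' @export
setMethod("chromNames", "FounderGeno", function(x) chromNames(x@map))

#' @rdname accessors
#' @export
setMethod("founderCalls", "FounderGeno", function(x) x@geno)

#' @rdname accessors
#' @export
setMethod("founders", "FounderGeno", function(x) x@founders)

#' @rdname accessors
#' @export
setMethod("lineNames", "FounderGeno", function(x) rownames(x@geno))

#' @rdname accessors
#' @export
setMethod("lineNames", "FounderProb", function(x) dimnames(x@prob)[[1]])

#' @rdname accessors
#' @export
setMethod("probArray", "FounderProb", function(x) x@prob)

#' @rdname accessors
#' @export
setMethod("positionTable", "FounderProb", function(x)
  data.frame(chrom = x@chrom, cm = x@cm, marker = x@marker,
             atMarker = x@atMarker, onGrid = x@onGrid,
             stringsAsFactors = FALSE))

#' Scan profile as a data.frame
#'
#' @param x a \linkS4class{ScanResult}.
#' @return data.frame with chrom, cm, lod, pve, add1..add4 and the
#'   degenerate-design flag.
#' @rdname scanTable
#' @export
setMethod("scanTable", "ScanResult", function(x) {
  eff <- x@effects
  colnames(eff) <- paste0("add", 1:4)
  data.frame(chrom = x@chrom, cm = x@cm, lod = x@lod, pve = x@pve,
             eff, flagged = x@flagged, stringsAsFactors = FALSE)
})

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s)\n",
              length(object@marker), length(unique(object@chrom))))
  for (ch in head(unique(object@chrom), 5)) {
    i <- object@chrom == ch
    cat(sprintf("  %s: %d markers, %.1f cM\n", ch, sum(i),
                max(object@cm[i])))
  }
  if (length(unique(object@chrom)) > 5) cat("  ...\n")
})

setMethod("show", "FounderGeno", function(object) {
  cat(sprintf("FounderGeno: %d lines x %d markers (founders: %s)\n",
              nrow(object@geno), ncol(object@geno),
              paste(object@founders, collapse = ", ")))
})

setMethod("show", "FounderProb", function(object) {
  d <- dim(object@prob)
  cat(sprintf(
    "FounderProb: %d lines x %d positions x 4 founders (%d markers, %d grid)\n",
    d[1], d[2], sum(object@atMarker), sum(object@onGrid)))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s, trait %s): %d positions, max LOD %.2f\n",
              object@method, object@trait, length(object@cm),
              max(object@lod, na.rm = TRUE)))
})
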