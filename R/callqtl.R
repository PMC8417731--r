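# QTL calling: contiguous runs of LOD above threshold, peak position,
# flanking-marker physical interval, and region-merged naming.

#' Call QTL from a scan profile
#'
#' Maximal contiguous runs of grid positions with LOD at or above the
#' threshold (within one chromosome) become calls. The peak is the leftmost
#' maximum of the run; the reported support is the marker interval containing
#' the peak, with physical endpoints taken from the map (inclusive, as
#' printed).
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param map the \linkS4class{GeneticMap} the scan was run on.
#' @param lodThreshold LOD threshold (default 3).
#' @param treatment treatment label (e.g. "E1D1", "E2RD") carried through.
#' @return data.frame with one row per call: chrom, peak_cm, lod, pve,
#'   add1..add4, marker_left, marker_right, start_bp, end_bp, length_bp,
#'   treatment, method, trait. Empty scans yield an empty frame.
#' @examples
#' # see callQtl tests; typically used after imScan()/icimScan()
#' @export
callQtl <- function(scan, map, lodThreshold = 3, treatment = "") {
  stopifnot(is(scan, "ScanResult"), is(map, "GeneticMap"))
  cols <- c("chrom", "peak_cm", "lod", "pve", paste0("add", 1:4),
            "marker_left", "marker_right", "start_bp", "end_bp",
            "length_bp", "treatment", "method", "trait")
  empty <- data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(empty) <- cols
  rows <- list()
  for (ch in unique(scan@chrom)) {
    i <- which(scan@chrom == ch)
    above <- scan@lod[i] >= lodThreshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      run <- i[starts[k]:ends[k]]
      peak <- run[which.max(scan@lod[run])]  # which.max: leftmost tie
      mi <- which(map@chrom == ch)
      mcm <- map@cm[mi]
      pcm <- scan@cm[peak]
      left <- if (any(mcm <= pcm + 1e-9)) max(which(mcm <= pcm + 1e-9))
              else 1L
      right <- if (any(mcm >= pcm - 1e-9)) min(which(mcm >= pcm - 1e-9))
               else length(mcm)
      if (right == left) {
        # peak exactly on a marker: support is the adjacent marker interval
        if (right < length(mcm)) right <- left + 1L
        else if (left > 1L) left <- left - 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, peak_cm = pcm, lod = scan@lod[peak],
        pve = scan@pve[peak],
        add1 = scan@effects[peak, 1], add2 = scan@effects[peak, 2],
        add3 = scan@effects[peak, 3], add4 = scan@effects[peak, 4],
        marker_left = map@marker[mi][left],
        marker_right = map@marker[mi][right],
        start_bp = map@bp[mi][left], end_bp = map@bp[mi][right],
        length_bp = map@bp[mi][right] - map@bp[mi][left],
        treatment = treatment, method = scan@method, trait = scan@trait,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Name QTL calls with region merging
#'
#' Calls (possibly from several treatments, methods and traits) are grouped
#' into regions per chromosome; calls whose marker intervals overlap (or,
#' with `merge = "identical"`, share both flanking markers) belong to one
#' region and share a sequence number. Sequence numbers run along the
#' chromosome in physical order, separately within each trait, giving names
#' `qlNN-<chrom>-<k>` for the node-number trait and `qlRDNN-<chrom>-<k>` for
#' the response-to-density trait. When a region carries both traits, each
#' row's `xref` holds its name under the other trait.
#'
#' @param calls data.frame of calls from [callQtl()] (rows may be
#'   concatenated across treatments/methods/traits).
#' @param merge `"overlap"` (default) or `"identical"` flanking markers.
#' @param prefix name stem (default "ql"; the association module uses "qn").
#' @return The input with columns `region`, `name` and `xref` added.
#' @export
nameQtl <- function(calls, merge = c("overlap", "identical"),
                    prefix = "ql") {
  merge <- match.arg(merge)
  if (!nrow(calls)) {
    calls$region <- character(0); calls$name <- character(0)
    calls$xref <- character(0)
    return(calls)
  }
  calls$region <- NA_character_
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    if (merge == "identical") {
      key <- paste(calls$marker_left[i], calls$marker_right[i])
      grp <- match(key, unique(key))
    } else {
      ir <- IRanges::IRanges(start = calls$start_bp[i],
                             end = calls$end_bp[i])
      ov <- IRanges::findOverlaps(ir, IRanges::reduce(ir))
      grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    }
    starts <- tapply(calls$start_bp[i], grp, min)
    ord <- rank(starts, ties.method = "first")
    calls$region[i] <- sprintf("%s:%d", ch, ord[as.character(grp)])
  }
  traitOf <- calls$trait
  calls$name <- NA_character_
  for (tr in unique(traitOf)) {
    ti <- which(traitOf == tr)
    for (ch in unique(calls$chrom[ti])) {
      ci <- ti[calls$chrom[ti] == ch]
      regs <- unique(calls$region[ci][order(calls$start_bp[ci])])
      k <- match(calls$region[ci], regs)
      stem <- if (identical(tr, "RD")) paste0(prefix, "RDNN")
              else paste0(prefix, "NN")
      calls$name[ci] <- sprintf("%s-%d-%d", stem,
                                chromNumber(ch), k)
    }
  }
  calls$xref <- NA_character_
  for (rg in unique(calls$region)) {
    ri <- which(calls$region == rg)
    trs <- unique(traitOf[ri])
    if (length(trs) > 1L) {
      for (j in ri) {
        other <- ri[traitOf[ri] != traitOf[j]][1]
        calls$xref[j] <- calls$name[other]
      }
    }
  }
  calls
}
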