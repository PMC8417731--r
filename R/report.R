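# Cross-result reporting: stability classification, candidate selection,
# linkage-association co-location, Venn tallies, candidate windows and gene
# intersection.

#' Classify QTL stability across methods, densities and environments
#'
#' A record id's support sets are the distinct methods, densities (D1/D2/RD)
#' and environments it was detected in. Default rule: stable when at least
#' one support dimension has two or more values (e.g. detected by both IM
#' and ICIM). Strict rule: all three dimensions multi-supported.
#'
#' @param records data.frame with columns id, method, density, env (one row
#'   per detection).
#' @param rule `"any"` (default) or `"strict"`.
#' @return data.frame per id: nMethods, nDensities, nEnvs, stable, plus the
#'   collapsed support sets.
#' @export
classifyStability <- function(records, rule = c("any", "strict")) {
  rule <- match.arg(rule)
  stopifnot(all(c("id", "method", "density", "env") %in% names(records)))
  ids <- unique(records$id)
  rows <- lapply(ids, function(i) {
    r <- records[records$id == i, ]
    nm <- length(unique(r$method)); nd <- length(unique(r$density))
    ne <- length(unique(r$env))
    stable <- if (rule == "any") (nm >= 2 || nd >= 2 || ne >= 2)
              else (nm >= 2 && nd >= 2 && ne >= 2)
    data.frame(id = i, nMethods = nm, nDensities = nd, nEnvs = ne,
               methods = paste(sort(unique(r$method)), collapse = ";"),
               densities = paste(sort(unique(r$density)), collapse = ";"),
               envs = paste(sort(unique(r$env)), collapse = ";"),
               stable = stable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select candidate QTL/QTN for gene mining
#'
#' Linkage rule: a call qualifies when it is stable (repeatedly detected),
#' its best PVE exceeds `pveMin` percent, and its marker interval is shorter
#' than `maxLen` bp. Association rule: a record qualifies when it is
#' supported by at least two methods, or multiple environments, or
#' co-located with a linkage call, and its r2 exceeds `pveMin`.
#'
#' @param stability output of [classifyStability()].
#' @param calls named linkage calls (with `name`, `pve`, `length_bp`), or
#'   NULL.
#' @param qtns association records (with `name`, `r2`), or NULL.
#' @param colocated character vector of QTN ids co-located with linkage
#'   calls (see [colocate()]).
#' @param pveMin PVE threshold in percent (default 10, exclusive).
#' @param maxLen maximum linkage interval length in bp (default 6e5,
#'   exclusive).
#' @return data.frame: id, type, candidate, rule (trace of the decisive
#'   checks).
#' @export
selectCandidates <- function(stability, calls = NULL, qtns = NULL,
                             colocated = character(0), pveMin = 10,
                             maxLen = 6e5) {
  rows <- list()
  if (!is.null(calls) && nrow(calls)) {
    for (nm in unique(calls$name)) {
      sub <- calls[calls$name == nm, ]
      st <- stability$stable[stability$id == nm]
      stable <- length(st) && any(st)
      pve <- max(sub$pve, na.rm = TRUE)
      len <- min(sub$length_bp, na.rm = TRUE)
      ok <- stable && pve > pveMin && len < maxLen
      rows[[length(rows) + 1L]] <- data.frame(
        id = nm, type = "linkage", candidate = ok,
        rule = sprintf("stable=%s;PVE=%.2f>%g=%s;len=%d<%g=%s",
                       stable, pve, pveMin, pve > pveMin, len, maxLen,
                       len < maxLen), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(qtns) && nrow(qtns)) {
    for (nm in unique(qtns$name)) {
      sub <- qtns[qtns$name == nm, ]
      st <- stability[stability$id == nm, ]
      multiMethod <- nrow(st) && any(st$nMethods >= 2)
      multiEnv <- nrow(st) && any(st$nEnvs >= 2)
      coloc <- nm %in% colocated
      r2 <- max(sub$r2, na.rm = TRUE)
      ok <- (multiMethod || multiEnv || coloc) && r2 > pveMin
      rows[[length(rows) + 1L]] <- data.frame(
        id = nm, type = "association", candidate = ok,
        rule = sprintf("methods>=2=%s;envs>=2=%s;coloc=%s;r2=%.2f>%g=%s",
                       multiMethod, multiEnv, coloc, r2, pveMin,
                       r2 > pveMin), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(id = character(0), type = character(0),
                         candidate = logical(0), rule = character(0))
  rownames(out) <- NULL
  out
}

#' Co-locate association records inside linkage intervals
#'
#' A (QTN, QTL) pair co-locates when the QTN position lies within the QTL's
#' physical marker interval on the same chromosome, endpoints inclusive.
#'
#' @param calls linkage calls with name, chrom, start_bp, end_bp.
#' @param qtns association records with name, chrom, bp.
#' @return data.frame of pairs: qtn, qtl, chrom, bp, start_bp, end_bp.
#' @export
colocate <- function(calls, qtns) {
  if (!nrow(calls) || !nrow(qtns))
    return(data.frame(qtn = character(0), qtl = character(0),
                      chrom = character(0), bp = numeric(0),
                      start_bp = numeric(0), end_bp = numeric(0)))
  gq <- GenomicRanges::GRanges(qtns$chrom,
                               IRanges::IRanges(qtns$bp, qtns$bp))
  gl <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start_bp,
                                                calls$end_bp))
  ov <- GenomicRanges::findOverlaps(gq, gl)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- data.frame(qtn = qtns$name[qi], qtl = calls$name[si],
                    chrom = qtns$chrom[qi], bp = qtns$bp[qi],
                    start_bp = calls$start_bp[si],
                    end_bp = calls$end_bp[si], stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Venn-region tallies of distinct QTL over support sets
#'
#' Counts distinct ids per region of the set partition induced by a support
#' dimension (densities D1/D2/RD, or environments). Region labels are the
#' sorted support values joined by "&"; the counts sum to the number of
#' distinct ids.
#'
#' @param records data.frame with columns id and the support column.
#' @param by name of the support column (default "density").
#' @return list: regions (named integer vector), total.
#' @examples
#' vennTallies(data.frame(id = c("a", "b", "c", "c"),
#'                        density = c("D1", "D2", "D1", "D2")))
#' @export
vennTallies <- function(records, by = "density") {
  if (!nrow(records))
    return(list(regions = setNames(integer(0), character(0)), total = 0L))
  stopifnot(all(c("id", by) %in% names(records)))
  sets <- tapply(records[[by]], records$id, function(v)
    paste(sort(unique(v)), collapse = "&"))
  tab <- table(sets)
  list(regions = setNames(as.integer(tab), names(tab)),
       total = length(sets))
}

#' Candidate-gene windows around QTL intervals
#'
#' Extends each candidate interval by `flankBp` on both sides (the width
#' motivated by the population's LD decay), clamping the start at the first
#' base. Point records (QTN) are treated as 1-bp intervals.
#'
#' @param candidates data.frame with chrom and either start_bp/end_bp or bp.
#' @param flankBp flank on either side in bp (default 1e5).
#' @return A [GenomicRanges::GRanges] of windows, named by candidate id
#'   (column `name` or `id` when present).
#' @export
candidateWindows <- function(candidates, flankBp = 1e5) {
  if (!nrow(candidates)) return(GenomicRanges::GRanges())
  if (all(c("start_bp", "end_bp") %in% names(candidates))) {
    s <- candidates$start_bp; e <- candidates$end_bp
  } else {
    s <- e <- candidates$bp
  }
  if (any(s > e)) stop("interval start exceeds end")
  gr <- GenomicRanges::GRanges(candidates$chrom,
                               IRanges::IRanges(pmax(1, s - flankBp),
                                                e + flankBp))
  nm <- candidates$name
  if (is.null(nm)) nm <- candidates$id
  if (!is.null(nm)) names(gr) <- nm
  gr
}

#' Intersect candidate windows with gene annotation
#'
#' Imports a BED or GFF3 annotation (gene features are kept for GFF) and
#' returns the genes whose span overlaps any window.
#'
#' @param windows [GenomicRanges::GRanges] of candidate windows.
#' @param annotation file path (BED/GFF3) or a GRanges.
#' @return data.frame: gene, chrom, start, end, window (id of the first
#'   overlapped window).
#' @export
intersectGenes <- function(windows, annotation) {
  if (is.character(annotation)) {
    genes <- rtracklayer::import(annotation)
  } else genes <- annotation
  md <- GenomicRanges::mcols(genes)
  if ("type" %in% names(md)) {
    isGene <- as.character(md$type) == "gene"
    if (any(isGene)) genes <- genes[isGene]
  }
  ov <- GenomicRanges::findOverlaps(genes, windows)
  if (!length(ov))
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      window = character(0)))
  gi <- S4Vectors::queryHits(ov); wi <- S4Vectors::subjectHits(ov)
  first <- !duplicated(gi)
  gi <- gi[first]; wi <- wi[first]
  md <- GenomicRanges::mcols(genes)
  id <- if ("ID" %in% names(md)) as.character(md$ID[gi])
        else if ("Name" %in% names(md)) as.character(md$Name[gi])
        else if ("name" %in% names(md)) as.character(md$name[gi])
        else as.character(gi)
  wn <- names(windows)
  data.frame(gene = id,
             chrom = as.character(GenomicRanges::seqnames(genes))[gi],
             start = GenomicRanges::start(genes)[gi],
             end = GenomicRanges::end(genes)[gi],
             window = if (is.null(wn)) as.character(wi) else wn[wi],
             stringsAsFactors = FALSE)
}
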