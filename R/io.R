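# Plain-text readers and writers for the pipeline's tabular formats.

#' Write / read the genetic map as CSV
#'
#' Columns: chrom, marker, cm, bp.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path file path.
#' @return `readMapCsv` returns a \linkS4class{GeneticMap};
#'   `writeMapCsv` returns `path` invisibly.
#' @export
writeMapCsv <- function(map, path) {
  write.csv(mapTable(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMapCsv
#' @export
readMapCsv <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  new("GeneticMap", chrom = as.character(t$chrom),
      marker = as.character(t$marker), cm = as.numeric(t$cm),
      bp = as.numeric(t$bp))
}

#' Write / read a genotype matrix as CSV
#'
#' Lines x markers with line ids in the first column; values are founder
#' codes (1..4) or biallelic 0/1 alleles.
#'
#' @param geno matrix (lines x markers) or a \linkS4class{FounderGeno}.
#' @param path file path.
#' @return `readGenotypeCsv` returns an integer matrix; `writeGenotypeCsv`
#'   returns `path` invisibly.
#' @export
writeGenotypeCsv <- function(geno, path) {
  if (is(geno, "FounderGeno")) geno <- founderCalls(geno)
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeCsv
#' @export
readGenotypeCsv <- function(path) {
  t <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(t[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- t[[1]]
  m
}

#' Write / read the long phenotype table as CSV
#'
#' Columns: line, env, density, rep, value.
#'
#' @param pheno long phenotype data.frame.
#' @param path file path.
#' @return `readPhenotypeCsv` returns the data.frame; `writePhenotypeCsv`
#'   returns `path` invisibly.
#' @export
writePhenotypeCsv <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeCsv
#' @export
readPhenotypeCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write homozygous SNP genotypes as a minimal VCF
#'
#' One homozygous GT (0/0 or 1/1) per line and marker; REF/ALT are the
#' generic alleles A/T. Intended for interoperability with standard VCF
#' tooling on simulated data.
#'
#' @param snp lines x markers 0/1 matrix.
#' @param map \linkS4class{GeneticMap} with bp positions.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeVcf <- function(snp, map, path) {
  stopifnot(identical(colnames(snp), map@marker))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(snp)),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(snp))) {
    gt <- ifelse(is.na(snp[, j]), "./.",
                 ifelse(snp[, j] == 0, "0/0", "1/1"))
    writeLines(paste(c(map@chrom[j], format(map@bp[j], scientific = FALSE),
                       map@marker[j], "A", "T", ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}
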