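# Descriptive per-treatment summaries of the long phenotype table.

#' Per-line replicate means
#'
#' Averages the replicates of each line within environment x density, the
#' convention used for all line-level summaries and traits downstream.
#'
#' @param pheno long phenotype data.frame (line, env, density, rep, value).
#' @return data.frame: line, env, density, value (replicate mean).
#' @export
lineMeans <- function(pheno) {
  stopifnot(all(c("line", "env", "density", "value") %in% names(pheno)))
  out <- aggregate(value ~ line + env + density, data = pheno, FUN = mean)
  out[order(out$env, out$density, out$line), , drop = FALSE]
}

#' Summarize a trait per environment-by-density treatment
#'
#' Line replicate means are summarized per treatment: min, max, mean,
#' standard deviation (n-1), adjusted Fisher-Pearson skewness and excess
#' kurtosis (zero for a Gaussian). Constant groups report sd 0 and flag
#' skewness/kurtosis as undefined (NA) rather than 0.
#'
#' @param pheno long phenotype data.frame (line, env, density, rep, value).
#' @return data.frame: treatment, env, density, n, min, max, mean, std,
#'   skew, kurt, undefined (flag for degenerate groups).
#' @examples
#' ph <- data.frame(line = rep(c("a", "b", "c"), each = 2), env = "E1",
#'                  density = rep(c("D1", "D2"), 3), rep = 1,
#'                  value = c(10, 12, 11, 13, 12, 14))
#' summarizeTrait(ph)
#' @export
summarizeTrait <- function(pheno) {
  lm_ <- lineMeans(pheno)
  groups <- unique(lm_[, c("env", "density")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    v <- lm_$value[lm_$env == g$env & lm_$density == g$density]
    if (length(v) < 2L)
      warning("fewer than 2 observations in treatment ", g$env, g$density)
    s <- if (length(v) >= 2L) sd(v) else NA_real_
    degenerate <- !is.na(s) && s < .Machine$double.eps^0.5
    data.frame(treatment = paste0(g$env, g$density), env = g$env,
               density = g$density, n = length(v),
               min = min(v), max = max(v), mean = mean(v), std = s,
               skew = if (degenerate) NA_real_ else sampleSkewness(v),
               kurt = if (degenerate) NA_real_ else sampleKurtosis(v),
               undefined = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
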