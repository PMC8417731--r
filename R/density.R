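# The conditional "response to density" trait: the high-density phenotype
# with its linear regression on the low-density phenotype removed.

#' Response to density by the conditional-variable method
#'
#' RD_line = xD2 - (C_D1D2 / V_D1) * (xD1 - mean(xD1)), with covariance and
#' variance the sample (n-1) moments over lines. RD is exactly the intercept
#' plus residual of the OLS regression of xD2 on xD1, so cov(RD, xD1) = 0 and
#' mean(RD) = mean(xD2). Lines missing either density are dropped
#' (complete-case). A degenerate xD1 (variance below 1e-12) returns RD = xD2
#' with a warning, the slope being undefined.
#'
#' @param xD1,xD2 per-line replicate means under the two densities; both may
#'   be named by line (names are matched when both are named).
#' @return list of class `rdResult`: rd (named per line), slope, meanD1,
#'   varD1, covD1D2, n, dropped (count of incomplete lines).
#' @examples
#' responseToDensity(c(1, 2, 3), c(2, 4, 6))$rd   # 4 4 4
#' @export
responseToDensity <- function(xD1, xD2) {
  if (!is.null(names(xD1)) && !is.null(names(xD2))) {
    common <- intersect(names(xD1), names(xD2))
    dropped <- (length(xD1) - length(common)) + (length(xD2) - length(common))
    xD1 <- xD1[common]; xD2 <- xD2[common]
  } else {
    if (length(xD1) != length(xD2))
      stop("unnamed inputs must have equal length")
    dropped <- 0L
  }
  keep <- complete.cases(xD1, xD2)
  dropped <- dropped + sum(!keep)
  xD1 <- xD1[keep]; xD2 <- xD2[keep]
  n <- length(xD1)
  if (n < 3L) stop("need at least 3 complete line pairs")
  vD1 <- var(xD1)
  if (vD1 < 1e-12) {
    warning("degenerate variance under D1; returning RD = xD2")
    slope <- NA_real_
    rd <- xD2
  } else {
    slope <- cov(xD1, xD2) / vD1
    rd <- xD2 - slope * (xD1 - mean(xD1))
  }
  structure(list(rd = rd, slope = slope, meanD1 = mean(xD1), varD1 = vD1,
                 covD1D2 = cov(xD1, xD2), n = n, dropped = dropped),
            class = "rdResult")
}

#' Response-to-density trait table per environment
#'
#' Computes RD per environment on line replicate means; lines missing either
#' density within an environment are dropped for that environment.
#'
#' @param pheno long phenotype data.frame (line, env, density, rep, value).
#' @param d1,d2 density labels for the low- and high-density treatment.
#' @return data.frame: line, env, value (the RD trait), consumable by the
#'   scan and association modules as a trait named "RD".
#' @export
rdTable <- function(pheno, d1 = "D1", d2 = "D2") {
  lm_ <- lineMeans(pheno)
  out <- lapply(unique(lm_$env), function(ev) {
    a <- lm_[lm_$env == ev & lm_$density == d1, ]
    b <- lm_[lm_$env == ev & lm_$density == d2, ]
    res <- responseToDensity(setNames(a$value, a$line),
                             setNames(b$value, b$line))
    data.frame(line = names(res$rd), env = ev, value = unname(res$rd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
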