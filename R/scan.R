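# Four-founder genome scan: regression of the trait on founder-origin
# posterior dosages (Haley-Knott style), plain (IM) or adjusted by stepwise
# marker cofactors outside a window around the evaluation point (ICIM-style).

# Least-squares fit of y on the founder dosage matrix X (rows sum to 1, so
# the constant vector is in the column span and RSS1 <= RSS0). Returns the
# sum-to-zero effect deviations, RSS and a degenerate-design flag.
.fitFounder <- function(X, y) {
  qrx <- qr(X)
  rss1 <- sum(qr.resid(qrx, y)^2)
  beta <- qr.coef(qrx, y)
  flagged <- qrx$rank < 2L
  add <- beta - mean(beta, na.rm = TRUE)
  list(rss1 = rss1, add = add, flagged = flagged)
}

.lodFromRss <- function(n, rss0, rss1) {
  if (rss0 <= 0 || rss1 <= 0) return(0)
  max(0, n / 2 * log10(rss0 / rss1))
}

.matchTrait <- function(trait, lines) {
  if (!is.null(names(trait))) {
    trait <- trait[match(lines, names(trait))]
  } else if (length(trait) != length(lines)) {
    stop("trait must be named by line or have one value per line")
  }
  trait
}

#' Interval-mapping scan on founder-origin posteriors
#'
#' At each grid position the trait is regressed on the four founder posterior
#' dosages; LOD = (n/2) log10(RSS0/RSS1) against the intercept-only model,
#' the percent variance explained is 100 (1 - RSS1/RSS0), and founder
#' effects are reported as deviations from their mean (sum-to-zero Add
#' convention). Positions where all lines share one founder are flagged and
#' score LOD 0.
#'
#' @param probs a \linkS4class{FounderProb}.
#' @param trait numeric trait values, named by line (or ordered as the
#'   probability rows); at least 10 lines.
#' @param traitName label carried into the result (e.g. "NN" or "RD").
#' @param positions which evaluation positions to scan: "grid" (default) or
#'   "all".
#' @return A \linkS4class{ScanResult}.
#' @examples
#' map <- buildMap(1, 60, 7)
#' fg <- simulateFWRIL(map, 60, seed = 1)
#' pr <- inferFounderProbs(founderCalls(fg), map)
#' y <- rnorm(60) + (founderCalls(fg)[, 4] == 1)
#' sc <- imScan(pr, setNames(y, lineNames(fg)))
#' @export
imScan <- function(probs, trait, traitName = "NN",
                   positions = c("grid", "all")) {
  stopifnot(is(probs, "FounderProb"))
  positions <- match.arg(positions)
  lines <- lineNames(probs)
  y <- .matchTrait(trait, lines)
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n < 10L) stop("need at least 10 lines with trait values")
  sel <- if (positions == "grid") which(probs@onGrid)
         else seq_along(probs@cm)
  rss0 <- sum((y - mean(y))^2)
  p <- length(sel)
  lod <- pve <- rss1 <- numeric(p)
  flags <- logical(p)
  eff <- matrix(NA_real_, p, 4L)
  for (k in seq_len(p)) {
    X <- probs@prob[keep, sel[k], , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 4L)
    fit <- .fitFounder(X, y)
    rss1[k] <- fit$rss1
    lod[k] <- .lodFromRss(n, rss0, fit$rss1)
    pve[k] <- if (rss0 > 0) 100 * (1 - fit$rss1 / rss0) else NA_real_
    eff[k, ] <- fit$add
    flags[k] <- fit$flagged
    if (fit$flagged) lod[k] <- 0
  }
  new("ScanResult", chrom = probs@chrom[sel], cm = probs@cm[sel], lod = lod,
      pve = pve, effects = eff, rss0 = rss0, rss1 = rss1, n = as.integer(n),
      trait = traitName, method = "IM", flagged = flags)
}

# Stepwise selection of marker cofactors. Candidate blocks are the first
# three founder dosage columns at each marker (the fourth is collinear given
# the intercept). Forward steps add the best block with partial-F p-value
# below alphaIn; backward steps drop any block whose p-value rises above
# alphaOut.
.selectCofactors <- function(M, y, markerIdx, alphaIn, alphaOut,
                             maxSteps = 30L) {
  n <- length(y)
  sel <- integer(0)
  blockCols <- function(set) {
    if (!length(set)) return(NULL)
    do.call(cbind, lapply(set, function(k) M[[k]]))
  }
  withInt <- function(cols) {
    if (is.null(cols)) matrix(1, n, 1) else cbind(1, cols)
  }
  rssOf <- function(cols) sum(qr.resid(qr(withInt(cols)), y)^2)
  repeat {
    changed <- FALSE
    base <- blockCols(sel)
    rssBase <- rssOf(base)
    # forward
    cand <- setdiff(seq_along(M), sel)
    if (length(cand) && length(sel) < maxSteps) {
      pv <- vapply(cand, function(k) {
        X1 <- cbind(1, base, M[[k]])
        q1 <- qr(X1)
        rss1 <- sum(qr.resid(q1, y)^2)
        df1 <- q1$rank
        dfn <- df1 - (if (is.null(base)) 1L else qr(cbind(1, base))$rank)
        dfd <- n - df1
        if (dfn <= 0 || dfd <= 0 || rss1 <= 0) return(1)
        fstat <- ((rssBase - rss1) / dfn) / (rss1 / dfd)
        pf(fstat, dfn, dfd, lower.tail = FALSE)
      }, numeric(1))
      if (min(pv) < alphaIn) {
        sel <- c(sel, cand[which.min(pv)])
        changed <- TRUE
      }
    }
    # backward
    if (length(sel) > 1L) {
      full <- blockCols(sel)
      qf <- qr(cbind(1, full))
      rssFull <- sum(qr.resid(qf, y)^2)
      dfd <- n - qf$rank
      pv <- vapply(seq_along(sel), function(i) {
        red <- blockCols(sel[-i])
        qr_ <- qr(cbind(1, red))
        rssRed <- sum(qr.resid(qr_, y)^2)
        dfn <- qf$rank - qr_$rank
        if (dfn <= 0 || dfd <= 0 || rssFull <= 0) return(0)
        fstat <- ((rssRed - rssFull) / dfn) / (rssFull / dfd)
        pf(fstat, dfn, dfd, lower.tail = FALSE)
      }, numeric(1))
      if (max(pv) > alphaOut) {
        sel <- sel[-which.max(pv)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel
}

#' ICIM-style two-stage scan
#'
#' Stage one selects marker founder-dosage cofactors by stepwise regression
#' (entry at `alphaIn`, removal at `alphaOut`). Stage two rescans the genome:
#' at each position the trait is first adjusted for the selected cofactors
#' lying outside +/- `windowCM` of the position (a cofactor never adjusts its
#' own region), then fitted as in [imScan()]. With no cofactor selected the
#' result reduces to the plain interval-mapping scan.
#'
#' @inheritParams imScan
#' @param alphaIn,alphaOut stepwise entry/removal p-value thresholds.
#' @param windowCM half-width of the exclusion window around the evaluation
#'   position (default 10 cM).
#' @return A \linkS4class{ScanResult} (method "ICIM").
#' @export
icimScan <- function(probs, trait, traitName = "NN", alphaIn = 0.001,
                     alphaOut = 0.002, windowCM = 10) {
  stopifnot(is(probs, "FounderProb"))
  lines <- lineNames(probs)
  y <- .matchTrait(trait, lines)
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n < 10L) stop("need at least 10 lines with trait values")
  mk <- which(probs@atMarker)
  M <- lapply(mk, function(k) probs@prob[keep, k, 1:3, drop = TRUE])
  sel <- .selectCofactors(M, y, mk, alphaIn, alphaOut)
  selPos <- mk[sel]

  gridIdx <- which(probs@onGrid)
  p <- length(gridIdx)
  lod <- pve <- rss1 <- numeric(p)
  flags <- logical(p)
  eff <- matrix(NA_real_, p, 4L)
  rss0all <- sum((y - mean(y))^2)
  for (k in seq_len(p)) {
    pos <- gridIdx[k]
    active <- selPos[probs@chrom[selPos] != probs@chrom[pos] |
                       abs(probs@cm[selPos] - probs@cm[pos]) > windowCM]
    if (length(active)) {
      C <- do.call(cbind, lapply(match(active, mk), function(i) M[[i]]))
      yAdj <- qr.resid(qr(cbind(1, C)), y) + mean(y)
    } else yAdj <- y
    rss0 <- sum((yAdj - mean(yAdj))^2)
    X <- probs@prob[keep, pos, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 4L)
    fit <- .fitFounder(X, yAdj)
    rss1[k] <- fit$rss1
    lod[k] <- .lodFromRss(n, rss0, fit$rss1)
    pve[k] <- if (rss0all > 0) 100 * (1 - fit$rss1 / rss0) *
                (rss0 / rss0all) else NA_real_
    eff[k, ] <- fit$add
    flags[k] <- fit$flagged
    if (fit$flagged) lod[k] <- 0
  }
  new("ScanResult", chrom = probs@chrom[gridIdx], cm = probs@cm[gridIdx],
      lod = lod, pve = pve, effects = eff, rss0 = rss0all, rss1 = rss1,
      n = as.integer(n), trait = traitName, method = "ICIM",
      flagged = flags)
}
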