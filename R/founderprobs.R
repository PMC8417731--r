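# Founder-origin posteriors along the genome: a four-state forward-backward
# pass per chromosome, evaluated at the markers plus a regular cM grid.

# Transition matrix between two evaluation points a gap of `gapCM` apart.
# The per-meiosis recombination fraction (Haldane) is expanded to the
# selfed-RIL scale r* = 2r/(1+2r); conditional on an origin change the new
# founder is uniform over the other three.
.transition <- function(gapCM) {
  rs <- rilAdjust(haldaneR(gapCM))
  m <- matrix(rs / 3, 4, 4)
  diag(m) <- 1 - rs
  m
}

#' Founder-origin posterior probabilities
#'
#' Runs a forward-backward pass over the four founder origins along each
#' chromosome. Emissions at markers compare the line's observed biallelic
#' allele with each founder's allele (probability 1 on match, `eps` on
#' mismatch, uniform for missing); founder-coded input (values 1..4, no
#' parental haplotypes) yields point-mass emissions. Transitions between
#' adjacent evaluation points use the RIL-adjusted recombination
#' r* = 2r/(1+2r) with r the Haldane fraction of the cM gap. Posteriors are
#' returned at the markers and at a regular grid of `stepCM` inclusive of
#' both chromosome ends.
#'
#' @param geno lines x markers matrix: biallelic 0/1 (with
#'   `parentalHaplotypes` supplied) or founder-coded 1..4.
#' @param map the \linkS4class{GeneticMap}; markers must match `geno`
#'   columns.
#' @param parentalHaplotypes 4 x markers founder allele matrix, or NULL for
#'   founder-coded input.
#' @param stepCM evaluation grid step (default 1 cM).
#' @param eps emission floor for an allele mismatch (default 0.001).
#' @return A \linkS4class{FounderProb}.
#' @examples
#' map <- buildMap(1, 40, 5)
#' fg <- simulateFWRIL(map, 8, seed = 1)
#' pr <- inferFounderProbs(founderCalls(fg), map)
#' @export
inferFounderProbs <- function(geno, map, parentalHaplotypes = NULL,
                              stepCM = 1, eps = 0.001) {
  stopifnot(is(map, "GeneticMap"))
  if (!identical(colnames(geno), map@marker))
    stop("genotype columns do not match the map markers")
  founderCoded <- is.null(parentalHaplotypes)
  if (founderCoded) {
    v <- geno[!is.na(geno)]
    if (length(v) && (any(v < 1) || any(v > 4)))
      stop("founder-coded input must contain labels 1..4")
  }
  nL <- nrow(geno)
  chroms <- unique(map@chrom)
  posChrom <- posCm <- list(); posMarker <- list()
  probs <- list()

  for (ch in chroms) {
    mi <- which(map@chrom == ch)
    mcm <- map@cm[mi]
    L <- max(mcm)
    grid <- unique(c(seq(0, L, by = stepCM), L))
    allcm <- sort(unique(round(c(mcm, grid), 9)))
    isMarker <- allcm %in% round(mcm, 9)
    mIdx <- match(round(allcm, 9), round(mcm, 9))  # NA off-marker
    p <- length(allcm)

    # emissions: list over positions of nL x 4 matrices (NULL = uniform)
    emis <- vector("list", p)
    for (k in which(isMarker)) {
      j <- mi[mIdx[k]]
      obs <- geno[, j]
      E <- matrix(1, nL, 4L)
      if (founderCoded) {
        known <- !is.na(obs)
        E[known, ] <- 0
        E[cbind(which(known), obs[known])] <- 1
      } else {
        pa <- parentalHaplotypes[, j]
        for (f in 1:4) {
          E[, f] <- ifelse(is.na(obs), 1, ifelse(obs == pa[f], 1, eps))
        }
      }
      emis[[k]] <- E
    }

    trans <- lapply(seq_len(max(p - 1, 0)),
                    function(k) .transition(allcm[k + 1] - allcm[k]))

    # scaled forward-backward, vectorized over lines
    alpha <- vector("list", p)
    a <- matrix(0.25, nL, 4L)
    if (!is.null(emis[[1]])) a <- a * emis[[1]]
    a <- a / pmax(rowSums(a), .Machine$double.xmin)
    alpha[[1]] <- a
    if (p > 1) for (k in 2:p) {
      a <- alpha[[k - 1]] %*% trans[[k - 1]]
      if (!is.null(emis[[k]])) a <- a * emis[[k]]
      a <- a / pmax(rowSums(a), .Machine$double.xmin)
      alpha[[k]] <- a
    }
    b <- matrix(1, nL, 4L)
    post <- array(0, dim = c(nL, p, 4L))
    post[, p, ] <- alpha[[p]] * b
    if (p > 1) for (k in (p - 1):1) {
      bnext <- b
      if (!is.null(emis[[k + 1]])) bnext <- bnext * emis[[k + 1]]
      b <- bnext %*% t(trans[[k]])
      b <- b / pmax(rowSums(b), .Machine$double.xmin)
      post[, k, ] <- alpha[[k]] * b
    }
    norm <- apply(post, c(1, 2), sum)
    for (f in 1:4) post[, , f] <- post[, , f] / norm

    probs[[ch]] <- post
    posChrom[[ch]] <- rep(ch, p)
    posCm[[ch]] <- allcm
    posMarker[[ch]] <- ifelse(is.na(mIdx), NA_character_,
                              map@marker[mi][mIdx])
  }

  allChrom <- unlist(posChrom, use.names = FALSE)
  allCm <- unlist(posCm, use.names = FALSE)
  allMk <- unlist(posMarker, use.names = FALSE)
  prob <- array(0, dim = c(nL, length(allCm), 4L),
                dimnames = list(rownames(geno), NULL, NULL))
  off <- 0L
  for (ch in chroms) {
    p <- dim(probs[[ch]])[2]
    prob[, off + seq_len(p), ] <- probs[[ch]]
    off <- off + p
  }
  onGrid <- rep(FALSE, length(allCm))
  for (ch in chroms) {
    i <- which(allChrom == ch)
    L <- max(allCm[i])
    g <- unique(c(seq(0, L, by = stepCM), L))
    onGrid[i] <- round(allCm[i], 9) %in% round(g, 9)
  }
  new("FounderProb", prob = prob, chrom = allChrom, cm = allCm,
      atMarker = !is.na(allMk), onGrid = onGrid, marker = allMk, map = map)
}
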