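# Split-block phenotype simulation: the joint ANOVA model read forward.

#' Specify a simulated QTL
#'
#' A QTL is placed at a map position and assigns each founder allele an
#' additive effect (trait units); optionally an allele-by-density interaction
#' matrix. A line's allele at the QTL is its founder label at the nearest
#' marker.
#'
#' @param chrom chromosome id (must exist on the map used for simulation).
#' @param cm genetic position in cM.
#' @param effects numeric length 4, additive effect of each founder allele;
#'   a zero-sum vector keeps the trait mean at the design grand mean.
#' @param interaction 4 x nDensities matrix of allele-by-density effects
#'   (rows should sum to zero across densities); default none.
#' @param name optional label.
#' @return An object of class `QTLSpec` (a validated list).
#' @examples
#' qtlSpec("Chr01", 30, c(1.5, -0.5, -0.5, -0.5))
#' @export
qtlSpec <- function(chrom, cm, effects, interaction = NULL, name = NULL) {
  if (length(effects) != 4L) stop("effects must have length 4")
  if (!is.null(interaction)) {
    interaction <- as.matrix(interaction)
    if (nrow(interaction) != 4L)
      stop("interaction must be a 4 x nDensities matrix")
  }
  structure(list(chrom = chrom, cm = cm, effects = as.numeric(effects),
                 interaction = interaction,
                 name = if (is.null(name)) sprintf("q-%s-%.0fcM", chrom, cm)
                        else name),
            class = "QTLSpec")
}

#' Specify the split-block phenotype design
#'
#' Holds the design dimensions and the fixed and random components of the
#' phenotype model: grand mean, environment / density / main-block effects,
#' and the genotype-by-environment (GE), genotype-by-density-by-environment
#' (GDE) and residual variances.
#'
#' Defaults emulate the study population the package targets: 144 lines, five
#' environments by two densities by three replicates, a grand mean of 14
#' nodes, environment and density margins shrunk from the real population's
#' treatment means, GE and GDE variances at the published joint-analysis
#' estimates, and a residual standard deviation of 1.5 nodes.
#'
#' @param nLines number of lines.
#' @param envEffects named numeric, environment main effects.
#' @param densityEffects named numeric, density main effects.
#' @param repEffects numeric, main-block (replicate) effects.
#' @param mu grand mean (node-count units).
#' @param varGE,varGDE,varE variances (>= 0) of the GE, GDE and residual
#'   components.
#' @param seed master seed; every random draw of the simulation flows from it.
#' @return An object of class `DesignSpec` (a validated list).
#' @examples
#' designSpec(seed = 1)
#' @export
designSpec <- function(nLines = 144,
                       envEffects = c(E1 = 1.0, E2 = 0.2, E3 = -1.2,
                                      E4 = -0.6, E5 = 0.6),
                       densityEffects = c(D1 = -0.5, D2 = 0.5),
                       repEffects = c(-0.1, 0, 0.1),
                       mu = 14,
                       varGE = 0.35, varGDE = 4.37, varE = 2.25,
                       seed = NULL) {
  if (length(repEffects) < 1L) stop("need at least one replicate")
  if (length(densityEffects) < 1L) stop("need at least one density")
  if (any(c(varGE, varGDE, varE) < 0)) stop("variances must be >= 0")
  if (is.null(names(envEffects)))
    names(envEffects) <- paste0("E", seq_along(envEffects))
  if (is.null(names(densityEffects)))
    names(densityEffects) <- paste0("D", seq_along(densityEffects))
  structure(list(nLines = as.integer(nLines), envEffects = envEffects,
                 densityEffects = densityEffects, repEffects = repEffects,
                 mu = mu, varGE = varGE, varGDE = varGDE, varE = varE,
                 seed = seed),
            class = "DesignSpec")
}

#' Default QTL configuration for the bundled simulator
#'
#' Three QTL on separate chromosomes whose summed allelic variance is close
#' to the joint genotype variance published for the population the simulator
#' emulates (about 1.7 squared nodes); the third carries a small
#' allele-by-density interaction.
#'
#' @param densities density labels (default D1, D2).
#' @return list of [qtlSpec()] objects.
#' @export
defaultQtlSpecs <- function(densities = c("D1", "D2")) {
  d <- length(densities)
  inter3 <- matrix(0, 4, d)
  if (d >= 2) inter3[, 1:2] <- c(0.3, -0.1, -0.1, -0.1, -0.3, 0.1, 0.1, 0.1)
  list(
    qtlSpec("Chr01", 30, c(1.6, -0.6, -0.4, -0.6), name = "q1"),
    qtlSpec("Chr02", 50, c(-0.5, 1.2, -0.3, -0.4), name = "q2"),
    qtlSpec("Chr03", 20, c(0.4, 0.4, 0.2, -1.0), interaction = inter3,
            name = "q3"))
}

#' Simulate split-block phenotypes from founder genotypes
#'
#' Generates records x_eijr = mu + E_e + R_r + D_j + sum_q (a_i(q) +
#' ad_i(q),j) + GE_ei + GDE_eij + eps_eijr, where i(q) is the line's founder
#' label at the marker nearest QTL q, and GE, GDE and eps are independent
#' mean-zero Gaussian draws with the design's variances.
#'
#' @param founderGeno a \linkS4class{FounderGeno}.
#' @param qtlSpecs list of [qtlSpec()] objects (positions must lie on the
#'   genotypes' map); may be empty.
#' @param design a [designSpec()].
#' @return Long-format data.frame: line, env, density, rep, value.
#' @examples
#' map <- buildMap(3, 100, 11)
#' fg <- simulateFWRIL(map, 40, seed = 1)
#' ph <- simulatePhenotypes(fg, defaultQtlSpecs(), designSpec(seed = 1))
#' head(ph)
#' @export
simulatePhenotypes <- function(founderGeno, qtlSpecs = list(),
                               design = designSpec()) {
  stopifnot(is(founderGeno, "FounderGeno"), inherits(design, "DesignSpec"))
  map <- founderGeno@map
  geno <- founderGeno@geno
  nL <- nrow(geno)
  envs <- names(design$envEffects)
  dens <- names(design$densityEffects)
  nE <- length(envs); nD <- length(dens); nR <- length(design$repEffects)

  # founder label of each line at each QTL (nearest marker on its chromosome)
  qAllele <- lapply(qtlSpecs, function(q) {
    i <- which(map@chrom == q$chrom)
    if (!length(i)) stop(sprintf("QTL chromosome %s not on map", q$chrom))
    geno[, i[which.min(abs(map@cm[i] - q$cm))]]
  })

  # genetic value per line x density: additive + allele-by-density effects
  gval <- matrix(0, nL, nD, dimnames = list(rownames(geno), dens))
  for (k in seq_along(qtlSpecs)) {
    q <- qtlSpecs[[k]]
    a <- q$effects[qAllele[[k]]]
    gval <- gval + a  # recycled down columns
    if (!is.null(q$interaction)) {
      if (ncol(q$interaction) != nD)
        stop("interaction matrix must have one column per density")
      gval <- gval + q$interaction[qAllele[[k]], , drop = FALSE]
    }
  }

  withSeed(design$seed, {
    ge <- matrix(rnorm(nL * nE, 0, sqrt(design$varGE)), nL, nE,
                 dimnames = list(rownames(geno), envs))
    gde <- array(rnorm(nL * nE * nD, 0, sqrt(design$varGDE)),
                 dim = c(nL, nE, nD))
    out <- expand.grid(rep = seq_len(nR), density = dens, env = envs,
                       line = rownames(geno), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    li <- match(out$line, rownames(geno))
    ei <- match(out$env, envs)
    di <- match(out$density, dens)
    out$value <- design$mu +
      design$envEffects[ei] + design$repEffects[out$rep] +
      design$densityEffects[di] + gval[cbind(li, di)] +
      ge[cbind(li, ei)] + gde[cbind(li, ei, di)] +
      rnorm(nrow(out), 0, sqrt(design$varE))
    out <- out[, c("line", "env", "density", "rep", "value")]
    rownames(out) <- NULL
    out
  })
}
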