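# Split-block (split-plot) ANOVA: density is the main-plot factor with its
# own error stratum (the block-by-density term), genotype the sub-plot
# factor. Balanced data take the closed-form sums-of-squares path; anything
# unbalanced is routed to sequential (type-I) least squares with a warning.

.ssBetween <- function(y, f, mult, ybar) {
  m <- tapply(y, f, mean)
  mult * sum((m - ybar)^2)
}

.isBalanced <- function(...) {
  tab <- table(...)
  all(tab == tab[1])
}

.fRow <- function(ms, df, msDen, dfDen) {
  if (is.na(ms) || is.na(msDen) || dfDen == 0 || msDen <= 0)
    return(c(NA_real_, NA_real_))
  f <- ms / msDen
  c(f, pf(f, df, dfDen, lower.tail = FALSE))
}

#' Split-block ANOVA for one or several environments
#'
#' Balanced data use exact cell-mean projections, so sums of squares and
#' degrees of freedom are additive. F tests follow split-plot rules: density
#' (and, jointly, environment-by-density) is tested against the main-block
#' error stratum; genotype and its interactions against the residual.
#' Unbalanced data fall back to sequential (type-I) least squares in model
#' order, with a warning. Sources with zero degrees of freedom lose their F
#' test with a warning.
#'
#' @param pheno long phenotype data.frame (line, env, density, rep, value).
#' @param scope `"single"` (one environment) or `"joint"` (all environments).
#' @return data.frame of (source, df, ss, ms, f, p) with attributes
#'   `g`, `d`, `r`, `e`, `scope`, `balanced`.
#' @examples
#' map <- buildMap(1, 50, 6)
#' fg <- simulateFWRIL(map, 20, seed = 1)
#' ph <- simulatePhenotypes(fg, design = designSpec(nLines = 20, seed = 1))
#' splitBlockAnova(ph[ph$env == "E1", ], scope = "single")
#' @export
splitBlockAnova <- function(pheno, scope = c("single", "joint")) {
  scope <- match.arg(scope)
  need <- c("line", "density", "rep", "value")
  stopifnot(all(need %in% names(pheno)))
  if (scope == "single") {
    if ("env" %in% names(pheno) && length(unique(pheno$env)) > 1L)
      stop("single-environment scope but several environments present")
  } else {
    stopifnot("env" %in% names(pheno))
  }
  y <- pheno$value
  G <- factor(pheno$line); D <- factor(pheno$density)
  R <- factor(pheno$rep)
  g <- nlevels(G); d <- nlevels(D); r <- nlevels(R)
  if (scope == "joint") {
    E <- factor(pheno$env); e <- nlevels(E)
  } else e <- 1L

  balanced <- if (scope == "single") .isBalanced(G, D, R)
              else .isBalanced(G, D, R, factor(pheno$env))
  if (!balanced) {
    warning("unbalanced data: using sequential (type-I) least squares")
    return(.anovaSequential(pheno, scope, g, d, r, e))
  }

  ybar <- mean(y)
  sstot <- sum((y - ybar)^2)

  if (scope == "single") {
    mR <- tapply(y, R, mean); mD <- tapply(y, D, mean)
    mG <- tapply(y, G, mean)
    mRD <- tapply(y, list(D, R), mean)
    mGD <- tapply(y, list(G, D), mean)
    ssR <- g * d * sum((mR - ybar)^2)
    ssD <- g * r * sum((mD - ybar)^2)
    ssRD <- g * sum((sweep(sweep(mRD, 1, mD), 2, mR) + ybar)^2)
    ssG <- d * r * sum((mG - ybar)^2)
    ssGD <- r * sum((sweep(sweep(mGD, 1, mG), 2, mD) + ybar)^2)
    ssRes <- max(0, sstot - ssR - ssD - ssRD - ssG - ssGD)
    src <- c("R", "D", "RD", "G", "GD", "Residual", "Total")
    df <- c(r - 1, d - 1, (d - 1) * (r - 1), g - 1, (g - 1) * (d - 1),
            d * (g - 1) * (r - 1), g * d * r - 1)
    ss <- c(ssR, ssD, ssRD, ssG, ssGD, ssRes, sstot)
    ms <- ifelse(df > 0, ss / df, NA_real_)
    fp <- rbind(.fRow(ms[1], df[1], ms[3], df[3]),   # R vs main-block error
                .fRow(ms[2], df[2], ms[3], df[3]),   # D vs main-block error
                c(NA, NA),
                .fRow(ms[4], df[4], ms[6], df[6]),   # G vs residual
                .fRow(ms[5], df[5], ms[6], df[6]),   # GD vs residual
                c(NA, NA), c(NA, NA))
    if (any(df[c(1:5)] > 0 & df[c(3, 3, 3, 6, 6)] == 0))
      warning("an error stratum has 0 df; its F tests are dropped")
  } else {
    E <- factor(pheno$env)
    mE <- tapply(y, E, mean); mD <- tapply(y, D, mean)
    mG <- tapply(y, G, mean)
    mER <- tapply(y, list(E, R), mean)
    mED <- tapply(y, list(E, D), mean)
    mERD <- tapply(y, list(E, D, R), mean)
    mGD <- tapply(y, list(G, D), mean)
    mGE <- tapply(y, list(G, E), mean)
    mGDE <- tapply(y, list(G, D, E), mean)
    ssE <- g * d * r * sum((mE - ybar)^2)
    ssER <- g * d * sum(sweep(mER, 1, mE)^2)
    ssD <- g * r * e * sum((mD - ybar)^2)
    ssED <- g * r * sum((sweep(sweep(mED, 1, mE), 2, mD) + ybar)^2)
    # main-block error within environment: e*(r-1)*(d-1) df
    dev <- mERD
    for (ei in seq_len(e)) {
      dev[ei, , ] <- mERD[ei, , ] - outer(mED[ei, ] - mE[ei],
                                          mER[ei, ] - mE[ei], "+") - mE[ei]
    }
    ssERD <- g * sum(dev^2)
    ssG <- d * r * e * sum((mG - ybar)^2)
    ssGD <- r * e * sum((sweep(sweep(mGD, 1, mG), 2, mD) + ybar)^2)
    ssGE <- d * r * sum((sweep(sweep(mGE, 1, mG), 2, mE) + ybar)^2)
    dev3 <- mGDE
    for (ei in seq_len(e)) {
      dev3[, , ei] <- mGDE[, , ei] - mGD -
        outer(mGE[, ei] - mG, mED[ei, ] - mD, "+") + mE[ei] - ybar
    }
    ssGDE <- r * sum(dev3^2)
    ssRes <- max(0, sstot - ssE - ssER - ssD - ssED - ssERD - ssG -
                   ssGD - ssGE - ssGDE)
    src <- c("E", "E(R)", "D", "ED", "E(RD)", "G", "GD", "GE", "GDE",
             "Residual", "Total")
    df <- c(e - 1, e * (r - 1), d - 1, (e - 1) * (d - 1),
            e * (r - 1) * (d - 1), g - 1, (g - 1) * (d - 1),
            (g - 1) * (e - 1), (g - 1) * (d - 1) * (e - 1),
            e * d * (g - 1) * (r - 1), g * d * r * e - 1)
    ss <- c(ssE, ssER, ssD, ssED, ssERD, ssG, ssGD, ssGE, ssGDE, ssRes,
            sstot)
    ms <- ifelse(df > 0, ss / df, NA_real_)
    fp <- rbind(.fRow(ms[1], df[1], ms[2], df[2]),   # E vs E(R)
                c(NA, NA),
                .fRow(ms[3], df[3], ms[5], df[5]),   # D vs E(RD)
                .fRow(ms[4], df[4], ms[5], df[5]),   # ED vs E(RD)
                c(NA, NA),
                .fRow(ms[6], df[6], ms[10], df[10]),
                .fRow(ms[7], df[7], ms[10], df[10]),
                .fRow(ms[8], df[8], ms[10], df[10]),
                .fRow(ms[9], df[9], ms[10], df[10]),
                c(NA, NA), c(NA, NA))
    if (df[2] == 0 || df[5] == 0 || df[10] == 0)
      warning("an error stratum has 0 df; its F tests are dropped")
  }
  out <- data.frame(source = src, df = df, ss = ss, ms = ms,
                    f = fp[, 1], p = fp[, 2], stringsAsFactors = FALSE)
  attr(out, "g") <- g; attr(out, "d") <- d; attr(out, "r") <- r
  attr(out, "e") <- e; attr(out, "scope") <- scope
  attr(out, "balanced") <- TRUE
  out
}

# Sequential (type-I) fallback for unbalanced tables.
.anovaSequential <- function(pheno, scope, g, d, r, e) {
  dat <- data.frame(y = pheno$value, G = factor(pheno$line),
                    D = factor(pheno$density), R = factor(pheno$rep))
  if (scope == "single") {
    f <- y ~ R + D + R:D + G + D:G
    lab <- c("R", "D", "RD", "G", "GD", "Residual")
  } else {
    dat$E <- factor(pheno$env)
    f <- y ~ E + E:R + D + E:D + E:R:D + G + D:G + E:G + E:D:G
    lab <- c("E", "E(R)", "D", "ED", "E(RD)", "G", "GD", "GE", "GDE",
             "Residual")
  }
  fit <- lm(terms(f, keep.order = TRUE), data = dat)
  a <- anova(fit)
  df <- a$Df; ss <- a$`Sum Sq`
  df <- c(df, sum(df)); ss <- c(ss, sum(ss))
  lab <- c(lab, "Total")
  ms <- ifelse(df > 0, ss / df, NA_real_)
  k <- length(lab)
  iRes <- k - 1L
  iMB <- if (scope == "single") 3L else 5L  # main-block error row
  fcol <- pcol <- rep(NA_real_, k)
  testAgainst <- function(i, den) {
    v <- .fRow(ms[i], df[i], ms[den], df[den])
    fcol[i] <<- v[1]; pcol[i] <<- v[2]
  }
  if (scope == "single") {
    testAgainst(1, iMB); testAgainst(2, iMB)
    testAgainst(4, iRes); testAgainst(5, iRes)
  } else {
    testAgainst(1, 2); testAgainst(3, iMB); testAgainst(4, iMB)
    for (i in 6:9) testAgainst(i, iRes)
  }
  out <- data.frame(source = lab, df = df, ss = ss, ms = ms, f = fcol,
                    p = pcol, stringsAsFactors = FALSE)
  attr(out, "g") <- g; attr(out, "d") <- d; attr(out, "r") <- r
  attr(out, "e") <- e; attr(out, "scope") <- scope
  attr(out, "balanced") <- FALSE
  out
}

.msOf <- function(tab, source) {
  i <- match(source, tab$source)
  if (is.na(i)) stop(sprintf("source row '%s' missing from ANOVA table",
                             source))
  tab$ms[i]
}

#' Variance components by expected mean squares
#'
#' Method-of-moments estimates from a balanced split-block ANOVA table.
#' Single environment: residual = MS_res, sigma2_GD = (MS_GD - MS_res)/r,
#' sigma2_G = (MS_G - MS_GD)/(d r). Joint: sigma2_GDE = (MS_GDE - MS_res)/r,
#' sigma2_GD = (MS_GD - MS_GDE)/(e r), sigma2_GE = (MS_GE - MS_GDE)/(d r),
#' sigma2_G = (MS_G - MS_GD - MS_GE + MS_GDE)/(d e r). Negative estimates
#' are truncated to zero and recorded in the `truncated` field.
#'
#' @param anovaTable result of [splitBlockAnova()].
#' @param g,d,e,r design sizes; taken from the table's attributes when
#'   missing.
#' @return list of class `varianceComponents`: sigma2_G, sigma2_GD,
#'   sigma2_GE, sigma2_GDE (joint only), sigma2_res, plus `truncated`.
#' @export
estimateVarComp <- function(anovaTable, g = attr(anovaTable, "g"),
                            d = attr(anovaTable, "d"),
                            e = attr(anovaTable, "e"),
                            r = attr(anovaTable, "r")) {
  scope <- attr(anovaTable, "scope")
  msRes <- .msOf(anovaTable, "Residual")
  trunc0 <- function(x, lab, log) {
    if (!is.na(x) && x < 0) list(v = 0, log = c(log, lab))
    else list(v = x, log = log)
  }
  logv <- character(0)
  if (identical(scope, "joint")) {
    msGDE <- .msOf(anovaTable, "GDE")
    sGDE <- (msGDE - msRes) / r
    sGD <- (.msOf(anovaTable, "GD") - msGDE) / (e * r)
    sGE <- (.msOf(anovaTable, "GE") - msGDE) / (d * r)
    sG <- (.msOf(anovaTable, "G") - .msOf(anovaTable, "GD") -
             .msOf(anovaTable, "GE") + msGDE) / (d * e * r)
    for (nm in c("sG", "sGD", "sGE", "sGDE")) {
      z <- trunc0(get(nm), sub("^s", "sigma2_", nm), logv)
      assign(nm, z$v); logv <- z$log
    }
    out <- list(sigma2_G = sG, sigma2_GD = sGD, sigma2_GE = sGE,
                sigma2_GDE = sGDE, sigma2_res = msRes, truncated = logv)
  } else {
    sGD <- (.msOf(anovaTable, "GD") - msRes) / r
    sG <- (.msOf(anovaTable, "G") - .msOf(anovaTable, "GD")) / (d * r)
    for (nm in c("sG", "sGD")) {
      z <- trunc0(get(nm), sub("^s", "sigma2_", nm), logv)
      assign(nm, z$v); logv <- z$log
    }
    out <- list(sigma2_G = sG, sigma2_GD = sGD, sigma2_res = msRes,
                truncated = logv)
  }
  structure(out, class = "varianceComponents")
}

#' Residual variance implied by a genotype-by-density mean square
#'
#' Inverts the expected-mean-square relation MS_GD = sigma2 + r * sigma2_GD,
#' which recovers the residual variance from published mean squares and
#' variance components.
#'
#' @param msGD genotype-by-density mean square.
#' @param sigma2GD genotype-by-density variance component.
#' @param r number of replicates.
#' @return The residual variance sigma2 = msGD - r * sigma2GD.
#' @examples
#' residualFromComponents(11.92, 3.04, 3)  # 2.80
#' @export
residualFromComponents <- function(msGD, sigma2GD, r) msGD - r * sigma2GD

#' Broad-sense heritability on a line-mean basis
#'
#' Single environment: h2 = sigma2_G / (sigma2_G + sigma2_GD/d +
#' sigma2/(d r)). Joint over e environments: h2 = sigma2_G / (sigma2_G +
#' sigma2_GD/d + sigma2_GDE/(d e) + sigma2/(e d r)); `includeGE = TRUE` adds
#' a sigma2_GE/e term to the joint denominator for users who want the GE
#' stratum counted in the phenotypic variance of line means.
#'
#' @param vc named list or vector with sigma2_G, sigma2_GD, sigma2_res and,
#'   for the joint scope, sigma2_GDE (and sigma2_GE when `includeGE`); e.g.
#'   the result of [estimateVarComp()].
#' @param d number of densities.
#' @param r number of replicates.
#' @param e number of environments; leave NULL for the single-environment
#'   formula.
#' @param includeGE whether the joint denominator includes sigma2_GE/e
#'   (default FALSE).
#' @return list: h2, scope, d, r, e, includeGE; h2 is NA (with a warning)
#'   when every component is zero.
#' @examples
#' heritability(list(sigma2_G = 4.16, sigma2_GD = 3.04, sigma2_res = 2.80),
#'              d = 2, r = 3)$h2   # 0.68 at 2 dp
#' @export
heritability <- function(vc, d, r, e = NULL, includeGE = FALSE) {
  v <- function(nm, required = TRUE) {
    x <- vc[[nm]]
    if (is.null(x)) {
      if (required) stop(sprintf("component %s missing", nm))
      return(0)
    }
    x
  }
  sG <- v("sigma2_G"); sGD <- v("sigma2_GD"); sres <- v("sigma2_res")
  if (any(c(sG, sGD, sres) < 0)) stop("variance components must be >= 0")
  if (is.null(e)) {
    den <- sG + sGD / d + sres / (d * r)
    scope <- "single"
  } else {
    sGDE <- v("sigma2_GDE")
    den <- sG + sGD / d + sGDE / (d * e) + sres / (e * d * r)
    if (includeGE) den <- den + v("sigma2_GE", required = FALSE) / e
    scope <- "joint"
  }
  if (den <= 0) {
    warning("all variance components are zero; heritability undefined")
    h2 <- NA_real_
  } else h2 <- sG / den
  list(h2 = h2, scope = scope, d = d, r = r, e = e, includeGE = includeGE)
}
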