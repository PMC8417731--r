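test_that("summaries use n-1 sd, adjusted skewness and excess kurtosis", {
  v <- c(1, 2, 3, 4, 10)
  ph <- data.frame(line = sprintf("L%d", 1:5), env = "E1", density = "D1",
                   rep = 1, value = v)
  s <- summarizeTrait(ph)
  expect_equal(s$mean, 4)
  expect_equal(s$std, sd(v))
  expect_equal(s$skew, e1071::skewness(v, type = 2))
  expect_equal(s$kurt, e1071::kurtosis(v, type = 2))
  sym <- summarizeTrait(transform(ph, value = 1:5))
  expect_equal(sym$skew, 0)
})

test_that("constant treatments flag skewness and kurtosis as undefined", {
  ph <- data.frame(line = c("a", "b", "c"), env = "E1", density = "D1",
                   rep = 1, value = c(5, 5, 5))
  s <- summarizeTrait(ph)
  expect_equal(s$std, 0)
  expect_true(is.na(s$skew) && is.na(s$kurt))
  expect_true(s$undefined)
})

test_that("balanced split-block SS match the sequential projection oracle", {
  withr::with_seed(42, {
    for (dims in list(c(2, 2, 2), c(5, 2, 3), c(4, 3, 2))) {
      ph <- makeBalancedPheno(dims[1], dims[2], dims[3])
      tab <- splitBlockAnova(ph, "single")
      oracle <- anovaOracleSingle(ph)
      got <- setNames(tab$ss, tab$source)[names(oracle)]
      expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
      expect_equal(sum(tab$df[tab$source != "Total"]),
                   tab$df[tab$source == "Total"])
      expect_equal(sum(tab$ss[tab$source != "Total"]),
                   tab$ss[tab$source == "Total"], tolerance = 1e-8)
    }
  })
})

test_that("split-block degrees of freedom follow the design sizes", {
  withr::with_seed(1, ph <- makeBalancedPheno(144, 2, 3))
  tab <- splitBlockAnova(ph, "single")
  df <- setNames(tab$df, tab$source)
  expect_equal(unname(df["G"]), 143)
  expect_equal(unname(df["GD"]), 143)
  expect_equal(unname(df["Total"]), 863)
})

test_that("joint ANOVA is additive and its components are recoverable", {
  withr::with_seed(7, {
    g <- 40; d <- 2; r <- 3; e <- 3
    ph <- makeBalancedPheno(g, d, r, e)
    tab <- splitBlockAnova(ph, "joint")
    expect_equal(sum(tab$df[tab$source != "Total"]),
                 tab$df[tab$source == "Total"])
    expect_equal(sum(tab$ss[tab$source != "Total"]),
                 tab$ss[tab$source == "Total"], tolerance = 1e-8)
    expect_setequal(tab$source,
                    c("E", "E(R)", "D", "ED", "E(RD)", "G", "GD", "GE",
                      "GDE", "Residual", "Total"))
  })
})

test_that("a constant phenotype yields zero SS and no F statistics", {
  ph <- makeBalancedPheno(3, 2, 2, values = 7)
  tab <- splitBlockAnova(ph, "single")
  expect_true(all(tab$ss == 0))
  expect_true(all(is.na(tab$f)))
})

test_that("unbalanced data fall back to sequential least squares", {
  withr::with_seed(3, ph <- makeBalancedPheno(6, 2, 3))
  ph <- ph[-1, ]
  expect_warning(tab <- splitBlockAnova(ph, "single"), "unbalanced")
  expect_false(attr(tab, "balanced"))
  expect_equal(sum(tab$df[tab$source != "Total"]),
               tab$df[tab$source == "Total"])
})

test_that("variance components follow the expected mean squares", {
  withr::with_seed(13, ph <- makeBalancedPheno(20, 2, 3))
  tab <- splitBlockAnova(ph, "single")
  vc <- estimateVarComp(tab)
  ms <- setNames(tab$ms, tab$source)
  expect_equal(vc$sigma2_res, unname(ms["Residual"]))
  expect_equal(vc$sigma2_GD,
               max(0, unname((ms["GD"] - ms["Residual"]) / 3)))
  # published single-environment row: residual implied by the EMS relation
  expect_equal(residualFromComponents(11.92, 3.04, 3), 2.80)
})

test_that("MS_GD equal to the residual MS gives a zero GD component", {
  tab <- data.frame(source = c("R", "D", "RD", "G", "GD", "Residual",
                               "Total"),
                    df = c(2, 1, 2, 19, 19, 76, 119),
                    ss = NA, ms = c(1, 1, 1, 10, 2.5, 2.5, NA),
                    f = NA, p = NA)
  attr(tab, "scope") <- "single"
  attr(tab, "g") <- 20; attr(tab, "d") <- 2; attr(tab, "r") <- 3
  attr(tab, "e") <- 1
  vc <- estimateVarComp(tab)
  expect_equal(vc$sigma2_GD, 0)
  expect_equal(vc$sigma2_G, (10 - 2.5) / 6)
})

test_that("single-environment components are recovered from simulation", {
  withr::with_seed(17, {
    g <- 500; d <- 2; r <- 3
    gEff <- rnorm(g, 0, sqrt(2))
    gdEff <- matrix(rnorm(g * d, 0, sqrt(1)), g, d)
    ph <- makeBalancedPheno(g, d, r)
    li <- as.integer(factor(ph$line))
    di <- as.integer(factor(ph$density))
    ph$value <- 10 + gEff[li] + gdEff[cbind(li, di)] + rnorm(nrow(ph), 0, 1.5)
    vc <- estimateVarComp(splitBlockAnova(ph, "single"))
    expect_lt(abs(vc$sigma2_G - 2) / 2, 0.15)
    expect_lt(abs(vc$sigma2_GD - 1) / 1, 0.15)
    expect_lt(abs(vc$sigma2_res - 2.25) / 2.25, 0.15)
  })
})

test_that("genotype F p-values are uniform under within-stratum permutation", {
  withr::with_seed(29, {
    g <- 30; d <- 2; r <- 2
    ph <- makeBalancedPheno(g, d, r)
    pvals <- replicate(500, {
      perm <- ph
      for (dd in unique(ph$density)) for (rr in unique(ph$rep)) {
        i <- which(ph$density == dd & ph$rep == rr)
        perm$value[i] <- ph$value[sample(i)]
      }
      tab <- splitBlockAnova(perm, "single")
      tab$p[tab$source == "G"]
    })
    expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  })
})

test_that("heritability formulas behave at the boundaries and on Table rows", {
  expect_equal(heritability(list(sigma2_G = 3, sigma2_GD = 0,
                                 sigma2_res = 0), d = 2, r = 3)$h2, 1)
  expect_equal(heritability(list(sigma2_G = 0, sigma2_GD = 1,
                                 sigma2_res = 1), d = 2, r = 3)$h2, 0)
  expect_warning(
    h <- heritability(list(sigma2_G = 0, sigma2_GD = 0, sigma2_res = 0),
                      d = 2, r = 3)$h2, "undefined")
  expect_true(is.na(h))
  h5 <- heritability(list(sigma2_G = 4.16, sigma2_GD = 3.04,
                          sigma2_res = 2.80), d = 2, r = 3)$h2
  expect_equal(round(h5, 2), 0.68)
})

test_that("heritability is monotone in the signal and error components", {
  base <- list(sigma2_G = 2, sigma2_GD = 1.5, sigma2_res = 2)
  h0 <- heritability(base, d = 2, r = 3)$h2
  up <- base; up$sigma2_G <- 3
  expect_gt(heritability(up, d = 2, r = 3)$h2, h0)
  for (nm in c("sigma2_GD", "sigma2_res")) {
    worse <- base; worse[[nm]] <- base[[nm]] * 2
    expect_lt(heritability(worse, d = 2, r = 3)$h2, h0)
  }
})

test_that("the joint formula's GE-inclusive variant lowers heritability", {
  vc <- list(sigma2_G = 1.75, sigma2_GD = 0.05, sigma2_GE = 0.35,
             sigma2_GDE = 4.37, sigma2_res = 2.2)
  plain <- heritability(vc, d = 2, r = 3, e = 5)$h2
  withGE <- heritability(vc, d = 2, r = 3, e = 5, includeGE = TRUE)$h2
  expect_gt(plain, withGE)
})
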