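test_that("allele classes follow the posterior threshold", {
  p <- rbind(c(1, 0, 0, 0), c(0.4, 0.3, 0.2, 0.1), c(0.1, 0.75, 0.1, 0.05))
  cls <- assignAlleleClass(p, minProb = 0.7)
  expect_equal(as.integer(cls), c(1L, NA, 2L))
  expect_equal(attr(cls, "excluded"), 1L)
})

test_that("class misassignment at informative markers is below 1%", {
  map <- buildMap(1, 100, 26)
  fg <- simulateFWRIL(map, 150, seed = 41)
  ph <- simulateFounderHaplotypes(map, seed = 42)
  snp <- founderToSnp(fg, ph)
  pr <- inferFounderProbs(snp, map, parentalHaplotypes = ph)
  pos <- positionTable(pr)
  bad <- tot <- 0
  for (k in which(pos$atMarker)) {
    j <- match(pos$marker[k], mapTable(map)$marker)
    cls <- assignAlleleClass(probArray(pr)[, k, , drop = TRUE])
    truth <- founderCalls(fg)[, j]
    # informative marker for a line: its true founder's allele is unique
    informative <- vapply(truth, function(f) sum(ph[, j] == ph[f, j]) == 1L,
                          logical(1))
    ok <- !is.na(cls) & informative
    bad <- bad + sum(cls[ok] != truth[ok])
    tot <- tot + sum(ok)
  }
  expect_gt(tot, 300)
  expect_lt(bad / tot, 0.01)
})

test_that("the additive 2x2 table decomposes as hand-evaluated", {
  d <- decomposeDensityEffects(c(1, 2, 3, 4), cls = c(1, 1, 2, 2),
                               density = c("D1", "D2", "D1", "D2"))
  expect_equal(d$mu, 2.5)
  expect_equal(unname(d$G), c(-1, 1))
  expect_equal(unname(d$D), c(-0.5, 0.5))
  expect_true(all(abs(d$GD) < 1e-12))
  expect_equal(d$sigma2_G, 1)
  expect_equal(d$sigma2_GD, 0)
  expect_equal(d$sigma2_p, 1.25)
  expect_equal(d$pveA, 80)
  expect_equal(d$pveAD, 0)
})

test_that("the crossover 2x2 table decomposes as hand-evaluated", {
  d <- decomposeDensityEffects(c(1, 2, 4, 3), cls = c(1, 1, 2, 2),
                               density = c("D1", "D2", "D1", "D2"))
  expect_equal(unname(d$G), c(-1, 1))
  expect_equal(unname(d$D), c(0, 0))
  expect_true(all(abs(abs(d$GD) - 0.5) < 1e-12))
  expect_equal(d$sigma2_GD, 0.25)
  expect_equal(d$pveAD, 20)
})

test_that("a constant table zeroes the effects and flags the PVE shares", {
  expect_warning(
    d <- decomposeDensityEffects(rep(3, 8), cls = rep(1:2, each = 4),
                                 density = rep(c("D1", "D2"), 4)),
    "constant")
  expect_true(all(abs(d$G) < 1e-12))
  expect_true(is.na(d$pveA) && is.na(d$pveAD))
})

test_that("reconstruction and variance bounds hold on random balanced tables", {
  withr::with_seed(55, {
    for (k in 1:200) {
      g <- sample(2:4, 1); dd <- sample(2:3, 1); r <- sample(1:3, 1)
      y <- rnorm(g * dd * r, 10, 3)
      cls <- rep(rep(seq_len(g), each = dd * r))
      dens <- rep(rep(paste0("D", seq_len(dd)), each = r), g)
      d <- decomposeDensityEffects(y, cls, dens)
      recon <- outer(unname(d$G), unname(d$D), "+") + d$mu + unname(d$GD)
      expect_equal(unname(d$cellMeans), recon, tolerance = 1e-10)
      expect_lt(abs(sum(d$fI * d$G)), 1e-9)
      expect_lt(abs(sum(d$D)), 1e-9)
      expect_lte(d$pveA + d$pveAD, 100 + 1e-9)
    }
  })
})

test_that("effects are equivariant under shift and scale of the phenotype", {
  withr::with_seed(56, {
    y <- rnorm(24, 12, 2)
    cls <- rep(1:2, each = 12)
    dens <- rep(rep(c("D1", "D2"), each = 6), 2)
    d0 <- decomposeDensityEffects(y, cls, dens)
    dShift <- decomposeDensityEffects(y + 5, cls, dens)
    expect_equal(dShift$mu, d0$mu + 5)
    expect_equal(dShift$G, d0$G)
    expect_equal(dShift$pveA, d0$pveA)
    dScale <- decomposeDensityEffects(3 * y, cls, dens)
    expect_equal(dScale$G, 3 * d0$G)
    expect_equal(dScale$GD, 3 * d0$GD)
    expect_equal(dScale$pveA, d0$pveA)
    expect_equal(dScale$pveAD, d0$pveAD)
  })
})

.effectFixture <- function(seed, interaction = NULL, effects = c(2, 0, 0, -2)) {
  map <- buildMap(1, 60, 7)
  fg <- simulateFWRIL(map, 144, seed = seed)
  des <- designSpec(nLines = 144, envEffects = c(E1 = 0),
                    densityEffects = c(D1 = -0.5, D2 = 0.5),
                    repEffects = c(0, 0, 0), mu = 14,
                    varGE = 0, varGDE = 0, varE = 2.25, seed = seed + 1)
  q <- qtlSpec("Chr01", 30, effects, interaction = interaction)
  ph <- simulatePhenotypes(fg, list(q), des)
  pr <- inferFounderProbs(founderCalls(fg), map)
  cls <- assignAlleleClass(probArray(pr)[, which(positionTable(pr)$cm == 30)[1], ])
  ci <- cls[match(ph$line, lineNames(fg))]
  decomposeDensityEffects(ph$value, ci, ph$density)
}

test_that("zero-interaction QTL yield small interaction PVE shares", {
  hits <- sum(vapply(1:10, function(s) {
    d <- .effectFixture(200 + s)
    d$pveAD < d$pveA / 10
  }, logical(1)))
  expect_gte(hits, 9)
})

test_that("crossover interactions dominate the additive share", {
  inter <- cbind(c(1.5, -0.5, -0.5, -0.5), -c(1.5, -0.5, -0.5, -0.5))
  hits <- sum(vapply(1:10, function(s) {
    d <- .effectFixture(300 + s, interaction = inter,
                        effects = c(0, 0, 0, 0))
    d$pveAD > d$pveA
  }, logical(1)))
  expect_gte(hits, 8)
})

test_that("per-environment tables obey the zero-sum density pairing", {
  map <- buildMap(1, 60, 7)
  fg <- simulateFWRIL(map, 100, seed = 61)
  des <- designSpec(nLines = 100, envEffects = c(E1 = 0.4, E2 = -0.4),
                    densityEffects = c(D1 = -0.5, D2 = 0.5),
                    repEffects = c(0, 0, 0), mu = 14,
                    varGE = 0.3, varGDE = 1, varE = 2.25, seed = 62)
  q <- qtlSpec("Chr01", 30, c(1.5, -0.5, -0.5, -0.5))
  ph <- simulatePhenotypes(fg, list(q), des)
  pr <- inferFounderProbs(founderCalls(fg), map)
  y1 <- lineMeans(ph[ph$env == "E1" & ph$density == "D1", ])
  sc <- imScan(pr, setNames(y1$value, y1$line))
  calls <- nameQtl(callQtl(sc, map, lodThreshold = 1, treatment = "E1D1"))
  expect_gt(nrow(calls), 0)
  tab <- perEnvironmentEffectTable(calls, pr, ph)
  qtlRows <- tab[tab$qtl != "Total", ]
  for (i in 1:4) {
    a <- qtlRows[[paste0("add", i, "_D1")]]
    b <- qtlRows[[paste0("add", i, "_D2")]]
    ok <- !is.na(a) & !is.na(b)
    expect_equal(a[ok], -b[ok], tolerance = 1e-9)
  }
  tot <- tab[tab$qtl == "Total", ]
  expect_equal(tot$pveA,
               tapply(qtlRows$pveA, qtlRows$env, sum)[tot$env],
               ignore_attr = TRUE)
})
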