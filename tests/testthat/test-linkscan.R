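# Founder-origin posteriors and the four-founder genome scan.

test_that("founder-coded markers give point-mass posteriors summing to one", {
  map <- buildMap(1, 40, 5)
  fg <- simulateFWRIL(map, 20, seed = 1)
  pr <- inferFounderProbs(founderCalls(fg), map)
  pos <- positionTable(pr)
  s <- apply(probArray(pr), c(1, 2), sum)
  expect_true(all(abs(s - 1) < 1e-9))
  for (k in which(pos$atMarker)) {
    j <- match(pos$marker[k], mapTable(map)$marker)
    hit <- probArray(pr)[cbind(seq_len(20), k, founderCalls(fg)[, j])]
    expect_true(all(hit > 0.999))
  }
})

test_that("midpoint posteriors equal the two-point enumeration oracle", {
  d <- 20
  map <- twoMarkerMap(d)
  geno <- matrix(c(1L, 3L), nrow = 1,
                 dimnames = list("L1", c("mA", "mB")))
  pr <- inferFounderProbs(geno, map, stepCM = 10)
  pos <- positionTable(pr)
  mid <- which(pos$cm == 10)
  # oracle: P(m | f0 = 1, f20 = 3) by direct enumeration of transition
  # products over the four origins
  rs <- local({
    r <- 0.5 * (1 - exp(-0.02 * (d / 2)))
    2 * r / (1 + 2 * r)
  })
  Tm <- matrix(rs / 3, 4, 4); diag(Tm) <- 1 - rs
  w <- Tm[1, ] * Tm[, 3]
  expect_equal(unname(probArray(pr)[1, mid, ]), unname(w / sum(w)),
               tolerance = 1e-9)
})

test_that("a locally constant founder design scores LOD zero and is flagged", {
  map <- buildMap(1, 30, 4)
  geno <- matrix(1L, nrow = 12, ncol = 4,
                 dimnames = list(sprintf("L%02d", 1:12),
                                 mapTable(map)$marker))
  pr <- inferFounderProbs(geno, map)
  y <- setNames(rnorm(12), rownames(geno))
  sc <- imScan(pr, y)
  expect_true(all(sc@lod == 0))
  expect_true(all(sc@flagged))
})

test_that("scan effects at an informative marker equal class-mean deviations", {
  map <- buildMap(1, 40, 5)
  fg <- simulateFWRIL(map, 80, seed = 4)
  pr <- inferFounderProbs(founderCalls(fg), map)
  y <- setNames(rnorm(80, 14, 2), lineNames(fg))
  sc <- imScan(pr, y)
  j <- 3                                 # marker at 20 cM, on the grid
  cls <- founderCalls(fg)[, j]
  expect_gte(length(unique(cls)), 4)
  gm <- tapply(y, cls, mean)
  oracle <- gm - mean(gm)                # sum-to-zero class-mean deviations
  k <- which(sc@cm == mapTable(map)$cm[j])
  expect_equal(unname(sc@effects[k, as.integer(names(oracle))]),
               as.numeric(oracle), tolerance = 1e-8)
})

test_that("LOD is invariant to affine transformation of the trait", {
  map <- buildMap(1, 50, 6)
  fg <- simulateFWRIL(map, 60, seed = 6)
  pr <- inferFounderProbs(founderCalls(fg), map)
  y <- setNames(rnorm(60) + founderCalls(fg)[, 3], lineNames(fg))
  s1 <- imScan(pr, y)
  s2 <- imScan(pr, 3.7 * y - 21)
  expect_equal(s1@lod, s2@lod, tolerance = 1e-8)
})

test_that("with no cofactor selected the ICIM scan reduces to plain IM", {
  map <- buildMap(1, 50, 6)
  fg <- simulateFWRIL(map, 40, seed = 7)
  pr <- inferFounderProbs(founderCalls(fg), map)
  y <- setNames(rnorm(40), lineNames(fg))
  im <- imScan(pr, y)
  ic <- icimScan(pr, y, alphaIn = 0)     # entry threshold never met
  expect_equal(im@lod, ic@lod, tolerance = 1e-10)
  expect_equal(im@effects, ic@effects, tolerance = 1e-10)
  expect_equal(im@pve, ic@pve, tolerance = 1e-10)
})

test_that("the cofactor window protects a QTL from adjusting itself away", {
  map <- buildMap(1, 100, 26)
  fg <- simulateFWRIL(map, 144, seed = 8)
  pr <- inferFounderProbs(founderCalls(fg), map)
  eff <- c(2, -1, -0.5, -0.5)
  y <- setNames(eff[founderCalls(fg)[, 11]] + rnorm(144, 0, 1.5),
                lineNames(fg))
  ic <- icimScan(pr, y, alphaIn = 0.01, alphaOut = 0.02)
  truth <- mapTable(map)$cm[11]
  near <- abs(ic@cm - truth) <= 10
  expect_gte(max(ic@lod[near]), 3)
})

test_that("ICIM separates two linked QTL on one chromosome", {
  map <- buildMap(1, 100, 26)
  fg <- simulateFWRIL(map, 200, seed = 9)
  pr <- inferFounderProbs(founderCalls(fg), map)
  g <- founderCalls(fg)
  e1 <- c(2.5, -1.5, -0.5, -0.5)
  e2 <- c(-0.5, -0.5, -1.5, 2.5)
  y <- setNames(e1[g[, 6]] + e2[g[, 21]] + rnorm(200, 0, 1.5),
                lineNames(fg))
  ic <- icimScan(pr, y, alphaIn = 0.01, alphaOut = 0.02)
  cmv <- mapTable(map)$cm
  expect_gte(max(ic@lod[abs(ic@cm - cmv[6]) <= 10]), 3)
  expect_gte(max(ic@lod[abs(ic@cm - cmv[21]) <= 10]), 3)
})

test_that("doubling a QTL effect does not decrease the median peak LOD", {
  map <- buildMap(1, 100, 11)
  peaks <- function(scale) {
    vapply(1:5, function(s) {
      fg <- simulateFWRIL(map, 144, seed = 100 + s)
      pr <- inferFounderProbs(founderCalls(fg), map)
      y <- setNames(scale * c(1.5, -0.5, -0.5, -0.5)[founderCalls(fg)[, 6]] +
                      rnorm(144, 0, 2), lineNames(fg))
      max(imScan(pr, y)@lod)
    }, numeric(1))
  }
  withr::with_seed(10, l1 <- peaks(1))
  withr::with_seed(10, l2 <- peaks(2))
  expect_gte(median(l2), median(l1))
})

test_that("callQtl segments runs above threshold and names regions", {
  map <- buildMap(1, 100, 11)
  mkScan <- function(lod, trait = "NN", method = "IM") {
    p <- length(lod)
    new("ScanResult", chrom = rep("Chr01", p), cm = seq(0, 100, length.out = p),
        lod = lod, pve = rep(5, p), effects = matrix(0, p, 4),
        rss0 = 1, rss1 = rep(1, p), n = 144L, trait = trait,
        method = method, flagged = rep(FALSE, p))
  }
  # all below threshold: no calls
  expect_equal(nrow(callQtl(mkScan(rep(1, 21)), map)), 0)
  # two runs separated by a sub-threshold valley: exactly two calls
  lod <- c(0, 4, 5, 4, 1, 1, 4, 6, 2, 0, rep(0, 11))
  calls <- callQtl(mkScan(lod), map, treatment = "E1D1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$lod, c(5, 6))
  # two treatments peaking in the same interval share the sequence number
  c1 <- callQtl(mkScan(lod), map, treatment = "E1D1")
  c2 <- callQtl(mkScan(lod + 0.5), map, treatment = "E2D2")
  named <- nameQtl(rbind(c1, c2))
  expect_equal(named$name[1], named$name[3])
  expect_equal(named$name[2], named$name[4])
  # an RD-trait call in the same region cross-references the NN name
  c3 <- callQtl(mkScan(lod, trait = "RD"), map, treatment = "E1RD")
  named2 <- nameQtl(rbind(c1, c3))
  expect_match(named2$name[3], "^qlRDNN-1-1$")
  expect_equal(named2$xref[3], named2$name[1])
})
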