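test_that("marker filters apply the MAF/missing/het rules", {
  # hand-built matrix: 20 lines x 5 markers
  mk <- function(freqB, miss = 0, het = 0, n = 100) {
    nB <- round(freqB * n)
    nH <- round(het * n)
    g <- c(rep(2, nB - nH), rep(1, nH), rep(0, n - nB + nH - round(miss * n)),
           rep(NA, round(miss * n)))
    g[seq_len(n)]
  }
  geno <- rbind(perfect = mk(0.5), lowMaf = mk(0.09),
                missy = mk(0.5, miss = 0.4), hetty = mk(0.5, het = 0.10),
                borderline = mk(0.10))
  G <- GenotypeMatrix(geno, chrom = rep("chr1", 5), pos = 1:5)
  Gf <- filterMarkers(G)
  kept <- rownames(Gf)
  expect_true("perfect" %in% kept)
  expect_false("lowMaf" %in% kept)    # MAF 0.09 < 0.1 removed
  expect_false("missy" %in% kept)
  expect_false("hetty" %in% kept)
  expect_true("borderline" %in% kept) # MAF exactly 0.1 retained

  # brute-force oracle on a random matrix, and idempotence
  withr::with_seed(90, {
    rg <- matrix(sample(c(0, 1, 2, NA), 60 * 40, replace = TRUE,
                        prob = c(0.42, 0.04, 0.42, 0.12)), nrow = 60)
    rownames(rg) <- paste0("m", 1:60)
    colnames(rg) <- paste0("l", 1:40)
  })
  RG <- GenotypeMatrix(rg, chrom = rep("chr1", 60), pos = 1:60)
  RGf <- filterMarkers(RG)
  oracle <- vapply(seq_len(nrow(rg)), function(i) {
    v <- rg[i, ]
    fB <- mean(v, na.rm = TRUE) / 2
    maf <- min(fB, 1 - fB)
    if (is.nan(maf)) maf <- 0
    maf >= 0.1 && mean(is.na(v)) <= 0.30 &&
      mean(v == 1, na.rm = TRUE) <= 0.06
  }, logical(1))
  expect_setequal(rownames(RGf), rownames(rg)[oracle])
  expect_identical(rownames(filterMarkers(RGf)), rownames(RGf))
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroniThreshold(0.05, 8237), 0.05 / 8237)
  expect_equal(bonferroniThreshold(0.05, 8237), 6.07e-6, tolerance = 1e-3)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  m <- c(1, 10, 100, 1000)
  expect_true(all(diff(bonferroniThreshold(0.05, m)) < 0))
  expect_error(bonferroniThreshold(0.05, 0))
})

test_that("marker scan matches closed-form OLS and flags perfect signals", {
  pop <- smallPopulation(nLines = 80, seed = 91)
  g <- genoCodes(pop$G)
  # perfect signal: y = 2 * dose at marker 10
  y <- setNames(2 * g[10, ], colnames(g))
  res <- markerScan(y, pop$G)
  expect_equal(res$effect[10], 2, tolerance = 1e-9)
  expect_lt(res$p[10], 1e-20)
  expect_true(res$significant[10])

  # per-marker p equals lm() on small instances (het set missing)
  yr <- withr::with_seed(92, setNames(rnorm(80) + 0.5 * g[25, ],
                                      colnames(g)))
  res2 <- markerScan(yr, pop$G)
  for (i in c(1, 25, 37)) {
    x <- g[i, ]
    x[x == 1] <- NA
    sm <- summary(lm(yr ~ x))
    expect_equal(res2$effect[i], coef(sm)[2, 1], tolerance = 1e-10)
    expect_equal(res2$se[i], coef(sm)[2, 2], tolerance = 1e-10)
    expect_equal(res2$p[i], coef(sm)[2, 4], tolerance = 1e-10)
  }

  # monomorphic marker: p = 1, effect undefined
  gm <- rbind(mono = rep(0, 80), g[1:3, ])
  GM <- GenotypeMatrix(gm, chrom = rep("chr1", 4), pos = 1:4)
  rm3 <- markerScan(yr, GM)
  expect_equal(rm3$p[rm3$marker == "mono"], 1)
  expect_true(is.na(rm3$effect[rm3$marker == "mono"]))
})

test_that("the simulated 3-locus architecture is recovered by scan + epistasis", {
  pop <- smallPopulation(nLines = 300, seed = 93)
  Gf <- filterMarkers(pop$G)
  scan <- markerScan(pop$hd, Gf)
  # all three simulated main-effect loci exceed Bonferroni
  for (mk in c("chr1_m10", "chr2_m10", "chr3_m10")) {
    expect_true(scan$significant[scan$marker == mk], label = mk)
  }
  epi <- epistasisScan(pop$hd, Gf, scan$marker[scan$significant])
  hit <- epi$significant & grepl("chr1_", epi$marker1) &
    grepl("chr3_", epi$marker2)
  expect_true(any(hit))
})

test_that("pure interactions are caught and additive pairs stay null", {
  pop <- smallPopulation(nLines = 250, seed = 94)
  g <- genoCodes(pop$G)
  x1 <- g[10, ] - 1
  x2 <- g[50, ] - 1
  # sign-reversing epistasis: the second locus helps in one background and
  # hurts in the other, so its marginal effect is near zero
  y <- withr::with_seed(95,
    setNames(3 * x1 * x2 + rnorm(250, 0, 0.5), colnames(g)))
  epi <- epistasisScan(y, pop$G, c("chr1_m10", "chr3_m10"))
  expect_lt(epi$pInteraction[1], 1e-10)
  # oracle: two-way ANOVA on the four homozygote class means
  ok <- x1 != 0 & x2 != 0
  an <- anova(lm(y[ok] ~ factor(x1[ok]) * factor(x2[ok])))
  expect_equal(log10(epi$pInteraction[1]),
               log10(an$`Pr(>F)`[3]), tolerance = 0.35)

  # the marginal scan misses the sign-reversing locus entirely; only the
  # interaction model exposes it
  scan <- markerScan(y, pop$G)
  expect_false(scan$significant[scan$marker == "chr3_m10"])

  # additive trait: interaction p behaves like a null p-value
  yAdd <- withr::with_seed(96,
    setNames(x1 + 0.8 * x2 + rnorm(250, 0, 1), colnames(g)))
  ps <- vapply(1:40, function(i) {
    yp <- setNames(sample(yAdd), names(yAdd))
    epistasisScan(yp, pop$G, c("chr1_m10", "chr3_m10"))$pInteraction[1]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)

  # LOD is zero when the interaction adds nothing
  yFlat <- setNames(rep(c(1, 2), length.out = 250), colnames(g))
  epi0 <- epistasisScan(withr::with_seed(97, setNames(rnorm(250),
                                                      colnames(g))),
                        pop$G, c("chr1_m10", "chr3_m10"))
  expect_gte(epi0$lod[1], 0)

  # perfectly collinear pair is skipped with a flag
  dup <- rbind(a = g[10, ], b = g[10, ])
  GD <- GenotypeMatrix(dup, chrom = c("chr1", "chr1"), pos = 1:2)
  epiD <- epistasisScan(y, GD, c("a", "b"))
  expect_true(epiD$collinear[1])
  expect_true(is.na(epiD$pInteraction[1]))
})

test_that("segregation tests recover the 3:1 dominant-epistasis expectation", {
  # enumeration oracle: 4 equal two-locus inbred classes, 3 early : 1 late
  expect_equal(dominantEpistasisProportions(),
               c(early = 0.75, late = 0.25))
  exact <- segregationTest(225, 75)
  expect_equal(exact$chisq, 0)
  expect_equal(exact$p, 1)
  even <- segregationTest(150, 150)
  # oracle: sum((O-E)^2/E) with E = (225, 75) -> 25 + 75 = 100
  expect_equal(even$chisq, (150 - 225)^2 / 225 + (150 - 75)^2 / 75)
  expect_lt(even$p, 1e-10)
  expect_equal(even$expected, c(225, 75))
  expect_error(segregationTest(0, 0))
})

test_that("G-BLUP equals closed-form ridge on a tiny instance", {
  geno <- matrix(c(0, 2, 2, 0, 2,
                   2, 0, 2, 0, 0,
                   0, 0, 2, 2, 2), nrow = 3, byrow = TRUE)
  rownames(geno) <- paste0("m", 1:3)
  colnames(geno) <- paste0("l", 1:5)
  G <- GenotypeMatrix(geno, chrom = rep("chr1", 3), pos = 1:3)
  K <- genomicRelationship(G)
  # oracle: VanRaden by hand
  doses <- t(geno)
  p <- colMeans(doses) / 2
  Z <- sweep(doses, 2, 2 * p)
  expect_equal(K, tcrossprod(Z) / (2 * sum(p * (1 - p))),
               tolerance = 1e-12)

  # prediction of line 5 from 1-4 equals the hand mixed-model solution
  y <- c(l1 = 10, l2 = 12, l3 = 11, l4 = 14, l5 = 13)
  pred <- gblupPredict(y, K, testIdx = 5)
  fit <- phenoQTL:::.gblupREML(y[1:4], K[1:4, 1:4])
  A <- K[1:4, 1:4] + fit$lambda * diag(4)
  byHand <- fit$mu + K[5, 1:4, drop = FALSE] %*%
    solve(A, y[1:4] - fit$mu)
  expect_equal(as.numeric(pred), as.numeric(byHand), tolerance = 1e-10)
})

test_that("cross-validated prediction behaves across heritability regimes", {
  map <- makeGeneticMap(5, 30, 100)
  G <- simulateRILPopulation(map, 120, seed = 98)
  # near-noiseless additive polygenic trait: r close to 1
  yClean <- geneticValues(G, traitArchitecture(polygenicVar = 1), seed = 99)
  cvC <- genomicPredictionCV(yClean, G, reps = 20, seed = 100)
  expect_gt(cvC$meanR, 0.8)

  # h2 = 0.5 polygenic trait: variance-modelled ratio plausible and stable
  yNoisy <- withr::with_seed(101, yClean + rnorm(120, 0, 1))
  cvN <- genomicPredictionCV(yNoisy, G, reps = 60, seed = 102)
  expect_gt(cvN$meanR, 0.3)
  expect_true(cvN$varianceModeled > 0 && cvN$varianceModeled < 1.2)
  cvN2 <- genomicPredictionCV(yNoisy, G, reps = 60, seed = 103)
  expect_equal(cvN$meanR, cvN2$meanR, tolerance = 0.15)

  expect_error(genomicPredictionCV(yClean[1:10], G, reps = 5), ">= 30")
})
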