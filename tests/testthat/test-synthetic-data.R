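test_that("genetic maps are evenly spaced with the requested marker count", {
  m1 <- makeGeneticMap(1, 2, 100)
  expect_equal(nMarkers(m1), 2)
  expect_equal(unname(positions(m1)), c(0, 100))

  m2 <- makeGeneticMap(2, 3, 50)
  expect_equal(unname(positions(m2)), rep(c(0, 25, 50), 2))
  expect_equal(unname(chromosomes(m2)), rep(c("chr1", "chr2"), each = 3))

  # genome-scale map: 21 chromosomes x 400 markers
  m3 <- makeGeneticMap(21, 400, 150)
  expect_equal(nMarkers(m3), 8400)

  expect_error(makeGeneticMap(0, 2, 100))
  expect_error(makeGeneticMap(2, 0, 100))
})

test_that("RIL residual heterozygosity matches 0.5^g and alleles are balanced", {
  map <- makeGeneticMap(3, 20, 120)
  G <- simulateRILPopulation(map, 300, nSelfingGenerations = 5, seed = 11)
  g <- genoCodes(G)
  # mean het over 300 x 60 loci: expectation 0.5^5, binomial-ish MC error
  expect_equal(mean(g == 1), 0.5^5, tolerance = 0.25)
  # per-locus allele frequency ~ 0.5: every locus inside a generous
  # binomial CI (lines are near-homozygous, so n = 300 independent lines)
  fB <- alleleFreqB(G)
  ciHalf <- 4 * sqrt(0.25 / 300)
  expect_true(all(abs(fB - 0.5) < ciHalf))

  g3 <- simulateRILPopulation(map, 400, nSelfingGenerations = 3, seed = 12)
  expect_equal(mean(genoCodes(g3) == 1), 0.5^3, tolerance = 0.15)
})

test_that("markers on a zero-length chromosome are perfectly co-inherited", {
  map <- makeGeneticMap(1, 5, 0)
  G <- simulateRILPopulation(map, 80, seed = 3)
  g <- genoCodes(G)
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1)))
})

test_that("adjacent-marker recombination matches the Haldane map function", {
  # single meiosis distance d cM -> recombination fraction (1-exp(-2d/100))/2;
  # RILs accumulate recombination over selfing: R = 2r/(1+2r) (Haldane for
  # selfed inbreds). Check the realized RIL recombinant fraction against it.
  map <- makeGeneticMap(1, 2, 20)  # adjacent markers 20 cM apart
  G <- simulateRILPopulation(map, 2000, nSelfingGenerations = 8, seed = 5)
  g <- genoCodes(G)
  hom <- g[, g[1, ] != 1 & g[2, ] != 1, drop = FALSE]
  recFrac <- mean(hom[1, ] != hom[2, ])
  r <- (1 - exp(-2 * 0.20)) / 2
  expect_equal(recFrac, 2 * r / (1 + 2 * r), tolerance = 0.12)
})

test_that("segregation distortion pushes allele frequency toward the favoured allele", {
  map <- makeGeneticMap(1, 5, 80)
  # analytic expectation with gamete survival p = ratio/(ratio+1): track
  # genotype-class frequencies over selfing generations
  p <- 3 / 4
  freq <- c(AA = 0, AB = 1, BB = 0)
  for (g in 1:5) {
    freq <- c(AA = freq[["AA"]] + freq[["AB"]] * (1 - p)^2,
              AB = freq[["AB"]] * 2 * p * (1 - p),
              BB = freq[["BB"]] + freq[["AB"]] * p^2)
  }
  expectedB <- freq[["BB"]] + freq[["AB"]] / 2

  G <- simulateRILPopulation(map, 1500, nSelfingGenerations = 5,
                             distortion = list(marker = 3, ratio = 3),
                             seed = 9)
  fB <- alleleFreqB(G)[3]
  expect_gt(fB, 0.6)
  expect_equal(unname(fB), expectedB, tolerance = 0.05)
  expect_error(simulateRILPopulation(map, 10,
                                     distortion = list(marker = 99,
                                                       ratio = 3)),
               "outside map")
})

test_that("genetic values follow the architecture", {
  pop <- smallPopulation(nLines = 150, seed = 21)
  # null architecture: everyone at the intercept
  null <- traitArchitecture(intercept = 125)
  expect_true(all(geneticValues(pop$G, null, seed = 1) == 125))

  # sign-reversing two-locus architecture: enumeration of the four
  # homozygote class means gives the dominant-epistasis 3-alike-1-distinct
  # pattern
  arch <- traitArchitecture(
    qtl = data.frame(marker = c(10, 50), effect = c(1, 1)),
    interactions = data.frame(marker1 = 10, marker2 = 50, effect = 1),
    intercept = 0)
  val <- geneticValues(pop$G, arch, seed = 1)
  g <- genoCodes(pop$G)
  xA <- g[10, ] - 1
  xB <- g[50, ] - 1
  hom <- xA != 0 & xB != 0
  classMean <- tapply(val[hom], interaction(xA[hom], xB[hom]), mean)
  # oracle: direct enumeration mu + a*xA + b*xB + c*xA*xB
  enum <- c(`-1.-1` = -1, `1.-1` = -1, `-1.1` = -1, `1.1` = 3)
  expect_equal(classMean[names(enum)], enum[names(enum)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(abs(classMean - max(classMean)) < 1e-9), 1)

  # purely polygenic trait: sample variance of line values equals the
  # requested variance (exact by construction, checked across seeds)
  poly <- traitArchitecture(polygenicVar = 0.5, intercept = 0)
  for (s in 1:3) {
    v <- geneticValues(pop$G, poly, seed = s)
    expect_equal(var(v), 0.5, tolerance = 1e-10)
  }

  bad <- traitArchitecture(qtl = data.frame(marker = 9999, effect = 1))
  expect_error(geneticValues(pop$G, bad), "outside")
})

test_that("trial plots collapse to the genetic value when all variances are zero", {
  hd <- setNames(c(120, 125, 130), c("A", "B", "C"))
  tr <- simulateTrial(hd, rate = 0.3, nReps = 2, sigma2E = 0,
                      sigma2R = 0, seed = 1)
  expect_equal(nrow(tr), 6)
  spread <- tapply(tr$heading_date, tr$entry, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_equal(as.numeric(tapply(tr$heading_date, tr$entry,
                                 unique)[c("A", "B", "C")]),
               c(120, 125, 130))
  # curve anchored through the heading date
  expect_equal(tr$phi2, -tr$phi3 * tr$heading_date)
  expect_error(simulateTrial(hd, nReps = 2, nRows = 2, nCols = 2),
               "grid too small")
  expect_error(simulateTrial(hd, rhoRow = 1.2), "correlations")
})

test_that("spatial residuals follow the AR1 x AR1 correlogram", {
  hd <- setNames(rep(125, 50), sprintf("L%02d", 1:50))
  lag1 <- function(rhoRow, rhoCol, seed) {
    tr <- simulateTrial(hd, rate = 0.3, nReps = 2, nRows = 10, nCols = 10,
                        sigma2E = 1, rhoRow = rhoRow, rhoCol = rhoCol,
                        seed = seed)
    resid <- tr$heading_date - 125
    M <- matrix(NA_real_, 10, 10)
    M[cbind(tr$row, tr$col)] <- resid
    list(row = cor(as.vector(M[-1, ]), as.vector(M[-10, ])),
         col = cor(as.vector(M[, -1]), as.vector(M[, -10])))
  }
  # average the empirical lag-1 correlations over seeds (MC oracle)
  r0 <- sapply(1:30, function(s) unlist(lag1(0, 0, s)))
  expect_lt(abs(mean(r0["row", ])), 0.08)
  expect_lt(abs(mean(r0["col", ])), 0.08)
  r5 <- sapply(1:30, function(s) unlist(lag1(0.5, 0, s)))
  expect_equal(mean(r5["row", ]), 0.5, tolerance = 0.12)
})

test_that("visual scores discretize the latent curve and mislabel at the stated rates", {
  truth <- data.frame(plot = "p1", phi2 = -25, phi3 = 0.2)
  # noise off: exact asymptotes and midpoint
  s <- sampleVisualScores(truth, days = c(60, 125, 190), p10 = 0,
                          p20 = 0, seed = 1)
  expect_equal(s$percent, c(0, 50, 100))

  # noise on at an interior class: empirical shift frequencies
  big <- data.frame(plot = sprintf("p%05d", 1:100000), phi2 = -25,
                    phi3 = 0.2)
  sn <- sampleVisualScores(big, days = 125, seed = 2)
  shift <- abs(sn$percent - 50)
  expect_equal(mean(shift == 10), 0.10, tolerance = 0.1)
  expect_equal(mean(shift == 20), 0.05, tolerance = 0.1)
  expect_equal(mean(shift == 0), 0.85, tolerance = 0.02)
  expect_true(all(sn$percent %in% seq(0, 100, 10)))

  # boundary classes clip, support stays valid
  sb <- sampleVisualScores(big[1:20000, ], days = 60, seed = 3)
  expect_true(all(sb$percent %in% c(0, 10, 20)))
})

test_that("image predictions concentrate on the true class and vote to truth", {
  truth <- data.frame(plot = "p1", phi2 = -25, phi3 = 0.2)
  # confusion 0: every image a point mass on the true class (50% -> class 5)
  imgs <- simulateImagePredictions(truth, day = 125, nImages = 12,
                                   leak = 0, seed = 4)
  expect_equal(nrow(imgs), 12)
  P <- as.matrix(imgs[, paste0("p", seq(0, 100, 10))])
  expect_true(all(P[, "p50"] == 1))
  expect_equal(unname(rowSums(P)), rep(1, 12))

  # heavy leakage: individual argmax can err, plot consensus recovers truth
  imgs2 <- simulateImagePredictions(truth, day = 125, nImages = 60,
                                    leak = 0.3, nDraws = 25, seed = 5)
  P2 <- as.matrix(imgs2[, paste0("p", seq(0, 100, 10))])
  cls <- apply(P2, 1, which.max) - 1
  expect_equal(consensusPlot(cls), 5)
})

test_that("stochastic generators are bit-reproducible given a seed", {
  map <- makeGeneticMap(2, 10, 80)
  expect_identical(genoCodes(simulateRILPopulation(map, 20, seed = 99)),
                   genoCodes(simulateRILPopulation(map, 20, seed = 99)))
  hd <- setNames(rnorm(10) + 125, paste0("L", 1:10))
  expect_identical(simulateTrial(hd, seed = 7), simulateTrial(hd, seed = 7))
  tr <- simulateTrial(hd, seed = 7)
  expect_identical(sampleVisualScores(tr, 120:130, seed = 3),
                   sampleVisualScores(tr, 120:130, seed = 3))
  expect_false(identical(genoCodes(simulateRILPopulation(map, 20,
                                                         seed = 1)),
                         genoCodes(simulateRILPopulation(map, 20,
                                                         seed = 2))))
})
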