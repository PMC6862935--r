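# phenoQTL

Time-series phenology extraction, heritability estimation and QTL mapping
for biparental wheat field trials.

## The problem

High-throughput field phenotyping produces *time series* of per-plot
percent-heading scores — from breeder walk-throughs (scored in 10%
increments every 2–4 days) or from image classifiers scoring the same
plots. Turning those series into genetics-ready traits takes a chain of
steps that are usually scattered across ad-hoc scripts:

1. **Phenology extraction.** Each plot's progression is modelled with a
   logistic growth curve

   y_i = phi1 / (1 + exp(−(phi2 + phi3 · day))),

   with the asymptote fixed at phi1 = 100 (percent). The **heading date**
   is the day whose predicted value is closest to 50% (evaluated on a
   0.1-day grid over the full day range), matching the classical
   definition of heading as 50% of spikes emerged; the **rate of heading**
   is the slope phi3. Robustness anchors (0% at 10/20/30 days before the
   first score, 100% at 10/20/30 days after the last) pin the asymptotes.

2. **Quantitative genetics.** Plot values feed the mixed model
   y_ijk = g_i + y_j + r_k(j) + e, with entry, year and rep-within-year
   random and the residual either iid or carrying a separable AR1 ⊗ AR1
   correlation over field rows and columns. REML variance components give
   broad-sense heritability on a line-mean basis,
   H² = σ²G / (σ²G + σ²e/r) for one year, and
   H² = σ²G / (σ²G + σ²GY/y + σ²e/(yr)) across years, plus entry
   BLUPs/BLUEs.

3. **Genetic architecture.** In a biparental RIL population (no structure,
   no kinship) association reduces to single-marker regression
   y_i = β_{i,k} + e with Bonferroni control, followed by a two-way
   epistasis scan y_i = α_{i,j} + β_{i,k} + ε_{i,j·k} + e over the
   significant markers (F-test, with LOD = (n/2)·log10(RSS_add/RSS_full)),
   a 3:1 segregation χ² test for two-gene dominant epistasis, and G-BLUP
   cross-validation for polygenic traits such as the heading rate.

The package also ships the **label machinery** used around plot-image
classifiers — linear imputation of labels between scoring dates, 3×3
patch-grid geometry for 224 px patches in 672 px images, soft-label
targets (0.7 / 0.1 / 0.05 partial-credit mass), the mean-absolute-difference
error, and patch→image→plot consensus voting — and a **synthetic-data
generator** (F5 RIL genotypes under Haldane recombination, epistatic trait
architectures, spatially correlated trials, discretized scores with a
calibrated mislabel model of 10% one-class and 5% two-class errors) so the
entire pipeline is testable end to end without field data.

## Worked example

```r
library(phenoQTL)

map   <- makeGeneticMap(nChrom = 5, markersPerChrom = 20, chromLengthcM = 150)
G     <- simulateRILPopulation(map, nLines = 200, nSelfingGenerations = 5,
                               seed = 2024)
arch  <- traitArchitecture(
  qtl          = data.frame(marker = c(10, 30, 50), effect = c(2, 1.5, 1.5)),
  interactions = data.frame(marker1 = 10, marker2 = 50, effect = -1.5),
  polygenicVar = 0.25, intercept = 125)
hd    <- geneticValues(G, arch, seed = 2024)
trial <- simulateTrial(hd, rate = 0.3, nReps = 2, sigma2E = 0.25,
                       rhoRow = 0.3, rhoCol = 0.3, seed = 2024)
scores <- sampleVisualScores(trial, days = seq(112, 140, by = 3), seed = 2024)

phen <- fitPhenology(scores)
head(phen[, c("plot", "phi2", "phi3", "heading_date", "rate")], 3)
#>       plot      phi2      phi3 heading_date      rate
#> 1 Y1_P0001 -29.62056 0.2369171        125.0 0.2369171
#> 2 Y1_P0002 -41.80490 0.3319847        125.9 0.3319847
#> 3 Y1_P0003 -34.25212 0.2678850        127.9 0.2678850
```

The extracted dates track the simulated truth through the 10%-increment
discretization and mislabel noise (`seriesAgreement` prints
`MAE 0.38 d, RMSE 0.47 d, within 1 d 96%, slope 1.001` here): heading date
is recoverable to well under a day from 3-day scoring.

```r
tab <- merge(trial[, c("plot", "entry", "year", "rep", "row", "col")],
             phen[, c("plot", "heading_date", "rate")], by = "plot")
vc  <- fitVarianceComponents(tab, response = "heading_date", spatial = "ar1")
vc
#> VarianceComponents (ar1 residual, single year)
#>   sigma2G = 10.82  sigma2E = 0.4122
#>   rhoRow = 0.156  rhoCol = 0.245
#>   r = 2 rep(s), y = 1 year(s); REML logLik -780.141
heritability(vc, "single_year")
#> [1] 0.981
```

Heading date is highly heritable (H² ≈ 0.98 under these noise settings),
so entry BLUPs are nearly noise-free inputs for mapping:

```r
blup <- entryValues(tab, vc, response = "heading_date", mode = "BLUP")
Gf   <- filterMarkers(G)              # MAF >= 0.1, missing <= 30%, het <= 6%
scan <- markerScan(blup, Gf)          # Bonferroni at 0.05 / m
head(scan[order(scan$p), c("marker", "effect", "p", "significant")], 3)
#>      marker   effect            p significant
#> 10 chr1_m10 2.079879 2.008397e-22        TRUE
#> 9   chr1_m9 1.722487 4.056625e-15        TRUE
#> 29 chr2_m10 1.650178 1.733158e-14        TRUE

epi <- epistasisScan(blup, Gf, scan$marker[scan$significant])
head(epi[order(epi$pInteraction),
         c("marker1", "marker2", "interaction", "lod", "significant")], 1)
#>     marker1  marker2 interaction      lod significant
#> 78 chr1_m10 chr3_m10   -1.152071 14.72046        TRUE
```

The scan recovers the three simulated main-effect loci (the top markers sit
at or beside them), and the epistasis scan recovers the simulated
chr1 × chr3 interaction — the sign-reversing architecture in which the
distal locus acts oppositely depending on the photoperiod-analogue
background.

A one-call version of this whole flow, with CSV outputs and a manifest, is
`runPipeline(pipelineConfig(...), outDir)`.

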