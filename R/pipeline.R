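#' Pipeline configuration with field-trial defaults
#'
#' Assembles (and validates) the parameter set driving [runPipeline()].
#' Defaults follow the field protocol the package models: asymptote fixed
#' at 100%, 0.1-day grid for the 50% intersect, asymptote anchors at 10,
#' 20 and 30 days, soft-label masses 0.7/0.1/0.05, experiment-wise alpha
#' 0.05, marker filters MAF 0.1 / missing 0.30 / het 0.06, 10% masking
#' with 100 cross-validation replications.
#'
#' @param ... overrides of any default (unknown names are an error).
#' @return validated named list of parameters.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # synthetic population
    nChrom = 21, markersPerChrom = 20, chromLengthcM = 150,
    nLines = 300, nSelfingGenerations = 5,
    qtlEffects = c(2.0, 1.5), interactionEffect = 1.5,
    polygenicVarHD = 0.25, interceptHD = 125,
    rateMean = 0.3, polygenicVarRate = 0.002,
    # trial
    nReps = 2, nYears = 1, sigma2Y = 0, sigma2R = 0.05, sigma2E = 0.25,
    rhoRow = 0.3, rhoCol = 0.3,
    # scoring
    scoreInterval = 3, p10 = 0.10, p20 = 0.05,
    # phenology
    gridStep = 0.1, anchorOffsets = c(10, 20, 30),
    # genetics
    alpha = 0.05, mafMin = 0.1, missMax = 0.30, hetMax = 0.06,
    maskFraction = 0.10, cvReps = 100,
    # control
    stages = c("simulate", "phenology", "heritability", "scan",
               "epistasis", "predict"),
    spatial = "iid",
    seed = 1,
    scoresFile = NULL, genotypesFile = NULL, mapFile = NULL,
    layoutFile = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  inUnit <- function(x) is.numeric(x) && x >= 0 && x <= 1
  if (!inUnit(cfg$mafMin) || cfg$mafMin > 0.5)
    stop("mafMin must lie in [0, 0.5]")
  for (nm in c("missMax", "hetMax", "alpha", "maskFraction", "p10", "p20"))
    if (!inUnit(cfg[[nm]])) stop(nm, " must lie in [0, 1]")
  if (cfg$p10 + cfg$p20 > 1) stop("p10 + p20 must be <= 1")
  if (abs(cfg$rhoRow) >= 1 || abs(cfg$rhoCol) >= 1)
    stop("AR1 correlations must lie in (-1, 1)")
  if (cfg$gridStep <= 0) stop("gridStep must be positive")
  unknown <- setdiff(cfg$stages, c("simulate", "phenology", "heritability",
                                   "scan", "epistasis", "predict"))
  if (length(unknown)) stop("unknown stages: ",
                            paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of overrides (keys as in [pipelineConfig()]).
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full synthetic-to-genetics pipeline
#'
#' Executes the enabled stages in order: `simulate` (RIL genotypes, trait
#' architecture, field trial, visual scores), `phenology` (per-plot
#' logistic fits, heading date and rate), `heritability` (variance
#' components and H2 for both traits), `scan` (single-marker association),
#' `epistasis` (pairwise scan over significant markers) and `predict`
#' (G-BLUP cross-validation of the rate trait). Result tables are written
#' as CSV under `outDir` together with `manifest.json` (package version,
#' seed, parameter hash, record counts); a rerun with the same
#' configuration reproduces the outputs byte for byte. When `simulate` is
#' disabled, score/genotype/layout tables are read from the configured
#' file paths; a stage whose input is missing raises an error naming it.
#'
#' @param config list from [pipelineConfig()] (or a YAML path).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results per stage.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempdir()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list(config = config)
  counts <- list()
  stages <- config$stages

  if ("simulate" %in% stages) {
    map <- makeGeneticMap(config$nChrom, config$markersPerChrom,
                          config$chromLengthcM)
    G <- simulateRILPopulation(map, config$nLines,
                               config$nSelfingGenerations, seed = seed)
    m <- nMarkers(map)
    mpc <- config$markersPerChrom
    # three-locus heading-date architecture on separate chromosomes:
    # two photoperiod-like main-effect loci plus an interacting distal locus
    qtlIdx <- c(round(mpc / 2), mpc + round(mpc / 2), 3 * mpc)
    qtlIdx <- pmin(qtlIdx, m)
    arch <- traitArchitecture(
      qtl = data.frame(marker = qtlIdx,
                       effect = c(config$qtlEffects,
                                  config$interactionEffect)[1:3]),
      interactions = data.frame(marker1 = qtlIdx[1], marker2 = qtlIdx[3],
                                effect = -config$interactionEffect),
      polygenicVar = config$polygenicVarHD,
      intercept = config$interceptHD, trait = "heading_date")
    archRate <- traitArchitecture(
      polygenicVar = config$polygenicVarRate, intercept = config$rateMean,
      trait = "rate")
    hd <- geneticValues(G, arch, seed = seed)
    rate <- geneticValues(G, archRate, seed = seed + 1)
    rate <- pmax(rate, 0.05)
    truth <- simulateTrial(hd, rate, nReps = config$nReps,
                           nYears = config$nYears,
                           sigma2Y = config$sigma2Y,
                           sigma2R = config$sigma2R,
                           sigma2E = config$sigma2E,
                           rhoRow = config$rhoRow, rhoCol = config$rhoCol,
                           seed = seed)
    days <- seq(floor(min(truth$heading_date)) - 9,
                ceiling(max(truth$heading_date)) + 9,
                by = config$scoreInterval)
    scores <- sampleVisualScores(truth, days, p10 = config$p10,
                                 p20 = config$p20, seed = seed)
    writeGenotypesCSV(G, file.path(outDir, "genotypes.csv"),
                      file.path(outDir, "map.csv"))
    writeTable(truth[, c("plot", "entry", "year", "rep", "row", "col")],
               file.path(outDir, "layout.csv"))
    writeTable(scores, file.path(outDir, "scores.csv"))
    res$G <- G
    res$truth <- truth
    res$scores <- scores
    res$architecture <- arch
    counts$markers <- m
    counts$lines <- config$nLines
    counts$plots <- nrow(truth)
    counts$scores <- nrow(scores)
  } else {
    if (!is.null(config$scoresFile)) res$scores <-
      readScores(config$scoresFile)
    if (!is.null(config$genotypesFile)) res$G <-
      readGenotypes(config$genotypesFile, mapFile = config$mapFile)
    if (!is.null(config$layoutFile)) res$truth <-
      utils::read.csv(config$layoutFile)
  }

  if ("phenology" %in% stages) {
    if (is.null(res$scores))
      stop("phenology stage needs a score table (simulate stage or ",
           "scoresFile)")
    phen <- fitPhenology(res$scores, step = config$gridStep)
    writeTable(phen, file.path(outDir, "phenology.csv"))
    res$phenology <- phen
    counts$plotsFit <- sum(phen$converged)
  }

  if ("heritability" %in% stages) {
    if (is.null(res$phenology) || is.null(res$truth))
      stop("heritability stage needs phenology output and a layout table")
    tab <- merge(res$truth[, c("plot", "entry", "year", "rep", "row",
                               "col")],
                 res$phenology[, c("plot", "heading_date", "rate")],
                 by = "plot")
    mode <- if (length(unique(tab$year)) > 1) "multi_year" else
      "single_year"
    vcHD <- fitVarianceComponents(tab, response = "heading_date",
                                  spatial = config$spatial)
    vcRate <- fitVarianceComponents(tab, response = "rate",
                                    spatial = config$spatial)
    h2 <- data.frame(
      trait = c("heading_date", "rate"),
      H2 = c(heritability(vcHD, mode), heritability(vcRate, mode)),
      sigma2G = c(vcHD@sigma2G, vcRate@sigma2G),
      sigma2E = c(vcHD@sigma2E, vcRate@sigma2E))
    writeTable(h2, file.path(outDir, "heritability.csv"))
    res$varianceComponents <- list(heading_date = vcHD, rate = vcRate)
    res$heritability <- h2
    res$entryBLUP <- list(
      heading_date = entryValues(tab, vcHD, "heading_date", "BLUP"),
      rate = entryValues(tab, vcRate, "rate", "BLUP"))
  }

  if (any(c("scan", "epistasis", "predict") %in% stages) &&
      is.null(res$G))
    stop("genetic stages need genotypes (simulate stage or genotypesFile)")

  if ("scan" %in% stages) {
    yv <- res$entryBLUP$heading_date
    if (is.null(yv)) stop("scan stage needs heritability stage BLUPs")
    Gf <- filterMarkers(res$G, config$mafMin, config$missMax,
                        config$hetMax)
    counts$markersFiltered <- nrow(Gf)
    scan <- markerScan(yv, Gf, alpha = config$alpha)
    writeTable(scan, file.path(outDir, "scan.csv"))
    res$Gfiltered <- Gf
    res$scan <- scan
    counts$significantMarkers <- sum(scan$significant)
  }

  if ("epistasis" %in% stages) {
    if (is.null(res$scan)) stop("epistasis stage needs scan output")
    sig <- res$scan$marker[res$scan$significant]
    if (length(sig) >= 2) {
      epi <- epistasisScan(res$entryBLUP$heading_date, res$Gfiltered,
                           sig, alpha = config$alpha)
      writeTable(epi, file.path(outDir, "epistasis.csv"))
      res$epistasis <- epi
      counts$significantPairs <- sum(epi$significant)
    } else {
      message("fewer than 2 significant markers: epistasis scan skipped")
    }
  }

  if ("predict" %in% stages) {
    yv <- res$entryBLUP$rate
    if (is.null(yv)) stop("predict stage needs heritability stage BLUPs")
    cv <- genomicPredictionCV(yv, res$G,
                              maskFraction = config$maskFraction,
                              reps = config$cvReps, seed = seed)
    writeTable(data.frame(rep = seq_along(cv$r), r = cv$r),
               file.path(outDir, "prediction_cv.csv"))
    res$prediction <- cv
  }

  manifest <- list(
    package = "phenoQTL",
    version = as.character(utils::packageVersion("phenoQTL")),
    seed = seed,
    parameterHash = configHash(config),
    stages = stages,
    counts = counts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Hash of a pipeline configuration
#'
#' md5 over the deparsed, name-sorted configuration; identical
#' configurations always hash identically.
#'
#' @param config configuration list.
#' @return character md5 hash.
#' @export
configHash <- function(config) {
  config <- config[order(names(config))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config, control = "all"), tf)
  unname(tools::md5sum(tf))
}
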