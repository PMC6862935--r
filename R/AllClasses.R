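#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GeneticMap: marker positions on a linkage map
#'
#' Holds an ordered set of markers with chromosome assignments and positions
#' in centimorgans. Positions must be strictly increasing within each
#' chromosome and chromosome lengths positive.
#'
#' @slot marker character vector of marker ids.
#' @slot chrom character vector, chromosome of each marker.
#' @slot pos numeric vector, map position of each marker in cM.
#' @slot chromLength named numeric vector of chromosome lengths in cM.
#'
#' @seealso [makeGeneticMap()]
#' @export
setClass("GeneticMap",
  representation(
    marker = "character",
    chrom = "character",
    pos = "numeric",
    chromLength = "numeric"
  )
)

setValidity("GeneticMap", function(object) {
  msgs <- character()
  n <- length(object@marker)
  if (length(object@chrom) != n || length(object@pos) != n)
    msgs <- c(msgs, "marker, chrom and pos must have equal length")
  if (any(object@chromLength < 0))
    msgs <- c(msgs, "chromosome lengths must be >= 0")
  if (is.null(names(object@chromLength)))
    msgs <- c(msgs, "chromLength must be named by chromosome")
  if (length(msgs) == 0L) {
    for (ch in unique(object@chrom)) {
      p <- object@pos[object@chrom == ch]
      strict <- !ch %in% names(object@chromLength) ||
        object@chromLength[[ch]] > 0
      if (length(p) > 1L && any(if (strict) diff(p) <= 0 else diff(p) < 0)) {
        msgs <- c(msgs, sprintf(
          "positions not strictly increasing on chromosome %s", ch))
      }
      if (!ch %in% names(object@chromLength))
        msgs <- c(msgs, sprintf("no length recorded for chromosome %s", ch))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TraitArchitecture: genetic architecture of a simulated trait
#'
#' Describes a trait as a small set of additive QTL, pairwise epistatic
#' interactions (product coding of the two loci), and a polygenic background
#' spread across all markers.
#'
#' @slot qtl data.frame with columns `marker` (index into the map) and
#'   `effect` (days per allele substitution between homozygote classes).
#' @slot interactions data.frame with columns `marker1`, `marker2`,
#'   `effect` (days, coefficient of the product of the two locus codes).
#' @slot polygenicVar non-negative scalar, variance (days^2) of the
#'   polygenic background across lines.
#' @slot intercept scalar, population mean on the trait scale.
#' @slot trait either "heading_date" or "rate".
#'
#' @seealso [traitArchitecture()], [geneticValues()]
#' @export
setClass("TraitArchitecture",
  representation(
    qtl = "data.frame",
    interactions = "data.frame",
    polygenicVar = "numeric",
    intercept = "numeric",
    trait = "character"
  )
)

setValidity("TraitArchitecture", function(object) {
  msgs <- character()
  if (!all(c("marker", "effect") %in% names(object@qtl)))
    msgs <- c(msgs, "qtl must have columns marker, effect")
  if (nrow(object@interactions) &&
      !all(c("marker1", "marker2", "effect") %in% names(object@interactions)))
    msgs <- c(msgs, "interactions must have columns marker1, marker2, effect")
  if (length(object@polygenicVar) != 1L || object@polygenicVar < 0)
    msgs <- c(msgs, "polygenicVar must be a single non-negative number")
  if (!object@trait %in% c("heading_date", "rate"))
    msgs <- c(msgs, "trait must be 'heading_date' or 'rate'")
  if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: coded genotypes for a mapping population
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"geno"`
#' holding genotype codes (markers in rows, lines in columns) and rowData
#' columns `chrom` and `pos` (cM or bp). Codes are 0 (parent-A homozygote),
#' 1 (heterozygote), 2 (parent-B homozygote) and `NA` (missing).
#'
#' @seealso [GenotypeMatrix()], [simulateRILPopulation()], [readGenotypes()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("must carry an assay named 'geno'")
  g <- SummarizedExperiment::assay(object, "geno")
  if (!all(g[!is.na(g)] %in% c(0, 1, 2)))
    msgs <- c(msgs, "genotype codes must be 0, 1, 2 or NA")
  rd <- rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd))) {
    msgs <- c(msgs, "rowData must have columns chrom, pos")
  } else {
    ch <- as.character(rd$chrom)
    ord <- order(match(ch, unique(ch)), rd$pos)
    if (!identical(ord, seq_len(nrow(rd))))
      msgs <- c(msgs, "markers must be ordered by (chrom, pos)")
  }
  if (length(msgs)) msgs else TRUE
})

#' LogisticFit: per-plot logistic growth-curve fit
#'
#' Result of fitting y = phi1 / (1 + exp(-(phi2 + phi3 * day))) with the
#' asymptote phi1 fixed at 100 (percent heading) to one plot's time series.
#'
#' @slot phi1 fixed asymptote, always 100.
#' @slot phi2 intercept on the logit scale (unitless).
#' @slot phi3 slope on the logit scale (per day); the rate of heading.
#' @slot sse residual sum of squares at the optimum.
#' @slot converged logical convergence flag.
#' @slot nObs number of (day, percent) observations used.
#' @slot dayRange range of the days used in fitting (after any anchoring).
#'
#' @seealso [fitLogistic()], [headingDate()], [headingRate()]
#' @export
setClass("LogisticFit",
  representation(
    phi1 = "numeric",
    phi2 = "numeric",
    phi3 = "numeric",
    sse = "numeric",
    converged = "logical",
    nObs = "integer",
    dayRange = "numeric"
  )
)

setValidity("LogisticFit", function(object) {
  msgs <- character()
  if (!isTRUE(all.equal(object@phi1, 100)))
    msgs <- c(msgs, "phi1 is fixed at 100")
  if (object@converged && (!is.finite(object@phi2) || !is.finite(object@phi3)))
    msgs <- c(msgs, "converged fits must have finite phi2 and phi3")
  if (length(msgs)) msgs else TRUE
})

#' VarianceComponents: REML estimates for the plot-level mixed model
#'
#' Variance-component estimates for the model
#' y_ijk = g_i + y_j + r_k(j) + e, with the residual either iid or
#' carrying a separable AR1 x AR1 correlation over field rows and columns.
#'
#' @slot sigma2G total genetic (entry) variance.
#' @slot sigma2GY genotype-by-year variance (`NA` for single-year fits;
#'   estimated as the year-specific entry deviation variance).
#' @slot sigma2Y year variance (`NA` for single-year fits).
#' @slot sigma2R replication-within-year variance (`NA` for single-year fits).
#' @slot sigma2E residual variance.
#' @slot rhoRow,rhoCol AR1 correlations over rows/columns (0 for iid fits).
#' @slot nReps replications per year, `r` in the heritability formulas.
#' @slot nYears number of years, `y`.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged logical flag from the optimizer.
#' @slot spatial "iid" or "ar1".
#'
#' @seealso [fitVarianceComponents()], [heritability()]
#' @export
setClass("VarianceComponents",
  representation(
    sigma2G = "numeric",
    sigma2GY = "numeric",
    sigma2Y = "numeric",
    sigma2R = "numeric",
    sigma2E = "numeric",
    rhoRow = "numeric",
    rhoCol = "numeric",
    nReps = "numeric",
    nYears = "numeric",
    logLik = "numeric",
    converged = "logical",
    spatial = "character"
  )
)

setValidity("VarianceComponents", function(object) {
  msgs <- character()
  vars <- c(object@sigma2G, object@sigma2E)
  if (any(vars < 0, na.rm = TRUE))
    msgs <- c(msgs, "variances must be non-negative")
  if (abs(object@rhoRow) >= 1 || abs(object@rhoCol) >= 1)
    msgs <- c(msgs, "AR1 correlations must lie in (-1, 1)")
  if (!object@spatial %in% c("iid", "ar1"))
    msgs <- c(msgs, "spatial must be 'iid' or 'ar1'")
  if (length(msgs)) msgs else TRUE
})
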