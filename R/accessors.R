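#' @rdname GeneticMap-class
#' @param nChrom number of chromosomes.
#' @param markersPerChrom markers per chromosome.
#' @param chromLengthcM chromosome length in cM (recycled across chromosomes).
#' @details `makeGeneticMap()` builds an evenly spaced map: on each
#'   chromosome, `markersPerChrom` markers at positions
#'   `seq(0, chromLengthcM, length.out = markersPerChrom)` (a single marker
#'   sits at 0 cM). Chromosomes are named `"chr1" ... "chrN"`, markers
#'   `"chr<i>_m<j>"`.
#' @return a [GeneticMap-class] object with
#'   `nChrom * markersPerChrom` markers.
#' @examples
#' map <- makeGeneticMap(nChrom = 2, markersPerChrom = 3, chromLengthcM = 50)
#' positions(map)
#' @export
makeGeneticMap <- function(nChrom, markersPerChrom, chromLengthcM) {
  if (nChrom < 1 || markersPerChrom < 1 || any(chromLengthcM < 0))
    stop("nChrom, markersPerChrom must be >= 1 and chromLengthcM >= 0")
  nChrom <- as.integer(nChrom)
  markersPerChrom <- as.integer(markersPerChrom)
  lens <- rep_len(as.numeric(chromLengthcM), nChrom)
  chromNames <- paste0("chr", seq_len(nChrom))
  names(lens) <- chromNames
  chrom <- rep(chromNames, each = markersPerChrom)
  pos <- unlist(lapply(lens, function(L) {
    if (markersPerChrom == 1L) 0 else seq(0, L, length.out = markersPerChrom)
  }), use.names = FALSE)
  marker <- paste0(chrom, "_m", rep(seq_len(markersPerChrom), nChrom))
  new("GeneticMap", marker = marker, chrom = chrom, pos = pos,
      chromLength = lens)
}

#' @describeIn GeneticMap-class marker positions in cM (named by marker).
#' @param map,object a `GeneticMap`.
#' @export
positions <- function(map) stats::setNames(map@pos, map@marker)

#' @describeIn GeneticMap-class chromosome of each marker.
#' @export
chromosomes <- function(map) stats::setNames(map@chrom, map@marker)

#' @describeIn GeneticMap-class number of markers on the map.
#' @export
nMarkers <- function(map) {
  if (is(map, "GeneticMap")) length(map@marker) else nrow(map)
}

#' @describeIn GeneticMap-class marker ids.
#' @export
markerIds <- function(map) {
  if (is(map, "GeneticMap")) map@marker else rownames(map)
}

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s)\n",
              length(object@marker), length(object@chromLength)))
  cat(sprintf("  lengths (cM): %s\n",
              paste(sprintf("%s=%g", names(object@chromLength),
                            object@chromLength), collapse = ", ")))
})

#' Construct a GenotypeMatrix
#'
#' @param geno numeric matrix of genotype codes, markers in rows and lines
#'   in columns (codes 0/1/2/NA; 0 and 2 are the two parental homozygotes).
#'   Rows must be named by marker, columns by line.
#' @param chrom,pos per-marker chromosome and position; taken from `map`
#'   when one is supplied.
#' @param map optional [GeneticMap-class] matching the rows of `geno`.
#'
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(geno, chrom = NULL, pos = NULL, map = NULL) {
  geno <- as.matrix(geno)
  if (!is.null(map)) {
    chrom <- map@chrom
    pos <- map@pos
    if (is.null(rownames(geno))) rownames(geno) <- map@marker
  }
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("m", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("line", seq_len(ncol(geno)))
  rd <- DataFrame(chrom = as.character(chrom), pos = as.numeric(pos),
                  row.names = rownames(geno))
  # sort by (chrom, pos), keeping chromosomes in order of first appearance
  # so chr10 does not sort before chr2
  ord <- order(match(rd$chrom, unique(rd$chrom)), rd$pos)
  se <- SummarizedExperiment(assays = list(geno = geno[ord, , drop = FALSE]),
                             rowData = rd[ord, , drop = FALSE])
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix genotype codes as a markers x lines matrix.
#' @param x a `GenotypeMatrix`.
#' @export
genoCodes <- function(x) SummarizedExperiment::assay(x, "geno")

#' @describeIn GenotypeMatrix marker map as a data.frame
#'   (marker, chrom, pos).
#' @export
markerMap <- function(x) {
  rd <- rowData(x)
  data.frame(marker = rownames(x), chrom = as.character(rd$chrom),
             pos = rd$pos, row.names = NULL)
}

#' @describeIn GenotypeMatrix per-marker frequency of the parent-B allele
#'   (code 2 counts twice, het once), ignoring missing calls.
#' @export
alleleFreqB <- function(x) {
  g <- genoCodes(x)
  rowMeans(g, na.rm = TRUE) / 2
}

#' @describeIn GenotypeMatrix per-marker heterozygote fraction among
#'   non-missing calls.
#' @export
hetRate <- function(x) {
  g <- genoCodes(x)
  rowMeans(g == 1, na.rm = TRUE)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d markers x %d lines\n",
              nrow(object), ncol(object)))
  g <- genoCodes(object)
  cat(sprintf("  missing: %.2f%%  het: %.2f%%\n",
              100 * mean(is.na(g)), 100 * mean(g == 1, na.rm = TRUE)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(as.character(rowData(object)$chrom))[1:min(5,
                length(unique(rowData(object)$chrom)))], collapse = ", ")))
})

#' Construct a TraitArchitecture
#'
#' @param qtl data.frame (marker, effect) of additive QTL; marker is an
#'   index into the map/genotype rows, effect in trait units per allele
#'   substitution between homozygote classes.
#' @param interactions data.frame (marker1, marker2, effect) of pairwise
#'   epistatic terms on the product of the two locus codes.
#' @param polygenicVar variance of the polygenic background (trait units^2).
#' @param intercept population mean.
#' @param trait "heading_date" or "rate".
#' @return a [TraitArchitecture-class].
#' @export
traitArchitecture <- function(qtl = data.frame(marker = integer(),
                                               effect = numeric()),
                              interactions = data.frame(marker1 = integer(),
                                                        marker2 = integer(),
                                                        effect = numeric()),
                              polygenicVar = 0, intercept = 0,
                              trait = c("heading_date", "rate")) {
  trait <- match.arg(trait)
  new("TraitArchitecture", qtl = qtl, interactions = interactions,
      polygenicVar = as.numeric(polygenicVar),
      intercept = as.numeric(intercept), trait = trait)
}

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf(
    "TraitArchitecture (%s): %d QTL, %d interaction(s), polygenic var %g\n",
    object@trait, nrow(object@qtl), nrow(object@interactions),
    object@polygenicVar))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf(
    "LogisticFit: phi1 = 100 (fixed), phi2 = %.4f, phi3 = %.4f\n",
    object@phi2, object@phi3))
  cat(sprintf("  SSE %.4g over %d obs; converged: %s\n",
              object@sse, object@nObs, object@converged))
  if (object@phi3 > 0)
    cat(sprintf("  50%% intersect (closed form): %.1f\n",
                -object@phi2 / object@phi3))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents (%s residual, %s)\n", object@spatial,
              if (object@nYears > 1) sprintf("%g years", object@nYears)
              else "single year"))
  cat(sprintf("  sigma2G = %.4g  sigma2E = %.4g", object@sigma2G,
              object@sigma2E))
  if (!is.na(object@sigma2GY)) cat(sprintf("  sigma2GY = %.4g",
                                           object@sigma2GY))
  cat("\n")
  if (object@spatial == "ar1")
    cat(sprintf("  rhoRow = %.3f  rhoCol = %.3f\n", object@rhoRow,
                object@rhoCol))
  cat(sprintf("  r = %g rep(s), y = %g year(s); REML logLik %.3f\n",
              object@nReps, object@nYears, object@logLik))
})
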