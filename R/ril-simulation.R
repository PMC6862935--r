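#' Simulate a biparental RIL population by single-seed descent
#'
#' Starting from an F1 that is heterozygous at every marker, each line is
#' selfed for `nSelfingGenerations` generations of single-seed descent.
#' Gametes are produced with crossovers placed under the Haldane model (no
#' interference): the crossover count per chromosome is Poisson with mean
#' `length_cM / 100` and crossover positions are uniform along the
#' chromosome. Expected residual heterozygosity per locus after g selfing
#' generations is 0.5^g (about 3.1% for g = 5).
#'
#' Segregation distortion is modelled as gametic viability selection at one
#' marker: each meiosis, a gamete carrying the disfavoured (parent-A) allele
#' at that marker survives with probability `1 / ratio`, pushing the
#' parent-B allele frequency above 0.5.
#'
#' @param map a [GeneticMap-class].
#' @param nLines number of RILs to simulate (>= 2).
#' @param nSelfingGenerations selfing generations from the F1 (>= 1).
#' @param distortion `NULL`, or `list(marker = <index or id>, ratio = k)`
#'   giving a k:1 survival advantage to gametes carrying the parent-B allele
#'   at that marker.
#' @param seed integer seed; the population is bit-reproducible given the
#'   seed.
#' @return a [GenotypeMatrix-class] with codes 0/1/2 and no missing data.
#' @examples
#' map <- makeGeneticMap(3, 20, 120)
#' G <- simulateRILPopulation(map, nLines = 50, seed = 1)
#' mean(hetRate(G))  # close to 0.5^5
#' @export
simulateRILPopulation <- function(map, nLines, nSelfingGenerations = 5,
                                  distortion = NULL, seed = 1) {
  stopifnot(is(map, "GeneticMap"))
  if (nLines < 2) stop("nLines must be >= 2")
  if (nSelfingGenerations < 1) stop("nSelfingGenerations must be >= 1")
  m <- length(map@marker)
  distIdx <- NA_integer_
  distRatio <- 1
  if (!is.null(distortion)) {
    distIdx <- if (is.character(distortion$marker)) {
      match(distortion$marker, map@marker)
    } else as.integer(distortion$marker)
    if (is.na(distIdx) || distIdx < 1L || distIdx > m)
      stop("distortion marker outside map")
    distRatio <- distortion$ratio
    if (distRatio <= 0) stop("distortion ratio must be positive")
  }
  chromNames <- names(map@chromLength)
  chromIdx <- lapply(chromNames, function(ch) which(map@chrom == ch))
  chromPos <- lapply(chromIdx, function(i) map@pos[i])
  chromLen <- unname(map@chromLength)

  .withStream(seed, "ril", {
    geno <- matrix(0L, nrow = m, ncol = nLines)
    for (ln in seq_len(nLines)) {
      h1 <- rep(0L, m)   # haplotypes: allele 0 = parent A, 1 = parent B
      h2 <- rep(1L, m)
      for (g in seq_len(nSelfingGenerations)) {
        g1 <- .meiosis(h1, h2, chromIdx, chromPos, chromLen,
                       distIdx, distRatio)
        g2 <- .meiosis(h1, h2, chromIdx, chromPos, chromLen,
                       distIdx, distRatio)
        h1 <- g1
        h2 <- g2
      }
      geno[, ln] <- h1 + h2
    }
    rownames(geno) <- map@marker
    colnames(geno) <- sprintf("RIL%03d", seq_len(nLines))
    GenotypeMatrix(geno, map = map)
  })
}

# One meiosis: recombine the two haplotypes chromosome by chromosome under
# Haldane (Poisson crossovers, uniform positions). Gametic viability
# selection at distIdx: gametes carrying allele 0 there are rejected with
# probability 1 - 1/ratio and redrawn.
.meiosis <- function(h1, h2, chromIdx, chromPos, chromLen,
                     distIdx = NA_integer_, distRatio = 1) {
  repeat {
    gam <- integer(length(h1))
    for (c in seq_along(chromIdx)) {
      idx <- chromIdx[[c]]
      pos <- chromPos[[c]]
      L <- chromLen[c]
      nxo <- if (L > 0) stats::rpois(1L, L / 100) else 0L
      start <- sample.int(2L, 1L) - 1L
      if (nxo == 0L) {
        phase <- rep(start, length(idx))
      } else {
        xo <- sort(stats::runif(nxo, 0, L))
        phase <- (start + findInterval(pos, xo)) %% 2L
      }
      gam[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
    }
    if (is.na(distIdx) || distRatio == 1) return(gam)
    if (gam[distIdx] == 1L) return(gam)            # favoured allele survives
    if (stats::runif(1L) < 1 / distRatio) return(gam)
  }
}

#' Genetic values of lines under a trait architecture
#'
#' Each line's value is
#' `intercept + sum(additive) + sum(interaction) + polygenic`, where a QTL
#' with effect a contributes `a * x` under the symmetric dose coding
#' x in \{-1, 0, +1\} for genotype codes \{0, 1, 2\} (a heterozygote thus
#' takes the midpoint of the two homozygote effects), an interaction with
#' effect b contributes `b * x_j * x_k`, and the polygenic term is a sum of
#' small normal effects over all markers rescaled so its sample variance
#' across lines equals `polygenicVar` exactly.
#'
#' @param G a [GenotypeMatrix-class].
#' @param arch a [TraitArchitecture-class]; marker indices refer to rows
#'   of `G`.
#' @param seed integer seed for the polygenic draw.
#' @return named numeric vector of per-line trait values.
#' @export
geneticValues <- function(G, arch, seed = 1) {
  stopifnot(is(G, "GenotypeMatrix"), is(arch, "TraitArchitecture"))
  g <- genoCodes(G)
  m <- nrow(g)
  idx <- c(arch@qtl$marker, arch@interactions$marker1,
           arch@interactions$marker2)
  if (length(idx) && (any(idx < 1) || any(idx > m)))
    stop("architecture marker index outside the genotype matrix")
  x <- g - 1           # dose coding -1/0/+1; NA propagates
  val <- rep(arch@intercept, ncol(g))
  if (nrow(arch@qtl)) {
    for (i in seq_len(nrow(arch@qtl)))
      val <- val + arch@qtl$effect[i] * x[arch@qtl$marker[i], ]
  }
  if (nrow(arch@interactions)) {
    for (i in seq_len(nrow(arch@interactions))) {
      val <- val + arch@interactions$effect[i] *
        x[arch@interactions$marker1[i], ] * x[arch@interactions$marker2[i], ]
    }
  }
  if (arch@polygenicVar > 0) {
    poly <- .withStream(seed, "values", {
      u <- stats::rnorm(m)
      z <- drop(crossprod(x, u))   # lines-length vector
      s <- stats::sd(z)
      if (s == 0) stats::rnorm(ncol(g), 0, sqrt(arch@polygenicVar))
      else (z - mean(z)) / s * sqrt(arch@polygenicVar)
    })
    val <- val + poly
  }
  stats::setNames(as.numeric(val), colnames(g))
}
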