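#' Filter markers on MAF, missingness and heterozygosity
#'
#' Retains markers with minor allele frequency >= `mafMin`, missing-call
#' rate <= `missMax` and heterozygote rate <= `hetMax` — the standard
#' post-imputation cleanup for GBS markers in an inbred mapping population.
#' The removal counts per rule are attached as attribute `"removed"`
#' (a marker failing several rules is counted under each).
#'
#' @param G a [GenotypeMatrix-class].
#' @param mafMin minimum minor allele frequency (default 0.1).
#' @param missMax maximum missing fraction (default 0.30).
#' @param hetMax maximum heterozygosity (default 0.06).
#' @return the filtered [GenotypeMatrix-class] (possibly with zero
#'   markers, with a warning).
#' @export
filterMarkers <- function(G, mafMin = 0.1, missMax = 0.30, hetMax = 0.06) {
  g <- genoCodes(G)
  freqB <- rowMeans(g, na.rm = TRUE) / 2
  maf <- pmin(freqB, 1 - freqB)
  miss <- rowMeans(is.na(g))
  het <- rowMeans(g == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  maf[is.nan(maf)] <- 0
  failMaf <- maf < mafMin
  failMiss <- miss > missMax
  failHet <- het > hetMax
  keep <- !(failMaf | failMiss | failHet)
  if (!any(keep)) warning("no markers pass the filters")
  out <- G[keep, ]
  attr(out, "removed") <- c(maf = sum(failMaf), missing = sum(failMiss),
                            het = sum(failHet), total = sum(!keep))
  out
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha experiment-wise type-I error rate (default 0.05).
#' @param m number of tests (markers or marker pairs).
#' @return per-test p-value threshold `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 8237)  # 6.07e-6
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (any(m < 1)) stop("m must be >= 1")
  alpha / m
}

#' Single-marker association scan
#'
#' Regresses the per-line trait on the genotype code at each marker
#' (`y_i = mu + beta_k * g_ik + e`) and reports the allele-substitution
#' effect, its standard error, the two-sided t-test p-value and -log10 p.
#' In a biparental RIL population there is no population structure or
#' kinship to correct for, so simple regression is the exact model.
#' Heterozygotes are set missing by default (the effect is a substitution
#' between homozygote classes); set `het = "midpoint"` to keep them as
#' dose 1. Significance is flagged at the Bonferroni threshold
#' `alpha / m` over the scanned markers.
#'
#' @param y named per-line trait values.
#' @param G a [GenotypeMatrix-class]; columns matched to `names(y)` when
#'   both are named.
#' @param alpha experiment-wise alpha for the Bonferroni flag.
#' @param het "missing" (default) or "midpoint".
#' @param minN minimum non-missing lines per marker (markers below are
#'   reported with `p = NA`).
#' @return data.frame (marker, chrom, pos, n, effect, se, p, neglog10p,
#'   significant) with the threshold in attribute `"threshold"`.
#'   Monomorphic markers get `p = 1` and an `NA` effect.
#' @export
markerScan <- function(y, G, alpha = 0.05, het = c("missing", "midpoint"),
                       minN = 10) {
  het <- match.arg(het)
  g <- genoCodes(G)
  if (!is.null(names(y)) && !is.null(colnames(g))) {
    common <- intersect(colnames(g), names(y))
    if (!length(common)) stop("no lines shared between y and G")
    g <- g[, common, drop = FALSE]
    y <- y[common]
  }
  if (ncol(g) != length(y)) stop("y length does not match lines in G")
  if (het == "missing") g[g == 1] <- NA

  m <- nrow(g)
  yMat <- matrix(rep(y, each = m), nrow = m)
  ok <- !is.na(g) & !is.na(yMat)
  g0 <- ifelse(ok, g, 0)
  y0 <- ifelse(ok, yMat, 0)
  n <- rowSums(ok)
  sx <- rowSums(g0)
  sy <- rowSums(y0)
  sxx <- rowSums(g0^2)
  sxy <- rowSums(g0 * y0)
  syy <- rowSums(y0^2)
  ssx <- sxx - sx^2 / n
  ssy <- syy - sy^2 / n
  ssxy <- sxy - sx * sy / n

  beta <- ssxy / ssx
  rss <- pmax(ssy - beta * ssxy, 0)
  df <- n - 2
  se <- sqrt(rss / df / ssx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  mono <- ssx <= 0
  beta[mono] <- NA
  se[mono] <- NA
  p[mono] <- 1
  lowN <- n < minN
  p[lowN & !mono] <- NA

  thr <- bonferroniThreshold(alpha, m)
  mm <- markerMap(G)
  out <- data.frame(marker = mm$marker, chrom = mm$chrom, pos = mm$pos,
                    n = n, effect = beta, se = se, p = p,
                    neglog10p = -log10(p),
                    significant = !is.na(p) & p < thr,
                    row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

#' Two-way epistasis scan over significant markers
#'
#' For each unordered pair (j, k) of the supplied markers, compares the full
#' model `y = mu + a*g_j + b*g_k + c*(g_j*g_k) + e` against the additive
#' model without the product term. The interaction is tested by the extra
#' sum-of-squares F-test, and evidence is also reported as
#' `LOD = (n/2) * log10(RSS_additive / RSS_full)`. Pairs are flagged
#' significant at the Bonferroni threshold over the number of tested pairs.
#' Perfectly collinear pairs are skipped with `NA` and a flag.
#'
#' @param y named per-line trait values.
#' @param G a [GenotypeMatrix-class].
#' @param markers character vector of marker ids (>= 2), typically the
#'   significant markers of [markerScan()].
#' @param alpha experiment-wise alpha over pairs.
#' @param het heterozygote handling as in [markerScan()].
#' @return data.frame (marker1, marker2, alphaEffect, betaEffect,
#'   interaction, pInteraction, lod, significant, collinear).
#' @export
epistasisScan <- function(y, G, markers, alpha = 0.05,
                          het = c("missing", "midpoint")) {
  het <- match.arg(het)
  if (length(markers) < 2) stop("need >= 2 markers to scan pairs")
  g <- genoCodes(G)
  if (!is.null(names(y))) {
    common <- intersect(colnames(g), names(y))
    g <- g[, common, drop = FALSE]
    y <- y[common]
  }
  if (het == "missing") g[g == 1] <- NA
  idx <- match(markers, rownames(g))
  if (anyNA(idx)) stop("markers not found in G: ",
                       paste(markers[is.na(idx)], collapse = ", "))
  pairs <- utils::combn(seq_along(markers), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- idx[pairs[1, k]]
    j <- idx[pairs[2, k]]
    x1 <- g[i, ]
    x2 <- g[j, ]
    ok <- !is.na(x1) & !is.na(x2) & !is.na(y)
    x1 <- x1[ok]; x2 <- x2[ok]; yy <- y[ok]
    base <- data.frame(marker1 = markers[pairs[1, k]],
                       marker2 = markers[pairs[2, k]],
                       alphaEffect = NA_real_, betaEffect = NA_real_,
                       interaction = NA_real_, pInteraction = NA_real_,
                       lod = NA_real_, significant = FALSE,
                       collinear = FALSE)
    if (length(yy) < 5 || stats::var(x1) == 0 || stats::var(x2) == 0 ||
        abs(stats::cor(x1, x2)) > 1 - 1e-12) {
      base$collinear <- TRUE
      return(base)
    }
    full <- stats::lm(yy ~ x1 + x2 + I(x1 * x2))
    red <- stats::lm(yy ~ x1 + x2)
    if (anyNA(stats::coef(full))) {       # product collinear with mains
      base$collinear <- TRUE
      return(base)
    }
    cmp <- stats::anova(red, full)
    rssRed <- cmp$RSS[1]
    rssFull <- cmp$RSS[2]
    nUse <- length(yy)
    base$alphaEffect <- stats::coef(full)[["x1"]]
    base$betaEffect <- stats::coef(full)[["x2"]]
    base$interaction <- stats::coef(full)[["I(x1 * x2)"]]
    base$pInteraction <- cmp$`Pr(>F)`[2]
    base$lod <- max(0, (nUse / 2) * log10(rssRed / rssFull))
    base
  })
  out <- do.call(rbind, res)
  nTested <- sum(!out$collinear)
  thr <- bonferroniThreshold(alpha, max(nTested, 1))
  out$significant <- !is.na(out$pInteraction) & out$pInteraction < thr
  attr(out, "threshold") <- thr
  out
}

#' Two-gene dominant-epistasis segregation test
#'
#' Pearson chi-square test of an observed early/late split against the
#' 3:1 expectation of a two-gene dominant epistasis model in inbred lines
#' (the four equally frequent two-locus homozygote classes give three
#' early-type classes and one late).
#'
#' @param nEarly,nLate observed counts of the two phenotype classes.
#' @param probs expected proportions (default `c(0.75, 0.25)`).
#' @return list with `chisq`, `df`, `p` and the expected counts.
#' @examples
#' segregationTest(225, 75)  # chisq 0, p 1
#' @export
segregationTest <- function(nEarly, nLate, probs = c(0.75, 0.25)) {
  nTot <- nEarly + nLate
  if (nTot < 1) stop("need at least one line")
  ht <- stats::chisq.test(c(nEarly, nLate), p = probs)
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = unname(ht$expected))
}

#' Expected class proportions under two-gene dominant epistasis
#'
#' Enumerates the four equally frequent two-locus homozygote classes of an
#' inbred population and pools phenotypes under dominant epistasis (the
#' "late" phenotype requires the late allele at both loci): 3 early : 1
#' late.
#'
#' @return named numeric c(early, late) = c(0.75, 0.25).
#' @export
dominantEpistasisProportions <- function() {
  classes <- expand.grid(locus1 = c(0, 2), locus2 = c(0, 2))
  late <- classes$locus1 == 2 & classes$locus2 == 2
  c(early = mean(!late), late = mean(late))
}
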