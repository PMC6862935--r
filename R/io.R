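# CSV and minimal-VCF input/output. Conventions at the boundary: plot
# (row, col) coordinates and VCF positions are 1-based; genotype CSVs are
# lines x markers with a header of marker ids.

#' Read a genotype matrix from CSV or VCF
#'
#' CSV: a lines x markers table, first column line ids, remaining columns
#' genotype codes 0/1/2 (blank or NA = missing), with a companion map CSV
#' (columns marker, chrom, pos) supplied via `mapFile`. VCF: biallelic
#' records only, GT field; `0/0 -> 0`, het `-> 1`, `1/1 -> 2`, `./.` ->
#' missing. Multiallelic records are skipped with a message. Markers are
#' sorted by (chrom, pos) in the result.
#'
#' @param path file path.
#' @param format "csv" or "vcf" (guessed from the extension by default).
#' @param mapFile map CSV for `format = "csv"`; when omitted, markers are
#'   placed on one pseudo-chromosome at consecutive positions.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "csv", "vcf"),
                          mapFile = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "csv"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE)
    lines <- as.character(tab[[1]])
    geno <- t(as.matrix(tab[, -1, drop = FALSE]))  # markers x lines
    storage.mode(geno) <- "double"
    if (any(!geno[!is.na(geno)] %in% c(0, 1, 2)))
      stop("invalid genotype codes in ", path)
    colnames(geno) <- lines
    if (!is.null(mapFile)) {
      mp <- utils::read.csv(mapFile)
      idx <- match(rownames(geno), mp$marker)
      if (anyNA(idx)) stop("markers missing from map file")
      chrom <- mp$chrom[idx]
      pos <- mp$pos[idx]
    } else {
      chrom <- rep("chr0", nrow(geno))
      pos <- seq_len(nrow(geno))
    }
    return(GenotypeMatrix(geno, chrom = chrom, pos = pos))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- matrix(NA_real_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  code[clean %in% c("0/0")] <- 0
  code[clean %in% c("0/1", "1/0")] <- 1
  code[clean %in% c("1/1")] <- 2
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_",
                                         fix[, "POS"])[is.na(ids) |
                                                       ids == "."]
  rownames(code) <- ids
  GenotypeMatrix(code, chrom = fix[, "CHROM"],
                 pos = as.numeric(fix[, "POS"]))
}

#' Write a genotype matrix as CSV (plus map CSV)
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output CSV path (lines x markers).
#' @param mapPath optional path for the companion map CSV
#'   (marker, chrom, pos).
#' @return `path`, invisibly.
#' @export
writeGenotypesCSV <- function(G, path, mapPath = NULL) {
  g <- t(genoCodes(G))   # lines x markers
  tab <- data.frame(line = rownames(g), g, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(mapPath))
    utils::write.csv(markerMap(G), mapPath, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCF 4.2 with GT-only genotypes, one sample per line;
#' REF/ALT are placeholder A/B parent alleles. cM positions are scaled by
#' 1e4 to integer coordinates (VCF POS must be a 1-based integer).
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(G, path) {
  g <- genoCodes(G)
  mm <- markerMap(G)
  gtStr <- matrix("./.", nrow(g), ncol(g))
  gtStr[!is.na(g) & g == 0] <- "0/0"
  gtStr[!is.na(g) & g == 1] <- "0/1"
  gtStr[!is.na(g) & g == 2] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=phenoQTL",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
  pos <- as.integer(round(mm$pos * 1e4)) + 1L
  for (i in seq_len(nrow(g))) {
    writeLines(paste(c(mm$chrom[i], pos[i], mm$marker[i], "A", "T", ".",
                       "PASS", ".", "GT", gtStr[i, ]), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read / write plot-level score and layout tables
#'
#' Thin CSV wrappers fixing the column contracts used across the package:
#' scores are (plot, day, percent, source), layouts are
#' (plot, entry, year, rep, row, col, ...).
#'
#' @param path CSV path.
#' @param x data.frame to write.
#' @return a data.frame, or (for writers) `path` invisibly.
#' @export
readScores <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("plot", "day", "percent")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readScores
#' @export
writeTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
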