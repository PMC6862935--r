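#' Impute a percent-heading label between two scoring dates
#'
#' Images taken on days without a visual score inherit a label interpolated
#' from the scores immediately before and after: a weighted average of the
#' two scores with weights proportional to the distance to the *other*
#' scoring date, i.e. linear interpolation in the day,
#' `PCT(day) = PCT_prev * (next - day)/(next - prev) +
#'             PCT_next * (day - prev)/(next - prev)`.
#' Scoring days are recovered exactly.
#'
#' @param prev,next. lists or data.frames with fields `day` and `percent`
#'   (the scores directly before and after the imaging date).
#' @param day imaging day of year, in `[prev$day, next.$day]`.
#' @return continuous percent in [0, 100].
#' @examples
#' imputePercentLabel(list(day = 120, percent = 20),
#'                    list(day = 124, percent = 40), day = 121)  # 25
#' @export
imputePercentLabel <- function(prev, next., day) {
  t0 <- prev$day
  t1 <- next.$day
  if (t1 <= t0) stop("next. day must be after prev day")
  if (any(day < t0) || any(day > t1))
    stop("day outside [prev$day, next.$day]")
  w <- (day - t0) / (t1 - t0)
  prev$percent * (1 - w) + next.$percent * w
}

#' Patch-grid geometry for cropping images into classifier inputs
#'
#' Computes the top-left-anchored offsets of a `gridRows x gridCols` grid of
#' square patches of `patch` pixels inside an image, the geometry used to
#' feed 224 x 224 patches from 672 x 672 images into a patch classifier.
#'
#' @param imageW,imageH image dimensions in pixels.
#' @param gridRows,gridCols grid dimensions.
#' @param patch patch side length in pixels.
#' @return list with the inputs plus `offsets`, a data.frame of `x`, `y`
#'   pixel offsets (0-based, row-major), one row per patch.
#' @examples
#' g <- gridPatches(672, 672, 3, 3, 224)
#' nrow(g$offsets)  # 9
#' @export
gridPatches <- function(imageW, imageH, gridRows = 3, gridCols = 3,
                        patch = 224) {
  if (patch > imageW || patch > imageH)
    stop("patch larger than image")
  if (gridCols * patch > imageW || gridRows * patch > imageH)
    stop("grid does not fit inside the image")
  offs <- expand.grid(x = (seq_len(gridCols) - 1L) * patch,
                      y = (seq_len(gridRows) - 1L) * patch,
                      KEEP.OUT.ATTRS = FALSE)[, c("x", "y")]
  list(imageW = imageW, imageH = imageH, gridRows = gridRows,
       gridCols = gridCols, patch = patch,
       offsets = offs[order(offs$y, offs$x), , drop = FALSE])
}

#' Soft-label target distribution with partial credit
#'
#' Builds the 11-class target distribution for a percent-heading label:
#' mass 0.7 on the labelled class, 0.1 on each class one step (10%) away
#' and 0.05 on each class two steps (20%) away. Mass that would fall
#' outside the class range is added back to the labelled class so the
#' vector sums to exactly 1 and the labelled class stays strictly dominant.
#'
#' @param classIndex labelled class, 0-based in `0:(nClasses-1)`
#'   (class k = 10k percent heading).
#' @param nClasses number of classes (11 for 0--100% in 10% steps).
#' @return numeric vector of length `nClasses`, named by percent class,
#'   non-negative, summing to 1.
#' @examples
#' buildSoftLabel(5)["50"]  # 0.7
#' buildSoftLabel(0)        # boundary: 0.85, 0.1, 0.05, 0, ...
#' @export
buildSoftLabel <- function(classIndex, nClasses = 11) {
  if (length(classIndex) != 1 || classIndex < 0 || classIndex > nClasses - 1)
    stop("classIndex out of range")
  classIndex <- as.integer(classIndex)
  mass <- c(`-2` = 0.05, `-1` = 0.1, `0` = 0.7, `1` = 0.1, `2` = 0.05)
  p <- numeric(nClasses)
  for (d in -2:2) {
    j <- classIndex + d
    m <- mass[[as.character(d)]]
    if (j >= 0 && j <= nClasses - 1) p[j + 1L] <- p[j + 1L] + m
    else p[classIndex + 1L] <- p[classIndex + 1L] + m
  }
  names(p) <- as.character(seq(0, by = 10, length.out = nClasses))
  p
}

#' Partial-credit error between two class distributions
#'
#' The training error used with soft labels: the mean over classes of the
#' absolute difference between the predicted and target distributions.
#' Zero iff the distributions are identical; symmetric; satisfies the
#' triangle inequality (it is the L1 distance divided by the number of
#' classes).
#'
#' @param pred,target probability vectors of equal length.
#' @return non-negative scalar.
#' @export
softLabelError <- function(pred, target) {
  if (length(pred) != length(target))
    stop("pred and target must have equal length")
  mean(abs(pred - target))
}

#' Consensus class for one image from its patch predictions
#'
#' Sums the per-patch class distributions and returns the class with the
#' largest total mass — the image-level consensus over all patches. Ties
#' break toward the lower class index.
#'
#' @param patchPredictions matrix (patches x classes) or list of
#'   probability vectors.
#' @return 0-based consensus class index.
#' @export
consensusImage <- function(patchPredictions) {
  if (is.list(patchPredictions))
    patchPredictions <- do.call(rbind, patchPredictions)
  patchPredictions <- as.matrix(patchPredictions)
  if (nrow(patchPredictions) < 1) stop("need at least one patch")
  total <- colSums(patchPredictions)
  unname(which.max(total) - 1L)  # which.max takes the first (lowest) on ties
}

#' Plot-level consensus by majority vote over image labels
#'
#' @param imageClasses vector of per-image labels (class indices, or any
#'   atomic labels such as "awned"/"awnless").
#' @return the majority label; ties break toward the lower (first in sort
#'   order) label.
#' @export
consensusPlot <- function(imageClasses) {
  if (length(imageClasses) < 1) stop("need at least one image")
  lev <- sort(unique(imageClasses))     # numeric sort for numeric labels
  counts <- vapply(lev, function(l) sum(imageClasses == l), integer(1))
  lev[which.max(counts)]                # first max = lowest label on ties
}

#' Impute labels for an imaging-date table from a visual-score table
#'
#' For each (plot, day) in `imagingDays`, finds the visual scores directly
#' before and after that day for the same plot and applies
#' [imputePercentLabel()]. Days coinciding with a scoring day take that
#' score directly; days outside the scored window are returned as `NA`.
#'
#' @param scores data.frame (plot, day, percent) of visual scores.
#' @param imagingDays data.frame (plot, day) of imaging dates.
#' @return `imagingDays` with an added `percent` column.
#' @export
imputeLabelTable <- function(scores, imagingDays) {
  out <- imagingDays
  out$percent <- NA_real_
  for (i in seq_len(nrow(imagingDays))) {
    s <- scores[scores$plot == imagingDays$plot[i], , drop = FALSE]
    s <- s[order(s$day), , drop = FALSE]
    d <- imagingDays$day[i]
    if (!nrow(s) || d < min(s$day) || d > max(s$day)) next
    if (d %in% s$day) {
      out$percent[i] <- s$percent[match(d, s$day)]
    } else {
      lo <- max(which(s$day < d))
      out$percent[i] <- imputePercentLabel(
        list(day = s$day[lo], percent = s$percent[lo]),
        list(day = s$day[lo + 1L], percent = s$percent[lo + 1L]), d)
    }
  }
  out
}
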