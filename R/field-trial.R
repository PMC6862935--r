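#' Simulate a replicated field trial with spatially correlated plot noise
#'
#' Lays `nReps` replicates of each entry per year onto a `nRows x nCols`
#' grid (plots filled row-major, reps in consecutive blocks) and draws the
#' plot-level heading date as
#' `line genetic value + year effect + rep-within-year effect + residual`,
#' where the residual field over the grid has a separable AR1 x AR1
#' correlation over rows and columns with variance `sigma2E`. Each line's
#' curve steepness phi3 is taken from its rate trait (vector `rate`), and
#' the latent plot curve is anchored through its heading date via
#' `phi2 = -phi3 * heading_date`.
#'
#' @param headingValue named per-line genetic values for heading date
#'   (day of year), e.g. from [geneticValues()].
#' @param rate named per-line values of the rate trait phi3 (per day);
#'   recycled scalar allowed. Values must be positive.
#' @param nReps replications per year.
#' @param nYears number of years.
#' @param nRows,nCols field grid dimensions; `nRows * nCols` must hold all
#'   plots of one year.
#' @param sigma2Y,sigma2R,sigma2E variances of the year effect,
#'   rep-within-year effect and spatial residual (days^2).
#' @param rhoRow,rhoCol AR1 correlations in (-1, 1).
#' @param seed integer seed.
#' @return data.frame of plot truth: `plot, entry, year, rep, row, col,
#'   phi2, phi3, heading_date` (one row per plot; `heading_date` includes
#'   all non-genetic effects, so replicate plots of a line differ unless all
#'   variances are zero).
#' @export
simulateTrial <- function(headingValue, rate = 0.3, nReps = 2, nYears = 1,
                          nRows = NULL, nCols = NULL,
                          sigma2Y = 0, sigma2R = 0, sigma2E = 1,
                          rhoRow = 0, rhoCol = 0, seed = 1) {
  nLines <- length(headingValue)
  if (is.null(names(headingValue)))
    names(headingValue) <- sprintf("RIL%03d", seq_len(nLines))
  rate <- rep_len(rate, nLines)
  if (any(rate <= 0)) stop("rate (phi3) must be positive")
  if (abs(rhoRow) >= 1 || abs(rhoCol) >= 1)
    stop("AR1 correlations must lie in (-1, 1)")
  nPlotsYear <- nLines * nReps
  if (is.null(nCols)) nCols <- ceiling(sqrt(nPlotsYear))
  if (is.null(nRows)) nRows <- ceiling(nPlotsYear / nCols)
  if (nRows * nCols < nPlotsYear)
    stop("grid too small: nRows * nCols < nLines * nReps")

  .withStream(seed, "trial", {
    yearEff <- stats::rnorm(nYears, 0, sqrt(sigma2Y))
    out <- vector("list", nYears)
    Lr <- chol(.ar1(nRows, rhoRow))
    Lc <- chol(.ar1(nCols, rhoCol))
    plotId <- 0L
    for (yj in seq_len(nYears)) {
      repEff <- stats::rnorm(nReps, 0, sqrt(sigma2R))
      # separable AR1 x AR1 field: E = sqrt(s2e) * t(Lr) Z Lc
      Z <- matrix(stats::rnorm(nRows * nCols), nRows, nCols)
      E <- sqrt(sigma2E) * t(Lr) %*% Z %*% Lc
      entry <- rep(names(headingValue), nReps)
      repNo <- rep(seq_len(nReps), each = nLines)
      cell <- seq_len(nPlotsYear)
      row <- (cell - 1L) %/% nCols + 1L
      col <- (cell - 1L) %% nCols + 1L
      hd <- headingValue[entry] + yearEff[yj] + repEff[repNo] +
        E[cbind(row, col)]
      phi3 <- rate[match(entry, names(headingValue))]
      out[[yj]] <- data.frame(
        plot = sprintf("Y%d_P%04d", yj, cell),
        entry = entry, year = yj, rep = repNo, row = row, col = col,
        phi2 = -phi3 * hd, phi3 = phi3, heading_date = as.numeric(hd),
        row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Sample discretized visual percent-heading scores from plot truth
#'
#' Evaluates the latent logistic curve
#' `100 / (1 + exp(-(phi2 + phi3 * day)))` on the observation days, rounds
#' to the nearest 10% (breeder scores come in 10% increments), then applies
#' the mislabel model: with probability `p10` the score is shifted one
#' class (10%) up or down, and with probability `p20` two classes (20%),
#' direction chosen with equal probability and the result clipped to
#' [0, 100]. No monotone correction is applied, matching raw field scoring.
#'
#' @param truth data.frame of plot truth from [simulateTrial()] (columns
#'   `plot`, `phi2`, `phi3`).
#' @param days numeric vector of observation days (day of year).
#' @param p10,p20 mislabel rates for one- and two-class shifts; defaults
#'   are the rates estimated from repeated visual scoring (10% and 5%).
#' @param seed integer seed.
#' @return data.frame (plot, day, percent, source = "visual").
#' @export
sampleVisualScores <- function(truth, days, p10 = 0.10, p20 = 0.05,
                               seed = 1) {
  stopifnot(all(c("plot", "phi2", "phi3") %in% names(truth)))
  if (p10 + p20 > 1) stop("p10 + p20 must be <= 1")
  .withStream(seed, "scores", {
    grid <- expand.grid(i = seq_len(nrow(truth)), day = days,
                        KEEP.OUT.ATTRS = FALSE)
    curve <- 100 * stats::plogis(truth$phi2[grid$i] +
                                 truth$phi3[grid$i] * grid$day)
    score <- round(curve / 10) * 10
    n <- length(score)
    u <- stats::runif(n)
    shift <- ifelse(u < p10, 10, ifelse(u < p10 + p20, 20, 0))
    sign <- sample(c(-1, 1), n, replace = TRUE)
    score <- pmin(100, pmax(0, score + sign * shift))
    data.frame(plot = truth$plot[grid$i], day = grid$day,
               percent = score, source = "visual",
               stringsAsFactors = FALSE)
  })
}

#' Simulate image-level class-probability predictions for a plot-day
#'
#' Emulates a patch-based classifier scoring `nImages` images of one plot on
#' one day. The true 11-class label is the latent curve value rounded to the
#' nearest 10%. Each image's reported class distribution is the empirical
#' distribution of `nDraws` internal draws from a tridiagonal confusion
#' kernel that puts mass `1 - 2*leak` on the true class and `leak` on each
#' adjacent class (boundary mass folded onto the true class). With
#' `leak = 0` every image reports a point mass on the true class.
#'
#' @param truth one row of plot truth (`plot`, `phi2`, `phi3`).
#' @param day day of year.
#' @param nImages images captured for the plot on that day (>= 1).
#' @param leak per-neighbour confusion mass in [0, 0.5).
#' @param nDraws internal draws per image (patch analogues).
#' @param seed integer seed.
#' @return data.frame with `image`, `plot`, `day` and class columns
#'   `p0, p10, ..., p100`; one row per image, each row summing to 1.
#' @export
simulateImagePredictions <- function(truth, day, nImages = 12, leak = 0,
                                     nDraws = 9, seed = 1) {
  if (nImages < 1) stop("nImages must be >= 1")
  if (leak < 0 || leak >= 0.5) stop("leak must be in [0, 0.5)")
  trueClass <- round(100 * stats::plogis(truth$phi2[1] +
                                         truth$phi3[1] * day) / 10)  # 0..10
  kern <- numeric(11)
  kern[trueClass + 1L] <- 1 - 2 * leak
  for (d in c(-1L, 1L)) {
    j <- trueClass + d
    if (j >= 0L && j <= 10L) kern[j + 1L] <- kern[j + 1L] + leak
    else kern[trueClass + 1L] <- kern[trueClass + 1L] + leak
  }
  .withStream(seed, "images", {
    probs <- t(vapply(seq_len(nImages), function(i) {
      draws <- sample.int(11L, nDraws, replace = TRUE, prob = kern)
      tabulate(draws, nbins = 11L) / nDraws
    }, numeric(11)))
    colnames(probs) <- paste0("p", seq(0, 100, by = 10))
    data.frame(image = sprintf("%s_d%g_img%02d", truth$plot[1], day,
                               seq_len(nImages)),
               plot = truth$plot[1], day = day, probs,
               stringsAsFactors = FALSE)
  })
}
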