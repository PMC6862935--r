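#' Add asymptote anchor points to a percent-heading series
#'
#' To stabilise the logistic fit, 0% points are added 10, 20 and 30 days
#' before the first observation and 100% points 10, 20 and 30 days after
#' the last one — dates on which no plot had started, or every plot had
#' finished, heading. Exactly six points are added; the originals are kept
#' unchanged and the result is sorted by day.
#'
#' @param series data.frame with columns `day` and `percent` (one plot).
#' @param offsets days before/after at which to anchor (default 10, 20, 30).
#' @return the augmented series, sorted by day, with a `source` column
#'   marking added rows as "anchor".
#' @export
augmentAnchors <- function(series, offsets = c(10, 20, 30)) {
  if (!nrow(series)) stop("series is empty")
  first <- min(series$day)
  last <- max(series$day)
  anchors <- data.frame(
    day = c(first - offsets, last + offsets),
    percent = rep(c(0, 100), each = length(offsets)))
  orig <- series[, c("day", "percent"), drop = FALSE]
  orig$source <- if ("source" %in% names(series))
    as.character(series$source) else "observed"
  anchors$source <- "anchor"
  out <- rbind(orig, anchors)
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the per-plot logistic heading curve
#'
#' Fits `y = 100 / (1 + exp(-(phi2 + phi3 * day)))` to one plot's
#' time-series percent-heading by nonlinear least squares, with the
#' asymptote fixed at 100. The optimizer is a damped Gauss--Newton
#' (Levenberg--Marquardt style) iteration on (phi2, phi3); it stops when
#' the SSE improves by less than `tol` or after `maxIter` iterations.
#' Starting values come from a logit-scale regression: percents are clipped
#' into [1, 99], logit-transformed, and regressed on day to give phi3, with
#' phi2 anchored so the curve passes near the observation closest to 50%.
#'
#' @param series data.frame with `day` and `percent`; typically the output
#'   of [augmentAnchors()]. Needs at least 3 distinct days with values on
#'   both sides of 50% for a stable fit.
#' @param tol SSE-change convergence tolerance.
#' @param maxIter maximum iterations.
#' @return a [LogisticFit-class]; non-convergence is flagged, not thrown.
#' @examples
#' d <- 110:135
#' s <- data.frame(day = d, percent = 100 * plogis(-25 + 0.2 * d))
#' fitLogistic(s)
#' @export
fitLogistic <- function(series, tol = 1e-8, maxIter = 200) {
  day <- as.numeric(series$day)
  y <- as.numeric(series$percent)
  keep <- is.finite(day) & is.finite(y)
  day <- day[keep]
  y <- y[keep]
  if (length(unique(day)) < 3)
    stop("need at least 3 distinct days")
  if (all(y == 0) || all(y == 100))
    stop("degenerate series: all observations at one asymptote")

  # logit-scale initialisation (clip only for the transform)
  pc <- pmin(99, pmax(1, y)) / 100
  lg <- stats::qlogis(pc)
  sl <- stats::coef(stats::lm(lg ~ day))
  slopeInit <- max(as.numeric(sl[2]), 1e-3)
  # midpoint init from the 50% crossing: midway between the last day below
  # and the first day above 50 (falls back to the closest-to-50 day)
  below <- day[y < 50]
  above <- day[y > 50]
  mid <- if (length(below) && length(above)) {
    (max(below) + min(above)) / 2
  } else day[which.min(abs(y - 50))]
  # second slope candidate from the 25-75% span of the crossing region
  span <- if (length(below) && length(above))
    max(1, min(above) - max(below)) else diff(range(day)) / 4
  starts <- list(c(-slopeInit * mid, slopeInit),
                 c(-(2.2 / span) * mid, 2.2 / span))

  sseOf <- function(p2, p3) {
    f <- 100 * stats::plogis(p2 + p3 * day)
    sum((y - f)^2)
  }
  best <- NULL
  for (st in starts) {
    run <- .lmLogistic(day, y, st[1], st[2], sseOf, tol, maxIter)
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  new("LogisticFit", phi1 = 100, phi2 = as.numeric(best$phi2),
      phi3 = as.numeric(best$phi3), sse = as.numeric(best$sse),
      converged = best$converged, nObs = length(y),
      dayRange = range(day))
}

# damped Gauss-Newton iteration from one start
.lmLogistic <- function(day, y, phi2, phi3, sseOf, tol, maxIter) {
  sse <- sseOf(phi2, phi3)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    p <- stats::plogis(phi2 + phi3 * day)
    f <- 100 * p
    w <- 100 * p * (1 - p)               # df/dphi2
    J <- cbind(w, w * day)
    r <- y - f
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    step <- tryCatch(
      solve(JtJ + lambda * diag(diag(JtJ), 2), g),
      error = function(e) NULL)
    if (is.null(step)) {
      lambda <- lambda * 10
      next
    }
    newSse <- sseOf(phi2 + step[1], phi3 + step[2])
    if (newSse <= sse) {
      improved <- sse - newSse
      phi2 <- phi2 + step[1]
      phi3 <- phi3 + step[2]
      sse <- newSse
      lambda <- max(lambda / 10, 1e-12)
      if (improved < tol) {
        converged <- TRUE
        break
      }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  list(phi2 = phi2, phi3 = phi3, sse = sse, converged = converged)
}

#' Heading date: the day whose predicted heading is closest to 50%
#'
#' Evaluates the fitted curve on a grid at `step`-day increments over the
#' full range of the (anchored) days and returns the grid day minimizing
#' |prediction - 50|, i.e. the 50% intersect. For a rising curve this
#' agrees with the closed form `-phi2/phi3` to within half a grid step
#' whenever that value lies inside the range. Ties take the earliest day.
#'
#' @param fit a [LogisticFit-class].
#' @param dayRange length-2 numeric; defaults to the fit's day range.
#' @param step grid increment in days (default 0.1).
#' @return day of year, rounded to one decimal.
#' @export
headingDate <- function(fit, dayRange = fit@dayRange, step = 0.1) {
  if (!fit@converged) stop("fit did not converge")
  if (fit@phi3 <= 0) stop("phi3 <= 0: no rising curve, heading undefined")
  grid <- seq(dayRange[1], dayRange[2], by = step)
  pred <- 100 * stats::plogis(fit@phi2 + fit@phi3 * grid)
  round(grid[which.min(abs(pred - 50))], 1)
}

#' Rate of heading
#'
#' The slope phi3 of the fitted logistic curve: how fast a plot progresses
#' through heading (per day on the logit scale). phi2 stays available on
#' the fit object for reporting.
#'
#' @param fit a [LogisticFit-class].
#' @return phi3 (per day).
#' @export
headingRate <- function(fit) {
  if (!fit@converged) stop("fit did not converge")
  fit@phi3
}

#' Fit phenology for every plot in a score table
#'
#' Runs [augmentAnchors()], [fitLogistic()] and [headingDate()] per plot.
#'
#' @param scores data.frame (plot, day, percent, ...).
#' @param step grid increment for the 50% intersect.
#' @param anchor add asymptote anchors before fitting (default TRUE).
#' @return data.frame (plot, phi2, phi3, heading_date, rate, converged,
#'   sse); plots whose fit fails or does not converge carry `NA` dates.
#' @export
fitPhenology <- function(scores, step = 0.1, anchor = TRUE) {
  plots <- unique(scores$plot)
  res <- lapply(plots, function(p) {
    s <- scores[scores$plot == p, , drop = FALSE]
    if (anchor) s <- augmentAnchors(s)
    fit <- tryCatch(fitLogistic(s), error = function(e) NULL)
    if (is.null(fit) || !fit@converged || fit@phi3 <= 0) {
      return(data.frame(plot = p, phi2 = NA_real_, phi3 = NA_real_,
                        heading_date = NA_real_, rate = NA_real_,
                        converged = FALSE, sse = NA_real_))
    }
    data.frame(plot = p, phi2 = fit@phi2, phi3 = fit@phi3,
               heading_date = headingDate(fit, step = step),
               rate = headingRate(fit), converged = TRUE, sse = fit@sse)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Agreement statistics between two heading-date measurements
#'
#' Compares per-plot heading dates from two methods (e.g. visual scoring
#' vs classifier predictions): mean absolute error, root mean square error,
#' the fractions of plots agreeing within 1 and 2 days, and the slope of
#' the least-squares regression of method B on method A (1 = no bias).
#'
#' @param datesA,datesB numeric vectors of per-plot heading dates; if
#'   named, they are matched by name.
#' @return list with `mae`, `rmse`, `within1`, `within2`, `slope`, `n`.
#' @export
seriesAgreement <- function(datesA, datesB) {
  if (!is.null(names(datesA)) && !is.null(names(datesB))) {
    common <- intersect(names(datesA), names(datesB))
    if (!length(common)) stop("no common plots between the two sets")
    datesA <- datesA[common]
    datesB <- datesB[common]
  }
  if (length(datesA) != length(datesB))
    stop("mismatched plot sets")
  keep <- is.finite(datesA) & is.finite(datesB)
  a <- datesA[keep]
  b <- datesB[keep]
  if (length(a) < 2) stop("need at least 2 matched plots")
  d <- b - a
  eps <- 1e-9
  list(mae = mean(abs(d)),
       rmse = sqrt(mean(d^2)),
       within1 = mean(abs(d) <= 1 + eps),
       within2 = mean(abs(d) <= 2 + eps),
       slope = if (stats::var(a) == 0) NA_real_ else
         as.numeric(stats::coef(stats::lm(b ~ a))[2]),
       n = length(a))
}
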