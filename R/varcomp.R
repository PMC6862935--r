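# REML for the plot-level model y_ijk = mu + g_i + y_j + r_k(j) [+ gy_ij] + e,
# residual iid or separable AR1xAR1 over the field (row, col) grid within
# year. The residual variance is profiled out, so the optimizer works over
# variance ratios (log scale) and AR1 correlations (atanh scale) only.

.zMatrix <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  colnames(Z) <- levels(f)
  Z
}

# residual correlation matrix: identity, or ar1xar1 within year
.residCor <- function(plots, spatial, rhoRow, rhoCol) {
  n <- nrow(plots)
  if (spatial == "iid") return(diag(n))
  dr <- abs(outer(plots$row, plots$row, "-"))
  dc <- abs(outer(plots$col, plots$col, "-"))
  sameYear <- outer(plots$year, plots$year, "==")
  R <- (rhoRow^dr) * (rhoCol^dc) * sameYear
  R
}

# profiled restricted log-likelihood; returns list(logLik, sigma2E, beta)
.remlProfile <- function(y, X, kernels, gammas, R0) {
  n <- length(y)
  p <- ncol(X)
  V0 <- R0
  for (i in seq_along(kernels)) V0 <- V0 + gammas[i] * kernels[[i]]
  C <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(C)) return(list(logLik = -Inf))
  ldV <- 2 * sum(log(diag(C)))
  Vi_y <- backsolve(C, forwardsolve(t(C), y))
  Vi_X <- backsolve(C, forwardsolve(t(C), X))
  XtViX <- crossprod(X, Vi_X)
  ldX <- determinant(XtViX, logarithm = TRUE)$modulus
  beta <- solve(XtViX, crossprod(X, Vi_y))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  if (yPy <= 0) return(list(logLik = -Inf))
  s2 <- yPy / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ldV + as.numeric(ldX))
  list(logLik = ll, sigma2E = s2, beta = beta, V0 = V0, C = C)
}

#' Estimate variance components by REML
#'
#' Fits the mixed model `y = mu + entry + [year + rep:year + entry:year] + e`
#' to a plot table by restricted maximum likelihood. Entry is always random;
#' year, replication-within-year and entry-by-year terms enter only when the
#' table spans more than one year. The residual is iid, or carries a
#' separable AR1 x AR1 correlation over field rows and columns within each
#' year. The restricted likelihood is maximized directly over log variance
#' ratios and atanh-transformed correlations, with the residual variance
#' profiled out; a derivative-free simplex with restarts does the search
#' (Brent when only one ratio is free).
#'
#' @param plots data.frame with columns `entry`, `year`, `rep`, `row`,
#'   `col` and the response named by `response`.
#' @param response name of the response column (default "value").
#' @param spatial residual structure, "iid" or "ar1".
#' @param nRestarts simplex restarts from perturbed starts (>= 1).
#' @return a [VarianceComponents-class].
#' @examples
#' \dontrun{
#' vc <- fitVarianceComponents(plotTable, response = "heading_date")
#' heritability(vc, "single_year")
#' }
#' @export
fitVarianceComponents <- function(plots, response = "value",
                                  spatial = c("iid", "ar1"),
                                  nRestarts = 3) {
  spatial <- match.arg(spatial)
  need <- c("entry", "year", "rep", response)
  if (spatial == "ar1") need <- c(need, "row", "col")
  if (!all(need %in% names(plots)))
    stop("plot table must have columns: ", paste(need, collapse = ", "))
  plots <- plots[is.finite(plots[[response]]), , drop = FALSE]
  y <- plots[[response]]
  n <- length(y)
  if (n < 2 || length(unique(plots$entry)) < 2)
    stop("singular design: need >= 2 plots and >= 2 entries")
  if (max(table(plots$entry, plots$year)) < 2 &&
      length(unique(plots$year)) < 2)
    stop("all entries unreplicated in a single year: variance not separable")

  multiYear <- length(unique(plots$year)) > 1
  X <- matrix(1, n, 1)
  Zg <- .zMatrix(plots$entry)
  kernels <- list(G = tcrossprod(Zg))
  if (multiYear) {
    Zy <- .zMatrix(plots$year)
    Zr <- .zMatrix(interaction(plots$year, plots$rep, drop = TRUE))
    Zgy <- .zMatrix(interaction(plots$entry, plots$year, drop = TRUE))
    kernels <- c(kernels, list(Y = tcrossprod(Zy), R = tcrossprod(Zr),
                               GY = tcrossprod(Zgy)))
  }
  nk <- length(kernels)
  nrho <- if (spatial == "ar1") 2L else 0L

  objective <- function(theta) {
    gammas <- exp(theta[seq_len(nk)])
    if (any(!is.finite(gammas))) return(1e10)
    rhoR <- if (nrho) tanh(theta[nk + 1L]) else 0
    rhoC <- if (nrho) tanh(theta[nk + 2L]) else 0
    R0 <- .residCor(plots, spatial, rhoR, rhoC)
    pr <- .remlProfile(y, X, kernels, gammas, R0)
    if (!is.finite(pr$logLik)) 1e10 else -pr$logLik
  }

  npar <- nk + nrho
  start <- c(rep(0, nk), rep(0, nrho))
  best <- NULL
  starts <- list(start)
  if (nRestarts > 1) {
    for (k in seq_len(nRestarts - 1))
      starts[[k + 1]] <- start + c(rep(c(-1.5, 1.5), length.out = nk) * k,
                                   rep(0, nrho))
  }
  for (s in starts) {
    fit <- if (npar == 1) {
      stats::optim(s, objective, method = "Brent", lower = -25, upper = 25)
    } else {
      stats::optim(s, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  gammas <- stats::setNames(exp(theta[seq_len(nk)]), names(kernels))
  rhoR <- if (nrho) tanh(theta[nk + 1L]) else 0
  rhoC <- if (nrho) tanh(theta[nk + 2L]) else 0
  R0 <- .residCor(plots, spatial, rhoR, rhoC)
  pr <- .remlProfile(y, X, kernels, gammas, R0)
  s2e <- pr$sigma2E
  # ratios driven to ~0 are genuinely zero at double precision
  comp <- gammas * s2e
  comp[gammas < 1e-10] <- 0

  repsPerYear <- tapply(plots$rep, plots$year,
                        function(r) length(unique(r)))
  new("VarianceComponents",
      sigma2G = comp[["G"]],
      sigma2GY = if (multiYear) comp[["GY"]] else NA_real_,
      sigma2Y = if (multiYear) comp[["Y"]] else NA_real_,
      sigma2R = if (multiYear) comp[["R"]] else NA_real_,
      sigma2E = s2e,
      rhoRow = rhoR, rhoCol = rhoC,
      nReps = as.numeric(stats::median(repsPerYear)),
      nYears = length(unique(plots$year)),
      logLik = pr$logLik,
      converged = if (npar == 1) TRUE else best$convergence == 0,
      spatial = spatial)
}

#' Broad-sense heritability on a line-mean basis
#'
#' Single-year: `H2 = s2G / (s2G + s2E / r)`. Multi-year at one location:
#' `H2 = s2G / (s2G + s2GY / y + s2E / (y * r))`, with `r` replications
#' per year and `y` years.
#'
#' @param vc a [VarianceComponents-class].
#' @param mode "single_year" or "multi_year".
#' @return H2 in [0, 1].
#' @examples
#' vc <- new("VarianceComponents", sigma2G = 1, sigma2GY = NA_real_,
#'           sigma2Y = NA_real_, sigma2R = NA_real_, sigma2E = 1,
#'           rhoRow = 0, rhoCol = 0, nReps = 2, nYears = 1,
#'           logLik = 0, converged = TRUE, spatial = "iid")
#' heritability(vc)  # 1 / (1 + 1/2) = 0.667
#' @export
heritability <- function(vc, mode = c("single_year", "multi_year")) {
  mode <- match.arg(mode)
  r <- vc@nReps
  if (r < 1) stop("need r >= 1 replications")
  if (mode == "single_year") {
    denom <- vc@sigma2G + vc@sigma2E / r
  } else {
    yn <- vc@nYears
    if (yn < 1) stop("need y >= 1 years")
    s2gy <- if (is.na(vc@sigma2GY)) 0 else vc@sigma2GY
    denom <- vc@sigma2G + s2gy / yn + vc@sigma2E / (yn * r)
  }
  if (denom <= 0) stop("zero total variance: heritability undefined")
  vc@sigma2G / denom
}

#' Entry-level BLUPs or BLUEs
#'
#' BLUP: entry enters as a random effect with variance from `vc`; the
#' returned values are `mu + u_i`, the shrunken predictions from the mixed
#' model equations. BLUE: entry is a fixed effect and values are the
#' generalized least squares estimates of entry means. Both use the year /
#' rep-within-year terms (multi-year tables) and the residual structure of
#' the supplied fit.
#'
#' @param plots plot table as in [fitVarianceComponents()].
#' @param vc a fitted [VarianceComponents-class]; fitted on the fly when
#'   `NULL`.
#' @param response response column name.
#' @param mode "BLUP" or "BLUE".
#' @return named numeric vector of per-entry values.
#' @export
entryValues <- function(plots, vc = NULL, response = "value",
                        mode = c("BLUP", "BLUE")) {
  mode <- match.arg(mode)
  if (is.null(vc))
    vc <- fitVarianceComponents(plots, response = response)
  plots <- plots[is.finite(plots[[response]]), , drop = FALSE]
  y <- plots[[response]]
  n <- length(y)
  multiYear <- length(unique(plots$year)) > 1
  Zg <- .zMatrix(plots$entry)
  entries <- colnames(Zg)
  R0 <- .residCor(plots, vc@spatial, vc@rhoRow, vc@rhoCol)
  Vother <- vc@sigma2E * R0
  if (multiYear) {
    Zy <- .zMatrix(plots$year)
    Zr <- .zMatrix(interaction(plots$year, plots$rep, drop = TRUE))
    Zgy <- .zMatrix(interaction(plots$entry, plots$year, drop = TRUE))
    Vother <- Vother + vc@sigma2Y * tcrossprod(Zy) +
      vc@sigma2R * tcrossprod(Zr) + vc@sigma2GY * tcrossprod(Zgy)
  }
  if (mode == "BLUE") {
    X <- Zg
    Vi_X <- solve(Vother, X)
    beta <- solve(crossprod(X, Vi_X), crossprod(Vi_X, y))
    return(stats::setNames(as.numeric(beta), entries))
  }
  # BLUP: V = s2G Zg Zg' + Vother; u = s2G Zg' V^-1 (y - mu)
  V <- vc@sigma2G * tcrossprod(Zg) + Vother
  X <- matrix(1, n, 1)
  Vi_X <- solve(V, X)
  Vi_y <- solve(V, y)
  mu <- as.numeric(solve(crossprod(X, Vi_X), crossprod(X, Vi_y)))
  u <- vc@sigma2G * crossprod(Zg, solve(V, y - mu * X[, 1]))
  stats::setNames(as.numeric(mu + u), entries)
}
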