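#' @include AllClasses.R models.R
NULL

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around the product-moment correlation used for
#' every goodness-of-fit coefficient in the package.
#'
#' @param x,y numeric vectors of equal length, >= 3 finite pairs, both with
#'   positive variance.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

## r between observed and fitted, NA when either side is constant
.obsFitR <- function(obs, fit) {
  if (stats::var(obs) == 0 || stats::var(fit) == 0) return(NA_real_)
  stats::cor(obs, fit)
}

#' Linear least-squares fit
#'
#' Ordinary least squares of `y` on `x - xShift`, optionally with the
#' intercept forced to zero. The goodness-of-fit `r` is the Pearson
#' correlation of `x` and `y` (reported `NA` for a constant response).
#'
#' @param x,y numeric vectors, >= 3 finite pairs, >= 2 distinct `x`.
#' @param throughOrigin logical, force intercept to 0 (default FALSE).
#' @param xShift predictor offset subtracted before fitting (default 0).
#' @return `list(model = ` [LinearLinkModel-class]`, fit = `
#'   [FitResult-class]`)`.
#' @examples
#' ph <- seq(6.75, 6.98, length.out = 8)
#' fitLinear(ph, 32.83 + 12.71 * ph)$model
#' @export
fitLinear <- function(x, y, throughOrigin = FALSE, xShift = 0) {
  if (length(x) != length(y))
    stop("mismatched lengths of x and y", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (length(unique(x)) < 2 || stats::var(x) == 0)
    stop("zero x-variance: slope undefined", call. = FALSE)
  xs <- x - xShift
  if (throughOrigin) {
    lmfit <- stats::lm(y ~ 0 + xs)
    slope <- unname(stats::coef(lmfit)[1])
    intercept <- 0
    ## summary.lm warns on numerically perfect fits; the NA fallback covers
    ## genuinely degenerate designs
    sev <- suppressWarnings(sqrt(diag(stats::vcov(lmfit))))
    se <- c(slope = unname(sev[1]), intercept = NA_real_)
  } else {
    lmfit <- stats::lm(y ~ xs)
    cf <- stats::coef(lmfit)
    intercept <- unname(cf[1])
    slope <- unname(cf[2])
    sev <- suppressWarnings(sqrt(diag(stats::vcov(lmfit))))
    se <- c(slope = unname(sev[2]), intercept = unname(sev[1]))
  }
  r <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)
  model <- linearLinkModel(slope = slope, intercept = intercept,
                           xShift = xShift)
  res <- y - evalLinearLink(model, x)
  fit <- .fitResult(params = c(slope = slope, intercept = intercept,
                               xShift = xShift),
                    stderr = c(se, xShift = NA_real_),
                    r = r, residuals = res, converged = TRUE, nIter = 0L,
                    units = c(slope = "response/predictor",
                              intercept = "response", xShift = "predictor"))
  list(model = model, fit = fit)
}

## Bounded Levenberg-Marquardt with the package's convergence contract.
## Returns par, stderr, converged, niter, residuals.
.lmFit <- function(par, lower, residFun, maxiter = 500L, ptol = 1e-10) {
  out <- minpack.lm::nls.lm(
    par = par, fn = residFun, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ptol = ptol,
                                         ftol = 1e-12))
  conv <- out$info %in% 1:4
  se <- tryCatch({
    s <- summary(out)
    unname(s$coefficients[, "Std. Error"])
  }, error = function(e) rep(NA_real_, length(par)))
  list(par = setNames(as.numeric(out$par), names(par)),
       stderr = setNames(se, names(par)),
       converged = conv, niter = as.integer(out$niter),
       residuals = as.numeric(out$fvec))
}

#' Fit the exponential relaxation model
#'
#' Nonlinear least squares of `(y0 - yInf) * exp(-D/DC) + yInf` over
#' `(y0, yInf, DC)`, with `DC` bounded positive. Initialization: `y0` from
#' the value at the smallest dose, `yInf` from the value at the largest,
#' `DC` at a third of the dose range. Convergence: relative parameter change
#' below 1e-10 or 500 iterations; a non-converged fit is returned with
#' `converged = FALSE`, not raised as an error.
#'
#' @param doses,values numeric vectors (kGy, property units), >= 4 points
#'   spanning a positive dose range.
#' @return `list(model = ` [RelaxationModel-class]`, fit = `
#'   [FitResult-class]`)`.
#' @examples
#' d <- seq(0, 400, 25)
#' y <- evalRelaxation(relaxationModel(6.98, 6.75, 73.4), d)
#' fitRelaxation(d, y)$model
#' @export
fitRelaxation <- function(doses, values) {
  if (length(doses) != length(values))
    stop("mismatched lengths", call. = FALSE)
  if (length(doses) < 4)
    stop("need at least 4 points for 3 parameters", call. = FALSE)
  if (diff(range(doses)) <= 0)
    stop("doses must span a positive range", call. = FALSE)
  ord <- order(doses)
  d <- doses[ord]; y <- values[ord]
  start <- c(y0 = y[1], yInf = y[length(y)], DC = diff(range(d)) / 3)
  resid <- function(p) y - ((p[1] - p[2]) * exp(-d / p[3]) + p[2])
  out <- .lmFit(start, lower = c(-Inf, -Inf, 1e-8), resid)
  p <- out$par
  if (p["DC"] <= 0) out$converged <- FALSE
  model <- relaxationModel(p["y0"], p["yInf"], max(p["DC"], 1e-8))
  fitted <- evalRelaxation(model, d)
  fit <- .fitResult(params = p, stderr = out$stderr,
                    r = .obsFitR(y, fitted), residuals = y - fitted,
                    converged = out$converged, nIter = out$niter,
                    units = c(y0 = "property", yInf = "property", DC = "kGy"))
  list(model = model, fit = fit)
}

## initial D0: smallest positive dose where the series re-crosses its
## initial value (linear interpolation); fallback mid-range
.initD0 <- function(d, g) {
  for (k in seq_along(d)[-1]) {
    if (d[k - 1] > 0 && g[k - 1] * g[k] <= 0) {
      w <- abs(g[k - 1]) + abs(g[k])
      return(if (w == 0) d[k - 1]
             else d[k - 1] + (d[k] - d[k - 1]) * abs(g[k - 1]) / w)
    }
  }
  mean(range(d))
}

#' Fit the sigmoid-modulated intensity-dose model
#'
#' Bounded nonlinear least squares of
#' `I(D) = iInit + D (D - D0) f(D)` with the generalized sigmoid specific
#' function, over `(D0, fMax, fMin, alpha, Dc)` and optionally `iInit`.
#'
#' Initialization: `iInit` from the observation at the smallest dose; `D0`
#' from the smallest positive dose at which the series re-crosses its
#' initial value (linear interpolation between samples, mid-range
#' fallback); the empirical specific function
#' `g(D) = (I(D) - iInit) / (D (D - D0))`, evaluated away from its poles,
#' seeds `fMax`/`fMin` from its extremes and `Dc` from its steepest
#' descent; `alpha` starts at 4 / (dose range). Bounds: `D0 >= 0`,
#' `alpha > 0`. A fit ending with `fMax <= fMin` or `alpha` at its bound
#' is flagged `converged = FALSE`.
#'
#' @param doses,intensities numeric vectors (kGy, counts).
#' @param iInitFixed optional counts; when supplied, the pre-irradiation
#'   intensity is held fixed at this value and only the five shape
#'   parameters are fitted (needs >= 6 points; >= 7 when `iInit` is free).
#' @return `list(model = ` [IntensityDoseModel-class]`, fit = `
#'   [FitResult-class]`)`.
#' @export
fitIntensityDose <- function(doses, intensities, iInitFixed = NULL) {
  if (length(doses) != length(intensities))
    stop("mismatched lengths", call. = FALSE)
  fixI <- !is.null(iInitFixed)
  if (length(doses) < (if (fixI) 6 else 7))
    stop("too few points for the number of free parameters", call. = FALSE)
  if (diff(range(doses)) <= 0)
    stop("doses must span a positive range", call. = FALSE)
  ord <- order(doses)
  d <- doses[ord]; I <- intensities[ord]
  iInit0 <- if (fixI) as.numeric(iInitFixed) else I[1]
  g <- I - iInit0
  D0init <- .initD0(d, g)
  femp <- g / (d * (d - D0init))
  step <- stats::median(diff(d))
  ok <- is.finite(femp) & d > 1e-6 & abs(d - D0init) > step
  fe <- femp[ok]; de <- d[ok]
  if (length(fe) < 2) { fe <- c(-1e-3, 1e-3); de <- range(d) }
  slopes <- diff(fe) / diff(de)
  DcInit <- if (length(slopes) && any(is.finite(slopes)))
    de[which.min(slopes)] else mean(range(d))
  eval6 <- function(iInit, D0, fMax, fMin, alpha, Dc) {
    z <- alpha * (d - Dc)
    s <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    iInit + d * (d - D0) * (fMin + (fMax - fMin) * s)
  }
  if (fixI) {
    start <- c(D0 = D0init, fMax = max(fe), fMin = min(fe),
               alpha = 4 / diff(range(d)), Dc = DcInit)
    lower <- c(0, -Inf, -Inf, 1e-8, -Inf)
    resid <- function(p) I - eval6(iInit0, p[1], p[2], p[3], p[4], p[5])
  } else {
    start <- c(iInit = iInit0, D0 = D0init, fMax = max(fe), fMin = min(fe),
               alpha = 4 / diff(range(d)), Dc = DcInit)
    lower <- c(1e-12, 0, -Inf, -Inf, 1e-8, -Inf)
    resid <- function(p) I - eval6(p[1], p[2], p[3], p[4], p[5], p[6])
  }
  if (start["fMax"] <= start["fMin"])
    start[c("fMax", "fMin")] <- start["fMin"] + c(1e-3, -1e-3)
  out <- .lmFit(start, lower, resid)
  p <- out$par
  iInitHat <- if (fixI) iInit0 else unname(p["iInit"])
  if (p["fMax"] <= p["fMin"] || p["alpha"] <= 2e-8) out$converged <- FALSE
  model <- tryCatch(
    intensityDoseModel(iInitHat, max(unname(p["D0"]), 1e-8),
      specificFunctionParams(
        fMax = max(p["fMax"], p["fMin"] + 1e-12), fMin = unname(p["fMin"]),
        alpha = max(p["alpha"], 1e-8), Dc = unname(p["Dc"]))),
    error = function(e) NULL)
  fitted <- if (is.null(model)) rep(NA_real_, length(d))
            else evalIntensityModel(model, d)
  params <- c(iInit = iInitHat, p[setdiff(names(p), "iInit")])
  stderr <- c(iInit = if (fixI) NA_real_ else unname(out$stderr["iInit"]),
              out$stderr[setdiff(names(p), "iInit")])
  fit <- .fitResult(params = params, stderr = stderr,
                    r = if (all(is.finite(fitted))) .obsFitR(I, fitted)
                        else NA_real_,
                    residuals = I - fitted,
                    converged = out$converged && !is.null(model),
                    nIter = out$niter,
                    units = c(iInit = "counts", D0 = "kGy",
                              fMax = "intensity/kGy^2",
                              fMin = "intensity/kGy^2", alpha = "1/kGy",
                              Dc = "kGy"))
  list(model = model, fit = fit)
}
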