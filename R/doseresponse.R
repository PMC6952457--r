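#' @include AllClasses.R models.R fitting.R
NULL

#' Optimized dose of an intensity-dose model
#'
#' The positive dose at which the modeled peak intensity returns exactly to
#' its pre-irradiation value. Analytically this is the nonzero root `D0` of
#' the quadratic factor `D (D - D0)`; the closed-form value is verified by
#' bracketing root-finding of `I(D) - iInit` over `(0, 2 D0]` and the
#' numeric root is attached as attribute `"numericRoot"`.
#'
#' @param m a converged [IntensityDoseModel-class].
#' @return the optimized dose in kGy (equal to `m@D0`), with attribute
#'   `numericRoot`.
#' @export
findOptimizedDose <- function(m) {
  stopifnot(is(m, "IntensityDoseModel"))
  validObject(m)
  f <- function(D) evalIntensityModel(m, D) - m@iInit
  ## bracket the quadratic-factor root at D0 tightly: besides 0 and D0, f
  ## also vanishes wherever the sigmoid itself crosses zero (fMin < 0 < fMax),
  ## so the bracket must isolate D0
  h <- 1e-3 * m@D0
  while (h > 1e-12 * m@D0 && f(m@D0 - h) * f(m@D0 + h) > 0) h <- h / 2
  if (f(m@D0 - h) * f(m@D0 + h) > 0)
    return(structure(m@D0, numericRoot = NA_real_))
  root <- stats::uniroot(f, c(m@D0 - h, m@D0 + h), tol = 1e-12)$root
  structure(m@D0, numericRoot = root)
}

#' Detect discrete extrema of a dose series
#'
#' Interior sample points strictly greater (local maximum) or strictly
#' smaller (local minimum) than both neighbours. Endpoints are never
#' reported. A tie with a neighbour (plateau) suppresses the point and sets
#' the `plateau` attribute of the result.
#'
#' @param s a [DoseSeries-class] with >= 3 points.
#' @return data.frame with columns `dose` and `kind` (`"min"`/`"max"`),
#'   possibly empty; attribute `plateau` is TRUE when ties were seen.
#' @examples
#' dh2 <- doseSeries("dH2", c(0, 5, 15, 20, 40, 50),
#'                   c(116.9, 141.9, 81.80, 144.0, 130.0, 115.7), "kJ/g")
#' detectDiscreteExtrema(dh2)
#' @export
detectDiscreteExtrema <- function(s) {
  stopifnot(is(s, "DoseSeries"))
  if (length(s@doses) < 3) stop("need at least 3 points", call. = FALSE)
  v <- s@values; d <- s@doses
  n <- length(v)
  out <- data.frame(dose = numeric(), kind = character(),
                    stringsAsFactors = FALSE)
  plateau <- FALSE
  for (i in 2:(n - 1)) {
    if (v[i] == v[i - 1] || v[i] == v[i + 1]) { plateau <- TRUE; next }
    if (v[i] > v[i - 1] && v[i] > v[i + 1])
      out <- rbind(out, data.frame(dose = d[i], kind = "max"))
    else if (v[i] < v[i - 1] && v[i] < v[i + 1])
      out <- rbind(out, data.frame(dose = d[i], kind = "min"))
  }
  attr(out, "plateau") <- plateau
  out
}

#' Mutual correlation between two dose series
#'
#' Inner-joins the two series on their dose grids (exact equality after
#' rounding to 1e-6 kGy) and fits the second series linearly against the
#' first. With `deviation = TRUE` both series are first reduced to
#' deviations from their zero-dose value, the form used to link UV-content
#' and water-content deviations.
#'
#' @param a,b [DoseSeries-class] objects sharing >= 3 doses.
#' @param deviation logical, fit on deviations from the dose-0 value
#'   (default FALSE, i.e. raw values as in the melting-point-vs-pH link).
#' @param throughOrigin passed to [fitLinear()] (default FALSE).
#' @return `list(model = LinearLinkModel, fit = FitResult)`.
#' @export
mutualCorrelation <- function(a, b, deviation = FALSE, throughOrigin = FALSE) {
  stopifnot(is(a, "DoseSeries"), is(b, "DoseSeries"))
  ka <- round(a@doses, 6); kb <- round(b@doses, 6)
  shared <- intersect(ka, kb)
  if (length(shared) < 3)
    stop("fewer than 3 shared doses between '", a@label, "' and '",
         b@label, "'", call. = FALSE)
  x <- a@values[match(shared, ka)]
  y <- b@values[match(shared, kb)]
  if (deviation) {
    i0 <- if (0 %in% shared) match(0, shared) else 1L
    x <- x - x[i0]
    y <- y - y[i0]
  }
  fitLinear(x, y, throughOrigin = throughOrigin)
}

#' Evaluate a model beyond the observed dose range
#'
#' Evaluates an intensity-dose or relaxation model on an arbitrary grid,
#' flags the points beyond the observed maximum dose, and summarizes the
#' monotonicity of the extrapolated region ("increasing", "decreasing",
#' "none", or "not monotone"). The sigmoid's horizontal asymptote is what
#' makes the extrapolation meaningful: beyond it the intensity model is
#' dominated by `D (D - D0) fMin`.
#'
#' @param m an [IntensityDoseModel-class] or [RelaxationModel-class].
#' @param doseGrid numeric dose grid in kGy.
#' @param observedMaxDose numeric(1), largest dose actually measured.
#' @return `list(doses =, values =, extrapolated = logical flags,
#'   trend = character)`.
#' @export
extrapolateModel <- function(m, doseGrid, observedMaxDose) {
  .checkDose(doseGrid)
  vals <- modelEval(m, doseGrid)
  flags <- doseGrid > observedMaxDose
  trend <- "none"
  if (sum(flags) >= 2) {
    dv <- diff(vals[flags][order(doseGrid[flags])])
    trend <- if (all(dv <= 0)) "decreasing"
             else if (all(dv >= 0)) "increasing"
             else "not monotone"
  }
  list(doses = doseGrid, values = vals, extrapolated = flags, trend = trend)
}

#' Run the full dose-response analysis
#'
#' Dispatches each series to the model family named in the configuration
#' (`"intensity"`, `"relaxation"` or `"none"`), scans every series for
#' discrete extrema, computes the requested mutual correlations, and
#' assembles a deterministic [AnalysisReport-class]. Derived doses: the
#' optimized dose `D0` and sigmoid characteristic dose `delta = 1/alpha`
#' for intensity fits, the relaxation dose `DC` for relaxation fits;
#' doses from non-converged fits are flagged provisional.
#'
#' @param seriesBundle named list of [DoseSeries-class] objects.
#' @param config list with optional elements `models` (named character
#'   vector mapping series labels to families), `correlations` (list of
#'   `c(a, b)` label pairs), `deviation` (logical for the correlation
#'   form), `iInitFixed` (named numeric for intensity fits).
#' @return an [AnalysisReport-class].
#' @export
analyze <- function(seriesBundle, config = list()) {
  if (!length(seriesBundle)) stop("no series supplied", call. = FALSE)
  if (is.null(names(seriesBundle)))
    names(seriesBundle) <- vapply(seriesBundle, seriesLabel, character(1))
  models <- config$models
  fits <- list()
  derived <- data.frame(series = character(), quantity = character(),
                        dose_kGy = numeric(), provisional = logical(),
                        stringsAsFactors = FALSE)
  for (lab in names(seriesBundle)) {
    fam <- if (!is.null(models) && lab %in% names(models)) models[[lab]]
           else "none"
    s <- seriesBundle[[lab]]
    if (fam == "none") next
    res <- tryCatch(switch(fam,
      relaxation = fitRelaxation(doses(s), measurements(s)),
      intensity = fitIntensityDose(doses(s), measurements(s),
        iInitFixed = config$iInitFixed[[lab]]),
      stop("unknown model family '", fam, "' for series '", lab, "'",
           call. = FALSE)),
      error = function(e)
        stop("fit failed for series '", lab, "': ", conditionMessage(e),
             call. = FALSE))
    fits[[lab]] <- res
    prov <- !converged(res$fit)
    if (fam == "relaxation") {
      derived <- rbind(derived, data.frame(
        series = lab, quantity = "DC", dose_kGy = res$model@DC,
        provisional = prov))
    } else if (!is.null(res$model)) {
      derived <- rbind(derived, data.frame(
        series = rep(lab, 2), quantity = c("D0", "delta"),
        dose_kGy = c(as.numeric(findOptimizedDose(res$model)),
                     characteristicDose(res$model@sfp)),
        provisional = rep(prov, 2)))
    }
  }
  extrema <- lapply(seriesBundle, function(s) {
    e <- detectDiscreteExtrema(s)
    attr(e, "plateau") <- attr(e, "plateau")
    e
  })
  correlations <- list()
  for (pair in config$correlations) {
    key <- paste(pair[1], pair[2], sep = "~")
    correlations[[key]] <- mutualCorrelation(
      seriesBundle[[pair[1]]], seriesBundle[[pair[2]]],
      deviation = isTRUE(config$deviation))
  }
  extrapolations <- list()
  for (lab in names(fits)) {
    m <- fits[[lab]]$model
    if (is.null(m)) next
    dmax <- max(doses(seriesBundle[[lab]]))
    grid <- seq(0, 2 * dmax, length.out = 41)
    extrapolations[[lab]] <- extrapolateModel(m, grid, dmax)
  }
  new("AnalysisReport", fits = fits, derived = derived, extrema = extrema,
      correlations = correlations, extrapolations = extrapolations,
      config = config)
}

#' Serialize an analysis report
#'
#' Deterministic JSON rendering of an [AnalysisReport-class]: identical
#' inputs and configuration yield byte-identical output.
#'
#' @param report an [AnalysisReport-class].
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when written to a file.
#' @export
reportToJSON <- function(report, path = NULL) {
  stopifnot(is(report, "AnalysisReport"))
  payload <- list(
    fits = lapply(report@fits, function(f)
      list(model = if (is.null(f$model)) NULL else modelToRecord(f$model),
           fit = fitResultToRecord(f$fit))),
    derived = report@derived,
    extrema = lapply(report@extrema, function(e)
      list(points = e, plateau = isTRUE(attr(e, "plateau")))),
    correlations = lapply(report@correlations, function(cr)
      list(model = modelToRecord(cr$model), fit = fitResultToRecord(cr$fit))),
    extrapolations = report@extrapolations)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
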