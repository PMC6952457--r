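#' @include models.R
NULL

.modelUnits <- list(
  SpecificFunctionParams = c(fMax = "intensity/kGy^2", fMin = "intensity/kGy^2",
                             alpha = "1/kGy", Dc = "kGy"),
  IntensityDoseModel = c(iInit = "counts", D0 = "kGy"),
  RelaxationModel = c(y0 = "property", yInf = "property", DC = "kGy"),
  LinearLinkModel = c(slope = "response/predictor", intercept = "response",
                      xShift = "predictor"))

#' Serialize a model to a flat record
#'
#' Converts any model object to a JSON-compatible list
#' `list(model_type =, params =, units =)`, and back. Nested specific
#' function parameters of an intensity-dose model are flattened into the
#' parameter map.
#'
#' @param m a model object ([SpecificFunctionParams-class],
#'   [IntensityDoseModel-class], [RelaxationModel-class] or
#'   [LinearLinkModel-class]).
#' @return `modelToRecord()`: a named list; `modelFromRecord()`: the model
#'   object rebuilt from such a list.
#' @examples
#' rec <- modelToRecord(relaxationModel(6.98, 6.75, 73.4))
#' identical(modelFromRecord(rec)@DC, 73.4)
#' @export
modelToRecord <- function(m) {
  type <- class(m)[1]
  params <- switch(type,
    SpecificFunctionParams = list(fMax = m@fMax, fMin = m@fMin,
                                  alpha = m@alpha, Dc = m@Dc),
    IntensityDoseModel = list(iInit = m@iInit, D0 = m@D0,
                              fMax = m@sfp@fMax, fMin = m@sfp@fMin,
                              alpha = m@sfp@alpha, Dc = m@sfp@Dc),
    RelaxationModel = list(y0 = m@y0, yInf = m@yInf, DC = m@DC),
    LinearLinkModel = list(slope = m@slope, intercept = m@intercept,
                           xShift = m@xShift),
    stop("not a serializable model: ", type, call. = FALSE))
  units <- as.list(.modelUnits[[type]])
  if (type == "IntensityDoseModel")
    units <- c(units, as.list(.modelUnits$SpecificFunctionParams))
  list(model_type = type, params = params, units = units[names(params)])
}

#' @param record a list as produced by `modelToRecord()` (or parsed from its
#'   JSON form).
#' @rdname modelToRecord
#' @export
modelFromRecord <- function(record) {
  if (!is.list(record) || is.null(record$model_type) || is.null(record$params))
    stop("record must be a list with 'model_type' and 'params'", call. = FALSE)
  p <- lapply(record$params, as.numeric)
  switch(record$model_type,
    SpecificFunctionParams =
      specificFunctionParams(p$fMax, p$fMin, p$alpha, p$Dc),
    IntensityDoseModel =
      intensityDoseModel(p$iInit, p$D0,
        specificFunctionParams(p$fMax, p$fMin, p$alpha, p$Dc)),
    RelaxationModel = relaxationModel(p$y0, p$yInf, p$DC),
    LinearLinkModel = linearLinkModel(p$slope, p$intercept, p$xShift),
    stop("unknown model_type: ", record$model_type, call. = FALSE))
}

#' Serialize a FitResult to a JSON-compatible list
#'
#' @param fr a [FitResult-class] object.
#' @return a named list with parameter names, units, estimates, standard
#'   errors, goodness-of-fit `r`, convergence flag and iteration count.
#' @export
fitResultToRecord <- function(fr) {
  stopifnot(is(fr, "FitResult"))
  list(params = as.list(fr@params),
       stderr = as.list(fr@stderr),
       units = as.list(fr@units),
       r = fr@r, converged = fr@converged, n_iter = fr@nIter)
}
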