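#' @include AllGenerics.R
NULL

#' Evaluate a dose-response model on a dose grid
#'
#' Generic model evaluation: every model class in the package (specific
#' function, intensity-dose, relaxation, linear link) evaluates elementwise
#' over a numeric grid; the output has the same length as the input.
#'
#' @param object a model object.
#' @param x numeric vector of doses in kGy (or predictor values for a
#'   [LinearLinkModel-class]).
#' @param ... passed to methods (e.g. `variant` for the specific function).
#' @return numeric vector, same length as `x`.
#' @export
setGeneric("modelEval", function(object, x, ...) standardGeneric("modelEval"))

#' @rdname accessors
#' @export
setGeneric("dose", function(object) standardGeneric("dose"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setGeneric("seriesLabel", function(object) standardGeneric("seriesLabel"))

#' @rdname accessors
#' @export
setGeneric("seriesUnits", function(object) standardGeneric("seriesUnits"))

#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setGeneric("fitStderr", function(object) standardGeneric("fitStderr"))

#' @rdname accessors
#' @export
setGeneric("goodnessR", function(object) standardGeneric("goodnessR"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))
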