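#' @rdname PathwayCloud-class
#' @param x,object a \code{PathwayCloud} (or other object as documented).
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname PathwayCloud-class
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname RoleAnnotatedPathway-class
#' @param x a \code{RoleAnnotatedPathway} or \code{PathwayCloud}.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname PathwayCloud-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ExpressionStudy-class
#' @param x an \code{ExpressionStudy}.
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("youngSamples", function(x) standardGeneric("youngSamples"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("oldSamples", function(x) standardGeneric("oldSamples"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname DrugLibrary-class
#' @param x a \code{DrugLibrary}.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname DrugLibrary-class
#' @export
setGeneric("drugEffects", function(x) standardGeneric("drugEffects"))

#' @rdname DisturbanceReport-class
#' @param x a \code{DisturbanceReport}.
#' @export
setGeneric("pasMatrix", function(x) standardGeneric("pasMatrix"))

#' @rdname DisturbanceReport-class
#' @export
setGeneric("pasMean", function(x) standardGeneric("pasMean"))

#' @rdname DisturbanceReport-class
#' @export
setGeneric("disturbance", function(x) standardGeneric("disturbance"))

#' @rdname DisturbanceReport-class
#' @export
setGeneric("disturbanceMean", function(x) standardGeneric("disturbanceMean"))

#' @rdname DisturbanceReport-class
#' @export
setGeneric("skippedGenes", function(x) standardGeneric("skippedGenes"))
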