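#' @rdname PlatformMatrix-class
#' @param x,object a \linkS4class{PlatformMatrix}.
#' @export
setGeneric("platformType", function(x) standardGeneric("platformType"))

#' @rdname PlatformMatrix-class
#' @export
setGeneric("scaleType", function(x) standardGeneric("scaleType"))

#' @rdname PlatformMatrix-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname MappingResult-class
#' @param x a \linkS4class{MappingResult}.
#' @export
setGeneric("mappingEdges", function(x) standardGeneric("mappingEdges"))

#' @rdname MappingResult-class
#' @param side \code{"probe"} or \code{"gene"}.
#' @export
setGeneric("mappingGroups", function(x, side = c("probe", "gene"))
  standardGeneric("mappingGroups"))

#' @rdname TransferAssessment-class
#' @param x a \linkS4class{TransferAssessment}.
#' @export
setGeneric("pairedMetrics", function(x) standardGeneric("pairedMetrics"))

#' Extract the T-index of an assessment
#'
#' @param x a \linkS4class{TransferAssessment}.
#' @param clipped return the value clipped to [0, 1]?
#' @return numeric(1).
#' @export
setGeneric("transferIndex", function(x, clipped = FALSE)
  standardGeneric("transferIndex"))

#' @rdname ModelEnsemble-class
#' @param x a \linkS4class{ModelEnsemble}.
#' @export
setGeneric("ensembleRecords", function(x) standardGeneric("ensembleRecords"))
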