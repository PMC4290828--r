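# Accessors and show() methods for the package classes.

#' @rdname PlatformMatrix-class
#' @export
setMethod("platformType", "PlatformMatrix", function(x) x@platform)

#' @rdname PlatformMatrix-class
#' @export
setMethod("scaleType", "PlatformMatrix", function(x) x@scaleType)

#' @rdname PlatformMatrix-class
#' @export
setMethod("exprValues", "PlatformMatrix", function(x) assay(x, "expr"))

#' @rdname MappingResult-class
#' @export
setMethod("mappingEdges", "MappingResult", function(x) x@edges)

#' @rdname MappingResult-class
#' @export
setMethod("mappingGroups", "MappingResult",
  function(x, side = c("probe", "gene")) {
    side <- match.arg(side)
    if (side == "probe") x@probeGroup else x@geneGroup
  })

#' @rdname TransferAssessment-class
#' @export
setMethod("pairedMetrics", "TransferAssessment", function(x) x@metrics)

#' @rdname transferIndex
#' @export
setMethod("transferIndex", "TransferAssessment", function(x, clipped = FALSE) {
  if (clipped) x@tIndexClipped else x@tIndex
})

#' @rdname ModelEnsemble-class
#' @export
setMethod("ensembleRecords", "ModelEnsemble", function(x) x@records)

setMethod("show", "PlatformMatrix", function(object) {
  cat(sprintf("PlatformMatrix: %d features x %d samples [%s, %s]\n",
              nrow(object), ncol(object), object@platform, object@scaleType))
})

setMethod("show", "ProbeAnnotation", function(object) {
  nal <- sum(lengths(object@alignments) > 0)
  cat(sprintf("ProbeAnnotation: %d probe sets (%d with genome alignments)\n",
              length(object@probeIds), nal))
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d genes, %d exons total\n",
              length(object@geneIds), sum(lengths(object@exons))))
})

setMethod("show", "MappingResult", function(object) {
  pg <- table(factor(object@probeGroup, levels = .GROUPS))
  gg <- table(factor(object@geneGroup, levels = .GROUPS))
  cat(sprintf("MappingResult: %d edges\n", nrow(object@edges)))
  cat("  probe side:", paste(sprintf("%s=%d", names(pg), pg), collapse = " "),
      "\n")
  cat("  gene side: ", paste(sprintf("%s=%d", names(gg), gg), collapse = " "),
      "\n")
})

setMethod("show", "EndpointDefinition", function(object) {
  ntr <- sum(object@partition == "training")
  nva <- sum(object@partition == "validation")
  cat(sprintf("EndpointDefinition '%s' (%s): %d training / %d validation\n",
              object@name, object@kind, ntr, nva))
})

setMethod("show", "TrainedModel", function(object) {
  p <- paste(names(object@params),
             vapply(object@params, function(v) paste(format(v), collapse = "/"),
                    ""), sep = "=", collapse = ", ")
  cat(sprintf("TrainedModel [%s; %s]: %d-feature signature, %d training samples\n",
              object@algorithm, p, length(object@signature),
              length(object@trainSamples)))
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d %s models [endpoint %s, %s, group %s]\n",
              length(object@records), object@algorithm, object@endpoint,
              object@platform, object@group))
})

setMethod("show", "TransferAssessment", function(object) {
  cat(sprintf("TransferAssessment [%s level, %s, group %s, %s]\n",
              object@level, object@direction, object@group, object@algorithm))
  cat(sprintf("  %d model pairs; mean source acc %.3f, mean target acc %.3f\n",
              nrow(object@metrics), mean(object@metrics$source_acc),
              mean(object@metrics$target_acc)))
  cat(sprintf("  T-index %.3f (clipped %.3f); mean kappa %.3f\n",
              object@tIndex, object@tIndexClipped,
              mean(object@metrics$kappa)))
})

setMethod("show", "CoxModelResult", function(object) {
  cat(sprintf("CoxModelResult [%s]: %d genes; c(train)=%.3f c(valid)=%.3f (P=%.3g)\n",
              object@platform, length(object@signature), object@cTrain,
              object@cValid, object@pValid))
})
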