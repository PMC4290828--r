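#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
NULL

.PLATFORMS <- c("microarray", "rnaseq")
.SCALES <- c("log2_intensity", "log2_count", "zscore", "linear")
.GROUPS <- c("A", "B", "C", "D")

#' Expression matrix with platform and scale tags
#'
#' A features x samples expression container extending
#' \linkS4class{SummarizedExperiment}, tagged with the measurement platform
#' (\code{"microarray"} or \code{"rnaseq"}) and the scale state of the values
#' (\code{"log2_intensity"}, \code{"log2_count"}, \code{"zscore"} or
#' \code{"linear"}). Missing values are refused: imputation is out of scope.
#'
#' @slot platform character(1), one of \code{"microarray"}, \code{"rnaseq"}.
#' @slot scaleType character(1), the scale state of the stored values.
#'
#' @seealso [PlatformMatrix()] for construction, [exprValues()],
#'   [platformType()], [scaleType()].
#' @export
setClass("PlatformMatrix",
  contains = "SummarizedExperiment",
  representation(platform = "character", scaleType = "character")
)

setValidity("PlatformMatrix", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || !object@platform %in% .PLATFORMS)
    msg <- c(msg, sprintf("platform must be one of: %s",
                          paste(.PLATFORMS, collapse = ", ")))
  if (length(object@scaleType) != 1L || !object@scaleType %in% .SCALES)
    msg <- c(msg, sprintf("scale must be one of: %s",
                          paste(.SCALES, collapse = ", ")))
  v <- assay(object)
  if (anyNA(v))
    msg <- c(msg, "expression values contain NA; imputation is not supported")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "feature and sample identifiers are required")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated feature ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' Probe/probe-set annotation table
#'
#' Parsed platform annotation for an array: per probe set, the public gene
#' identifiers it is annotated with (gene symbols, RefSeq transcript IDs,
#' Ensembl gene IDs, Entrez gene IDs) and its genome alignments. ID sets may
#' be empty; a probe may carry zero alignments.
#'
#' @slot probeIds character vector of unique probe-set identifiers.
#' @slot geneSymbols,refseqIds,ensemblIds,entrezIds
#'   \linkS4class{CharacterList} parallel to \code{probeIds}.
#' @slot alignments \linkS4class{GRangesList} parallel to \code{probeIds};
#'   elements may be empty.
#' @export
setClass("ProbeAnnotation",
  representation(
    probeIds = "character",
    geneSymbols = "CharacterList",
    refseqIds = "CharacterList",
    ensemblIds = "CharacterList",
    entrezIds = "CharacterList",
    alignments = "GRangesList"
  )
)

setValidity("ProbeAnnotation", function(object) {
  n <- length(object@probeIds)
  msg <- character()
  if (anyDuplicated(object@probeIds)) msg <- c(msg, "probe ids must be unique")
  for (sl in c("geneSymbols", "refseqIds", "ensemblIds", "entrezIds",
               "alignments"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, sprintf("slot %s length != number of probes", sl))
  if (length(msg)) msg else TRUE
})

#' RNA-seq gene model set
#'
#' Genes with their public identifiers and exon structures, as parsed from a
#' GTF/GFF gene-model file or constructed from a plain gene-ID list (in which
#' case exon lists are empty and only ID mapping is possible).
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot publicIds \linkS4class{CharacterList} of public IDs
#'   (symbol/RefSeq/Ensembl/Entrez), parallel to \code{geneIds}; may be empty.
#' @slot exons \linkS4class{GRangesList} of exon intervals per gene.
#' @export
setClass("GeneModels",
  representation(
    geneIds = "character",
    publicIds = "CharacterList",
    exons = "GRangesList"
  )
)

setValidity("GeneModels", function(object) {
  msg <- character()
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique")
  if (length(object@publicIds) != length(object@geneIds) ||
      length(object@exons) != length(object@geneIds))
    msg <- c(msg, "publicIds and exons must be parallel to geneIds")
  if (length(msg)) msg else TRUE
})

#' Probe-to-gene mapping with A/B/C/D group labels
#'
#' The bipartite probe/gene mapping graph plus the mapping-complexity group
#' of every feature on both sides. Groups partition each side: A one-to-one,
#' B maps to a single counterpart that itself maps back to several features,
#' C maps to several counterparts, D unmapped.
#'
#' @slot edges data.frame with columns \code{probe_id}, \code{gene_id},
#'   \code{evidence} (\code{"id"} or \code{"location"}), \code{id_type},
#'   \code{overlap_bp}, \code{n_exons_hit}; one row per deduplicated edge.
#' @slot probeGroup,geneGroup named character vectors over the full feature
#'   universe on each side, values in \code{A,B,C,D}.
#' @slot params list of the location-mapping parameters used (may be empty
#'   for ID mapping).
#' @export
setClass("MappingResult",
  representation(
    edges = "data.frame",
    probeGroup = "character",
    geneGroup = "character",
    params = "list"
  )
)

setValidity("MappingResult", function(object) {
  msg <- character()
  need <- c("probe_id", "gene_id", "evidence", "id_type", "overlap_bp",
            "n_exons_hit")
  if (!all(need %in% colnames(object@edges)))
    msg <- c(msg, "edges must have columns probe_id/gene_id/evidence/id_type/overlap_bp/n_exons_hit")
  if (!all(object@probeGroup %in% .GROUPS) ||
      !all(object@geneGroup %in% .GROUPS))
    msg <- c(msg, "group labels must be in A/B/C/D")
  if (is.null(names(object@probeGroup)) || is.null(names(object@geneGroup)))
    msg <- c(msg, "group vectors must be named by feature id")
  if (length(msg)) msg else TRUE
})

#' Clinical endpoint with predefined train/validation partition
#'
#' A binary class label or a right-censored survival outcome per sample,
#' together with the predefined assignment of each sample to the training or
#' the validation set.
#'
#' @slot name endpoint name.
#' @slot kind \code{"binary"} or \code{"survival"}.
#' @slot labels named numeric 0/1 vector (binary endpoints; empty otherwise).
#' @slot time,event named numeric vectors (survival endpoints; empty
#'   otherwise), \code{time > 0}, \code{event} in 0/1.
#' @slot partition named character vector, \code{"training"} or
#'   \code{"validation"} per sample, covering all samples of the endpoint.
#' @export
setClass("EndpointDefinition",
  representation(
    name = "character",
    kind = "character",
    labels = "numeric",
    time = "numeric",
    event = "numeric",
    partition = "character"
  )
)

setValidity("EndpointDefinition", function(object) {
  msg <- character()
  if (!object@kind %in% c("binary", "survival"))
    msg <- c(msg, "kind must be 'binary' or 'survival'")
  if (!all(object@partition %in% c("training", "validation")))
    msg <- c(msg, "partition values must be 'training' or 'validation'")
  if (object@kind == "binary") {
    if (!all(object@labels %in% c(0, 1)))
      msg <- c(msg, "binary labels must be 0/1")
    tr <- names(object@partition)[object@partition == "training"]
    if (length(tr) && length(unique(object@labels[tr])) < 2)
      msg <- c(msg, "both classes must be present in the training set")
  } else {
    if (any(object@time <= 0)) msg <- c(msg, "survival times must be positive")
    if (!all(object@event %in% c(0, 1))) msg <- c(msg, "events must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' A fitted classification model
#'
#' One fitted classifier: the algorithm, its hyper-parameters, the ordered
#' signature (feature ids) it consumes, the fitted state, and the identifiers
#' of the samples it was fitted on.
#'
#' @slot algorithm \code{"knn"}, \code{"nsc"} or \code{"svm"}.
#' @slot params named list of hyper-parameters (\code{k}; \code{delta};
#'   \code{cost}, \code{kernel}).
#' @slot signature ordered character vector of feature ids (non-empty).
#' @slot fit algorithm-specific fitted state.
#' @slot trainSamples sample ids used for fitting.
#' @slot platform,scale tags of the training data.
#' @export
setClass("TrainedModel",
  representation(
    algorithm = "character",
    params = "list",
    signature = "character",
    fit = "list",
    trainSamples = "character",
    platform = "character",
    scale = "character"
  )
)

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("knn", "nsc", "svm"))
    msg <- c(msg, "algorithm must be knn/nsc/svm")
  if (length(object@signature) == 0)
    msg <- c(msg, "signature must be non-empty")
  if (length(msg)) msg else TRUE
})

#' An ensemble of models from the resampling protocol
#'
#' The result of the stratified-resampling training protocol: one record per
#' 70/30 split, each holding the selected signature/parameters, the holdout
#' accuracy that selected them, and the model refitted on the full training
#' set.
#'
#' @slot endpoint,platform,group,algorithm ensemble provenance tags.
#' @slot records list of per-split records (fields \code{split_seed},
#'   \code{params}, \code{signature}, \code{holdout_acc}, \code{model}).
#' @export
setClass("ModelEnsemble",
  representation(
    endpoint = "character",
    platform = "character",
    group = "character",
    algorithm = "character",
    records = "list"
  )
)

#' A transferability assessment
#'
#' Paired per-model metrics from one transfer procedure (signature level or
#' model level, in one direction), with the per-pair kappa values, the
#' T-index and bootstrap confidence intervals.
#'
#' @slot direction \code{"array2rnaseq"} or \code{"rnaseq2array"}.
#' @slot level \code{"signature"} or \code{"model"}.
#' @slot group,endpoint,algorithm,dataForm provenance tags.
#' @slot metrics data.frame, one row per model pair: \code{source_acc},
#'   \code{target_acc}, \code{source_auc}, \code{target_auc}, \code{kappa}.
#' @slot tIndex unclipped T-index; \code{tIndexClipped} its [0,1] companion.
#' @slot summary list of ensemble means and 95% bootstrap CIs.
#' @export
setClass("TransferAssessment",
  representation(
    direction = "character",
    level = "character",
    group = "character",
    endpoint = "character",
    algorithm = "character",
    dataForm = "character",
    metrics = "data.frame",
    tIndex = "numeric",
    tIndexClipped = "numeric",
    summary = "list"
  )
)

#' A fitted Cox survival model with its evaluation
#'
#' @slot signature selected feature ids.
#' @slot coefficients named log-hazard coefficients.
#' @slot cTrain training concordance index.
#' @slot cValid,pValid validation concordance index and its p-value against
#'   0.5.
#' @slot platform platform tag.
#' @export
setClass("CoxModelResult",
  representation(
    signature = "character",
    coefficients = "numeric",
    cTrain = "numeric",
    cValid = "numeric",
    pValid = "numeric",
    platform = "character"
  )
)
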