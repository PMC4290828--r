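# Full factorial study-design enumeration and end-to-end process execution.

#' Define a transferability study design
#'
#' The factorial axes of the two assessment levels. Signature level crosses
#' mapping groups x binary endpoints x algorithms x directions (each
#' process trains n_splits models and builds n_splits transferred
#' counterparts) plus groups x survival endpoints x directions Cox
#' processes (two models each). Model level additionally crosses the two
#' data forms, excludes group C, and trains n_splits models per binary
#' process (one per Cox process).
#'
#' @param sigGroups,sigBinaryEndpoints,sigAlgorithms,sigDirections,
#'   sigSurvivalEndpoints signature-level axes.
#' @param modGroups,modBinaryEndpoints,modAlgorithms,modDirections,
#'   modDataForms,modSurvivalEndpoints model-level axes.
#' @param nSplits resampling splits per binary process (>= 1).
#' @return a validated design list.
#' @export
studyDesign <- function(sigGroups = c("A", "B", "C"),
                        sigBinaryEndpoints = character(),
                        sigAlgorithms = c("knn", "nsc", "svm"),
                        sigDirections = c("array2rnaseq", "rnaseq2array"),
                        sigSurvivalEndpoints = character(),
                        modGroups = c("A", "B"),
                        modBinaryEndpoints = sigBinaryEndpoints,
                        modAlgorithms = sigAlgorithms,
                        modDirections = sigDirections,
                        modDataForms = c("zscored", "raw_log2"),
                        modSurvivalEndpoints = sigSurvivalEndpoints,
                        nSplits = 500) {
  if (nSplits < 1) stop("nSplits must be >= 1")
  if ("C" %in% modGroups)
    stop("group C is excluded from model-level assessment")
  as.list(environment())
}

#' The published study's design
#'
#' Three mapping groups, eight binary endpoints, three algorithms, two
#' directions and six survival endpoints at the signature level; two
#' groups and two data forms at the model level; 500 splits.
#'
#' @return a [studyDesign()].
#' @export
referenceStudyDesign <- function() {
  studyDesign(
    sigBinaryEndpoints = c("A_EFS_All", "B_OS_All", "C_SEX_All",
                           "D_FAV_All", "E_EFS_HR", "F_OS_HR",
                           "AML_Sex", "AML_CytoRisk"),
    sigSurvivalEndpoints = c("A_EFS_All_t", "B_OS_All_t", "E_EFS_HR_t",
                             "F_OS_HR_t", "AML_EFS_t", "AML_OS_t"),
    nSplits = 500)
}

#' Enumerate the process plan of a study design
#'
#' Expands the factorial axes into one descriptor per process and computes
#' the expected model counts: signature-level binary processes contribute
#' 2 x nSplits models (trained + transferred) and Cox processes 2; model-
#' level binary processes contribute nSplits models and Cox processes 1.
#'
#' @param design a [studyDesign()].
#' @return list: \code{processes} (data.frame of descriptors with
#'   \code{n_models}), \code{nSignatureProcesses},
#'   \code{nModelProcesses}, \code{nSignatureModels},
#'   \code{nModelModels}, \code{nTotalModels}.
#' @export
enumeratePlan <- function(design) {
  if (design$nSplits < 1) stop("nSplits must be >= 1")
  sigBin <- expand.grid(level = "signature", group = design$sigGroups,
                        endpoint = design$sigBinaryEndpoints,
                        algorithm = design$sigAlgorithms,
                        direction = design$sigDirections,
                        data_form = "raw_log2",
                        stringsAsFactors = FALSE)
  sigCox <- expand.grid(level = "signature", group = design$sigGroups,
                        endpoint = design$sigSurvivalEndpoints,
                        algorithm = "cox", direction = design$sigDirections,
                        data_form = "raw_log2", stringsAsFactors = FALSE)
  modBin <- expand.grid(level = "model", group = design$modGroups,
                        endpoint = design$modBinaryEndpoints,
                        algorithm = design$modAlgorithms,
                        direction = design$modDirections,
                        data_form = design$modDataForms,
                        stringsAsFactors = FALSE)
  modCox <- expand.grid(level = "model", group = design$modGroups,
                        endpoint = design$modSurvivalEndpoints,
                        algorithm = "cox", direction = design$modDirections,
                        data_form = "zscored", stringsAsFactors = FALSE)
  proc <- rbind(sigBin, sigCox, modBin, modCox)
  proc$n_models <- ifelse(proc$level == "signature",
                          ifelse(proc$algorithm == "cox", 2,
                                 2 * design$nSplits),
                          ifelse(proc$algorithm == "cox", 1,
                                 design$nSplits))
  nSigP <- nrow(sigBin) + nrow(sigCox)
  nModP <- nrow(modBin) + nrow(modCox)
  nSigM <- sum(proc$n_models[proc$level == "signature"])
  nModM <- sum(proc$n_models[proc$level == "model"])
  list(processes = proc,
       nSignatureProcesses = nSigP, nModelProcesses = nModP,
       nSignatureModels = nSigM, nModelModels = nModM,
       nTotalModels = nSigM + nModM)
}

# z-scored train/validation views of a study bundle, restricted to a group
.processMatrices <- function(bundle, descriptor, zscore) {
  srcIsArray <- descriptor$direction == "array2rnaseq"
  src <- if (srcIsArray) bundle$array else bundle$rnaseq
  tgt <- if (srcIsArray) bundle$rnaseq else bundle$array
  ep <- if (descriptor$algorithm == "cox") bundle$survival else bundle$binary
  # each side is restricted to its own side's group
  srcG <- subsetByGroup(src, bundle$mapping, descriptor$group)
  tgtGroup <- descriptor$group
  # the counterpart features live in the mirrored gene-side group
  mirror <- c(A = "A", B = "C", C = "B")
  tgtG <- subsetByGroup(tgt, bundle$mapping,
                        if (srcIsArray) mirror[[tgtGroup]] else
                          names(mirror)[match(tgtGroup, mirror)])
  if (zscore) {
    srcG <- perSampleZscore(srcG)
    tgtG <- perSampleZscore(tgtG)
  }
  pick <- function(m, ids) PlatformMatrix(
    exprValues(m)[, intersect(ids, colnames(exprValues(m))), drop = FALSE],
    platformType(m), scaleType(m))
  tr <- partitionSamples(ep, "training")
  va <- partitionSamples(ep, "validation")
  list(endpoint = ep,
       sourceTrain = pick(srcG, tr), sourceValid = pick(srcG, va),
       targetTrain = pick(tgtG, tr), targetValid = pick(tgtG, va))
}

#' Run one assessment process end-to-end
#'
#' Dispatches a plan descriptor to the signature-level, model-level or Cox
#' machinery on a synthetic (or user-assembled) study bundle, and
#' optionally writes the report files. Deterministic per (descriptor,
#' seed).
#'
#' @param descriptor one row of the plan's \code{processes} data.frame (or
#'   an equivalent named list).
#' @param bundle a study bundle as returned by [generateStudy()].
#' @param nSplits resampling splits for binary processes.
#' @param seed RNG seed.
#' @param outDir optional output directory for report files.
#' @param ... forwarded to [trainEnsemble()] (e.g. \code{maxFeatures},
#'   \code{paramGrid}).
#' @return a \linkS4class{TransferAssessment} (binary) or the
#'   [coxTransfer()] result list.
#' @export
runProcess <- function(descriptor, bundle, nSplits = 50, seed = 1,
                       outDir = NULL, ...) {
  descriptor <- as.list(descriptor)
  isCox <- descriptor$algorithm == "cox"
  zscore <- descriptor$level == "model" &&
    identical(descriptor$data_form, "zscored")
  mats <- .processMatrices(bundle, descriptor, zscore = zscore || isCox)
  if (isCox) {
    res <- coxTransfer(descriptor$level,
                       mats$sourceTrain, mats$sourceValid,
                       mats$targetTrain, mats$targetValid,
                       mats$endpoint, bundle$mapping,
                       direction = descriptor$direction,
                       group = descriptor$group)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(list(
        level = descriptor$level, direction = descriptor$direction,
        group = descriptor$group,
        signature = res$source@signature,
        coefficients = as.list(res$source@coefficients),
        c_source = res$source@cValid, p_source = res$source@pValid,
        c_target = res$target@cValid, p_target = res$target@pValid,
        p_source_gt_target = res$comparison$p),
        file.path(outDir, "cox_result.json"), auto_unbox = TRUE,
        digits = NA)
    }
    return(res)
  }
  ens <- trainEnsemble(mats$sourceTrain, mats$endpoint,
                       descriptor$algorithm, group = descriptor$group,
                       nSplits = nSplits, masterSeed = seed, ...)
  res <- if (descriptor$level == "signature") {
    signatureLevelAssessment(ens, mats$sourceValid, mats$targetTrain,
                             mats$targetValid, mats$endpoint,
                             bundle$mapping,
                             direction = descriptor$direction, seed = seed)
  } else {
    modelLevelAssessment(ens, mats$sourceValid, mats$targetValid,
                         mats$endpoint, bundle$mapping,
                         direction = descriptor$direction,
                         dataForm = descriptor$data_form, seed = seed)
  }
  if (!is.null(outDir)) writeAssessment(res, outDir)
  res
}

#' Summarize completed assessments
#'
#' One row per completed process: mean source/target accuracy and AUC,
#' mean kappa with its band, T-index, and a degradation flag raised when
#' the mean target accuracy falls more than \code{dropThreshold} below the
#' mean source accuracy.
#'
#' @param assessments list of \linkS4class{TransferAssessment} objects.
#' @param dropThreshold accuracy-drop threshold for the degradation flag
#'   (default 0.05).
#' @return data.frame summary table.
#' @export
summarizeReport <- function(assessments, dropThreshold = 0.05) {
  stopifnot(length(assessments) >= 1)
  rows <- lapply(assessments, function(a) {
    s <- a@summary
    data.frame(level = a@level, direction = a@direction, group = a@group,
               endpoint = a@endpoint, algorithm = a@algorithm,
               data_form = a@dataForm,
               n_pairs = nrow(a@metrics),
               source_acc = s$meanSourceAcc, target_acc = s$meanTargetAcc,
               source_auc = s$meanSourceAuc, target_auc = s$meanTargetAuc,
               kappa = s$meanKappa, kappa_band = s$kappaBand,
               t_index = a@tIndex,
               degraded = s$meanTargetAcc < s$meanSourceAcc - dropThreshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
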