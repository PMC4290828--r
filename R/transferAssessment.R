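# The two transfer procedures: signature-level (carry signature +
# parameters, refit on the other platform) and model-level (apply the
# fitted model unchanged to counterpart features), in both directions.

.sourceSide <- function(direction) {
  if (direction == "array2rnaseq") "probe" else "gene"
}

# counterpart candidates of one source feature, as a character vector
.counterparts <- function(edges, feature, side) {
  if (side == "probe") edges$gene_id[edges$probe_id == feature]
  else edges$probe_id[edges$gene_id == feature]
}

#' Resolve a signature onto the other platform
#'
#' Maps each source feature to one target feature. Degree-1 features
#' (groups A and source-side B) map to their unique counterpart; degree >1
#' features (source-side C) map to the single counterpart chosen by
#' \code{policy} (default: the candidate with the highest mean expression
#' in the target training matrix, ties broken lexicographically by id).
#' Output preserves the source order and length; repeated counterparts are
#' permitted. A group-D feature in the signature is a hard error.
#'
#' @param signature ordered source feature ids.
#' @param mapping a \linkS4class{MappingResult}.
#' @param direction \code{"array2rnaseq"} or \code{"rnaseq2array"}.
#' @param targetTrain target-platform training \linkS4class{PlatformMatrix}
#'   (used by the expression policy).
#' @param policy \code{"highest_mean"} or \code{"first_id"}
#'   (lexicographically first candidate).
#' @return character vector of target feature ids, same length/order.
#' @export
resolveSignature <- function(signature, mapping,
                             direction = c("array2rnaseq", "rnaseq2array"),
                             targetTrain = NULL,
                             policy = c("highest_mean", "first_id")) {
  direction <- match.arg(direction)
  policy <- match.arg(policy)
  side <- .sourceSide(direction)
  groups <- mappingGroups(mapping, side)
  unknown <- setdiff(signature, names(groups))
  if (length(unknown))
    stop("signature feature(s) absent from mapping: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (any(groups[signature] == "D"))
    stop("signature contains unmapped (group D) feature(s)")
  edges <- mappingEdges(mapping)
  tmeans <- NULL
  if (policy == "highest_mean") {
    if (is.null(targetTrain))
      stop("policy 'highest_mean' requires the target training matrix")
    tv <- exprValues(targetTrain)
    tmeans <- rowMeans(tv)
  }
  vapply(signature, function(f) {
    cand <- sort(unique(.counterparts(edges, f, side)))
    if (length(cand) == 1) return(cand)
    if (policy == "first_id") return(cand[1])
    mu <- tmeans[cand]
    mu[is.na(mu)] <- -Inf
    cand[order(-mu, cand)][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Build the untrained counterpart of a trained model
#'
#' Refits the same algorithm with the SAME hyper-parameters on all target-
#' platform training samples, using the resolved signature; no re-selection
#' of features or parameters takes place. This is the "untrained model" of
#' the signature-level transfer.
#'
#' @param record one ensemble record (fields \code{params},
#'   \code{signature}).
#' @param targetTrain target-platform training \linkS4class{PlatformMatrix}.
#' @param endpoint the binary \linkS4class{EndpointDefinition}.
#' @param mapping a \linkS4class{MappingResult}.
#' @param direction transfer direction.
#' @param policy counterpart policy for ambiguous features.
#' @return a \linkS4class{TrainedModel} on the target platform.
#' @export
buildUntrainedCounterpart <- function(record, targetTrain, endpoint, mapping,
                                      direction = c("array2rnaseq",
                                                    "rnaseq2array"),
                                      policy = "highest_mean") {
  direction <- match.arg(direction)
  resolved <- resolveSignature(record$signature, mapping, direction,
                               targetTrain = targetTrain, policy = policy)
  trIds <- intersect(partitionSamples(endpoint, "training"),
                     colnames(exprValues(targetTrain)))
  y <- endpoint@labels[trIds]
  v <- exprValues(targetTrain)[, trIds, drop = FALSE]
  # repeated counterparts keep the model's input dimensionality
  vSig <- v[resolved, , drop = FALSE]
  rownames(vSig) <- make.unique(resolved)
  m <- fitClassifier(record$model@algorithm, record$params, vSig, y,
                     signature = rownames(vSig))
  m@platform <- platformType(targetTrain)
  m@scale <- scaleType(targetTrain)
  m@fit$resolved <- resolved  # raw target ids, order-parallel to signature
  m
}

.assembleAssessment <- function(direction, level, group, endpoint, algorithm,
                                dataForm, srcAcc, tgtAcc, srcAuc, tgtAuc,
                                kappas, seed) {
  metrics <- data.frame(source_acc = srcAcc, target_acc = tgtAcc,
                        source_auc = srcAuc, target_auc = tgtAuc,
                        kappa = kappas)
  ti <- tIndex(srcAcc, tgtAcc)
  summ <- list(
    meanSourceAcc = mean(srcAcc), meanTargetAcc = mean(tgtAcc),
    meanSourceAuc = mean(srcAuc), meanTargetAuc = mean(tgtAuc),
    meanKappa = mean(kappas),
    ciSourceAcc = bootstrapCI(srcAcc, seed = deriveSeed(seed, 11)),
    ciTargetAcc = bootstrapCI(tgtAcc, seed = deriveSeed(seed, 12)),
    ciKappa = bootstrapCI(kappas, seed = deriveSeed(seed, 13)),
    kappaBand = kappaBand(mean(kappas)))
  new("TransferAssessment", direction = direction, level = level,
      group = group, endpoint = endpoint, algorithm = algorithm,
      dataForm = dataForm, metrics = metrics, tIndex = ti$t,
      tIndexClipped = ti$tClipped, summary = summ)
}

#' Signature-level transferability assessment
#'
#' For each model of the source-platform ensemble: evaluate it on the
#' source validation samples, build its untrained counterpart on the target
#' platform ([buildUntrainedCounterpart()]), evaluate the counterpart on
#' the target validation samples, and assemble paired metrics, the
#' per-pair kappa of the two validation prediction vectors, and the T-index
#' over the paired accuracies. Both matrices are on the log2 scale; the
#' counterpart is recalibrated by refitting, so no z-scoring is required at
#' this level.
#'
#' @param ensemble source \linkS4class{ModelEnsemble}.
#' @param sourceValid source-platform validation
#'   \linkS4class{PlatformMatrix}.
#' @param targetTrain,targetValid target-platform training and validation
#'   matrices.
#' @param endpoint the binary \linkS4class{EndpointDefinition}.
#' @param mapping a \linkS4class{MappingResult}.
#' @param direction transfer direction (source platform first).
#' @param policy counterpart policy for ambiguous (group C) features.
#' @param seed seed for bootstrap CIs.
#' @return a \linkS4class{TransferAssessment}.
#' @export
signatureLevelAssessment <- function(ensemble, sourceValid, targetTrain,
                                     targetValid, endpoint, mapping,
                                     direction = c("array2rnaseq",
                                                   "rnaseq2array"),
                                     policy = "highest_mean", seed = 1) {
  direction <- match.arg(direction)
  recs <- ensemble@records
  svIds <- intersect(partitionSamples(endpoint, "validation"),
                     colnames(exprValues(sourceValid)))
  tvIds <- intersect(partitionSamples(endpoint, "validation"),
                     colnames(exprValues(targetValid)))
  ySrc <- endpoint@labels[svIds]
  yTgt <- endpoint@labels[tvIds]
  sv <- exprValues(sourceValid)[, svIds, drop = FALSE]
  tv <- exprValues(targetValid)[, tvIds, drop = FALSE]
  n <- length(recs)
  srcAcc <- tgtAcc <- srcAuc <- tgtAuc <- kap <- numeric(n)
  for (i in seq_len(n)) {
    prS <- predictWithScores(recs[[i]]$model, sv)
    cp <- buildUntrainedCounterpart(recs[[i]], targetTrain, endpoint,
                                    mapping, direction, policy)
    tvSig <- tv[cp@fit$resolved, , drop = FALSE]
    rownames(tvSig) <- cp@signature
    prT <- predictWithScores(cp, tvSig)
    srcAcc[i] <- binaryAccuracy(prS$label, ySrc)
    tgtAcc[i] <- binaryAccuracy(prT$label, yTgt)
    srcAuc[i] <- aucScore(prS$score, ySrc)
    tgtAuc[i] <- aucScore(prT$score, yTgt)
    shared <- intersect(svIds, tvIds)
    kap[i] <- cohenKappa(prS$label[match(shared, svIds)],
                         prT$label[match(shared, tvIds)])
  }
  .assembleAssessment(direction, "signature", ensemble@group,
                      endpoint@name, ensemble@algorithm, "raw_log2",
                      srcAcc, tgtAcc, srcAuc, tgtAuc, kap, seed)
}

#' Model-level transferability assessment
#'
#' Each source model predicts BOTH validation sets with its fitted state
#' untouched: the target validation matrix is assembled by substituting
#' each model feature with its unique counterpart's values (z-scored when
#' \code{dataForm = "zscored"}). Only mapping groups A and B are eligible;
#' group C is rejected because its ambiguous mapping relationships are not
#' suitable for cross-platform prediction. The raw log2 form is permitted
#' for the no-transform comparison experiment, with a warning.
#'
#' @param ensemble source \linkS4class{ModelEnsemble} (trained on z-scored
#'   data for \code{dataForm = "zscored"}).
#' @param sourceValid,targetValid validation matrices on the two platforms,
#'   on the scale matching \code{dataForm}.
#' @param endpoint the binary \linkS4class{EndpointDefinition}.
#' @param mapping a \linkS4class{MappingResult}.
#' @param direction transfer direction (source platform first).
#' @param dataForm \code{"zscored"} or \code{"raw_log2"}.
#' @param seed seed for bootstrap CIs.
#' @return a \linkS4class{TransferAssessment}.
#' @export
modelLevelAssessment <- function(ensemble, sourceValid, targetValid,
                                 endpoint, mapping,
                                 direction = c("array2rnaseq",
                                               "rnaseq2array"),
                                 dataForm = c("zscored", "raw_log2"),
                                 seed = 1) {
  direction <- match.arg(direction)
  dataForm <- match.arg(dataForm)
  if (ensemble@group == "C")
    stop("group C has ambiguous mapping relationships and is not ",
         "suitable for cross-platform model-level prediction")
  if (dataForm == "raw_log2")
    warning("model-level assessment without z-scoring: cross-platform ",
            "accuracies are expected to collapse")
  side <- .sourceSide(direction)
  edges <- mappingEdges(mapping)
  svIds <- intersect(partitionSamples(endpoint, "validation"),
                     colnames(exprValues(sourceValid)))
  tvIds <- intersect(partitionSamples(endpoint, "validation"),
                     colnames(exprValues(targetValid)))
  ySrc <- endpoint@labels[svIds]
  yTgt <- endpoint@labels[tvIds]
  sv <- exprValues(sourceValid)[, svIds, drop = FALSE]
  tv <- exprValues(targetValid)[, tvIds, drop = FALSE]
  recs <- ensemble@records
  n <- length(recs)
  srcAcc <- tgtAcc <- srcAuc <- tgtAuc <- kap <- numeric(n)
  for (i in seq_len(n)) {
    model <- recs[[i]]$model
    sig <- model@signature
    counterpart <- vapply(sig, function(f) {
      cand <- unique(.counterparts(edges, f, side))
      if (length(cand) != 1)
        stop("model feature ", f, " lacks a unique counterpart")
      cand
    }, character(1), USE.NAMES = FALSE)
    tvSig <- tv[counterpart, , drop = FALSE]
    rownames(tvSig) <- sig
    prS <- predictWithScores(model, sv)
    prT <- predictWithScores(model, tvSig)
    srcAcc[i] <- binaryAccuracy(prS$label, ySrc)
    tgtAcc[i] <- binaryAccuracy(prT$label, yTgt)
    srcAuc[i] <- aucScore(prS$score, ySrc)
    tgtAuc[i] <- aucScore(prT$score, yTgt)
    shared <- intersect(svIds, tvIds)
    kap[i] <- cohenKappa(prS$label[match(shared, svIds)],
                         prT$label[match(shared, tvIds)])
  }
  .assembleAssessment(direction, "model", ensemble@group, endpoint@name,
                      ensemble@algorithm, dataForm,
                      srcAcc, tgtAcc, srcAuc, tgtAuc, kap, seed)
}

#' Write an assessment report
#'
#' One TSV row per model pair plus a JSON summary (means, CIs, T-index).
#'
#' @param assessment a \linkS4class{TransferAssessment}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeAssessment <- function(assessment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(assessment@metrics, file.path(dir, "model_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- c(list(direction = assessment@direction, level = assessment@level,
                 group = assessment@group, endpoint = assessment@endpoint,
                 algorithm = assessment@algorithm,
                 data_form = assessment@dataForm,
                 t_index = assessment@tIndex,
                 t_index_clipped = assessment@tIndexClipped),
            assessment@summary)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
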