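# Cox survival workflow: median-intensity filter, concordance-index gene
# ranking, LOOCV one-step forward selection, final fit, concordance-index
# evaluation with significance, and both transfer levels.
#
# The partial-likelihood fit is delegated to survival::coxph (Efron ties);
# Harrell's c-index, its normal-approximation p-value and the paired
# comparison are implemented here.

#' Median-intensity feature filter
#'
#' Keeps the features whose median across the training samples is strictly
#' greater than the global median of all values in the training matrix.
#'
#' @param X features x samples matrix or \linkS4class{PlatformMatrix}
#'   (training samples only).
#' @return character vector of retained feature ids (possibly empty).
#' @export
medianIntensityFilter <- function(X) {
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  stopifnot(nrow(v) >= 1)
  med <- apply(v, 1, stats::median)
  rownames(v)[med > stats::median(v)]
}

# Pairwise Harrell score matrix machinery. For usable pairs (the member
# with the earlier time has event = 1, times distinct), score 1 if risks
# are concordant with failure order, 0.5 on risk ties, 0 otherwise.
.cindexParts <- function(risk, time, event) {
  n <- length(risk)
  dt <- outer(time, time, "-")       # dt[i,j] = t_i - t_j
  early <- dt < 0 & event == 1       # [i,j]: i fails first, with an event
  dr <- outer(risk, risk, "-")
  sc <- matrix(0, n, n)
  sc[early & dr > 0] <- 1
  sc[early & dr == 0] <- 0.5
  list(score = sc + t(sc), usable = early | t(early))
}

#' Harrell's concordance index with a p-value against 0.5
#'
#' The probability that, of a usable sample pair, the member with the
#' higher predicted risk fails first (ties in risk count 1/2); 0.5 random,
#' 1 perfect, 0 anti-perfect. The p-value is a two-sided normal
#' approximation for c = 0.5 with a leave-one-out jackknife standard
#' error.
#'
#' @param risk numeric risk scores (higher = earlier failure expected).
#' @param time positive survival/censoring times.
#' @param event 0/1 event indicators.
#' @return list: \code{c}, \code{p}, \code{se}, \code{nPairs}.
#' @export
concordanceIndex <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  parts <- .cindexParts(risk, time, event)
  M <- sum(parts$usable) / 2
  if (M < 1) stop("zero usable pairs for the concordance index")
  S <- sum(parts$score) / 2
  cidx <- S / M
  # jackknife over samples from row totals
  si <- rowSums(parts$score); mi <- rowSums(parts$usable)
  ok <- (M - mi) > 0
  cloo <- (S - si[ok]) / (M - mi[ok])
  n <- length(cloo)
  se <- if (n > 1) sqrt((n - 1) / n * sum((cloo - mean(cloo))^2)) else NA_real_
  p <- if (!is.na(se) && se > 0) 2 * stats::pnorm(-abs(cidx - 0.5) / se)
       else if (cidx == 0.5) 1 else 0
  list(c = cidx, p = p, se = se, nPairs = M)
}

#' Rank genes by marginal concordance
#'
#' Each gene's expression is used as the risk score; genes with
#' concordance-index p-value < \code{alpha} are kept and ordered by
#' decreasing |c - 0.5| (so protective and hazardous genes both rank
#' high), ties broken lexicographically by id.
#'
#' @param X features x samples matrix (training samples, pre-filtered by
#'   [medianIntensityFilter()]).
#' @param time,event the survival outcome over the columns of X.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame (gene, c, p) in rank order; may have zero rows.
#' @export
rankGenesByCindex <- function(X, time, event, alpha = 0.01) {
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  res <- lapply(rownames(v), function(g) {
    ci <- concordanceIndex(v[g, ], time, event)
    data.frame(gene = g, c = ci$c, p = ci$p)
  })
  res <- do.call(rbind, res)
  res <- res[res$p < alpha, , drop = FALSE]
  res <- res[order(-abs(res$c - 0.5), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.coxRisk <- function(fit, newX) {
  # linear predictor for a features-in-rows matrix, centered as coxph does
  beta <- stats::coef(fit)
  drop(crossprod(newX[names(beta), , drop = FALSE], beta))
}

.fitCox <- function(X, time, event) {
  df <- data.frame(t(X))
  colnames(df) <- rownames(X)
  df$.time <- time; df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", rownames(X)), collapse = " + ")))
  survival::coxph(fml, data = df, ties = "efron")
}

#' LOOCV one-step forward gene selection
#'
#' Iterates the ranked genes in order; each candidate is tentatively added
#' and the leave-one-out cross-validated concordance is computed (each
#' left-out sample's risk predicted by a Cox fit on the rest; performance =
#' c of the out-of-fold risks against the observed outcomes). The candidate
#' is kept iff the LOOCV c strictly improves. Stops at the end of the list
#' or at \code{maxGenes}. A Cox fit failure rejects the candidate.
#'
#' @param X features x samples training matrix.
#' @param time,event survival outcome over the columns of X.
#' @param ranked character vector of candidate genes in rank order.
#' @param maxGenes signature size cap (default 50).
#' @return list: \code{signature}, \code{cLoocv} (the final LOOCV c, NA if
#'   empty).
#' @export
loocvForwardSelect <- function(X, time, event, ranked, maxGenes = 50) {
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  n <- ncol(v)
  loocvC <- function(sig) {
    risks <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      fit <- .fitCox(v[sig, -i, drop = FALSE], time[-i], event[-i])
      risks[i] <- .coxRisk(fit, v[sig, i, drop = FALSE])
    }
    concordanceIndex(risks, time, event)$c
  }
  signature <- character()
  bestC <- -Inf
  for (g in ranked) {
    if (length(signature) >= maxGenes) break
    cand <- c(signature, g)
    cNew <- tryCatch(suppressWarnings(loocvC(cand)),
                     error = function(e) NA_real_)
    if (is.na(cNew)) next  # fit failure: candidate rejected
    if (cNew > bestC) {
      signature <- cand
      bestC <- cNew
    }
  }
  list(signature = signature, cLoocv = if (length(signature)) bestC else NA_real_)
}

#' Fit the final Cox model and evaluate it
#'
#' Proportional-hazards fit by partial-likelihood maximization (Efron ties)
#' on all training samples with the selected signature; the linear
#' predictor defines the risk. Validation concordance and its p-value
#' against 0.5 are attached when validation data are supplied.
#'
#' @param X training matrix restricted to the signature (features x
#'   samples).
#' @param time,event training outcome.
#' @param validX,validTime,validEvent optional validation data.
#' @param platform platform tag.
#' @return a \linkS4class{CoxModelResult}.
#' @export
fitFinalCox <- function(X, time, event, validX = NULL, validTime = NULL,
                        validEvent = NULL, platform = "microarray") {
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  stopifnot(nrow(v) >= 1)
  if (sum(event) == 0) stop("all samples censored: no usable events")
  fit <- .fitCox(v, time, event)
  if (anyNA(stats::coef(fit))) stop("Cox model did not converge")
  beta <- stats::coef(fit)
  names(beta) <- rownames(v)
  cTr <- concordanceIndex(.coxRisk(fit, v), time, event)$c
  cVa <- pVa <- NA_real_
  if (!is.null(validX)) {
    vv <- if (is(validX, "PlatformMatrix")) exprValues(validX)
          else as.matrix(validX)
    ci <- concordanceIndex(.coxRisk(fit, vv), validTime, validEvent)
    cVa <- ci$c; pVa <- ci$p
  }
  new("CoxModelResult", signature = rownames(v), coefficients = beta,
      cTrain = cTr, cValid = cVa, pValid = pVa, platform = platform)
}

#' Compare two concordance indices on shared samples
#'
#' One-sided paired test that the first model's concordance is greater than
#' the second's, from the jackknife variance of the per-sample difference
#' of concordance contributions (normal approximation). Identical risk
#' vectors give p = 0.5; swapping the models maps p to 1 - p.
#'
#' @param riskA,riskB risk vectors of the two models over the SAME samples.
#' @param time,event the shared survival outcome.
#' @return list: \code{p} (one-sided, A > B), \code{cA}, \code{cB},
#'   \code{delta}, \code{se}.
#' @export
compareCindex <- function(riskA, riskB, time, event) {
  if (length(riskA) != length(riskB) || length(riskA) != length(time))
    stop("risk vectors and outcome must cover the same samples")
  pa <- .cindexParts(riskA, time, event)
  pb <- .cindexParts(riskB, time, event)
  M <- sum(pa$usable) / 2
  if (M < 1) stop("zero usable pairs")
  cA <- sum(pa$score) / 2 / M
  cB <- sum(pb$score) / 2 / M
  delta <- cA - cB
  # jackknife of the paired difference
  sa <- rowSums(pa$score); sb <- rowSums(pb$score); mi <- rowSums(pa$usable)
  ok <- (M - mi) > 0
  dloo <- ((sum(pa$score) / 2 - sa[ok]) - (sum(pb$score) / 2 - sb[ok])) /
    (M - mi[ok])
  nj <- length(dloo)
  se <- if (nj > 1) sqrt((nj - 1) / nj * sum((dloo - mean(dloo))^2))
        else NA_real_
  p <- if (!is.na(se) && se > 0) stats::pnorm(-delta / se)
       else if (delta == 0) 0.5 else if (delta > 0) 0 else 1
  list(p = p, cA = cA, cB = cB, delta = delta, se = se)
}

#' Train a Cox model through the full selection workflow
#'
#' Median-intensity filter, concordance ranking at P < 0.01, LOOCV forward
#' selection, final fit on all training samples.
#'
#' @param X training matrix (features x samples).
#' @param time,event training outcome.
#' @param maxGenes forward-selection cap.
#' @param platform platform tag.
#' @return list: \code{result} (\linkS4class{CoxModelResult} or NULL when
#'   no gene was selectable), \code{ranked} (the ranking table).
#' @export
trainCoxWorkflow <- function(X, time, event, maxGenes = 50,
                             platform = "microarray") {
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  kept <- medianIntensityFilter(v)
  if (length(kept) == 0) {
    warning("median-intensity filter retained no features")
    return(list(result = NULL, ranked = NULL))
  }
  ranked <- rankGenesByCindex(v[kept, , drop = FALSE], time, event)
  if (nrow(ranked) == 0) {
    warning("no gene passed the concordance-index filter")
    return(list(result = NULL, ranked = ranked))
  }
  sel <- loocvForwardSelect(v[kept, , drop = FALSE], time, event,
                            ranked$gene, maxGenes = maxGenes)
  if (length(sel$signature) == 0) {
    warning("forward selection returned an empty signature")
    return(list(result = NULL, ranked = ranked))
  }
  res <- fitFinalCox(v[sel$signature, , drop = FALSE], time, event,
                     platform = platform)
  list(result = res, ranked = ranked)
}

#' Cox transferability assessment
#'
#' Signature level: the source-platform Cox model is trained through the
#' full workflow and evaluated on the source validation samples; its
#' signature is resolved to the target platform and the coefficients are
#' RE-ESTIMATED on the target training samples; the two validation
#' concordances are compared with [compareCindex()]. Model level (z-scored
#' data, groups A/B): the source coefficients are applied unchanged to the
#' resolved target validation features.
#'
#' @param level \code{"signature"} or \code{"model"}.
#' @param sourceTrain,sourceValid,targetTrain,targetValid
#'   \linkS4class{PlatformMatrix} objects (group-restricted; z-scored for
#'   the model level).
#' @param endpoint a survival \linkS4class{EndpointDefinition} (shared
#'   samples on both platforms).
#' @param mapping a \linkS4class{MappingResult}.
#' @param direction transfer direction.
#' @param group mapping group of the feature set (model level rejects C).
#' @param maxGenes forward-selection cap.
#' @return list: \code{source}, \code{target}
#'   (\linkS4class{CoxModelResult}), \code{comparison} (from
#'   [compareCindex()], p for source c > target c).
#' @export
coxTransfer <- function(level = c("signature", "model"),
                        sourceTrain, sourceValid, targetTrain, targetValid,
                        endpoint, mapping,
                        direction = c("array2rnaseq", "rnaseq2array"),
                        group = "A", maxGenes = 50) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  stopifnot(endpoint@kind == "survival")
  if (level == "model" && group == "C")
    stop("group C is not eligible for model-level Cox transfer")
  trIds <- intersect(partitionSamples(endpoint, "training"),
                     colnames(exprValues(sourceTrain)))
  vaIds <- intersect(partitionSamples(endpoint, "validation"),
                     colnames(exprValues(sourceValid)))
  tT <- endpoint@time[trIds]; eT <- endpoint@event[trIds]
  tV <- endpoint@time[vaIds]; eV <- endpoint@event[vaIds]
  sTr <- exprValues(sourceTrain)[, trIds, drop = FALSE]
  sVa <- exprValues(sourceValid)[, vaIds, drop = FALSE]
  tTr <- exprValues(targetTrain)[, trIds, drop = FALSE]
  tVa <- exprValues(targetValid)[, vaIds, drop = FALSE]
  wf <- trainCoxWorkflow(sTr, tT, eT, maxGenes = maxGenes,
                         platform = platformType(sourceTrain))
  if (is.null(wf$result)) stop("source Cox workflow selected no signature")
  sig <- wf$result@signature
  resolved <- resolveSignature(sig, mapping, direction,
                               targetTrain = targetTrain)
  srcRisk <- drop(crossprod(sVa[sig, , drop = FALSE],
                            wf$result@coefficients))
  ciS <- concordanceIndex(srcRisk, tV, eV)
  src <- wf$result
  src@cValid <- ciS$c; src@pValid <- ciS$p
  if (level == "signature") {
    tgtX <- tTr[resolved, , drop = FALSE]
    rownames(tgtX) <- make.unique(resolved)
    tgt <- fitFinalCox(tgtX, tT, eT, platform = platformType(targetTrain))
    tgtRisk <- drop(crossprod(tVa[resolved, , drop = FALSE],
                              tgt@coefficients))
  } else {
    beta <- wf$result@coefficients
    tgtRisk <- drop(crossprod(tVa[resolved, , drop = FALSE], beta))
    tgt <- new("CoxModelResult", signature = resolved,
               coefficients = stats::setNames(as.numeric(beta),
                                              resolved),
               cTrain = NA_real_, cValid = NA_real_, pValid = NA_real_,
               platform = platformType(targetValid))
  }
  ciT <- concordanceIndex(tgtRisk, tV, eV)
  tgt@cValid <- ciT$c; tgt@pValid <- ciT$p
  cmp <- compareCindex(srcRisk, tgtRisk, tV, eV)
  list(source = src, target = tgt, comparison = cmp)
}
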