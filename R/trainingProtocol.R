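# The ensemble training protocol: stratified 70/30 splits, per-split
# t-test/fold-change feature ranking, sequential forward selection by steps
# of two with a parameter search, and refit of the winner on the full
# training set.

#' Construct an endpoint definition
#'
#' @param name endpoint name.
#' @param kind \code{"binary"} or \code{"survival"}.
#' @param labels named 0/1 vector (binary).
#' @param time,event named numeric vectors (survival).
#' @param partition named character vector of \code{"training"} /
#'   \code{"validation"} assignments covering all samples.
#' @return an \linkS4class{EndpointDefinition}.
#' @export
endpointDefinition <- function(name, kind = c("binary", "survival"),
                               labels = numeric(), time = numeric(),
                               event = numeric(), partition) {
  kind <- match.arg(kind)
  new("EndpointDefinition", name = name, kind = kind,
      labels = labels, time = time, event = event, partition = partition)
}

#' Sample ids of one partition of an endpoint
#'
#' @param endpoint an \linkS4class{EndpointDefinition}.
#' @param which \code{"training"} or \code{"validation"}.
#' @return character vector of sample ids.
#' @export
partitionSamples <- function(endpoint, which = c("training", "validation")) {
  which <- match.arg(which)
  names(endpoint@partition)[endpoint@partition == which]
}

#' Default hyper-parameter grids
#'
#' k in \{1, 3, 5, 7, 9, 11\} (odd only), Delta in \{0, 0.5, 1, 2, 4\},
#' linear-kernel cost C in \{0.1, 1, 10\}.
#'
#' @param algorithm \code{"knn"}, \code{"nsc"} or \code{"svm"}.
#' @return list of parameter lists, in grid order.
#' @export
defaultParamGrid <- function(algorithm = c("knn", "nsc", "svm")) {
  switch(match.arg(algorithm),
    knn = lapply(c(1, 3, 5, 7, 9, 11), function(k) list(k = k)),
    nsc = lapply(c(0, 0.5, 1, 2, 4), function(d) list(delta = d)),
    svm = lapply(c(0.1, 1, 10), function(C)
      list(cost = C, kernel = "linear")))
}

#' Stratified random 70/30 split
#'
#' Within each class, \code{round(ratio * n_class)} samples go to the inner
#' training part (at least one sample of each class in each part); the rest
#' form the holdout. Reproducible under \code{seed}.
#'
#' @param labels named 0/1 vector over the training samples; each class must
#'   have >= 2 members.
#' @param ratio inner-training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with character vectors \code{inner} and \code{holdout}.
#' @export
stratifiedSplit <- function(labels, ratio = 0.7, seed = 1) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0, 1)))
  for (cl in c(0, 1))
    if (sum(labels == cl) < 2)
      stop("class ", cl, " has fewer than 2 training members")
  withSeed(seed, {
    inner <- character()
    for (cl in c(0, 1)) {
      ids <- names(labels)[labels == cl]
      nIn <- min(max(round(ratio * length(ids)), 1L), length(ids) - 1L)
      inner <- c(inner, sample(ids, nIn))
    }
    list(inner = inner, holdout = setdiff(names(labels), inner))
  })
}

#' Rank candidate features by t-test filter and fold change
#'
#' Features passing a two-sample Welch t-test at P < \code{alpha} are kept
#' and ordered by decreasing absolute class-mean difference (the log
#' fold change, since inputs are log-scale), ties broken lexicographically
#' by feature id. May return an empty vector when nothing passes.
#'
#' @param X features x samples matrix (inner training samples).
#' @param y 0/1 labels parallel to columns (>= 2 samples per class).
#' @param alpha t-test significance threshold (default 0.05).
#' @return ordered character vector of feature ids.
#' @export
rankCandidateFeatures <- function(X, y, alpha = 0.05) {
  X <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  y <- as.numeric(y)
  stopifnot(ncol(X) == length(y), sum(y == 0) >= 2, sum(y == 1) >= 2)
  x0 <- X[, y == 0, drop = FALSE]; x1 <- X[, y == 1, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  se2 <- v0 / n0 + v1 / n1
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.na(p)] <- 1  # zero-variance, zero-difference features
  fc <- abs(m1 - m0)
  keep <- which(p < alpha)
  ids <- rownames(X)[keep]
  ids[order(-fc[keep], ids)]
}

#' Select the best signature size and parameters on one split
#'
#' Sequential forward selection by steps of two: for every parameter
#' combination in the grid and every even signature size s in \{2, 4, ...,
#' min(maxFeatures, n ranked)\} (the top-s ranked features), a model is fit
#' on the inner training part and scored by accuracy on the holdout. The
#' winner maximizes holdout accuracy; ties prefer the smaller signature,
#' then the simpler parameters (smaller k, larger Delta, smaller C), then
#' grid order. An empty ranked list falls back to the top-2 features by
#' absolute fold change without the P filter, with a warning.
#'
#' @param X features x samples matrix over the training samples.
#' @param y named 0/1 labels over the training samples.
#' @param split list from [stratifiedSplit()].
#' @param algorithm classifier name.
#' @param paramGrid list of parameter lists (default
#'   [defaultParamGrid()]).
#' @param maxFeatures largest signature size considered (default 100).
#' @param step signature size increment (default 2).
#' @param ranked optional precomputed ranking (default: computed on the
#'   inner part).
#' @return list: \code{params}, \code{signature}, \code{holdout_acc}.
#' @export
selectBestModel <- function(X, y, split, algorithm,
                            paramGrid = defaultParamGrid(algorithm),
                            maxFeatures = 100, step = 2, ranked = NULL) {
  X <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  yIn <- y[split$inner]; yHold <- y[split$holdout]
  Xin <- X[, split$inner, drop = FALSE]
  Xhold <- X[, split$holdout, drop = FALSE]
  if (is.null(ranked)) ranked <- rankCandidateFeatures(Xin, yIn)
  if (length(ranked) < 2) {
    warning("t-test filter left <2 features; falling back to top-2 by |FC|")
    fc <- abs(rowMeans(Xin[, yIn == 1, drop = FALSE]) -
              rowMeans(Xin[, yIn == 0, drop = FALSE]))
    ids <- rownames(X)
    ranked <- ids[order(-fc, ids)][seq_len(min(2L, length(ids)))]
  }
  sizes <- seq(step, min(maxFeatures, length(ranked)), by = step)
  simplicity <- function(algorithm, p) switch(algorithm,
    knn = p$k, nsc = -p$delta, svm = p$cost)
  best <- NULL
  for (gi in seq_along(paramGrid)) {
    p <- paramGrid[[gi]]
    for (s in sizes) {
      sig <- ranked[seq_len(s)]
      acc <- tryCatch({
        m <- fitClassifier(algorithm, p, Xin[sig, , drop = FALSE], yIn,
                           signature = sig)
        pr <- predictWithScores(m, Xhold[sig, , drop = FALSE])
        binaryAccuracy(pr$label, yHold)
      }, error = function(e) NA_real_)
      if (is.na(acc)) next
      better <- is.null(best) || acc > best$acc ||
        (acc == best$acc && (s < best$s ||
          (s == best$s && simplicity(algorithm, p) <
             simplicity(algorithm, best$params))))
      if (better) best <- list(params = p, s = s, acc = acc, sig = sig)
    }
  }
  if (is.null(best)) stop("no candidate model could be fit on this split")
  list(params = best$params, signature = best$sig,
       holdout_acc = best$acc)
}

#' Train a model ensemble under the resampling protocol
#'
#' For each of \code{nSplits} seeded stratified 70/30 splits of the training
#' samples: rank features on the inner part, select the best signature size
#' and parameters by holdout accuracy, then refit the selected
#' specification on ALL training samples. Per-split seeds are derived from
#' \code{masterSeed} by a counter scheme so any split is reproducible in
#' isolation.
#'
#' @param X \linkS4class{PlatformMatrix} (already group-restricted and on
#'   the intended scale).
#' @param endpoint binary \linkS4class{EndpointDefinition}.
#' @param algorithm classifier name.
#' @param group mapping-group tag recorded on the ensemble.
#' @param nSplits number of splits (study-scale default 500; pass smaller
#'   for desk-scale runs).
#' @param masterSeed master RNG seed.
#' @param paramGrid,maxFeatures,ratio forwarded to the inner operations.
#' @return a \linkS4class{ModelEnsemble}.
#' @export
trainEnsemble <- function(X, endpoint, algorithm, group = "A",
                          nSplits = 500, masterSeed = 1,
                          paramGrid = defaultParamGrid(algorithm),
                          maxFeatures = 100, ratio = 0.7) {
  stopifnot(endpoint@kind == "binary", nSplits >= 1)
  trIds <- intersect(partitionSamples(endpoint, "training"),
                     colnames(exprValues(X)))
  y <- endpoint@labels[trIds]
  v <- exprValues(X)[, trIds, drop = FALSE]
  records <- vector("list", nSplits)
  for (i in seq_len(nSplits)) {
    seed <- deriveSeed(masterSeed, i)
    split <- stratifiedSplit(y, ratio = ratio, seed = seed)
    sel <- selectBestModel(v, y, split, algorithm, paramGrid = paramGrid,
                           maxFeatures = maxFeatures)
    refit <- fitClassifier(algorithm, sel$params,
                           v[sel$signature, , drop = FALSE], y,
                           signature = sel$signature)
    refit@platform <- platformType(X)
    refit@scale <- scaleType(X)
    records[[i]] <- list(split_seed = seed, params = sel$params,
                         signature = sel$signature,
                         holdout_acc = sel$holdout_acc, model = refit)
  }
  new("ModelEnsemble", endpoint = endpoint@name, platform = platformType(X),
      group = group, algorithm = algorithm, records = records)
}

#' Evaluate an ensemble on validation samples
#'
#' Per-model accuracy and AUC on the validation partition, with ensemble
#' means and 95% percentile-bootstrap confidence intervals over the
#' per-model metric vectors.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param X validation \linkS4class{PlatformMatrix} (same platform/scale as
#'   training; samples disjoint from training).
#' @param endpoint the binary \linkS4class{EndpointDefinition}.
#' @param seed seed for the bootstrap CIs.
#' @return list: \code{perModel} data.frame (accuracy, auc), per-model
#'   \code{predictions} matrix (models x samples), \code{meanAccuracy},
#'   \code{meanAUC}, \code{ciAccuracy}, \code{ciAUC}.
#' @export
evaluateEnsemble <- function(ensemble, X, endpoint, seed = 1) {
  vaIds <- intersect(partitionSamples(endpoint, "validation"),
                     colnames(exprValues(X)))
  if (length(vaIds) == 0) stop("no validation samples present in the matrix")
  y <- endpoint@labels[vaIds]
  v <- exprValues(X)[, vaIds, drop = FALSE]
  recs <- ensemble@records
  preds <- matrix(NA_real_, nrow = length(recs), ncol = length(vaIds),
                  dimnames = list(NULL, vaIds))
  acc <- auc <- numeric(length(recs))
  for (i in seq_along(recs)) {
    pr <- predictWithScores(recs[[i]]$model, v)
    preds[i, ] <- pr$label
    acc[i] <- binaryAccuracy(pr$label, y)
    auc[i] <- aucScore(pr$score, y)
  }
  list(perModel = data.frame(accuracy = acc, auc = auc),
       predictions = preds,
       meanAccuracy = mean(acc), meanAUC = mean(auc),
       ciAccuracy = bootstrapCI(acc, seed = deriveSeed(seed, 1)),
       ciAUC = bootstrapCI(auc, seed = deriveSeed(seed, 2)))
}
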