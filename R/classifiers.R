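# The three binary classifiers as fit/predict contracts with continuous
# class-1 scores. k-NN and the nearest-shrunken-centroid rule are
# implemented here; the maximum-margin classifier delegates to e1071::svm.

.asFeatureMatrix <- function(X, signature) {
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  missing <- setdiff(signature, rownames(v))
  if (length(missing))
    stop("matrix lacks signature feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  v[signature, , drop = FALSE]
}

#' Fit a binary classifier
#'
#' Fits one of three algorithms on a feature-restricted expression matrix:
#' \describe{
#'   \item{knn}{stores the training exemplars; prediction is by majority
#'     vote of the k Euclidean-nearest exemplars.}
#'   \item{nsc}{nearest shrunken centroids: per-class centroids
#'     \eqn{\bar x_{ik}}, overall centroid \eqn{\bar x_i}, pooled
#'     within-class s.d. \eqn{s_i}, fudge \eqn{s_0 = \mathrm{median}(s_i)},
#'     \eqn{m_k = \sqrt{1/n_k - 1/n}}, standardized offsets
#'     \eqn{d_{ik} = (\bar x_{ik} - \bar x_i)/(m_k (s_i + s_0))} soft-
#'     thresholded by \eqn{\Delta}: \eqn{d'_{ik} =
#'     \mathrm{sign}(d_{ik})(|d_{ik}| - \Delta)_+}; class priors are the
#'     training class frequencies.}
#'   \item{svm}{linear-kernel maximum-margin classifier via
#'     \code{e1071::svm} at cost C (no internal rescaling).}
#' }
#'
#' @param algorithm \code{"knn"}, \code{"nsc"} or \code{"svm"}.
#' @param params named list: \code{k} (odd) for knn; \code{delta} (>= 0) for
#'   nsc; \code{cost} (> 0) and optional \code{kernel} for svm.
#' @param X features x samples matrix (or \linkS4class{PlatformMatrix})
#'   restricted to the signature.
#' @param y 0/1 labels, named by sample or parallel to columns; both classes
#'   must be present.
#' @param signature ordered feature ids (default: rownames of X).
#' @return a \linkS4class{TrainedModel}.
#' @export
fitClassifier <- function(algorithm = c("knn", "nsc", "svm"), params, X, y,
                          signature = NULL) {
  algorithm <- match.arg(algorithm)
  v <- if (is(X, "PlatformMatrix")) exprValues(X) else as.matrix(X)
  if (is.null(signature)) signature <- rownames(v)
  v <- .asFeatureMatrix(X, signature)
  y <- as.numeric(y)
  stopifnot(length(y) == ncol(v), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  fit <- switch(algorithm,
    knn = {
      k <- params$k
      stopifnot(!is.null(k), k >= 1)
      if (k >= ncol(v)) stop("k must be smaller than the training size")
      list(exemplars = v, labels = y, k = as.integer(k))
    },
    nsc = {
      delta <- params$delta
      stopifnot(!is.null(delta), delta >= 0)
      n <- ncol(v)
      classes <- c(0, 1)
      nk <- vapply(classes, function(cl) sum(y == cl), numeric(1))
      cent <- vapply(classes, function(cl)
        rowMeans(v[, y == cl, drop = FALSE]), numeric(nrow(v)))
      cent <- matrix(cent, nrow = nrow(v),
                     dimnames = list(rownames(v), c("c0", "c1")))
      overall <- rowMeans(v)
      ss <- rowSums(matrix(vapply(classes, function(cl) {
        vc <- v[, y == cl, drop = FALSE]
        rowSums((vc - cent[, paste0("c", cl)])^2)
      }, numeric(nrow(v))), nrow = nrow(v)))
      si <- sqrt(ss / (n - 2))
      s0 <- stats::median(si)
      mk <- sqrt(1 / nk - 1 / n)
      dik <- sweep(cent - overall, 1, si + s0, "/")
      dik <- sweep(dik, 2, mk, "/")
      dshr <- sign(dik) * pmax(abs(dik) - delta, 0)
      shrunk <- overall + sweep(sweep(dshr, 2, mk, "*"), 1, si + s0, "*")
      list(centroids = shrunk, si = si, s0 = s0,
           priors = nk / n, delta = delta)
    },
    svm = {
      cost <- params$cost
      kernel <- params$kernel %||% "linear"
      stopifnot(!is.null(cost), cost > 0)
      yf <- factor(y, levels = c(0, 1))
      m <- e1071::svm(x = t(v), y = yf, kernel = kernel, cost = cost,
                      scale = FALSE)
      # orientation of decision values toward class "1"
      dv <- attr(stats::predict(m, t(v), decision.values = TRUE),
                 "decision.values")
      flip <- grepl("^0/1$", colnames(dv)[1])
      list(svm = m, flip = flip, cost = cost, kernel = kernel)
    })
  new("TrainedModel", algorithm = algorithm, params = params,
      signature = signature, fit = fit,
      trainSamples = colnames(v) %||% as.character(seq_len(ncol(v))),
      platform = if (is(X, "PlatformMatrix")) platformType(X) else
        NA_character_,
      scale = if (is(X, "PlatformMatrix")) scaleType(X) else NA_character_)
}

# Squared Euclidean distances between columns of train and test matrices.
.colDist2 <- function(train, test) {
  d2 <- outer(colSums(train^2), colSums(test^2), "+") -
    2 * crossprod(train, test)
  pmax(d2, 0)
}

#' Predict labels and class-1 scores
#'
#' Per-sample predicted label and continuous class-1 score:
#' \describe{
#'   \item{knn}{score = fraction of the k nearest exemplars in class 1
#'     (distance ties resolved toward class-0 exemplars, then training
#'     order); label = majority vote, 0.5 breaking to class 0.}
#'   \item{nsc}{discriminant \eqn{\delta_k(x) = \sum_i (x_i - \bar
#'     x'_{ik})^2/(s_i + s_0)^2 - 2\log\pi_k}; label = argmin (ties to class
#'     0); score = class-1 posterior \eqn{e^{-\delta_1/2} /
#'     (e^{-\delta_0/2} + e^{-\delta_1/2})}.}
#'   \item{svm}{score = decision value oriented toward class 1; label = its
#'     sign, 0 breaking to class 0.}
#' }
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param X matrix or \linkS4class{PlatformMatrix} containing all signature
#'   features (same scale as training).
#' @return data.frame with columns \code{sample}, \code{label},
#'   \code{score}.
#' @export
predictWithScores <- function(model, X) {
  v <- .asFeatureMatrix(X, model@signature)
  n <- ncol(v)
  out <- switch(model@algorithm,
    knn = {
      f <- model@fit
      d2 <- .colDist2(f$exemplars, v)
      score <- vapply(seq_len(n), function(j) {
        o <- order(d2[, j], f$labels, seq_along(f$labels))
        mean(f$labels[o[seq_len(f$k)]])
      }, numeric(1))
      list(label = as.numeric(score > 0.5), score = score)
    },
    nsc = {
      f <- model@fit
      den <- (f$si + f$s0)^2
      d0 <- colSums((v - f$centroids[, "c0"])^2 / den) - 2 * log(f$priors[1])
      d1 <- colSums((v - f$centroids[, "c1"])^2 / den) - 2 * log(f$priors[2])
      m <- pmin(d0, d1)
      e0 <- exp(-(d0 - m) / 2); e1 <- exp(-(d1 - m) / 2)
      list(label = as.numeric(d1 < d0), score = e1 / (e0 + e1))
    },
    svm = {
      f <- model@fit
      dv <- attr(stats::predict(f$svm, t(v), decision.values = TRUE),
                 "decision.values")[, 1]
      if (f$flip) dv <- -dv
      list(label = as.numeric(dv > 0), score = unname(dv))
    })
  data.frame(sample = colnames(v) %||% as.character(seq_len(n)),
             label = out$label, score = out$score,
             stringsAsFactors = FALSE, row.names = NULL)
}
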