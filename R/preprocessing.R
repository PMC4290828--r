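#' Construct a PlatformMatrix
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param platform \code{"microarray"} or \code{"rnaseq"}.
#' @param scale scale state of the values: \code{"log2_intensity"},
#'   \code{"log2_count"}, \code{"zscore"} or \code{"linear"}.
#' @return a \linkS4class{PlatformMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' PlatformMatrix(m, "rnaseq", "log2_count")
#' @export
PlatformMatrix <- function(values, platform = c("microarray", "rnaseq"),
                           scale = c("log2_intensity", "log2_count",
                                     "zscore", "linear")) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  se <- SummarizedExperiment(assays = list(expr = values))
  new("PlatformMatrix", se, platform = platform, scaleType = scale)
}

#' Load an expression matrix from a tab-delimited file
#'
#' Reads a rectangular TSV whose first column holds feature identifiers and
#' whose header row holds sample identifiers, and tags the result with its
#' platform and scale. Duplicate identifiers, ragged rows and missing cells
#' are hard errors; imputation is out of scope.
#'
#' @param path path to the TSV file.
#' @inheritParams PlatformMatrix
#' @return a \linkS4class{PlatformMatrix}.
#' @export
loadExpression <- function(path, platform, scale) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV must have >= 1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicated feature ids in ", path)
  if (anyDuplicated(colnames(df)[-1])) stop("duplicated sample ids in ", path)
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1]))
  if (anyNA(vals)) stop("NA or non-numeric cells in ", path)
  PlatformMatrix(vals, platform, scale)
}

#' Write a PlatformMatrix to a tab-delimited file
#'
#' Inverse of [loadExpression()]: first column \code{feature_id}, one column
#' per sample. A sidecar \code{<path>.meta} records platform and scale.
#'
#' @param m a \linkS4class{PlatformMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(m, path) {
  v <- exprValues(m)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("platform\t", platformType(m)),
               paste0("scale\t", scaleType(m))),
             paste0(path, ".meta"))
  invisible(path)
}

#' Log2-transform linear-scale values
#'
#' \code{value <- log2(value + pseudocount)}; negative inputs are an error.
#' The scale tag is advanced to the platform's log2 scale.
#'
#' @param m a \linkS4class{PlatformMatrix} on the linear scale.
#' @param pseudocount non-negative offset added before the log (default 1).
#' @return a \linkS4class{PlatformMatrix} on the log2 scale.
#' @export
log2Transform <- function(m, pseudocount = 1) {
  stopifnot(is(m, "PlatformMatrix"), pseudocount >= 0)
  v <- exprValues(m)
  if (any(v < 0)) stop("negative values cannot be log2-transformed")
  out <- log2(v + pseudocount)
  scale <- if (platformType(m) == "microarray") "log2_intensity"
           else "log2_count"
  PlatformMatrix(out, platformType(m), scale)
}

#' Per-sample z-score transformation
#'
#' Standardizes each sample (column) independently to mean 0 and standard
#' deviation 1 (n-1 denominator). Because the transform is strictly
#' per-column, no information crosses samples or data sets; training and
#' validation sets are transformed independently by construction.
#'
#' @param m a \linkS4class{PlatformMatrix} with >= 2 features.
#' @return a \linkS4class{PlatformMatrix} with scale \code{"zscore"}.
#' @export
perSampleZscore <- function(m) {
  stopifnot(is(m, "PlatformMatrix"))
  v <- exprValues(m)
  if (nrow(v) < 2) stop("per-sample z-scoring needs >= 2 features")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop("constant sample column(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  out <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  PlatformMatrix(out, platformType(m), "zscore")
}

#' Restrict an expression matrix to one mapping group
#'
#' Keeps only the features assigned to the requested mapping group on the
#' matrix's own side (probe side for microarray, gene side for RNA-seq),
#' preserving the original feature order.
#'
#' @param m a \linkS4class{PlatformMatrix}.
#' @param mapping a \linkS4class{MappingResult}.
#' @param group \code{"A"}, \code{"B"} or \code{"C"}.
#' @return a \linkS4class{PlatformMatrix} restricted to the group.
#' @export
subsetByGroup <- function(m, mapping, group = c("A", "B", "C")) {
  group <- match.arg(group)
  side <- if (platformType(m) == "microarray") "probe" else "gene"
  gr <- mappingGroups(mapping, side)
  keep <- rownames(exprValues(m)) %in% names(gr)[gr == group]
  if (!any(keep))
    stop("no features of group ", group, " present in the matrix")
  PlatformMatrix(exprValues(m)[keep, , drop = FALSE], platformType(m),
                 scaleType(m))
}
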