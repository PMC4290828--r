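# Shared fixtures and independent oracles for the test suite.

# Small instance for fast tests. The C concordance target is lowered: with
# only 4 C probes (8 pairs), the planted endpoint shift alone drags the
# zero-noise within-sample Spearman below the default 0.54 target.
tinySpec <- function(...) {
  fixtureSpec(nProbes = c(A = 12, B = 6, C = 4, D = 4), nSamples = 60,
              nSignal = 6, concordance = c(A = 0.87, B = 0.60, C = 0.30),
              ...)
}

# One small study bundle shared across test files (computed lazily once).
.studyCache <- new.env(parent = emptyenv())
getTinyStudy <- function() {
  if (is.null(.studyCache$st))
    .studyCache$st <- generateStudy(tinySpec(), seed = 42)
  .studyCache$st
}

# Independent brute-force oracle for location mapping: plain double loop
# over probes x genes on extracted coordinate vectors, overlap of 1-based
# inclusive intervals computed directly, per-exon totals summed across
# alignments.
bruteLocationMap <- function(annot, genes, params = locationMappingParams()) {
  grDf <- function(gr) data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  alnList <- lapply(seq_along(annot@probeIds),
                    function(i) grDf(annot@alignments[[i]]))
  exList <- lapply(seq_along(genes@geneIds),
                   function(j) grDf(genes@exons[[j]]))
  hits <- list()
  for (i in seq_along(annot@probeIds)) {
    alns <- alnList[[i]]
    if (nrow(alns) == 0) next
    for (j in seq_along(genes@geneIds)) {
      ex <- exList[[j]]
      if (nrow(ex) == 0) next
      exTotals <- numeric(nrow(ex))
      for (e in seq_len(nrow(ex))) {
        tot <- 0
        for (a in seq_len(nrow(alns))) {
          if (alns$chrom[a] != ex$chrom[e]) next
          if (params$requireSameStrand && alns$strand[a] != "*" &&
              ex$strand[e] != "*" && alns$strand[a] != ex$strand[e]) next
          tot <- tot + max(0, min(alns$end[a], ex$end[e]) -
                              max(alns$start[a], ex$start[e]) + 1)
        }
        exTotals[e] <- tot
      }
      if (max(exTotals) > params$minOverlapBp ||
          sum(exTotals >= 1) >= params$minExons)
        hits[[length(hits) + 1L]] <-
          data.frame(probe_id = annot@probeIds[i],
                     gene_id = genes@geneIds[j])
    }
  }
  if (length(hits) == 0)
    return(data.frame(probe_id = character(), gene_id = character()))
  out <- do.call(rbind, hits)
  out[order(out$probe_id, out$gene_id), , drop = FALSE]
}

# Simple GRanges helpers for hand-built mapping cases.
gr1 <- function(start, end, strand = "+", chrom = "chrS") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand)
}

makeAnnot <- function(probeIds, alignments, symbols = NULL) {
  n <- length(probeIds)
  if (is.null(symbols)) symbols <- rep(list(character()), n)
  new("ProbeAnnotation", probeIds = probeIds,
      geneSymbols = IRanges::CharacterList(symbols),
      refseqIds = IRanges::CharacterList(rep(list(character()), n)),
      ensemblIds = IRanges::CharacterList(rep(list(character()), n)),
      entrezIds = IRanges::CharacterList(rep(list(character()), n)),
      alignments = GenomicRanges::GRangesList(alignments))
}

makeGenes <- function(geneIds, exons, publicIds = NULL) {
  if (is.null(publicIds)) publicIds <- rep(list(character()),
                                           length(geneIds))
  new("GeneModels", geneIds = geneIds,
      publicIds = IRanges::CharacterList(publicIds),
      exons = GenomicRanges::GRangesList(exons))
}

# A labelled toy matrix with two well-separated classes.
separableToy <- function(nFeat = 6, nPerClass = 12, gap = 4, seed = 99) {
  set.seed(seed)
  n <- 2 * nPerClass
  y <- rep(c(0, 1), each = nPerClass)
  X <- matrix(rnorm(nFeat * n), nFeat, n,
              dimnames = list(sprintf("f%02d", seq_len(nFeat)),
                              sprintf("s%02d", seq_len(n))))
  sig <- seq_len(min(2, nFeat))
  X[sig, y == 1] <- X[sig, y == 1] + gap
  names(y) <- colnames(X)
  list(X = X, y = y)
}
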