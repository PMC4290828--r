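# Cross-platform gene mapping: annotation parsing, ID and genome-location
# mapping, and the A/B/C/D mapping-complexity classification.

#' Location-mapping parameters
#'
#' A probe set maps to a gene by genome location when its alignment overlap
#' with some single exon exceeds \code{minOverlapBp} base pairs (strict
#' greater-than), or when it overlaps at least \code{minExons} distinct
#' exons of the gene by at least 1 bp each.
#'
#' @param minOverlapBp single-exon overlap threshold in bp (default 40,
#'   strict \code{>}).
#' @param minExons minimum number of distinct exons for the multi-exon rule
#'   (default 2).
#' @param requireSameStrand require matching strands when both the alignment
#'   and the exon carry a known strand (default TRUE); unknown strands
#'   (\code{"*"}) always match.
#' @return a named list of validated parameters.
#' @export
locationMappingParams <- function(minOverlapBp = 40, minExons = 2,
                                  requireSameStrand = TRUE) {
  stopifnot(minOverlapBp >= 0, minExons >= 1)
  list(minOverlapBp = as.integer(minOverlapBp),
       minExons = as.integer(minExons),
       requireSameStrand = isTRUE(requireSameStrand))
}

# Normalize a public gene ID for matching: case-folded, RefSeq/Ensembl-style
# version suffixes stripped (NM_0001.2 == NM_0001).
normalizeId <- function(x) sub("\\.[0-9]+$", "", toupper(x))

.splitMulti <- function(x, delim = "///") {
  if (is.na(x) || x == "" || x == "---") return(character())
  parts <- trimws(strsplit(x, delim, fixed = TRUE)[[1]])
  parts[parts != "" & parts != "---"]
}

# "chr1:100-200 (+) // 95 // direct" -> GRanges row, or NULL if unparseable.
.parseAlignment <- function(cell) {
  loc <- trimws(strsplit(cell, "//", fixed = TRUE)[[1]][1])
  m <- regmatches(loc, regexec(
    "^([^:[:space:]]+):([0-9]+)-([0-9]+)(?:[[:space:]]*\\(([+-])\\))?$", loc))[[1]]
  if (length(m) == 0) return(NULL)
  s <- as.integer(m[3]); e <- as.integer(m[4])
  if (is.na(s) || is.na(e) || s > e) return(NULL)
  GRanges(m[2], IRanges(s, e), strand = if (m[5] == "") "*" else m[5])
}

#' Parse a NetAffx-style probe annotation CSV
#'
#' One record per probe set: the public gene IDs the probe set is annotated
#' with and its genome alignments. Multi-valued cells are split on
#' \code{"///"}; fields within an alignment cell on \code{"//"}; missing
#' values are \code{"---"} or empty. Alignment coordinates are 1-based
#' inclusive. A missing probe-ID column is a hard error; an unparseable
#' alignment cell drops that alignment with a warning and keeps the record.
#'
#' @param path path to the annotation CSV.
#' @param columns named character vector mapping the roles \code{probe},
#'   \code{symbol}, \code{refseq}, \code{ensembl}, \code{entrez},
#'   \code{alignments} to column names in the file.
#' @return a \linkS4class{ProbeAnnotation}.
#' @export
parseProbeAnnotation <- function(path,
    columns = c(probe = "Probe Set ID", symbol = "Gene Symbol",
                refseq = "RefSeq Transcript ID", ensembl = "Ensembl",
                entrez = "Entrez Gene", alignments = "Alignments")) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!columns[["probe"]] %in% colnames(df))
    stop("annotation file lacks the probe-ID column '", columns[["probe"]], "'")
  getcol <- function(role) {
    cn <- columns[[role]]
    if (!is.null(cn) && !is.na(cn) && cn %in% colnames(df)) df[[cn]]
    else rep("", nrow(df))
  }
  ids <- df[[columns[["probe"]]]]
  if (anyDuplicated(ids)) stop("duplicated probe ids in ", path)
  splitCol <- function(role)
    CharacterList(lapply(getcol(role), .splitMulti))
  aln <- lapply(getcol("alignments"), function(cell) {
    parts <- .splitMulti(cell)
    if (length(parts) == 0) return(GRanges())
    parsed <- lapply(parts, .parseAlignment)
    bad <- vapply(parsed, is.null, TRUE)
    if (any(bad))
      warning("dropped ", sum(bad), " unparseable alignment(s)")
    if (all(bad)) GRanges() else do.call(c, parsed[!bad])
  })
  new("ProbeAnnotation", probeIds = ids,
      geneSymbols = splitCol("symbol"), refseqIds = splitCol("refseq"),
      ensemblIds = splitCol("ensembl"), entrezIds = splitCol("entrez"),
      alignments = GRangesList(aln))
}

#' Parse RNA-seq gene models from a GTF/GFF file
#'
#' Exon features are grouped by their gene identifier attribute; all other
#' feature types are ignored. Coordinates stay 1-based inclusive per the
#' format. Public IDs are taken from \code{gene_name} attributes when
#' present. A file without exon features is a hard error; an exon without a
#' gene attribute is skipped with a warning.
#'
#' @param path path to a GTF2.2/GFF3 file.
#' @return a \linkS4class{GeneModels}.
#' @export
parseGeneModels <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  gid <- as.character(gr$gene_id %||% rep(NA_character_, length(gr)))
  if (anyNA(gid) || any(gid == "")) {
    drop <- is.na(gid) | gid == ""
    warning("skipped ", sum(drop), " exon(s) without a gene identifier")
    gr <- gr[!drop]; gid <- gid[!drop]
    if (length(gr) == 0) stop("no exon features with gene identifiers in ", path)
  }
  geneIds <- unique(gid)
  pub <- lapply(geneIds, function(g) {
    nm <- unique(as.character(gr$gene_name[gid == g]))
    nm[!is.na(nm) & nm != ""]
  })
  exons <- GRangesList(lapply(geneIds, function(g) {
    x <- gr[gid == g]
    S4Vectors::mcols(x) <- NULL
    x
  }))
  new("GeneModels", geneIds = geneIds, publicIds = CharacterList(pub),
      exons = exons)
}

#' Build a GeneModels object from a plain gene-ID list
#'
#' For pipelines that quantified against a gene list rather than a GTF; the
#' genes carry their own ID as the sole public ID and no exons, so only ID
#' mapping is possible.
#'
#' @param path text file with one gene identifier per line.
#' @return a \linkS4class{GeneModels} with empty exon lists.
#' @export
geneModelsFromIdList <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids[trimws(ids) != ""])
  if (anyDuplicated(ids)) stop("duplicated gene ids in ", path)
  new("GeneModels", geneIds = ids,
      publicIds = CharacterList(as.list(ids)),
      exons = GRangesList(rep(list(GRanges()), length(ids))))
}

.newEdges <- function(probe = character(), gene = character(),
                      evidence = character(), id_type = character(),
                      overlap = integer(), nex = integer()) {
  data.frame(probe_id = probe, gene_id = gene, evidence = evidence,
             id_type = id_type, overlap_bp = overlap, n_exons_hit = nex,
             stringsAsFactors = FALSE)
}

#' Map probes to genes by public gene IDs
#'
#' An edge (probe, gene) is emitted when any probe ID of any type in
#' \code{precedence} matches one of the gene's public IDs; matching is
#' case-insensitive with RefSeq/Ensembl version suffixes stripped. Edge
#' evidence records the first matching ID type in precedence order; edges
#' are deduplicated per (probe, gene).
#'
#' @param annot a \linkS4class{ProbeAnnotation}.
#' @param genes a \linkS4class{GeneModels}.
#' @param precedence ordered non-empty subset of
#'   \code{c("refseq", "symbol", "ensembl", "entrez")}.
#' @return edge data.frame (see \linkS4class{MappingResult}).
#' @export
mapByGeneId <- function(annot, genes,
                        precedence = c("refseq", "symbol", "ensembl",
                                       "entrez")) {
  stopifnot(length(precedence) >= 1,
            all(precedence %in% c("refseq", "symbol", "ensembl", "entrez")))
  slotFor <- c(refseq = "refseqIds", symbol = "geneSymbols",
               ensembl = "ensemblIds", entrez = "entrezIds")
  # gene lookup: normalized public id -> gene index
  gids <- rep(seq_along(genes@geneIds), lengths(genes@publicIds))
  gkeys <- normalizeId(unlist(genes@publicIds, use.names = FALSE))
  found <- list()
  for (type in precedence) {
    pl <- slot(annot, slotFor[[type]])
    pidx <- rep(seq_along(annot@probeIds), lengths(pl))
    pkeys <- normalizeId(unlist(pl, use.names = FALSE))
    if (length(pkeys) == 0) next
    # a key can match several genes: expand via a key -> gene-indices map
    keymap <- split(gids, gkeys)
    hits <- keymap[pkeys]            # absent keys yield NULL elements
    nhit <- lengths(hits)
    if (sum(nhit) == 0) next
    p <- rep(pidx, nhit)
    g <- unlist(hits, use.names = FALSE)
    key <- paste(p, g)
    new <- !key %in% names(found)
    for (k in unique(key[new])) found[[k]] <- type
  }
  if (length(found) == 0) return(.newEdges())
  parts <- do.call(rbind, strsplit(names(found), " ", fixed = TRUE))
  .newEdges(annot@probeIds[as.integer(parts[, 1])],
            genes@geneIds[as.integer(parts[, 2])],
            rep("id", length(found)),
            unlist(found, use.names = FALSE),
            rep(NA_integer_, length(found)),
            rep(NA_integer_, length(found)))
}

#' Map probes to genes by genome location
#'
#' For every probe alignment / exon pair on the same chromosome (and strand
#' when required and both known), overlaps of the 1-based inclusive
#' intervals are summed per exon across the probe's alignments. An edge
#' (probe, gene) is emitted iff the total overlap with some single exon of
#' the gene is strictly greater than \code{minOverlapBp}, or the probe
#' overlaps at least \code{minExons} distinct exons of the gene by >= 1 bp
#' each. Evidence stores the largest per-exon overlap and the number of
#' distinct exons hit.
#'
#' @inheritParams mapByGeneId
#' @param params see [locationMappingParams()].
#' @return edge data.frame (see \linkS4class{MappingResult}).
#' @export
mapByLocation <- function(annot, genes, params = locationMappingParams()) {
  aln <- unlist(annot@alignments, use.names = FALSE)
  if (length(aln) == 0 || sum(lengths(genes@exons)) == 0) return(.newEdges())
  alnProbe <- rep(seq_along(annot@probeIds), lengths(annot@alignments))
  ex <- unlist(genes@exons, use.names = FALSE)
  exGene <- rep(seq_along(genes@geneIds), lengths(genes@exons))
  exId <- seq_along(ex)  # distinct exon identity is positional
  ov <- GenomicRanges::findOverlaps(aln, ex, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (length(ov) == 0) return(.newEdges())
  qa <- S4Vectors::queryHits(ov); sa <- S4Vectors::subjectHits(ov)
  if (params$requireSameStrand) {
    s1 <- as.character(strand(aln))[qa]
    s2 <- as.character(strand(ex))[sa]
    keep <- s1 == "*" | s2 == "*" | s1 == s2
    qa <- qa[keep]; sa <- sa[keep]
    if (length(qa) == 0) return(.newEdges())
  }
  w <- pmin(end(aln)[qa], end(ex)[sa]) - pmax(start(aln)[qa], start(ex)[sa]) + 1L
  # total overlap per (probe, exon), summed over the probe's alignments
  pe <- data.frame(p = alnProbe[qa], e = sa, w = w)
  agg <- stats::aggregate(w ~ p + e, pe, sum)
  agg$g <- exGene[agg$e]
  # per (probe, gene): max single-exon total and count of distinct exons hit
  key <- paste(agg$p, agg$g)
  maxw <- tapply(agg$w, key, max)
  nex <- tapply(agg$e, key, function(x) length(unique(x)))
  keys <- names(maxw)
  pass <- (maxw > params$minOverlapBp) | (nex >= params$minExons)
  if (!any(pass)) return(.newEdges())
  parts <- do.call(rbind, strsplit(keys[pass], " ", fixed = TRUE))
  .newEdges(annot@probeIds[as.integer(parts[, 1])],
            genes@geneIds[as.integer(parts[, 2])],
            rep("location", sum(pass)), rep(NA_character_, sum(pass)),
            as.integer(maxw[pass]), as.integer(nex[pass]))
}

#' Classify features into mapping groups A/B/C/D
#'
#' With deg(p) the number of distinct genes a probe maps to and deg(g) the
#' number of distinct probes a gene maps to: a probe is A when deg(p) = 1
#' and its gene has deg(g) = 1; B when deg(p) = 1 but its gene has deg(g) >
#' 1; C when deg(p) > 1; D when deg(p) = 0. The gene side is classified
#' symmetrically. Probe-side B edges necessarily land on gene-side C genes
#' and vice versa.
#'
#' @param edges edge data.frame from [mapByGeneId()] or [mapByLocation()].
#' @param probes character vector: the full probe universe.
#' @param genes character vector: the full gene universe.
#' @param params location-mapping parameters to record (optional).
#' @return a \linkS4class{MappingResult}.
#' @export
classifyMappingGroups <- function(edges, probes, genes, params = list()) {
  stopifnot(!anyDuplicated(probes), !anyDuplicated(genes))
  if (nrow(edges)) {
    if (!all(edges$probe_id %in% probes))
      stop("edge references unknown probe id")
    if (!all(edges$gene_id %in% genes))
      stop("edge references unknown gene id")
    edges <- edges[!duplicated(edges[c("probe_id", "gene_id")]), ,
                   drop = FALSE]
    edges <- edges[order(edges$probe_id, edges$gene_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  degP <- table(factor(edges$probe_id, levels = probes))
  degG <- table(factor(edges$gene_id, levels = genes))
  classify <- function(deg, otherDegOfPartner) {
    out <- rep("D", length(deg))
    out[deg > 1] <- "C"
    one <- deg == 1
    out[one] <- ifelse(otherDegOfPartner[one] > 1, "B", "A")
    out
  }
  # partner degree for degree-1 features
  pPartner <- rep(NA_real_, length(probes)); names(pPartner) <- probes
  gPartner <- rep(NA_real_, length(genes)); names(gPartner) <- genes
  if (nrow(edges)) {
    p1 <- names(degP)[degP == 1]
    m <- match(p1, edges$probe_id)
    pPartner[p1] <- as.numeric(degG[edges$gene_id[m]])
    g1 <- names(degG)[degG == 1]
    m <- match(g1, edges$gene_id)
    gPartner[g1] <- as.numeric(degP[edges$probe_id[m]])
  }
  pg <- classify(as.numeric(degP), pPartner)
  gg <- classify(as.numeric(degG), gPartner)
  names(pg) <- probes; names(gg) <- genes
  new("MappingResult", edges = edges, probeGroup = pg, geneGroup = gg,
      params = params)
}

#' Map and classify in one call
#'
#' Runs one of the two mapping methods and classifies both sides into
#' mapping groups. The methods are alternatives selected here, not merged.
#'
#' @inheritParams mapByLocation
#' @param method \code{"location"} or \code{"id"}.
#' @param precedence ID-type precedence for \code{method = "id"}.
#' @return a \linkS4class{MappingResult}.
#' @export
mapPlatforms <- function(annot, genes, method = c("location", "id"),
                         params = locationMappingParams(),
                         precedence = c("refseq", "symbol", "ensembl",
                                        "entrez")) {
  method <- match.arg(method)
  edges <- if (method == "location") mapByLocation(annot, genes, params)
           else mapByGeneId(annot, genes, precedence)
  classifyMappingGroups(edges, annot@probeIds, genes@geneIds,
                        if (method == "location") params else list())
}

# Resolved (probe, gene) pairs for a probe-side mapping group.
.groupPairs <- function(mapping, group) {
  ed <- mappingEdges(mapping)
  pg <- mappingGroups(mapping, "probe")
  members <- names(pg)[pg == group]
  ed <- ed[ed$probe_id %in% members, c("probe_id", "gene_id"), drop = FALSE]
  ed[order(ed$probe_id, ed$gene_id), , drop = FALSE]
}

#' Per-sample Spearman concordance between platforms
#'
#' For each sample shared by the two matrices, the Spearman correlation
#' between probe values and their mapped-gene values over the resolved pairs
#' of one mapping group (groups A and B: the unique counterpart; group C:
#' every probe-gene edge contributes a pair).
#'
#' @param arrayExpr microarray \linkS4class{PlatformMatrix}.
#' @param rnaseqExpr RNA-seq \linkS4class{PlatformMatrix}.
#' @param mapping a \linkS4class{MappingResult}.
#' @param group \code{"A"}, \code{"B"} or \code{"C"} (probe side).
#' @return list: \code{perSample} named numeric vector of per-sample r,
#'   \code{mean}, \code{sd}, \code{nPairs}.
#' @export
spearmanConcordance <- function(arrayExpr, rnaseqExpr, mapping,
                                group = c("A", "B", "C")) {
  group <- match.arg(group)
  pairs <- .groupPairs(mapping, group)
  av <- exprValues(arrayExpr); rv <- exprValues(rnaseqExpr)
  pairs <- pairs[pairs$probe_id %in% rownames(av) &
                 pairs$gene_id %in% rownames(rv), , drop = FALSE]
  if (nrow(pairs) < 3) stop("insufficient pairs for group ", group)
  samples <- intersect(colnames(av), colnames(rv))
  if (length(samples) == 0) stop("no shared samples")
  X <- av[pairs$probe_id, samples, drop = FALSE]
  Y <- rv[pairs$gene_id, samples, drop = FALSE]
  r <- vapply(seq_along(samples), function(j)
    stats::cor(X[, j], Y[, j], method = "spearman"), numeric(1))
  names(r) <- samples
  list(perSample = r, mean = mean(r), sd = stats::sd(r),
       nPairs = nrow(pairs))
}

#' Write mapping outputs as TSV files
#'
#' Emits the edge list, the per-side group assignments, and a group-size
#' summary into a directory.
#'
#' @param mapping a \linkS4class{MappingResult}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeMappingResult <- function(mapping, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(mappingEdges(mapping), file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (side in c("probe", "gene")) {
    gr <- mappingGroups(mapping, side)
    utils::write.table(
      data.frame(feature_id = names(gr), group = unname(gr)),
      file.path(dir, paste0(side, "_groups.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sizes <- data.frame(
    group = .GROUPS,
    n_probes = as.integer(table(factor(mappingGroups(mapping, "probe"),
                                       levels = .GROUPS))),
    n_genes = as.integer(table(factor(mappingGroups(mapping, "gene"),
                                      levels = .GROUPS))))
  utils::write.table(sizes, file.path(dir, "group_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
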