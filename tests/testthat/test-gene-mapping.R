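# Annotation parsing, ID/location mapping, and A/B/C/D classification.

test_that("annotation CSV parsing splits multi-valued cells and tolerates missing alignments", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    '"Probe Set ID","Gene Symbol","RefSeq Transcript ID","Ensembl","Entrez Gene","Alignments"',
    '"p1","TP53","NM_0001 /// NM_0002","---","7157","chr17:100-200 (+) // 95 // direct"',
    '"p2","BRCA1 /// BRCA2","---","ENSG01","---","---"',
    '"p3","---","---","---","---","chr1:50-80 (-)"'), path)
  tab <- parseProbeAnnotation(path)
  expect_equal(tab@probeIds, c("p1", "p2", "p3"))
  expect_equal(as.list(tab@refseqIds)[[1]], c("NM_0001", "NM_0002"))
  expect_equal(as.list(tab@geneSymbols)[[2]], c("BRCA1", "BRCA2"))
  expect_equal(lengths(tab@alignments), c(p1 = 1L, p2 = 0L, p3 = 1L),
               ignore_attr = TRUE)
  a1 <- tab@alignments[[1]]
  expect_equal(c(GenomicRanges::start(a1), GenomicRanges::end(a1)),
               c(100L, 200L))
  expect_equal(as.character(GenomicRanges::strand(tab@alignments[[3]])),
               "-")
})

test_that("annotation parsing errors and warnings follow the contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"Wrong","Alignments"', '"x","chr1:1-10 (+)"'), path)
  expect_error(parseProbeAnnotation(path), "probe-ID column")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"Probe Set ID","Alignments"',
               '"p1","chr1:10-5 (+) /// chr1:100-160 (+)"'), path2)
  expect_warning(tab <- parseProbeAnnotation(path2), "unparseable")
  expect_equal(length(tab@alignments[[1]]), 1L)  # bad one dropped, record kept
})

test_that("GTF parsing groups exons by gene and rejects exon-free files", {
  g <- makeGenes(c("g1", "g2"),
                 list(c(gr1(100, 200), gr1(300, 400)),
                      c(gr1(1000, 1100), gr1(1300, 1500))),
                 publicIds = list("SYM1", "SYM2"))
  path <- withr::local_tempfile(fileext = ".gtf")
  writeGtf(g, path)
  parsed <- parseGeneModels(path)
  expect_setequal(parsed@geneIds, c("g1", "g2"))
  expect_equal(unname(lengths(parsed@exons)), c(2L, 2L))
  expect_equal(GenomicRanges::start(parsed@exons[[match("g1", parsed@geneIds)]]),
               c(100L, 300L))
  # transcript-only file has no exon features
  path2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chrS", "src", "transcript", "1", "10", ".", "+", ".",
                   'gene_id "g1"; transcript_id "t";', sep = "\t"), path2)
  expect_error(parseGeneModels(path2), "no exon features")
})

test_that("synthetic fixture files round-trip to the generator's records", {
  dir <- withr::local_tempdir()
  fx <- generateAnnotationFixture(tinySpec(), seed = 7, dir = dir)
  annot <- parseProbeAnnotation(fx$files$annotation)
  genes <- parseGeneModels(fx$files$gtf)
  expect_equal(annot@probeIds, fx$annotation@probeIds)
  expect_equal(as.list(annot@geneSymbols), as.list(fx$annotation@geneSymbols),
               ignore_attr = TRUE)
  expect_setequal(genes@geneIds, fx$genes@geneIds)
  for (g in genes@geneIds)
    expect_equal(
      GenomicRanges::ranges(genes@exons[[match(g, genes@geneIds)]]),
      GenomicRanges::ranges(fx$genes@exons[[match(g, fx$genes@geneIds)]]),
      ignore_attr = TRUE)
  # and the parsed files reproduce the planted mapping exactly
  mp <- mapPlatforms(annot, genes, "location")
  expect_identical(mappingGroups(mp, "probe"),
                   mappingGroups(fx$expected, "probe"))
  expect_identical(mappingGroups(mp, "gene"),
                   mappingGroups(fx$expected, "gene"))
})

test_that("ID mapping matches a brute-force set-intersection scan", {
  expect_equal(nrow(mapByGeneId(makeAnnot(character(), list()),
                                makeGenes("g1", list(gr1(1, 10))))), 0L)
  annot <- makeAnnot("p1", list(GenomicRanges::GRanges()),
                     symbols = list("TP53"))
  genes <- makeGenes("g1", list(gr1(1, 10)), publicIds = list("TP53"))
  ed <- mapByGeneId(annot, genes)
  expect_equal(ed$probe_id, "p1")
  expect_equal(ed$id_type, "symbol")
  # random overlapping ID sets vs exhaustive double loop
  set.seed(31)
  for (rep in 1:5) {
    universe <- paste0("ID", 1:8)
    psets <- replicate(5, sample(universe, sample(0:3, 1)), simplify = FALSE)
    gsets <- replicate(4, sample(universe, sample(0:3, 1)), simplify = FALSE)
    annot <- makeAnnot(paste0("p", 1:5),
                       rep(list(GenomicRanges::GRanges()), 5),
                       symbols = psets)
    genes <- makeGenes(paste0("g", 1:4),
                       rep(list(GenomicRanges::GRanges()), 4),
                       publicIds = gsets)
    got <- mapByGeneId(annot, genes)
    got <- got[order(got$probe_id, got$gene_id), c("probe_id", "gene_id")]
    want <- do.call(rbind, lapply(1:5, function(i) do.call(rbind, lapply(
      1:4, function(j)
        if (length(intersect(toupper(psets[[i]]), toupper(gsets[[j]]))))
          data.frame(probe_id = paste0("p", i), gene_id = paste0("g", j))))))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$probe_id, want$gene_id), ]
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("ID matching is case-insensitive and version-stripped", {
  annot <- makeAnnot("p1", list(GenomicRanges::GRanges()),
                     symbols = list("nm_0001.2"))
  genes <- makeGenes("g1", list(gr1(1, 10)), publicIds = list("NM_0001"))
  expect_equal(nrow(mapByGeneId(annot, genes)), 1L)
})

test_that("location mapping honours the strict 40 bp and two-exon rules", {
  genes <- makeGenes("g1", list(c(gr1(100, 400), gr1(1000, 1400))))
  edge41 <- mapByLocation(makeAnnot("p", list(gr1(100, 140))), genes)
  expect_equal(nrow(edge41), 1L)       # overlap 41 > 40
  expect_equal(edge41$overlap_bp, 41L)
  edge40 <- mapByLocation(makeAnnot("p", list(gr1(100, 139))), genes)
  expect_equal(nrow(edge40), 0L)       # exactly 40: strict inequality
  # 10 bp on each of two exons trips the multi-exon rule
  twoEx <- mapByLocation(
    makeAnnot("p", list(c(gr1(391, 400), gr1(1000, 1009)))), genes)
  expect_equal(nrow(twoEx), 1L)
  expect_equal(twoEx$n_exons_hit, 2L)
  # strand mismatch blocks the edge unless strands are unknown
  minus <- makeAnnot("p", list(gr1(100, 200, strand = "-")))
  expect_equal(nrow(mapByLocation(minus, genes)), 0L)
  expect_equal(nrow(mapByLocation(
    minus, genes, locationMappingParams(requireSameStrand = FALSE))), 1L)
  star <- makeAnnot("p", list(gr1(100, 200, strand = "*")))
  expect_equal(nrow(mapByLocation(star, genes)), 1L)
})

test_that("location mapping equals the brute-force all-pairs scan on random instances", {
  for (seed in c(3, 17, 29)) {
    fx <- generateAnnotationFixture(
      fixtureSpec(nProbes = c(A = 5, B = 4, C = 3, D = 3), nSamples = 8,
                  nSignal = 2), seed = seed)
    got <- mapByLocation(fx$annotation, fx$genes)
    got <- got[order(got$probe_id, got$gene_id), c("probe_id", "gene_id")]
    want <- bruteLocationMap(fx$annotation, fx$genes)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("group classification follows the degree rules of the mapping table", {
  edges <- data.frame(probe_id = c("p1", "p2", "p3", "p5", "p5"),
                      gene_id = c("g1", "g2", "g2", "g3", "g4"),
                      evidence = "id", id_type = "symbol",
                      overlap_bp = NA_integer_, n_exons_hit = NA_integer_)
  mp <- classifyMappingGroups(edges, paste0("p", 1:5), paste0("g", 1:5))
  pg <- mappingGroups(mp, "probe"); gg <- mappingGroups(mp, "gene")
  expect_equal(unname(pg[c("p1", "p2", "p3", "p4", "p5")]),
               c("A", "B", "B", "D", "C"))
  expect_equal(unname(gg[c("g1", "g2", "g3", "g4", "g5")]),
               c("A", "C", "B", "B", "D"))
  expect_error(
    classifyMappingGroups(data.frame(probe_id = "nope", gene_id = "g1",
                                     evidence = "id", id_type = "symbol",
                                     overlap_bp = NA, n_exons_hit = NA),
                          "p1", "g1"),
    "unknown")
})

test_that("groups partition each side and B edges terminate in the other side's C", {
  for (seed in c(5, 13)) {
    fx <- generateAnnotationFixture(tinySpec(), seed = seed)
    mp <- mapPlatforms(fx$annotation, fx$genes, "location")
    for (side in c("probe", "gene")) {
      gr <- mappingGroups(mp, side)
      universe <- if (side == "probe") fx$annotation@probeIds
                  else fx$genes@geneIds
      expect_setequal(names(gr), universe)  # partition: all features, once
    }
    ed <- mappingEdges(mp)
    pg <- mappingGroups(mp, "probe"); gg <- mappingGroups(mp, "gene")
    bEdges <- ed[pg[ed$probe_id] == "B", ]
    expect_true(all(gg[bEdges$gene_id] == "C"))
    gB <- ed[gg[ed$gene_id] == "B", ]
    expect_true(all(pg[gB$probe_id] == "C"))
    expect_true(all(lengths(split(ed$gene_id, ed$probe_id))[
      names(pg)[pg == "D"]] == 0, na.rm = TRUE))
  }
})

test_that("mapping is deterministic under record reordering", {
  fx <- generateAnnotationFixture(tinySpec(), seed = 9)
  mp1 <- mapPlatforms(fx$annotation, fx$genes, "location")
  perm <- rev(seq_along(fx$annotation@probeIds))
  shuffled <- new("ProbeAnnotation",
                  probeIds = fx$annotation@probeIds[perm],
                  geneSymbols = fx$annotation@geneSymbols[perm],
                  refseqIds = fx$annotation@refseqIds[perm],
                  ensemblIds = fx$annotation@ensemblIds[perm],
                  entrezIds = fx$annotation@entrezIds[perm],
                  alignments = fx$annotation@alignments[perm])
  mp2 <- mapPlatforms(shuffled, fx$genes, "location")
  expect_identical(mappingEdges(mp1), mappingEdges(mp2))
  expect_identical(mappingGroups(mp1, "probe")[names(mappingGroups(mp2, "probe"))],
                   mappingGroups(mp2, "probe"))
})

test_that("per-sample Spearman concordance hits its closed-form endpoints", {
  st <- getTinyStudy()
  # identical values on both platforms give r = 1 per sample
  ed <- mappingEdges(st$mapping)
  pg <- mappingGroups(st$mapping, "probe")
  pa <- names(pg)[pg == "A"]
  ga <- ed$gene_id[match(pa, ed$probe_id)]
  vals <- exprValues(st$rnaseq)[ga, , drop = FALSE]
  rownames(vals) <- pa
  twin <- PlatformMatrix(vals, "microarray", "log2_intensity")
  sc <- spearmanConcordance(twin, st$rnaseq, st$mapping, "A")
  expect_equal(unname(sc$perSample), rep(1, ncol(vals)))
  # anti-ranked values give r = -1
  anti <- PlatformMatrix(-vals, "microarray", "log2_intensity")
  expect_equal(unname(spearmanConcordance(anti, st$rnaseq, st$mapping,
                                          "A")$perSample),
               rep(-1, ncol(vals)))
  # monotone distortion preserves ranks exactly
  mono <- PlatformMatrix(vals^3, "microarray", "log2_intensity")
  expect_equal(unname(spearmanConcordance(mono, st$rnaseq, st$mapping,
                                          "A")$perSample),
               rep(1, ncol(vals)))
  expect_error(spearmanConcordance(
    PlatformMatrix(vals[1:2, , drop = FALSE], "microarray",
                   "log2_intensity"),
    st$rnaseq, st$mapping, "A"), "insufficient")
})
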