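# Signature resolution, untrained counterparts, and both assessment levels.

makeTwinPair <- function(st) {
  # a degenerate twin platform: array values copied onto the gene ids
  ed <- mappingEdges(st$mapping)
  pg <- mappingGroups(st$mapping, "probe")
  pa <- names(pg)[pg == "A"]
  ga <- ed$gene_id[match(pa, ed$probe_id)]
  rnaA <- subsetByGroup(st$rnaseq, st$mapping, "A")
  twin <- exprValues(rnaA)[ga, , drop = FALSE]
  rownames(twin) <- pa
  list(arr = PlatformMatrix(twin, "microarray", "log2_intensity"),
       rna = rnaA, probes = pa, genes = ga)
}

test_that("signature resolution preserves order, length and policies", {
  st <- getTinyStudy()
  ed <- mappingEdges(st$mapping)
  pg <- mappingGroups(st$mapping, "probe")
  rna <- st$rnaseq
  # group A: bijection, order preserved
  pa <- head(names(pg)[pg == "A"], 4)
  got <- resolveSignature(pa, st$mapping, "array2rnaseq", rna)
  expect_equal(got, ed$gene_id[match(pa, ed$probe_id)])
  # two B probes sharing one gene: the gene appears twice
  pb <- names(pg)[pg == "B"]
  gb <- ed$gene_id[match(pb, ed$probe_id)]
  shared <- names(which(table(gb) > 1))[1]
  two <- pb[gb == shared][1:2]
  expect_equal(resolveSignature(two, st$mapping, "array2rnaseq", rna),
               rep(shared, 2))
  # group C: candidate with the highest target-training mean wins
  pc <- names(pg)[pg == "C"][1]
  cand <- sort(ed$gene_id[ed$probe_id == pc])
  mu <- rowMeans(exprValues(rna))[cand]
  expect_equal(resolveSignature(pc, st$mapping, "array2rnaseq", rna),
               cand[which.max(mu)])
  expect_equal(resolveSignature(pc, st$mapping, "array2rnaseq",
                                policy = "first_id"), cand[1])
  # group D feature: hard error
  pd <- names(pg)[pg == "D"][1]
  expect_error(resolveSignature(c(pa[1], pd), st$mapping, "array2rnaseq",
                                rna), "group D")
})

test_that("untrained counterparts reuse parameters and round-trip over group A", {
  st <- getTinyStudy()
  arrA <- subsetByGroup(st$array, st$mapping, "A")
  rnaA <- subsetByGroup(st$rnaseq, st$mapping, "A")
  ens <- trainEnsemble(arrA, st$binary, "knn", group = "A", nSplits = 2,
                       masterSeed = 5)
  rec <- ensembleRecords(ens)[[1]]
  cp <- buildUntrainedCounterpart(rec, rnaA, st$binary, st$mapping,
                                  "array2rnaseq")
  expect_identical(cp@params, rec$params)             # same hyper-parameters
  expect_equal(length(cp@signature), length(rec$signature))
  expect_setequal(cp@trainSamples, partitionSamples(st$binary, "training"))
  # counterpart of the counterpart recovers the original signature
  recBack <- list(params = cp@params, signature = cp@fit$resolved,
                  model = cp)
  back <- buildUntrainedCounterpart(recBack, arrA, st$binary, st$mapping,
                                    "rnaseq2array")
  expect_equal(back@fit$resolved, rec$signature)
})

test_that("twin platforms give exact parity: T = mean accuracy, kappa = 1", {
  st <- getTinyStudy()
  tw <- makeTwinPair(st)
  ens <- trainEnsemble(tw$arr, st$binary, "knn", group = "A", nSplits = 3,
                       masterSeed = 8)
  sa <- signatureLevelAssessment(ens, tw$arr, tw$rna, tw$rna, st$binary,
                                 st$mapping, "array2rnaseq")
  m <- pairedMetrics(sa)
  expect_equal(m$source_acc, m$target_acc)
  expect_equal(m$kappa, rep(1, 3))
  expect_equal(transferIndex(sa), mean(m$source_acc))
  # model level on z-scored twins: identical predictions by construction
  zArr <- perSampleZscore(tw$arr); zRna <- perSampleZscore(tw$rna)
  ensZ <- trainEnsemble(zArr, st$binary, "knn", group = "A", nSplits = 3,
                        masterSeed = 8)
  ma <- modelLevelAssessment(ensZ, zArr, zRna, st$binary, st$mapping,
                             "array2rnaseq", "zscored")
  mm <- pairedMetrics(ma)
  expect_equal(mm$source_acc, mm$target_acc)
  expect_equal(mm$kappa, rep(1, 3))
  expect_equal(transferIndex(ma), mean(mm$source_acc))
})

test_that("signature-level transfer keeps ensemble size, algorithm and parameters", {
  st <- getTinyStudy()
  arrA <- subsetByGroup(st$array, st$mapping, "A")
  rnaA <- subsetByGroup(st$rnaseq, st$mapping, "A")
  ens <- trainEnsemble(arrA, st$binary, "nsc", group = "A", nSplits = 3,
                       masterSeed = 6)
  sa <- signatureLevelAssessment(ens, arrA, rnaA, rnaA, st$binary,
                                 st$mapping, "array2rnaseq")
  expect_equal(nrow(pairedMetrics(sa)), 3)
  expect_equal(sa@algorithm, "nsc")
  expect_equal(sa@level, "signature")
})

test_that("model-level transfer rejects group C and never refits the source model", {
  st <- getTinyStudy()
  arrC <- subsetByGroup(st$array, st$mapping, "C")
  zC <- perSampleZscore(arrC)
  ensC <- trainEnsemble(zC, st$binary, "knn", group = "C", nSplits = 2,
                        masterSeed = 4)
  rnaZ <- perSampleZscore(st$rnaseq)
  expect_error(modelLevelAssessment(ensC, zC, rnaZ, st$binary, st$mapping,
                                    "array2rnaseq", "zscored"),
               "group C")
  tw <- makeTwinPair(st)
  zArr <- perSampleZscore(tw$arr); zRna <- perSampleZscore(tw$rna)
  ens <- trainEnsemble(zArr, st$binary, "knn", group = "A", nSplits = 2,
                       masterSeed = 4)
  before <- lapply(ensembleRecords(ens), function(r) r$model@fit)
  expect_warning(
    modelLevelAssessment(ens, zArr, zRna, st$binary, st$mapping,
                         "array2rnaseq", "raw_log2"),
    "z-scoring")
  after <- lapply(ensembleRecords(ens), function(r) r$model@fit)
  expect_identical(before, after)  # fitted state untouched
})

test_that("group-B reverse transfer degrades at least as much as group A", {
  # gene-side B genes resolve to probes that mix several genes, so their
  # cross-platform concordance (and hence model-level transfer) is worse
  # than group A's; stochastic, so averaged over seeds
  probeMirror <- c(A = "A", B = "C")  # gene-side group -> paired probe group
  drops <- c(A = 0, B = 0)
  for (seed in c(77, 78)) {
    st <- generateStudy(
      fixtureSpec(nProbes = c(A = 30, B = 6, C = 16, D = 2),
                  nSamples = 120, nSignal = 9), seed = seed)
    for (g in c("A", "B")) {
      rnaG <- perSampleZscore(subsetByGroup(st$rnaseq, st$mapping, g))
      arrG <- perSampleZscore(subsetByGroup(st$array, st$mapping,
                                            probeMirror[[g]]))
      ens <- suppressWarnings(
        trainEnsemble(rnaG, st$binary, "knn", group = g, nSplits = 8,
                      masterSeed = seed))
      ma <- modelLevelAssessment(ens, rnaG, arrG, st$binary, st$mapping,
                                 "rnaseq2array", "zscored")
      s <- ma@summary
      drops[[g]] <- drops[[g]] + (s$meanSourceAcc - s$meanTargetAcc) / 2
    }
  }
  expect_gte(drops[["B"]] + 0.02, drops[["A"]])
})
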