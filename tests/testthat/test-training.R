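# Resampling protocol: splits, feature ranking, model selection, ensembles.

test_that("stratified 70/30 splits have the right per-class arithmetic", {
  y <- c(rep(1, 60), rep(0, 40))
  names(y) <- sprintf("s%03d", 1:100)
  sp <- stratifiedSplit(y, 0.7, seed = 5)
  expect_equal(sum(y[sp$inner] == 1), 42)
  expect_equal(sum(y[sp$inner] == 0), 28)
  expect_equal(sum(y[sp$holdout] == 1), 18)
  expect_equal(sum(y[sp$holdout] == 0), 12)
  expect_setequal(c(sp$inner, sp$holdout), names(y))
  expect_length(intersect(sp$inner, sp$holdout), 0)
  expect_identical(stratifiedSplit(y, 0.7, seed = 5), sp)
  expect_false(identical(stratifiedSplit(y, 0.7, seed = 6)$inner, sp$inner))
  expect_error(stratifiedSplit(c(a = 1, b = 0, c = 0), 0.7, 1),
               "fewer than 2")
  # proportions are preserved within rounding over many draws
  counts <- vapply(1:200, function(s) {
    sp <- stratifiedSplit(y, 0.7, seed = s)
    c(sum(y[sp$inner] == 1), length(sp$inner))
  }, numeric(2))
  expect_true(all(counts[1, ] == 42) && all(counts[2, ] == 70))
})

test_that("feature ranking applies the P < 0.05 filter then orders by |FC|", {
  set.seed(40)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("f%02d", 1:20), paste0("s", 1:n)))
  X["f07", y == 1] <- X["f07", y == 1] + 3   # planted strong feature
  ranked <- rankCandidateFeatures(X, y)
  expect_equal(ranked[1], "f07")
  # identical class means: excluded
  Xc <- rbind(X, flat = rep(c(1, 2), n / 2))
  expect_false("flat" %in% rankCandidateFeatures(Xc, y))
  # equal |FC| ties resolve lexicographically by id
  Xt <- matrix(rep(c(0, 1), each = 6, times = 2), 2, 12, byrow = TRUE,
               dimnames = list(c("zb", "aa"), paste0("s", 1:12)))
  Xt <- Xt + matrix(rnorm(24, sd = 0.01), 2, 12)
  Xt["aa", ] <- Xt["zb", ] + 0.5  # same class difference, distinct ids
  yt <- rep(c(0, 1), each = 6)
  r <- rankCandidateFeatures(Xt, yt)
  expect_equal(r, sort(r))
  # oracle agreement with direct t.test / mean-difference computation
  want <- sapply(rownames(X), function(f) {
    tt <- t.test(X[f, y == 1], X[f, y == 0])
    c(p = tt$p.value, fc = abs(mean(X[f, y == 1]) - mean(X[f, y == 0])))
  })
  keep <- colnames(want)[want["p", ] < 0.05]
  keep <- keep[order(-want["fc", keep], keep)]
  expect_equal(ranked, keep)
})

test_that("model selection enumerates the grid and applies the stated tie-breaks", {
  toy <- separableToy(nFeat = 6, nPerClass = 10, gap = 4, seed = 50)
  sp <- stratifiedSplit(toy$y, 0.7, seed = 1)
  grid <- list(list(k = 1), list(k = 3))
  sel <- selectBestModel(toy$X, toy$y, sp, "knn", paramGrid = grid,
                         maxFeatures = 6)
  # independent exhaustive evaluation over (params x sizes)
  ranked <- rankCandidateFeatures(toy$X[, sp$inner], toy$y[sp$inner])
  accs <- expand.grid(k = c(1, 3), s = seq(2, min(6, length(ranked)), 2))
  accs$acc <- mapply(function(k, s) {
    sig <- ranked[1:s]
    m <- fitClassifier("knn", list(k = k), toy$X[sig, sp$inner], toy$y[sp$inner],
                       signature = sig)
    binaryAccuracy(predictWithScores(m, toy$X[sig, sp$holdout])$label,
                   toy$y[sp$holdout])
  }, accs$k, accs$s)
  expect_equal(sel$holdout_acc, max(accs$acc))
  best <- accs[accs$acc == max(accs$acc), ]
  expect_equal(length(sel$signature), min(best$s))
  expect_equal(sel$params$k, min(best$k[best$s == min(best$s)]))
  # separable toy: perfect holdout, ties resolve to 2 features and k = 1
  expect_equal(sel$holdout_acc, 1)
  expect_equal(length(sel$signature), 2)
  expect_equal(sel$params$k, 1)
})

test_that("ensembles refit the winner on all training samples, reproducibly", {
  st <- getTinyStudy()
  arrA <- subsetByGroup(st$array, st$mapping, "A")
  ens <- trainEnsemble(arrA, st$binary, "knn", group = "A", nSplits = 4,
                       masterSeed = 3)
  trIds <- partitionSamples(st$binary, "training")
  for (rec in ensembleRecords(ens)) {
    expect_setequal(rec$model@trainSamples, trIds)   # refit on ALL training
    expect_true(length(rec$signature) %% 2 == 0)
    expect_true(length(rec$signature) <= 100)
    expect_true(rec$holdout_acc >= 0 && rec$holdout_acc <= 1)
  }
  ens2 <- trainEnsemble(arrA, st$binary, "knn", group = "A", nSplits = 4,
                        masterSeed = 3)
  expect_identical(lapply(ensembleRecords(ens), `[[`, "signature"),
                   lapply(ensembleRecords(ens2), `[[`, "signature"))
  expect_identical(vapply(ensembleRecords(ens), `[[`, 0, "holdout_acc"),
                   vapply(ensembleRecords(ens2), `[[`, 0, "holdout_acc"))
})

test_that("a separable toy yields perfect holdout accuracy in every record", {
  toy <- separableToy(nFeat = 8, nPerClass = 20, gap = 5, seed = 60)
  part <- setNames(rep("training", length(toy$y)), names(toy$y))
  ep <- endpointDefinition("toy", "binary", labels = toy$y, partition = part)
  X <- PlatformMatrix(toy$X, "microarray", "log2_intensity")
  ens <- trainEnsemble(X, ep, "knn", nSplits = 3, masterSeed = 2)
  expect_equal(vapply(ensembleRecords(ens), `[[`, 0, "holdout_acc"),
               rep(1, 3))
})

test_that("ensemble evaluation summarizes per-model metrics with percentile CIs", {
  st <- getTinyStudy()
  arrA <- subsetByGroup(st$array, st$mapping, "A")
  ens <- trainEnsemble(arrA, st$binary, "knn", group = "A", nSplits = 4,
                       masterSeed = 3)
  ev <- evaluateEnsemble(ens, arrA, st$binary)
  expect_equal(nrow(ev$perModel), 4)
  expect_true(all(ev$ciAccuracy >= min(ev$perModel$accuracy) &
                  ev$ciAccuracy <= max(ev$perModel$accuracy)))
  expect_equal(ev$meanAccuracy, mean(ev$perModel$accuracy))
  # invariant to validation sample order
  v <- exprValues(arrA)
  shuf <- PlatformMatrix(v[, rev(seq_len(ncol(v)))], "microarray",
                         "log2_intensity")
  ev2 <- evaluateEnsemble(ens, shuf, st$binary)
  expect_equal(ev2$perModel, ev$perModel)
})
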