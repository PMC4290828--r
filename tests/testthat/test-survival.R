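# Cox workflow: filters, concordance index, forward selection, transfer.

test_that("the median-intensity filter keeps features above the global median", {
  X <- rbind(lo = rep(2, 9), mid = rep(5, 9), hi = rep(9, 9))
  colnames(X) <- paste0("s", 1:9)
  expect_equal(medianIntensityFilter(X), "hi")
  allEq <- matrix(4, 3, 5, dimnames = list(c("a", "b", "c"), paste0("s", 1:5)))
  expect_length(medianIntensityFilter(allEq), 0)  # strict inequality
  X2 <- rbind(low = rnorm(20, 0), high = rnorm(20, 10))
  colnames(X2) <- paste0("s", 1:20)
  expect_true("high" %in% medianIntensityFilter(X2))
})

test_that("the concordance index hits 1, 0 and 0.5 at its defining extremes", {
  t <- c(5, 4, 3, 2, 1); e <- rep(1, 5)
  expect_equal(concordanceIndex(c(1, 2, 3, 4, 5), t, e)$c, 1)  # perfect
  expect_equal(concordanceIndex(c(5, 4, 3, 2, 1), t, e)$c, 0)  # anti-perfect
  set.seed(81)
  n <- 500
  tt <- rexp(n); ee <- rbinom(n, 1, 0.7); rr <- rnorm(n)
  ci <- concordanceIndex(rr, tt, ee)
  expect_lt(abs(ci$c - 0.5), 0.05)
  expect_gt(ci$p, 0.01)
  # complement identity on event-complete data
  ci1 <- concordanceIndex(rr[1:50], tt[1:50], rep(1, 50))
  ci2 <- concordanceIndex(-rr[1:50], tt[1:50], rep(1, 50))
  expect_equal(ci1$c + ci2$c, 1)
})

test_that("the concordance index agrees with the survival package on censored data", {
  set.seed(82)
  n <- 80
  tt <- rexp(n); ee <- rbinom(n, 1, 0.6); rr <- round(rnorm(n), 1)
  ours <- concordanceIndex(rr, tt, ee)$c
  ref <- survival::concordance(survival::Surv(tt, ee) ~ rr,
                               reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("gene ranking keeps P < 0.01 genes ordered by |c - 0.5|", {
  set.seed(83)
  n <- 120
  lat <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  h <- 0.1 * exp(1.5 * lat["g3", ])
  tt <- rexp(n, h); ee <- rep(1, n)
  ranked <- rankGenesByCindex(lat, tt, ee)
  expect_equal(ranked$gene[1], "g3")
  expect_true(all(ranked$p < 0.01))
  # a pure-noise gene is excluded at this n
  expect_false("g1" %in% ranked$gene && nrow(ranked) == 5)
  # ties resolve by id: duplicated rows have identical c
  dup <- lat[c("g3", "g3"), ]
  rownames(dup) <- c("zz", "aa")
  r2 <- rankGenesByCindex(dup, tt, ee)
  expect_equal(r2$gene, c("aa", "zz"))
})

test_that("LOOCV forward selection keeps the informative gene and honours maxGenes", {
  set.seed(84)
  n <- 60
  lat <- matrix(rnorm(4 * n), 4, n,
                dimnames = list(c("signal", "n1", "n2", "n3"),
                                paste0("s", 1:n)))
  h <- 0.1 * exp(1.2 * lat["signal", ])
  tt <- rexp(n, h); ee <- rep(1, n)
  ranked <- rankGenesByCindex(lat, tt, ee, alpha = 0.5)  # keep noise in list
  sel <- loocvForwardSelect(lat, tt, ee, ranked$gene)
  expect_true("signal" %in% sel$signature)
  top <- loocvForwardSelect(lat, tt, ee, ranked$gene, maxGenes = 1)
  expect_equal(top$signature, ranked$gene[1])
  empty <- loocvForwardSelect(lat, tt, ee, character())
  expect_length(empty$signature, 0)
  # the final LOOCV c never falls below that of the first accepted gene
  first <- loocvForwardSelect(lat, tt, ee, ranked$gene[1], maxGenes = 1)
  expect_gte(sel$cLoocv, first$cLoocv)
})

test_that("the final Cox fit recovers a planted hazard and respects invariances", {
  set.seed(85)
  n <- 200
  lat <- matrix(rnorm(2 * n), 2, n,
                dimnames = list(c("b1", "noise"), paste0("s", 1:n)))
  h <- 0.1 * exp(lat["b1", ])
  tt <- rexp(n, h); ee <- rep(1, n)
  fit <- fitFinalCox(lat["b1", , drop = FALSE], tt, ee)
  expect_lt(abs(fit@coefficients[["b1"]] - 1), 0.35)
  expect_gt(fit@cTrain, 0.6)
  expect_error(fitFinalCox(lat, tt, rep(0, n)), "censored")
  # affine rescaling of a gene rescales the coefficient inversely
  lat2 <- lat; lat2["b1", ] <- 10 * lat2["b1", ] + 3
  fit2 <- fitFinalCox(lat2["b1", , drop = FALSE], tt, ee)
  expect_equal(fit2@coefficients[["b1"]], fit@coefficients[["b1"]] / 10,
               tolerance = 1e-6)
})

test_that("the paired concordance comparison behaves like a one-sided test", {
  set.seed(86)
  n <- 100
  tt <- rexp(n); ee <- rep(1, n)
  r <- rnorm(n)
  expect_equal(compareCindex(r, r, tt, ee)$p, 0.5)
  perfect <- -tt  # higher risk fails first
  noise <- rnorm(n)
  cmp <- compareCindex(perfect, noise, tt, ee)
  expect_lt(cmp$p, 0.01)
  rev <- compareCindex(noise, perfect, tt, ee)
  expect_equal(rev$p, 1 - cmp$p, tolerance = 1e-10)
})

test_that("twin-platform Cox transfer is exactly symmetric", {
  st <- getTinyStudy()
  rnaA <- subsetByGroup(st$rnaseq, st$mapping, "A")
  # a degenerate twin: the array side holds the same values under probe ids
  ed <- mappingEdges(st$mapping)
  pg <- mappingGroups(st$mapping, "probe")
  pa <- names(pg)[pg == "A"]
  ga <- ed$gene_id[match(pa, ed$probe_id)]
  twin <- exprValues(rnaA)[ga, , drop = FALSE]
  rownames(twin) <- pa
  twinM <- PlatformMatrix(twin, "microarray", "log2_intensity")
  res <- coxTransfer("signature", twinM, twinM, rnaA, rnaA, st$survival,
                     st$mapping, "array2rnaseq", group = "A", maxGenes = 3)
  expect_equal(res$source@cValid, res$target@cValid, tolerance = 1e-10)
  expect_equal(res$comparison$p, 0.5, tolerance = 1e-10)
  expect_error(coxTransfer("model", twinM, twinM, rnaA, rnaA, st$survival,
                           st$mapping, "array2rnaseq", group = "C"),
               "group C")
})
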