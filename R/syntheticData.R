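# Synthetic paired-platform study generator: annotation fixtures with
# planted mapping groups, paired expression with group-dependent
# cross-platform concordance, and binary/survival endpoints of tunable
# difficulty. Every generator is a pure function of (spec, seed).

#' Specification of a synthetic paired-platform study
#'
#' Defaults emulate the study conditions the pipeline targets: per-feature
#' cross-platform Spearman concordance of 0.87 / 0.60 / 0.54 for mapping
#' groups A / B / C, a systematic additive offset between the platforms'
#' log2 scales, predefined stratified train/validation splits, and planted
#' differential / hazard genes.
#'
#' @param nProbes named integer vector: planted probe counts per group
#'   (default A = 120, B = 60, C = 40, D = 20).
#' @param genesPerC genes each group-C probe spans (default 2).
#' @param probesPerBGene probes sharing each B-side gene (default 2).
#' @param nDGenes unmapped genes on the RNA-seq side (default 12).
#' @param exonLen,intronLen,geneGap integer ranges (length-2) for the
#'   synthetic gene geometry in bp.
#' @param nSamples number of paired samples (default 300).
#' @param concordance named Spearman targets per group (defaults 0.87,
#'   0.60, 0.54).
#' @param platformShift additive offset of array log2 intensities relative
#'   to RNA-seq log2 counts (default 3).
#' @param rnaseqNoiseSd platform noise s.d. on the RNA-seq side (default
#'   0.25); array-side noise is calibrated per group against
#'   \code{concordance}.
#' @param nSignal number of differential genes planted for the binary
#'   endpoint (default 12, spread evenly over gene-side groups A/B/C).
#' @param delta class-1 mean shift of signal genes in latent s.d. units
#'   (default 1.5).
#' @param balance class-1 fraction (default 0.5).
#' @param trainFrac training fraction of the predefined partition
#'   (default 0.5).
#' @param baselineHazard exponential baseline hazard (default 0.1).
#' @param beta named log-hazard coefficients for the survival endpoint, or
#'   NULL to plant a single beta = 1 gene.
#' @param censRate target independent-censoring fraction in [0, 1)
#'   (default 0.3).
#' @return validated spec list.
#' @export
fixtureSpec <- function(nProbes = c(A = 120, B = 60, C = 40, D = 20),
                        genesPerC = 2, probesPerBGene = 2, nDGenes = 12,
                        exonLen = c(100, 300), intronLen = c(100, 400),
                        geneGap = c(500, 1500),
                        nSamples = 300,
                        concordance = c(A = 0.87, B = 0.60, C = 0.54),
                        platformShift = 3, rnaseqNoiseSd = 0.25,
                        nSignal = 12, delta = 1.5, balance = 0.5,
                        trainFrac = 0.5,
                        baselineHazard = 0.1, beta = NULL, censRate = 0.3) {
  stopifnot(all(c("A", "B", "C", "D") %in% names(nProbes)),
            all(nProbes >= 0), genesPerC >= 2, probesPerBGene >= 2,
            nSamples >= 4,
            all(concordance > 0 & concordance <= 1),
            censRate >= 0, censRate < 1,
            balance > 0, balance < 1, trainFrac > 0, trainFrac < 1,
            delta >= 0)
  if (nProbes[["B"]] %% probesPerBGene != 0)
    stop("nProbes['B'] must be a multiple of probesPerBGene")
  as.list(environment())
}

.fmtAln <- function(gr) {
  sprintf("%s:%d-%d (%s)", as.character(seqnames(gr)), start(gr), end(gr),
          as.character(strand(gr)))
}

#' Write a ProbeAnnotation as a NetAffx-style CSV
#'
#' @param annot a \linkS4class{ProbeAnnotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationCsv <- function(annot, path) {
  join <- function(cl) vapply(cl, function(x)
    if (length(x)) paste(x, collapse = " /// ") else "---", "")
  alns <- vapply(seq_along(annot@probeIds), function(i) {
    gr <- annot@alignments[[i]]
    if (length(gr) == 0) "---"
    else paste(.fmtAln(gr), collapse = " /// ")
  }, "")
  df <- data.frame(check.names = FALSE,
    `Probe Set ID` = annot@probeIds,
    `Gene Symbol` = join(annot@geneSymbols),
    `RefSeq Transcript ID` = join(annot@refseqIds),
    `Ensembl` = join(annot@ensemblIds),
    `Entrez Gene` = join(annot@entrezIds),
    `Alignments` = alns)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write GeneModels as a GTF file
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param path output path (.gtf).
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(genes, path) {
  ex <- unlist(genes@exons, use.names = FALSE)
  gid <- rep(genes@geneIds, lengths(genes@exons))
  pub <- vapply(genes@publicIds, function(x)
    if (length(x)) x[1] else NA_character_, "")
  gname <- rep(pub, lengths(genes@exons))
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = "xplat_synthetic", type = "exon", gene_id = gid,
    gene_name = gname,
    transcript_id = paste0(gid, ".t1"))
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

# One synthetic gene: exons laid left-to-right from `cursor`.
.makeGene <- function(cursor, nExons, spec, strand = "+") {
  starts <- ends <- integer(nExons)
  for (j in seq_len(nExons)) {
    len <- sample(spec$exonLen[1]:spec$exonLen[2], 1)
    starts[j] <- cursor
    ends[j] <- cursor + len - 1L
    cursor <- ends[j] + sample(spec$intronLen[1]:spec$intronLen[2], 1)
  }
  list(gr = GRanges("chrS", IRanges(starts, ends), strand = strand),
       nextCursor = max(ends) + sample(spec$geneGap[1]:spec$geneGap[2], 1))
}

# Probe alignment inside one exon with overlap > 40 bp.
.alignInExon <- function(exon, overlap = 60L) {
  w <- width(exon)
  ov <- min(overlap, w)
  GRanges(as.character(seqnames(exon)),
          IRanges(start(exon), start(exon) + ov - 1L),
          strand = as.character(strand(exon)))
}

#' Generate an annotation fixture with planted mapping groups
#'
#' Lays probes and genes out on one synthetic chromosome so that location
#' mapping under the default parameters reproduces exactly the planted
#' group memberships: group-A probes overlap a single exon of their own
#' gene by > 40 bp; group-B probes share one gene (several probes per
#' gene); group-C probes carry one alignment per spanned gene; group-D
#' probes have no alignments or align to a gene-free region. Probe ID
#' annotations mirror the planted gene symbols so that ID mapping yields
#' the same groups. The expected \linkS4class{MappingResult} is returned
#' as the test oracle.
#'
#' @param spec a [fixtureSpec()].
#' @param seed RNG seed.
#' @param dir optional directory; when given, the annotation CSV
#'   (\code{annotation.csv}) and GTF (\code{genes.gtf}) are written there.
#' @return list: \code{annotation} (\linkS4class{ProbeAnnotation}),
#'   \code{genes} (\linkS4class{GeneModels}), \code{expected}
#'   (\linkS4class{MappingResult}), \code{files} (paths or NULL).
#' @export
generateAnnotationFixture <- function(spec = fixtureSpec(), seed = 1,
                                      dir = NULL) {
  withSeed(deriveSeed(seed, 101), {
    cursor <- 1000L
    geneIds <- character(); exons <- list(); syms <- list()
    probeIds <- character(); pSyms <- list(); pRefs <- list()
    pAlns <- list()
    edgesP <- character(); edgesG <- character()
    gi <- 0L; pi <- 0L
    addGene <- function(nExons, strand = "+") {
      gi <<- gi + 1L
      g <- .makeGene(cursor, nExons, spec, strand)
      cursor <<- g$nextCursor
      id <- sprintf("G%04d", gi)
      geneIds <<- c(geneIds, id)
      exons[[id]] <<- g$gr
      syms[[id]] <<- c(sprintf("SYM%04d", gi), sprintf("NM_%06d", gi))
      id
    }
    addProbe <- function(alns, symbols, refseqs) {
      pi <<- pi + 1L
      id <- sprintf("P%05d", pi)
      probeIds <<- c(probeIds, id)
      pAlns[[id]] <<- alns
      pSyms[[id]] <<- symbols
      pRefs[[id]] <<- refseqs
      id
    }
    # group A: one probe <-> one gene
    for (i in seq_len(spec$nProbes[["A"]])) {
      g <- addGene(sample(2:4, 1))
      ex1 <- exons[[g]][sample(length(exons[[g]]), 1)]
      p <- addProbe(.alignInExon(ex1, sample(45:120, 1)),
                    syms[[g]][1], syms[[g]][2])
      edgesP <- c(edgesP, p); edgesG <- c(edgesG, g)
    }
    # group B (probe side): several probes share one gene
    nBGenes <- spec$nProbes[["B"]] / spec$probesPerBGene
    for (i in seq_len(nBGenes)) {
      g <- addGene(max(spec$probesPerBGene, sample(2:4, 1)))
      for (j in seq_len(spec$probesPerBGene)) {
        ex1 <- exons[[g]][j]
        p <- addProbe(.alignInExon(ex1, sample(45:120, 1)),
                      syms[[g]][1], syms[[g]][2])
        edgesP <- c(edgesP, p); edgesG <- c(edgesG, g)
      }
    }
    # group C (probe side): one probe spans several genes
    for (i in seq_len(spec$nProbes[["C"]])) {
      gs <- vapply(seq_len(spec$genesPerC), function(j)
        addGene(sample(2:3, 1)), "")
      alns <- do.call(c, lapply(gs, function(g)
        .alignInExon(exons[[g]][1], sample(45:120, 1))))
      p <- addProbe(alns,
                    vapply(gs, function(g) syms[[g]][1], ""),
                    vapply(gs, function(g) syms[[g]][2], ""))
      edgesP <- c(edgesP, rep(p, length(gs))); edgesG <- c(edgesG, gs)
    }
    # group D probes: unmappable (no alignment, or a gene-free region)
    for (i in seq_len(spec$nProbes[["D"]])) {
      if (i %% 2 == 0) {
        addProbe(GRanges(), sprintf("ORPHAN%04d", i), character())
      } else {
        aln <- GRanges("chrS", IRanges(cursor, cursor + 59L), strand = "+")
        cursor <- cursor + sample(spec$geneGap[1]:spec$geneGap[2], 1)
        addProbe(aln, sprintf("ORPHAN%04d", i), character())
      }
    }
    # group D genes: no probes
    for (i in seq_len(spec$nDGenes)) addGene(sample(2:4, 1))

    annot <- new("ProbeAnnotation", probeIds = probeIds,
                 geneSymbols = CharacterList(pSyms[probeIds]),
                 refseqIds = CharacterList(pRefs[probeIds]),
                 ensemblIds = CharacterList(rep(list(character()),
                                                length(probeIds))),
                 entrezIds = CharacterList(rep(list(character()),
                                               length(probeIds))),
                 alignments = GRangesList(pAlns[probeIds]))
    genes <- new("GeneModels", geneIds = geneIds,
                 publicIds = CharacterList(syms[geneIds]),
                 exons = GRangesList(exons[geneIds]))
    expected <- classifyMappingGroups(
      .newEdges(edgesP, edgesG, rep("location", length(edgesP)),
                rep(NA_character_, length(edgesP)),
                rep(NA_integer_, length(edgesP)),
                rep(NA_integer_, length(edgesP))),
      probeIds, geneIds, locationMappingParams())
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(annotation = file.path(dir, "annotation.csv"),
                    gtf = file.path(dir, "genes.gtf"))
      writeAnnotationCsv(annot, files$annotation)
      writeGtf(genes, files$gtf)
    }
    list(annotation = annot, genes = genes, expected = expected,
         files = files)
  })
}

# Mean per-sample Spearman between probe rows and gene rows over pairs.
.pairSpearman <- function(probeVals, geneVals, pairs) {
  X <- probeVals[pairs$probe_id, , drop = FALSE]
  Y <- geneVals[pairs$gene_id, , drop = FALSE]
  mean(vapply(seq_len(ncol(X)), function(j)
    stats::cor(X[, j], Y[, j], method = "spearman"), numeric(1)))
}

#' Generate paired-platform expression matrices
#'
#' A latent gene x sample matrix (gene means ~ N(7, 2), per-sample
#' deviations ~ N(0, 1)) drives both platforms. Each RNA-seq gene reads
#' its own latent; each array probe reads the mean of its mapped genes'
#' latents, offset by \code{platformShift}. Both platforms receive a small
#' base measurement noise (\code{rnaseqNoiseSd}) plus a group-specific
#' discordance term applied SYMMETRICALLY to the two sides (the probes of
#' a probe-side group and the genes they pair with), whose s.d. is
#' calibrated by monotone bisection so that the realized group-wise
#' Spearman concordance lands on the spec's targets. The symmetric split
#' keeps the two platforms' within-platform information content
#' comparable, as for two assays of the same RNA. Unmapped (group D)
#' features carry independent latents and group-A-level noise.
#'
#' @param spec a [fixtureSpec()].
#' @param mapping the fixture's \linkS4class{MappingResult}.
#' @param seed RNG seed.
#' @param latent optional pre-made latent matrix (genes x samples), e.g.
#'   after planting endpoint signal; generated when NULL.
#' @param calibTol calibration tolerance on the realized Spearman mean
#'   (default 0.01).
#' @return list: \code{array}, \code{rnaseq}
#'   (\linkS4class{PlatformMatrix}), \code{latent}, \code{noiseSd} (named
#'   per probe-side group; the per-side s.d. of the discordance term).
#' @export
generatePairedExpression <- function(spec, mapping, seed = 1, latent = NULL,
                                     calibTol = 0.01) {
  gg <- mappingGroups(mapping, "gene")
  pg <- mappingGroups(mapping, "probe")
  genes <- names(gg)
  probes <- names(pg)
  edges <- mappingEdges(mapping)
  nS <- spec$nSamples
  samples <- sprintf("S%03d", seq_len(nS))
  if (is.null(latent)) {
    latent <- withSeed(deriveSeed(seed, 201), {
      mu <- stats::rnorm(length(genes), 7, 2)
      matrix(mu + stats::rnorm(length(genes) * nS), length(genes), nS,
             dimnames = list(genes, samples))
    })
  } else {
    stopifnot(all(rownames(latent) == genes))
    samples <- colnames(latent)
    nS <- ncol(latent)
  }
  # probe base signal: mean of mapped gene latents; D probes independent
  base <- matrix(NA_real_, length(probes), nS,
                 dimnames = list(probes, samples))
  for (p in probes[pg != "D"]) {
    gs <- edges$gene_id[edges$probe_id == p]
    base[p, ] <- if (length(gs) == 1) latent[gs, ]
                 else colMeans(latent[gs, , drop = FALSE])
  }
  nD <- sum(pg == "D")
  if (nD > 0)
    base[pg == "D", ] <- withSeed(deriveSeed(seed, 203),
      matrix(stats::rnorm(nD, 7, 2) + stats::rnorm(nD * nS), nD, nS))
  noiseP <- withSeed(deriveSeed(seed, 204),
    matrix(stats::rnorm(length(base)), nrow(base), ncol(base),
           dimnames = dimnames(base)))
  noiseG <- withSeed(deriveSeed(seed, 205),
    matrix(stats::rnorm(length(latent)), nrow(latent), ncol(latent),
           dimnames = dimnames(latent)))
  arrayVals <- base + spec$platformShift +
    spec$rnaseqNoiseSd * withSeed(deriveSeed(seed, 206),
      matrix(stats::rnorm(length(base)), nrow(base), ncol(base)))
  rnaseq <- latent + spec$rnaseqNoiseSd * withSeed(deriveSeed(seed, 202),
    matrix(stats::rnorm(length(latent)), nrow(latent), ncol(latent)))
  dimnames(rnaseq) <- dimnames(latent)
  # gene-side group paired with each probe-side group: A<->A, B<->C, C<->B
  genePair <- c(A = "A", B = "C", C = "B")
  noiseSd <- c(A = 0, B = 0, C = 0)
  for (g in c("A", "B", "C")) {
    pairs <- .groupPairs(mapping, g)
    if (nrow(pairs) == 0) next
    target <- spec$concordance[[g]]
    pm <- probes[pg == g]
    gm <- genes[gg == genePair[[g]]]
    realized <- function(sd) {
      pv <- arrayVals[pm, , drop = FALSE] + sd * noiseP[pm, , drop = FALSE]
      gv <- rnaseq[gm, , drop = FALSE] + sd * noiseG[gm, , drop = FALSE]
      .pairSpearman(pv, gv, pairs)
    }
    r0 <- realized(0)
    if (!is.finite(r0) || nrow(pairs) < 3)
      stop("too few (or degenerate) pairs to calibrate concordance for ",
           "group ", g)
    if (r0 < target - 0.049)
      stop(sprintf(
        "concordance target %.2f for group %s unreachable (attained %.3f)",
        target, g, r0))
    if (r0 > target + calibTol) {
      lo <- 0; hi <- 8
      while (realized(hi) > target) hi <- hi * 2
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        r <- realized(mid)
        if (abs(r - target) <= calibTol) break
        if (r > target) lo <- mid else hi <- mid
      }
      noiseSd[[g]] <- mid
    }
    arrayVals[pm, ] <- arrayVals[pm, , drop = FALSE] +
      noiseSd[[g]] * noiseP[pm, , drop = FALSE]
    rnaseq[gm, ] <- rnaseq[gm, , drop = FALSE] +
      noiseSd[[g]] * noiseG[gm, , drop = FALSE]
  }
  if (nD > 0)
    arrayVals[pg == "D", ] <- arrayVals[pg == "D", , drop = FALSE] +
      noiseSd[["A"]] * noiseP[pg == "D", , drop = FALSE]
  dGenes <- gg == "D"
  if (any(dGenes))
    rnaseq[dGenes, ] <- rnaseq[dGenes, , drop = FALSE] +
      noiseSd[["A"]] * noiseG[dGenes, , drop = FALSE]
  list(array = PlatformMatrix(arrayVals, "microarray", "log2_intensity"),
       rnaseq = PlatformMatrix(rnaseq, "rnaseq", "log2_count"),
       latent = latent, noiseSd = noiseSd)
}

#' Plant a binary endpoint into the latent matrix
#'
#' Assigns 0/1 labels at the spec's class balance, shifts the latent means
#' of the planted signal genes by delta in class-1 samples, and defines a
#' stratified predefined train/validation partition. Signal genes are
#' spread evenly over gene-side groups A, B and C so every group-restricted
#' feature set carries signal.
#'
#' @param latent genes x samples latent matrix.
#' @param spec a [fixtureSpec()].
#' @param mapping the fixture's \linkS4class{MappingResult}.
#' @param seed RNG seed.
#' @param name endpoint name.
#' @return list: \code{endpoint} (\linkS4class{EndpointDefinition}),
#'   \code{roster} (planted signal genes), \code{latent} (shifted).
#' @export
generateBinaryEndpoint <- function(latent, spec, mapping, seed = 1,
                                   name = "synthetic_binary") {
  samples <- colnames(latent)
  n <- length(samples)
  gg <- mappingGroups(mapping, "gene")
  withSeed(deriveSeed(seed, 301), {
    n1 <- round(n * spec$balance)
    if (n1 < 2 || n - n1 < 2) stop("class balance infeasible for n")
    labels <- stats::setNames(rep(0, n), samples)
    labels[sample(samples, n1)] <- 1
    pools <- lapply(c("A", "B", "C"), function(g) names(gg)[gg == g])
    nPer <- ceiling(spec$nSignal / 3)
    roster <- unlist(lapply(pools, function(p)
      sample(p, min(nPer, length(p)))))
    roster <- roster[seq_len(min(length(roster), spec$nSignal))]
    if (length(roster) == 0) stop("no mapped genes to plant signal in")
    latent[roster, labels == 1] <- latent[roster, labels == 1] + spec$delta
    part <- stats::setNames(rep("validation", n), samples)
    for (cl in c(0, 1)) {
      ids <- samples[labels == cl]
      part[sample(ids, round(spec$trainFrac * length(ids)))] <- "training"
    }
    list(endpoint = endpointDefinition(name, "binary", labels = labels,
                                       partition = part),
         roster = roster, latent = latent)
  })
}

#' Generate a right-censored survival endpoint from the latent matrix
#'
#' Event times are exponential with hazard proportional to
#' \eqn{\exp(\beta \cdot x)} over the (row-centered) latent expression of
#' the beta genes; independent exponential censoring is calibrated so the
#' expected censored fraction equals the spec's rate.
#'
#' @param latent genes x samples latent matrix.
#' @param spec a [fixtureSpec()].
#' @param mapping the fixture's \linkS4class{MappingResult} (used to pick a
#'   default beta gene from gene-side group A).
#' @param seed RNG seed.
#' @param name endpoint name.
#' @param exclude genes not to use for the default beta (e.g. the binary
#'   signal roster).
#' @return list: \code{endpoint} (survival
#'   \linkS4class{EndpointDefinition}), \code{beta} (named coefficients).
#' @export
generateSurvivalEndpoint <- function(latent, spec, mapping, seed = 1,
                                     name = "synthetic_survival",
                                     exclude = character()) {
  samples <- colnames(latent)
  n <- length(samples)
  beta <- spec$beta
  if (is.null(beta)) {
    gg <- mappingGroups(mapping, "gene")
    pool <- setdiff(names(gg)[gg == "A"], exclude)
    # hazard genes are expressed genes: restrict to above-median abundance
    # so the planted effect survives the median-intensity filter
    mu <- rowMeans(latent)
    hi <- pool[mu[pool] > stats::median(mu)]
    if (length(hi)) pool <- hi
    if (length(pool) == 0) stop("no gene available for the hazard effect")
    beta <- stats::setNames(1, withSeed(deriveSeed(seed, 401),
                                        sample(pool, 1)))
  }
  stopifnot(all(names(beta) %in% rownames(latent)))
  x <- latent[names(beta), , drop = FALSE]
  x <- x - rowMeans(x)
  lp <- drop(crossprod(x, beta))
  withSeed(deriveSeed(seed, 402), {
    h <- spec$baselineHazard * exp(lp)
    T <- stats::rexp(n, rate = h)
    if (spec$censRate == 0) {
      time <- T; event <- rep(1, n)
    } else {
      f <- function(logTheta)
        mean(exp(logTheta) / (exp(logTheta) + h)) - spec$censRate
      theta <- exp(stats::uniroot(f, c(-30, 30))$root)
      C <- stats::rexp(n, rate = theta)
      time <- pmin(T, C)
      event <- as.numeric(T <= C)
    }
    names(time) <- names(event) <- samples
    part <- stats::setNames(rep("validation", n), samples)
    part[sample(samples, round(spec$trainFrac * n))] <- "training"
    list(endpoint = endpointDefinition(name, "survival", time = time,
                                       event = event, partition = part),
         beta = beta)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Annotation fixture, mapping, binary and survival endpoints, and the
#' paired expression matrices consistent with the planted signal, plus the
#' oracle (planted groups, signal roster, hazard coefficients).
#'
#' @param spec a [fixtureSpec()].
#' @param seed RNG seed.
#' @return list with elements \code{annotation}, \code{genes},
#'   \code{mapping} (the expected \linkS4class{MappingResult}),
#'   \code{array}, \code{rnaseq}, \code{latent}, \code{noiseSd},
#'   \code{binary} (endpoint), \code{roster}, \code{survival} (endpoint),
#'   \code{beta}.
#' @export
generateStudy <- function(spec = fixtureSpec(), seed = 1) {
  fx <- generateAnnotationFixture(spec, seed)
  mapping <- fx$expected
  genes <- names(mappingGroups(mapping, "gene"))
  samples <- sprintf("S%03d", seq_len(spec$nSamples))
  latent <- withSeed(deriveSeed(seed, 201), {
    mu <- stats::rnorm(length(genes), 7, 2)
    matrix(mu + stats::rnorm(length(genes) * spec$nSamples),
           length(genes), spec$nSamples,
           dimnames = list(genes, samples))
  })
  bin <- generateBinaryEndpoint(latent, spec, mapping, seed)
  expr <- generatePairedExpression(spec, mapping, seed, latent = bin$latent)
  surv <- generateSurvivalEndpoint(bin$latent, spec, mapping, seed,
                                   exclude = bin$roster)
  list(annotation = fx$annotation, genes = fx$genes, mapping = mapping,
       array = expr$array, rnaseq = expr$rnaseq, latent = expr$latent,
       noiseSd = expr$noiseSd, binary = bin$endpoint, roster = bin$roster,
       survival = surv$endpoint, beta = surv$beta)
}
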