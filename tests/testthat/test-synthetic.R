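test_that("simulation is byte-reproducible for a fixed seed", {
  cfg <- simConfig(nGenes = 40, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulateDataset(cfg, dir = d1)
  s2 <- simulateDataset(cfg, dir = d2)
  for (nm in names(s1$files)) {
    expect_identical(readLines(s1$files[[nm]]), readLines(s2$files[[nm]]),
                     info = nm)
  }
  expect_identical(s1$manifest$genes, s2$manifest$genes)
  # a different seed changes the data
  s3 <- simulateDataset(simConfig(nGenes = 40, seed = 10),
                        makeCoverage = FALSE)
  expect_false(identical(s1$manifest$genes$true_rpkm,
                         s3$manifest$genes$true_rpkm))
})

test_that("emitted files round-trip through the package readers without warnings", {
  d <- withr::local_tempdir()
  sim <- simulateDataset(simConfig(nGenes = 30, seed = 4), dir = d)
  expect_no_warning({
    cat2 <- loadAnnotation(sim$files[["annotation"]])
    m6a2 <- readPeaks(sim$files[["m6a"]])
    h3k2 <- readPeaks(sim$files[["h3k4me3"]])
    cov2 <- readCoverage(sim$files[["coverage"]])
    expr2 <- readExpression(sim$files[["expression"]])
  })
  expect_identical(geneIds(cat2), geneIds(sim$catalog))
  expect_equal(length(m6a2), length(sim$m6a))
  expect_equal(S4Vectors::mcols(peaks(m6a2))$summit,
               S4Vectors::mcols(peaks(sim$m6a))$summit)
  expect_equal(length(h3k2), length(sim$h3k4me3))
  expect_equal(librarySize(cov2), librarySize(sim$coverage),
               tolerance = 1e-5)
  expect_equal(unname(expr2[names(sim$expression)]),
               unname(sim$expression), tolerance = 1e-5)
})

test_that("a fresh dataset verifies cleanly; corruption is localized", {
  d <- withr::local_tempdir()
  sim <- simulateDataset(simConfig(nGenes = 30, seed = 6), dir = d)
  expect_length(verifyManifest(d), 0)

  # corrupt exactly one fold enrichment in the manifest
  bad <- sim$manifest
  i <- which(!is.na(bad$genes$fe_utr5))[1]
  bad$genes$fe_utr5[i] <- bad$genes$fe_utr5[i] * 2
  issues <- verifyManifest(d, manifest = bad)
  expect_length(issues, 1)
  expect_match(issues, bad$genes$gene_id[i])

  # truncated bedGraph is reported with the file name
  writeLines("chrS\t100", file.path(d, "h3k4me3.bedGraph"))
  expect_error(verifyManifest(d), "h3k4me3.bedGraph")

  # missing file is an error naming the file
  file.remove(file.path(d, "expression.tsv"))
  expect_error(verifyManifest(d), "expression.tsv")
})

test_that("sample moments match the configured distributions", {
  cfg <- simConfig(nGenes = 2000, seed = 13)
  sim <- simulateDataset(cfg, makeCoverage = FALSE)
  g <- sim$manifest$genes

  # truncated log-normal fold enrichment: mean of log(FE)
  lfe <- log(c(g$fe_utr5, g$fe_utr3))
  lfe <- lfe[!is.na(lfe)]
  a <- (log(cfg$feMin) - cfg$feMeanlog) / cfg$feSdlog
  expMean <- cfg$feMeanlog +
    cfg$feSdlog * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(lfe) - expMean), 3 * sd(lfe) / sqrt(length(lfe)))
  expect_true(all(c(g$fe_utr5, g$fe_utr3) > cfg$feMin, na.rm = TRUE))

  # UTR5 length log-moments
  u5 <- GenomicRanges::width(BiocGenerics::unlist(utr5(sim$catalog)))
  expect_lt(abs(mean(log(u5)) - cfg$utr5Len[["meanlog"]]),
            3 * sd(log(u5)) / sqrt(length(u5)))

  # group proportions
  frac <- table(g$group)[c("5only", "3only", "53", "none")] / nrow(g)
  for (k in names(frac)) {
    p <- cfg$groupFractions[[k]]
    expect_lt(abs(frac[[k]] - p), 3 * sqrt(p * (1 - p) / nrow(g)))
  }
})

test_that("summit jitter is centred and the no-noise null is exact", {
  cfg <- simConfig(nGenes = 1000, seed = 19, shiftBeta = 0)
  sim <- simulateDataset(cfg, makeCoverage = FALSE)
  err <- sim$manifest$genes$true_summit_offset_bp - cfg$baseSummitBp
  expect_lt(abs(mean(err)), 2)

  null <- simulateDataset(simConfig(nGenes = 50, seed = 19, shiftBeta = 0,
                                    noiseSdBp = 0), makeCoverage = FALSE)
  expect_true(all(null$manifest$genes$true_summit_offset_bp ==
                  null$manifest$base_summit_bp))
  # and the emitted H3K4me3 summits sit exactly at the base offset
  offs <- vapply(seq_len(50), function(i) {
    g <- null$manifest$genes$gene_id[i]
    pk <- peaks(null$h3k4me3)
    tssOffset(null$catalog, g,
              S4Vectors::mcols(pk)$summit[match(paste0("h3k4me3_", g),
                                                S4Vectors::mcols(pk)$name)])
  }, numeric(1))
  expect_true(all(offs == null$manifest$base_summit_bp))
})

test_that("decoy peaks exercise the filter without disturbing group truth", {
  sim <- simulateDataset(simConfig(nGenes = 80, seed = 23,
                                   decoyFraction = 0.3),
                         makeCoverage = FALSE)
  raw <- sim$m6a
  kept <- filterPeaks(raw)
  expect_lt(length(kept), length(raw))
  expect_true(all(S4Vectors::mcols(peaks(kept))$foldEnrichment > 1.5))
  d <- withr::local_tempdir()
  simulateDataset(simConfig(nGenes = 80, seed = 23, decoyFraction = 0.3),
                  dir = d, makeCoverage = FALSE)
  expect_length(verifyManifest(d), 0)
})

test_that("a fixed chromosome length that cannot hold the genes is refused", {
  expect_error(
    simulateDataset(simConfig(nGenes = 50, seed = 1, chromLen = 10000),
                    makeCoverage = FALSE),
    "increase chromLen")
})
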