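test_that("summit-based region assignment respects region boundaries", {
  cat <- toyCatalog()
  # 60 bp into the 5'UTR of gP (5'UTR ends at 160)
  a <- assignPeakRegion(makePeaks("chr1", 160), cat)
  expect_equal(a$gene_id, "gP")
  expect_equal(a$region, "UTR5")
  # 1 bp past the 5'UTR end -> CDS
  a <- assignPeakRegion(makePeaks("chr1", 161), cat)
  expect_equal(a$region, "CDS")
  # unannotated gap -> intergenic, no gene
  a <- assignPeakRegion(makePeaks("chr1", 1500), cat)
  expect_true(is.na(a$gene_id))
  expect_equal(a$region, "INTERGENIC")
  # minus-strand gene: summit in gM's 5'UTR (right end of the span)
  a <- assignPeakRegion(makePeaks("chr1", 2900), cat)
  expect_equal(a$gene_id, "gM")
  expect_equal(a$region, "UTR5")
})

test_that("overlapping genes resolve by nearest TSS, then smaller gene id", {
  mkGene <- function(id, s, e, strand) {
    sp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                 strand = strand)
    names(sp) <- id
    S4Vectors::mcols(sp)$transcript_id <- paste0(id, ".1")
    sp
  }
  sp <- c(mkGene("gA", 100, 1000, "+"), mkGene("gB", 500, 1400, "+"))
  lst <- function(s, e) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                strand = "+")
    S4Vectors::split(g, factor(c("gA", "gB"), levels = c("gA", "gB")))
  }
  cat2 <- GeneCatalog(sp, lst(c(100, 500), c(199, 599)),
                      lst(c(200, 600), c(899, 1299)),
                      lst(c(900, 1300), c(1000, 1400)),
                      c(chr1 = 2000))
  # summit 550: in gA's CDS and gB's 5'UTR; TSS distances 450 vs 50 -> gB
  a <- assignPeakRegion(makePeaks("chr1", 550), cat2)
  expect_equal(a$gene_id, "gB")
  expect_equal(a$region, "UTR5")
  # summit 300: only gA annotated there
  a <- assignPeakRegion(makePeaks("chr1", 300), cat2)
  expect_equal(a$gene_id, "gA")
})

test_that("group membership follows the strict-'only' rule over all region subsets", {
  sim <- simulateDataset(simConfig(nGenes = 10, seed = 2),
                         makeCoverage = FALSE)
  cat <- sim$catalog
  ids <- geneIds(cat)
  # one gene per non-empty subset of {UTR5, CDS, UTR3}
  subsets <- list("5" = "UTR5", "c" = "CDS", "3" = "UTR3",
                  "5c" = c("UTR5", "CDS"), "53" = c("UTR5", "UTR3"),
                  "c3" = c("CDS", "UTR3"), "5c3" = c("UTR5", "CDS", "UTR3"))
  summitIn <- function(g, reg) {
    rl <- switch(reg, UTR5 = utr5(cat), CDS = cds(cat),
                 UTR3 = utr3(cat))[[g]]
    GenomicRanges::start(rl)[1] + 5
  }
  summits <- unlist(lapply(seq_along(subsets), function(i)
    vapply(subsets[[i]], function(r) summitIn(ids[i], r), numeric(1))))
  gt <- buildGroups(makePeaks("chrS", summits), cat)

  inG <- function(g, lab) g %in% groupGenes(gt, lab)
  hit <- function(i) ids[i]
  # gene with only a 5'UTR peak
  expect_true(all(vapply(c("G_5UTR", "G_5only", "G_m6A"),
                         function(l) inG(hit(1), l), logical(1))))
  expect_false(inG(hit(1), "G_3UTR"))
  # CDS-only gene is in G_m6A only
  expect_true(inG(hit(2), "G_m6A"))
  expect_false(any(inG(hit(2), "G_5UTR"), inG(hit(2), "G_3UTR"),
                   inG(hit(2), "G_5only"), inG(hit(2), "G_3only")))
  # UTR5+CDS: in G_5UTR but a CDS peak disqualifies 'only'
  expect_true(inG(hit(4), "G_5UTR"))
  expect_false(inG(hit(4), "G_5only"))
  # UTR5+UTR3: both-UTR group, no 'only' membership
  expect_true(inG(hit(5), "G_53"))
  expect_false(inG(hit(5), "G_5only") || inG(hit(5), "G_3only"))
  # all three regions: 5UTR, 3UTR, 53 but neither 'only'
  expect_true(all(vapply(c("G_5UTR", "G_3UTR", "G_53"),
                         function(l) inG(hit(7), l), logical(1))))
  expect_false(inG(hit(7), "G_5only") || inG(hit(7), "G_3only"))
  # untouched genes are outside G_m6A
  expect_false(inG(ids[8], "G_m6A"))
})

test_that("assignment matches a brute-force linear scan on random fixtures", {
  for (seed in 1:4) {
    sim <- simulateDataset(simConfig(nGenes = 40, seed = seed),
                           makeCoverage = FALSE)
    L <- unname(genomeSizes(sim$catalog)[1])
    set.seed(seed + 100)
    summits <- sample(L, 60)
    a <- assignPeakRegion(makePeaks("chrS", summits), sim$catalog)
    tbl <- bruteRegionTable(sim$catalog)
    for (i in seq_along(summits)) {
      b <- bruteAssignRegion(tbl, "chrS", a$summit[i])
      expect_identical(a$gene_id[i], b$gene)
      expect_identical(a$region[i], b$region)
    }
  }
})

test_that("group-table identities hold on random peak sets", {
  for (seed in 1:5) {
    sim <- simulateDataset(simConfig(nGenes = 60, seed = seed,
                                     decoyFraction = 0.2),
                           makeCoverage = FALSE)
    L <- unname(genomeSizes(sim$catalog)[1])
    set.seed(seed)
    extra <- makePeaks("chrS", sample(L, 80))
    both <- PeakSet(c(peaks(sim$m6a), peaks(extra)), "mix")
    gt <- buildGroups(both, sim$catalog)  # validity enforces the identities
    g <- gt@groups
    expect_setequal(g$G_53, intersect(g$G_5UTR, g$G_3UTR))
    expect_length(intersect(g$G_5only, g$G_3only), 0)
    expect_true(all(g$G_5only %in% g$G_5UTR))
    expect_true(all(g$G_3only %in% g$G_3UTR))
    expect_true(all(unlist(g) %in% g$G_m6A))
    expect_true(all(g$G_m6A %in% geneIds(sim$catalog)))
  }
})

test_that("overlap percentages follow the two-way definition", {
  A <- sprintf("a%03d", 1:100)
  B <- c(A[1:60], sprintf("b%02d", 1:3))  # 63 genes, 60 shared
  s <- overlapStats(A, B)
  expect_equal(s$pct_A_with_B, 60)
  expect_equal(s$pct_of_B_covered, 100 * 60 / 63, tolerance = 1e-12)
  expect_equal(s$n_overlap, 60)

  same <- overlapStats(A, A)
  expect_equal(c(same$pct_A_with_B, same$pct_of_B_covered), c(100, 100))
  disj <- overlapStats(A, sprintf("z%d", 1:5))
  expect_equal(c(disj$pct_A_with_B, disj$pct_of_B_covered), c(0, 0))
  empty <- overlapStats(character(), A)
  expect_equal(c(empty$pct_A_with_B, empty$pct_of_B_covered), c(0, 0))

  for (i in 1:20) {
    set.seed(i)
    x <- sample(letters, sample(5:20, 1))
    y <- sample(letters, sample(5:20, 1))
    s <- overlapStats(x, y)
    b <- bruteOverlapStats(x, y)
    expect_equal(s$n_overlap, b$n_overlap)
    expect_equal(s$pct_A_with_B, b$pct_A_with_B)
    expect_equal(s$pct_of_B_covered, b$pct_of_B_covered)
  }
})

test_that("random-gene control is seeded, saturates, and matches the hypergeometric mean", {
  uni <- sprintf("g%04d", 1:1000)
  m6a <- uni[1:400]

  sat <- randomControl(m6a, 50, m6a, seed = 1, reps = 20)
  expect_equal(sat$mean_pct_A_with_B, 100)
  expect_equal(sat$sd_pct_A_with_B, 0)

  none <- randomControl(uni, 50, character(), seed = 1, reps = 5)
  expect_equal(none$mean_pct_A_with_B, 0)

  a <- randomControl(uni, 200, m6a, seed = 9, reps = 50)
  b <- randomControl(uni, 200, m6a, seed = 9, reps = 50)
  expect_identical(a$perRep, b$perRep)

  ctl <- randomControl(uni, 200, m6a, seed = 3, reps = 1000)
  se <- ctl$sd_pct_A_with_B / sqrt(ctl$reps)
  expect_lt(abs(ctl$mean_pct_A_with_B - 40), 3 * se + 1e-9)

  expect_error(randomControl(uni, 2000, m6a, seed = 1), "exceeds")
})

test_that("writer-loss fraction reproduces set-difference arithmetic", {
  sim <- simulateDataset(simConfig(
    nGenes = 120, seed = 21,
    groupFractions = c("5only" = 0.9, "3only" = 0.05, "53" = 0.0,
                       "none" = 0.05)), makeCoverage = FALSE)
  asg <- assignPeakRegion(sim$m6a, sim$catalog)
  g5 <- unique(asg$gene_id[asg$region == "UTR5" & !is.na(asg$gene_id)])
  expect_gte(length(g5), 100)
  g5 <- sort(g5)[1:100]
  wtPeaks <- peaks(sim$m6a)
  keepWt <- asg$gene_id %in% g5 & asg$region == "UTR5"
  wt <- PeakSet(wtPeaks[keepWt], "wt")
  mut <- PeakSet(wtPeaks[keepWt][asg$gene_id[keepWt] %in% g5[1:6]], "mut")

  expect_equal(writerLossFraction(wt, mut, sim$catalog, "UTR5"), 0.94)
  expect_equal(writerLossFraction(wt, wt, sim$catalog, "UTR5"), 0)
  emptyMut <- PeakSet(wtPeaks[0], "empty")
  expect_equal(writerLossFraction(wt, emptyMut, sim$catalog, "UTR5"), 1)
  expect_error(writerLossFraction(emptyMut, wt, sim$catalog, "UTR5"),
               "no reference genes")
})

test_that("group tables export one TSV row per m6A gene", {
  sim <- simulateDataset(simConfig(nGenes = 40, seed = 15),
                         makeCoverage = FALSE)
  gt <- buildGroups(filterPeaks(sim$m6a), sim$catalog)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGroupTable(gt, f)
  tab <- read.delim(f)
  expect_setequal(tab$gene_id, groupGenes(gt, "G_m6A"))
  g5 <- tab$gene_id[grepl("G_5only", tab$groups)]
  expect_setequal(g5, groupGenes(gt, "G_5only"))
})

test_that("marked genes use body overlap of at least 1 bp", {
  cat <- toyCatalog()
  # peak ending exactly at gP's first base
  p <- makePeaks("chr1", 96, halfWidth = 5)  # interval [91, 101]
  expect_equal(markedGenes(cat, p), "gP")
  p2 <- makePeaks("chr1", 50, halfWidth = 5)  # [45, 55]: outside both genes
  expect_length(markedGenes(cat, p2), 0)
  # promoter extension pulls in an upstream peak
  expect_equal(markedGenes(cat, p2, promoterExt = 100), "gP")
})
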