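test_that("GFF3 coordinates, UTR widths and TSS are strand-aware on a two-gene fixture", {
  cat <- toyCatalog()
  expect_equal(length(cat), 2L)
  expect_setequal(geneIds(cat), c("gP", "gM"))

  u5P <- utr5(cat)[["gP"]]
  expect_equal(GenomicRanges::start(u5P), 101)
  expect_equal(GenomicRanges::end(u5P), 160)
  expect_equal(GenomicRanges::width(u5P), 60)  # == 0-based [100,160)

  expect_equal(unname(tss(cat)["gP"]), 101)
  expect_equal(unname(tss(cat)["gM"]), 3000)
  expect_equal(unname(genomeSizes(cat)["chr1"]), 10000)
  expect_setequal(allGenes(cat), c("gP", "gM"))
})

test_that("representative transcript is the longest isoform, ties by smallest id", {
  expect_equal(selectModelTranscript(c("t.1", "t.2"), c(900, 1200)), "t.2")
  expect_equal(selectModelTranscript(c("AT1G01010.2", "AT1G01010.1"),
                                     c(500, 500)), "AT1G01010.1")
  expect_equal(selectModelTranscript("only.1", 100), "only.1")
  expect_error(selectModelTranscript(character(), numeric()), "no isoforms")

  lines <- c(toyGff3Lines(),
             "chr1\t.\tmRNA\t4001\t4500\t.\t+\t.\tID=gI.2;Parent=gI",
             "chr1\t.\tmRNA\t4001\t5200\t.\t+\t.\tID=gI.1;Parent=gI",
             "chr1\t.\tfive_prime_UTR\t4001\t4100\t.\t+\t.\tParent=gI.1",
             "chr1\t.\tCDS\t4101\t5000\t.\t+\t.\tParent=gI.1",
             "chr1\t.\tthree_prime_UTR\t5001\t5200\t.\t+\t.\tParent=gI.1",
             "chr1\t.\tCDS\t4001\t4500\t.\t+\t.\tParent=gI.2")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(lines, f)
  cat <- loadAnnotation(f)
  sp <- spans(cat)["gI"]
  expect_equal(S4Vectors::mcols(sp)$transcript_id, "gI.1")
  expect_equal(GenomicRanges::width(sp), 1200)
})

test_that("genes lacking UTRs stay in the catalog but leave the all-genes universe", {
  lines <- c(toyGff3Lines(),
             "chr1\t.\tmRNA\t6001\t6500\t.\t+\t.\tID=gN.1;Parent=gN",
             "chr1\t.\tCDS\t6001\t6500\t.\t+\t.\tParent=gN.1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(lines, f)
  cat <- loadAnnotation(f)
  expect_true("gN" %in% geneIds(cat))
  expect_false("gN" %in% allGenes(cat))
  expect_setequal(allGenes(cat), c("gP", "gM"))
})

test_that("malformed lines are reported with their line number", {
  lines <- toyGff3Lines()
  lines[4] <- "chr1\t.\tmRNA\t101\t1000\t.\t+"  # 7 fields
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(lines, f)
  expect_error(loadAnnotation(f), "line 4")

  lines <- toyGff3Lines()
  lines[5] <- "chr1\t.\tfive_prime_UTR\t200\t101\t.\t+\t.\tParent=gP.1"
  writeLines(lines, f)
  expect_error(loadAnnotation(f), "line 5")
})

test_that("overlapping CDS/UTR features raise a consistency error naming the transcript", {
  lines <- toyGff3Lines()
  lines[6] <- "chr1\t.\tCDS\t150\t800\t.\t+\t.\tParent=gP.1"  # overlaps 5'UTR
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(lines, f)
  expect_error(loadAnnotation(f), "gP.1")
})

test_that("GTF input is auto-detected and parsed equivalently", {
  gtf <- c(
    'chr1\tx\ttranscript\t101\t1000\t.\t+\t.\tgene_id "gP"; transcript_id "gP.1";',
    'chr1\tx\tfive_prime_utr\t101\t160\t.\t+\t.\tgene_id "gP"; transcript_id "gP.1";',
    'chr1\tx\tCDS\t161\t800\t.\t+\t.\tgene_id "gP"; transcript_id "gP.1";',
    'chr1\tx\tthree_prime_utr\t801\t1000\t.\t+\t.\tgene_id "gP"; transcript_id "gP.1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  cat <- loadAnnotation(f)
  expect_equal(geneIds(cat), "gP")
  expect_equal(unname(tss(cat)["gP"]), 101)
  expect_equal(GenomicRanges::width(utr5(cat)[["gP"]]), 60)
})

test_that("writing a catalog to GFF3 and re-loading reproduces it", {
  sim <- simulateDataset(simConfig(nGenes = 25, seed = 11),
                         makeCoverage = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(sim$catalog, f)
  back <- loadAnnotation(f)
  expect_identical(geneIds(back), geneIds(sim$catalog))
  expect_identical(genomeSizes(back), genomeSizes(sim$catalog))
  for (g in geneIds(back)) {
    for (acc in list(utr5, cds, utr3)) {
      a <- acc(back)[[g]]; b <- acc(sim$catalog)[[g]]
      expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
      expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
    }
  }
  expect_equal(unname(tss(back)), unname(tss(sim$catalog)))
})

test_that("tssOffset is signed, strand-mirrored, and increasing downstream", {
  cat <- toyCatalog()
  # definition on the plus strand
  expect_equal(tssOffset(cat, "gP", 161), 60)
  expect_equal(tssOffset(cat, "gP", 51), -50)
  # strand mirror: 60 bp downstream on the minus strand
  expect_equal(tssOffset(cat, "gM", 2940), 60)
  # zero at the TSS itself
  expect_equal(tssOffset(cat, "gP", tss(cat)[["gP"]]), 0)
  expect_equal(tssOffset(cat, "gM", tss(cat)[["gM"]]), 0)
  # strictly increasing along transcription direction
  posP <- seq(101, 1000, by = 50)
  expect_true(all(diff(tssOffset(cat, "gP", posP)) > 0))
  posM <- seq(3000, 2001, by = -50)
  expect_true(all(diff(tssOffset(cat, "gM", posM)) > 0))
  expect_error(tssOffset(cat, "nope", 1), "unknown gene")
})

test_that("mirroring a catalog's coordinates leaves TSS offsets unchanged", {
  sim <- simulateDataset(simConfig(nGenes = 20, seed = 7),
                         makeCoverage = FALSE)
  cat <- sim$catalog
  L <- unname(genomeSizes(cat)[1])
  mirror <- function(gr) {
    m <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr),
      IRanges::IRanges(L + 1 - GenomicRanges::end(gr),
                       L + 1 - GenomicRanges::start(gr)),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+", "-", "+"))
    names(m) <- names(gr)
    S4Vectors::mcols(m)$transcript_id <- S4Vectors::mcols(gr)$transcript_id
    m
  }
  mirrorList <- function(rl) {
    ids <- names(rl)
    flat <- BiocGenerics::unlist(rl, use.names = FALSE)
    gene <- rep(ids, S4Vectors::elementNROWS(rl))
    m <- mirror(flat)
    S4Vectors::split(m, factor(gene, levels = ids))
  }
  cat2 <- GeneCatalog(mirror(spans(cat)), mirrorList(utr5(cat)),
                      mirrorList(cds(cat)), mirrorList(utr3(cat)),
                      genomeSizes(cat))
  for (g in head(geneIds(cat), 10)) {
    pos <- tss(cat)[[g]] + sample(-200:200, 5)
    expect_equal(tssOffset(cat2, g, L + 1 - pos), tssOffset(cat, g, pos))
  }
})
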