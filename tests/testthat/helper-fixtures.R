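# Two-gene annotation fixture, one gene per strand, hand-checked coords.
#   gP (+): span chr1:101-1000, 5'UTR 101-160, CDS 161-800, 3'UTR 801-1000,
#           TSS 101  (the 0-based half-open 5'UTR [100,160) of width 60)
#   gM (-): span chr1:2001-3000, 3'UTR 2001-2200, CDS 2201-2850,
#           5'UTR 2851-3000, TSS 3000
toyGff3Lines <- function() {
  c("##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\t.\tgene\t101\t1000\t.\t+\t.\tID=gP",
    "chr1\t.\tmRNA\t101\t1000\t.\t+\t.\tID=gP.1;Parent=gP",
    "chr1\t.\tfive_prime_UTR\t101\t160\t.\t+\t.\tParent=gP.1",
    "chr1\t.\tCDS\t161\t800\t.\t+\t.\tParent=gP.1",
    "chr1\t.\tthree_prime_UTR\t801\t1000\t.\t+\t.\tParent=gP.1",
    "chr1\t.\tgene\t2001\t3000\t.\t-\t.\tID=gM",
    "chr1\t.\tmRNA\t2001\t3000\t.\t-\t.\tID=gM.1;Parent=gM",
    "chr1\t.\tthree_prime_UTR\t2001\t2200\t.\t-\t.\tParent=gM.1",
    "chr1\t.\tCDS\t2201\t2850\t.\t-\t.\tParent=gM.1",
    "chr1\t.\tfive_prime_UTR\t2851\t3000\t.\t-\t.\tParent=gM.1")
}

toyCatalog <- function() {
  f <- withr::local_tempfile(fileext = ".gff3",
                             .local_envir = parent.frame())
  writeLines(toyGff3Lines(), f)
  loadAnnotation(f)
}

writePeakFile <- function(lines) {
  f <- withr::local_tempfile(fileext = ".narrowPeak",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# construct a PeakSet in code: summits given in 1-based genomic bp
makePeaks <- function(chrom, summits, fe = 2, q = 1e-6, halfWidth = 20,
                      label = "test") {
  n <- length(summits)
  gr <- GenomicRanges::GRanges(
    rep(chrom, n),
    IRanges::IRanges(pmax(1, summits - halfWidth), summits + halfWidth),
    name = sprintf("p%03d", seq_len(n)),
    summit = as.integer(summits),
    foldEnrichment = rep_len(fe, n), qvalue = rep_len(q, n))
  PeakSet(gr, label)
}

# coverage track from (start0, end0, value) triplets, 0-based half-open
makeTrack <- function(chrom, start0, end0, value, genomeSizes = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               score = value)
  CoverageTrack(gr, genomeSizes)
}

# --- independent brute-force oracles ---------------------------------------

# flatten a catalog to a plain interval table once, so the brute-force
# scan below is free of S4 accessor overhead but still a linear scan
bruteRegionTable <- function(catalog) {
  rows <- list()
  tssAll <- tss(catalog)
  for (g in geneIds(catalog)) {
    for (reg in c("UTR5", "CDS", "UTR3")) {
      rl <- switch(reg, UTR5 = utr5(catalog), CDS = cds(catalog),
                   UTR3 = utr3(catalog))[[g]]
      if (!length(rl)) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, region = reg,
        chrom = as.character(GenomicRanges::seqnames(rl)),
        start = GenomicRanges::start(rl), end = GenomicRanges::end(rl),
        tss = tssAll[[g]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# linear scan over every annotated interval of every gene
bruteAssignRegion <- function(tbl, chrom, summit) {
  best <- list(gene = NA_character_, region = "INTERGENIC", d = Inf)
  for (i in seq_len(nrow(tbl))) {
    if (tbl$chrom[i] != chrom) next
    if (summit >= tbl$start[i] && summit <= tbl$end[i]) {
      g <- tbl$gene[i]
      d <- abs(summit - tbl$tss[i])
      better <- d < best$d || (d == best$d && !is.na(best$gene) &&
                               g < best$gene)
      if (is.na(best$gene) || better)
        best <- list(gene = g, region = tbl$region[i], d = d)
    }
  }
  best[c("gene", "region")]
}

bruteOverlapStats <- function(A, B) {
  A <- unique(A); B <- unique(B)
  ov <- 0L
  for (a in A) if (a %in% B) ov <- ov + 1L
  list(n_overlap = ov,
       pct_A_with_B = if (length(A)) 100 * ov / length(A) else 0,
       pct_of_B_covered = if (length(B)) 100 * ov / length(B) else 0)
}

# minimal TSS-anchored profile built directly from bin values
makeProfile <- function(values, binBp = 10, nGenes = 1L) {
  new("Profile", mode = "TSS_ANCHORED",
      binEdges = seq(0, length(values) * binBp, by = binBp),
      values = values,
      nGenesPerBin = rep(nGenes, length(values)),
      nGenes = nGenes, binBp = binBp, metadata = list())
}
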