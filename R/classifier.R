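.REGION_LABELS <- c("UTR5", "CDS", "UTR3", "INTERGENIC")

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.regionRanges <- function(catalog) {
  parts <- lapply(c(UTR5 = "utr5", CDS = "cds", UTR3 = "utr3"), function(sl) {
    rl <- slot(catalog, sl)
    g <- unlist(rl, use.names = FALSE)
    mcols(g)$gene_id <- rep(names(rl), lengths(rl))
    g
  })
  lab <- rep(names(parts), vapply(parts, length, integer(1)))
  g <- do.call(c, unname(parts))
  mcols(g)$region <- lab
  g
}

#' Assign m6A peaks to transcript regions by summit position
#'
#' Each peak is assigned to the annotated region (5'UTR, CDS or 3'UTR)
#' whose interval union contains the peak *summit*. A summit inside no
#' annotated region is `INTERGENIC` with no gene. When a summit falls in
#' regions of several (overlapping) genes, the gene whose TSS is nearest
#' to the summit wins; remaining ties go to the lexicographically smaller
#' gene id. Opposite-strand overlaps are assigned independently the same
#' way (peaks are strandless).
#'
#' @param p A `PeakSet` (typically [filterPeaks()] output).
#' @param catalog A `GeneCatalog`.
#' @return A data.frame with one row per peak: `name`, `chrom`, `summit`,
#'   `fold_enrichment`, `qvalue`, `gene_id` (NA when intergenic),
#'   `region` (one of UTR5/CDS/UTR3/INTERGENIC).
#' @export
assignPeakRegion <- function(p, catalog) {
  stopifnot(is(p, "PeakSet"), is(catalog, "GeneCatalog"))
  g <- p@peaks
  out <- data.frame(
    name = if (length(g)) mcols(g)$name else character(),
    chrom = as.character(seqnames(g)),
    summit = if (length(g)) mcols(g)$summit else integer(),
    fold_enrichment = if (length(g)) mcols(g)$foldEnrichment else numeric(),
    qvalue = if (length(g)) mcols(g)$qvalue else numeric(),
    gene_id = rep(NA_character_, length(g)),
    region = rep("INTERGENIC", length(g)),
    stringsAsFactors = FALSE)
  if (!length(g)) return(out)
  reg <- .regionRanges(catalog)
  summits <- GRanges(seqnames(g), IRanges(mcols(g)$summit, width = 1))
  hits <- findOverlaps(summits, reg, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  geneHit <- mcols(reg)$gene_id[sh]
  tssAll <- tss(catalog)
  d <- abs(mcols(g)$summit[qh] - tssAll[geneHit])
  o <- order(qh, d, geneHit, method = "radix")
  first <- !duplicated(qh[o])
  pick <- o[first]
  out$gene_id[qh[pick]] <- geneHit[pick]
  out$region[qh[pick]] <- mcols(reg)$region[sh[pick]]
  out
}

#' Build the five m6A-location gene groups
#'
#' Collects, per gene, the set of regions carrying its (summit-assigned)
#' m6A peaks and derives the groups: `G_5UTR` (>= 1 peak in the 5'UTR),
#' `G_3UTR` (likewise 3'UTR), `G_53` (both UTRs), `G_5only` / `G_3only`
#' (*every* peak of the gene in that UTR — a CDS peak disqualifies), and
#' `G_m6A` (any peak on the transcript). Intergenic peaks are ignored.
#'
#' @param m6a A `PeakSet`, already filtered (see [filterPeaks()]).
#' @param catalog A `GeneCatalog`.
#' @return A [GroupTable-class].
#' @export
buildGroups <- function(m6a, catalog) {
  asg <- assignPeakRegion(m6a, catalog)
  asg <- asg[!is.na(asg$gene_id), , drop = FALSE]
  labs <- split(asg$region, asg$gene_id)
  fe5 <- vapply(split(ifelse(asg$region == "UTR5", asg$fold_enrichment, NA_real_),
                      asg$gene_id),
                function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
                numeric(1))
  gm6a <- names(labs)
  has5 <- vapply(labs, function(l) "UTR5" %in% l, logical(1))
  has3 <- vapply(labs, function(l) "UTR3" %in% l, logical(1))
  only5 <- vapply(labs, function(l) all(l == "UTR5"), logical(1))
  only3 <- vapply(labs, function(l) all(l == "UTR3"), logical(1))
  groups <- list(
    G_5UTR = gm6a[has5],
    G_53 = gm6a[has5 & has3],
    G_5only = gm6a[only5],
    G_3only = gm6a[only3],
    G_3UTR = gm6a[has3],
    G_m6A = gm6a)
  perGene <- data.frame(
    gene_id = gm6a,
    regions = vapply(labs, function(l) paste(sort(unique(l)), collapse = ","),
                     character(1)),
    n_peaks = lengths(labs),
    best_utr5_fe = fe5,
    stringsAsFactors = FALSE, row.names = NULL)
  new("GroupTable", groups = groups, universe = geneIds(catalog),
      perGene = perGene)
}

#' Write a GroupTable as TSV
#'
#' One row per m6A gene: comma-joined group memberships, the set of
#' regions hit, the peak count and the strongest 5'UTR fold enrichment.
#'
#' @param gt A `GroupTable`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeGroupTable <- function(gt, path) {
  stopifnot(is(gt, "GroupTable"))
  pg <- perGeneRegions(gt)
  memberOf <- function(g) paste(
    .GROUP_LABELS[vapply(.GROUP_LABELS, function(l) g %in% gt@groups[[l]],
                         logical(1))], collapse = ",")
  pg$groups <- vapply(pg$gene_id, memberOf, character(1))
  utils::write.table(
    pg[, c("gene_id", "groups", "regions", "n_peaks", "best_utr5_fe")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene peak-region log of a GroupTable
#' @param groups A `GroupTable`.
#' @return data.frame (gene_id, regions, n_peaks, best_utr5_fe).
#' @export
perGeneRegions <- function(groups) {
  stopifnot(is(groups, "GroupTable"))
  groups@perGene
}

#' Two-way overlap statistics between gene sets
#'
#' Reports the two percentages read off a marked-genes comparison:
#' the percentage of set A carrying the B mark, `100 |A n B| / |A|`, and
#' the percentage of B covered by A, `100 |A n B| / |B|`. Empty sets give
#' 0 by definition.
#'
#' @param setA,setB Character vectors of gene ids.
#' @return An object of class `"OverlapStats"`: a list with `n_A`, `n_B`,
#'   `n_overlap`, `pct_A_with_B`, `pct_of_B_covered`.
#' @export
overlapStats <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  nAB <- length(intersect(setA, setB))
  structure(list(
    n_A = length(setA), n_B = length(setB), n_overlap = nAB,
    pct_A_with_B = if (length(setA)) 100 * nAB / length(setA) else 0,
    pct_of_B_covered = if (length(setB)) 100 * nAB / length(setB) else 0),
    class = "OverlapStats")
}

#' @export
print.OverlapStats <- function(x, ...) {
  cat(sprintf(
    "OverlapStats: |A|=%d, |B|=%d, overlap=%d\n  %.1f%% of A carry B; %.1f%% of B covered\n",
    x$n_A, x$n_B, x$n_overlap, x$pct_A_with_B, x$pct_of_B_covered))
  invisible(x)
}

#' Random-gene null for an overlap comparison
#'
#' Draws `reps` random gene sets of size `n` (without replacement) from
#' the universe and computes [overlapStats()] of each draw against the
#' m6A gene set, mirroring the "randomly generated genes with the same
#' number of targets" control. Seeded and reproducible.
#'
#' @param universe Character vector to draw from.
#' @param n Genes per draw (must not exceed the universe size).
#' @param m6aGenes Character vector of m6A-marked genes.
#' @param seed Integer seed.
#' @param reps Number of draws (default 100).
#' @return An object of class `"OverlapControl"`: list with means and SDs
#'   of both percentages plus the per-draw data.frame.
#' @export
randomControl <- function(universe, n, m6aGenes, seed, reps = 100) {
  universe <- unique(universe)
  if (n > length(universe))
    stop("n exceeds the size of the gene universe")
  stopifnot(reps >= 1)
  per <- .withSeed(seed, {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      s <- overlapStats(sample(universe, n), m6aGenes)
      data.frame(rep = r, pct_A_with_B = s$pct_A_with_B,
                 pct_of_B_covered = s$pct_of_B_covered)
    }))
  })
  structure(list(
    mean_pct_A_with_B = mean(per$pct_A_with_B),
    sd_pct_A_with_B = stats::sd(per$pct_A_with_B),
    mean_pct_of_B_covered = mean(per$pct_of_B_covered),
    sd_pct_of_B_covered = stats::sd(per$pct_of_B_covered),
    n = n, reps = reps, perRep = per),
    class = "OverlapControl")
}

#' @export
print.OverlapControl <- function(x, ...) {
  cat(sprintf(
    "OverlapControl (%d draws of %d genes):\n  %.1f%% (SD %.2f) of random genes carry the mark; cover %.1f%% (SD %.2f)\n",
    x$reps, x$n, x$mean_pct_A_with_B, x$sd_pct_A_with_B,
    x$mean_pct_of_B_covered, x$sd_pct_of_B_covered))
  invisible(x)
}

#' Fraction of region-methylated genes lost in a writer mutant
#'
#' Genes with at least one peak summit in `region` are collected in the
#' wild-type and mutant peak sets (filtered identically beforehand); the
#' returned value is the fraction of wild-type genes absent from the
#' mutant set, the writer-dependence readout.
#'
#' @param peaksWt,peaksMut `PeakSet` objects for wild type and mutant.
#' @param catalog A `GeneCatalog`.
#' @param region Region label, default `"UTR5"`.
#' @return Fraction in `[0, 1]`.
#' @export
writerLossFraction <- function(peaksWt, peaksMut, catalog, region = "UTR5") {
  region <- match.arg(region, c("UTR5", "CDS", "UTR3"))
  gw <- function(p) {
    a <- assignPeakRegion(p, catalog)
    unique(a$gene_id[a$region == region & !is.na(a$gene_id)])
  }
  gWt <- gw(peaksWt)
  if (!length(gWt)) stop("no reference genes: wild-type set has no ",
                         region, " peaks")
  gMut <- gw(peaksMut)
  length(setdiff(gWt, gMut)) / length(gWt)
}

#' Genes marked by a histone modification
#'
#' A gene counts as marked when its body (TSS to TES, optionally extended
#' upstream by a promoter margin) overlaps at least one peak interval by
#' >= 1 bp, the common marked-gene convention for H3K4me3/H3K27me3
#' ChIP-seq peak sets.
#'
#' @param catalog A `GeneCatalog`.
#' @param p A `PeakSet`.
#' @param promoterExt Upstream extension in bp (default 0).
#' @return Character vector of gene ids.
#' @export
markedGenes <- function(catalog, p, promoterExt = 0) {
  stopifnot(is(catalog, "GeneCatalog"), is(p, "PeakSet"))
  sp <- spans(catalog)
  if (promoterExt > 0) {
    plus <- as.character(strand(sp)) == "+"
    newStart <- ifelse(plus, pmax(1, start(sp) - promoterExt), start(sp))
    newEnd <- ifelse(plus, end(sp),
                     pmin(genomeSizes(catalog)[as.character(seqnames(sp))],
                          end(sp) + promoterExt))
    sp <- GRanges(seqnames(sp), IRanges(newStart, newEnd), strand = strand(sp))
    names(sp) <- geneIds(catalog)
  }
  hits <- findOverlaps(sp, p@peaks, ignore.strand = TRUE)
  unique(names(sp)[S4Vectors::queryHits(hits)])
}
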