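#' Synthetic-dataset configuration
#'
#' Defines the conditions the generator emulates: genes with annotated
#' 5'UTR/CDS/3'UTR on both strands of one synthetic chromosome; m6A peaks
#' placed region-specifically with log-normal fold enrichments; an
#' H3K4me3 coverage bump whose summit offset from the TSS grows with the
#' 5'UTR m6A enrichment; and expression negatively coupled to 5'UTR
#' enrichment. Defaults plant a 60-bp group shift on a 310-bp baseline
#' summit offset.
#'
#' @param nGenes Number of genes (>= 10; default 1000).
#' @param strandFraction Fraction of genes on the minus strand (0.5).
#' @param utr5Len,cdsLen,utr3Len Log-normal length parameters,
#'   `c(meanlog, sdlog)`; defaults centre on 150/1100/220 bp.
#' @param groupFractions Named proportions over `5only`, `3only`, `53`,
#'   `none`; must sum to 1.
#' @param feMeanlog,feSdlog Log-normal m6A fold-enrichment parameters
#'   (median 3).
#' @param feMin Lower truncation of emitted fold enrichments (1.5):
#'   peak files mimic caller output that already passed the
#'   fold-enrichment threshold.
#' @param baseSummitBp H3K4me3 bump offset downstream of the TSS for
#'   genes without 5'UTR m6A (310 bp).
#' @param shiftBeta Extra offset in bp per log2 unit of 5'UTR fold
#'   enrichment (the planted coupling); the default corresponds to a
#'   planted 60-bp group shift, see [shiftBetaFor()].
#' @param exprMu Mean log2 RPKM of unmethylated genes (3).
#' @param exprBeta log2-RPKM change per log2 fold-enrichment unit for
#'   genes with 5'UTR m6A; <= 0 plants the negative coupling (-0.6).
#' @param exprNoiseSd SD of log2-RPKM noise (0.8).
#' @param noiseSdBp Per-gene jitter SD of the bump centre (20 bp).
#' @param bumpSd SD of the Gaussian H3K4me3 bump (75 bp, roughly the +1
#'   nucleosome scale).
#' @param bumpAmpMeanlog,bumpAmpSdlog Log-normal bump-amplitude
#'   parameters.
#' @param background Uniform background coverage (0.2 per bp).
#' @param decoyFraction Fraction of additional m6A decoy peaks failing
#'   the FDR/fold-enrichment filter (0 by default).
#' @param geneSpacingBp Minimal intergenic spacing (2000 bp).
#' @param chromName Synthetic chromosome name.
#' @param chromLen Optional fixed chromosome length; genes that do not
#'   fit trigger an error advising a larger genome.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(nGenes = 1000, strandFraction = 0.5,
                      utr5Len = c(meanlog = log(150), sdlog = 0.35),
                      cdsLen = c(meanlog = log(1100), sdlog = 0.35),
                      utr3Len = c(meanlog = log(220), sdlog = 0.35),
                      groupFractions = c("5only" = 0.15, "3only" = 0.35,
                                         "53" = 0.15, "none" = 0.35),
                      feMeanlog = log(3), feSdlog = 0.5, feMin = 1.5,
                      baseSummitBp = 310,
                      shiftBeta = shiftBetaFor(60, log(3)),
                      exprMu = 3, exprBeta = -0.6, exprNoiseSd = 0.8,
                      noiseSdBp = 20, bumpSd = 75,
                      bumpAmpMeanlog = log(20), bumpAmpSdlog = 0.3,
                      background = 0.2, decoyFraction = 0,
                      geneSpacingBp = 2000, chromName = "chrS",
                      chromLen = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (nGenes < 10) stop("nGenes must be >= 10")
  if (abs(sum(groupFractions) - 1) > 1e-8)
    stop("groupFractions must sum to 1")
  if (!all(c("5only", "3only", "53", "none") %in% names(groupFractions)))
    stop("groupFractions must name 5only, 3only, 53, none")
  if (strandFraction < 0 || strandFraction > 1)
    stop("strandFraction must lie in [0, 1]")
  structure(cfg, class = "SimConfig")
}

# mean of log2(FE) when log(FE) ~ Normal(meanlog, sdlog) truncated below
# at log(feMin) -- the generator emits caller-thresholded fold enrichments
.truncMeanLog2Fe <- function(feMeanlog, feSdlog, feMin) {
  a <- (log(feMin) - feMeanlog) / feSdlog
  (feMeanlog + feSdlog * stats::dnorm(a) / (1 - stats::pnorm(a))) / log(2)
}

#' Coupling coefficient that plants a given group shift
#'
#' With fold enrichments FE = exp(Z), Z ~ Normal(feMeanlog, feSdlog)
#' truncated below at `log(feMin)` (emitted peaks mimic caller output
#' that already passed the fold-enrichment threshold), the mean extra
#' offset of 5'UTR-methylated genes is `shiftBeta * E[log2 FE]`. This
#' helper inverts that relation so a desired mean group shift `deltaBp`
#' can be planted directly.
#'
#' @param deltaBp Desired mean group shift in bp.
#' @param feMeanlog,feSdlog Log fold-enrichment parameters (defaults
#'   `log(3)`, 0.5).
#' @param feMin Lower fold-enrichment truncation (default 1.5).
#' @return The `shiftBeta` value (bp per log2 fold-enrichment unit).
#' @export
shiftBetaFor <- function(deltaBp, feMeanlog = log(3), feSdlog = 0.5,
                         feMin = 1.5) {
  deltaBp / .truncMeanLog2Fe(feMeanlog, feSdlog, feMin)
}

#' Planted mean group shift of a configuration
#' @param config A `SimConfig`.
#' @return Mean planted shift in bp.
#' @export
plantedShift <- function(config) {
  config$shiftBeta *
    .truncMeanLog2Fe(config$feMeanlog, config$feSdlog, config$feMin)
}

.simFileNames <- c(annotation = "genes.gff3", m6a = "m6a_peaks.narrowPeak",
                   h3k4me3 = "h3k4me3_peaks.narrowPeak",
                   coverage = "h3k4me3.bedGraph",
                   expression = "expression.tsv", manifest = "manifest.json")

#' Write a PeakSet as ENCODE narrowPeak
#' @param p A `PeakSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeNarrowPeak <- function(p, path) {
  g <- p@peaks
  q <- mcols(g)$qvalue
  ml10q <- ifelse(q <= 0, 99, -log10(q))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.\t%.4f\t-1\t%.4f\t%d",
                     as.character(seqnames(g)), start(g) - 1L, end(g),
                     mcols(g)$name, mcols(g)$foldEnrichment, ml10q,
                     mcols(g)$summit - start(g)),
             path)
  invisible(path)
}

#' Write a CoverageTrack as bedGraph
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (ch in names(track@cov)) {
    r <- track@cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       formatC(vals[keep], digits = 6, format = "g")), con)
  }
  invisible(path)
}

#' Generate a complete synthetic dataset with a truth manifest
#'
#' Lays `nGenes` genes (with 5'UTR/CDS/3'UTR structure, both strands
#' interleaved) on one synthetic chromosome with at least
#' `geneSpacingBp` spacing; places m6A peaks per group with log-normal
#' fold enrichments and summits inside the designated UTR; synthesizes an
#' H3K4me3 coverage track as a Gaussian bump per gene centred
#' `baseSummitBp (+ shiftBeta * log2(FE) for 5'UTR-methylated genes)`
#' downstream of the TSS plus Normal jitter, over a uniform background,
#' with a matching narrowPeak entry whose summit sits at the bump centre;
#' and draws expression as
#' `2^(exprMu + exprBeta * log2(FE_5UTR) + noise)`. All outputs are
#' byte-reproducible for a fixed seed.
#'
#' @param config A [simConfig()] object.
#' @param dir Optional output directory; when given, the standard files
#'   (GFF3, two narrowPeaks, bedGraph, expression TSV, manifest JSON) are
#'   written there.
#' @param makeCoverage Build the coverage track (default TRUE); disable
#'   for peak/expression-only studies where profiling is not needed.
#' @return List with `catalog` (GeneCatalog), `m6a` and `h3k4me3`
#'   (PeakSets, unfiltered), `coverage` (CoverageTrack or NULL),
#'   `expression` (named RPKM vector), `manifest` (list), and `files`
#'   (named paths or NULL).
#' @export
simulateDataset <- function(config, dir = NULL, makeCoverage = TRUE) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, .simulateImpl(config, dir, makeCoverage))
}

.simulateImpl <- function(config, dir, makeCoverage) {
  n <- config$nGenes
  ids <- sprintf("g%05d", seq_len(n))
  rln <- function(p, minBp) pmax(minBp, round(stats::rlnorm(n, p[1], p[2])))
  u5 <- rln(config$utr5Len, 30)
  cd <- rln(config$cdsLen, 90)
  u3 <- rln(config$utr3Len, 30)
  glen <- u5 + cd + u3
  strand <- ifelse(stats::runif(n) < config$strandFraction, "-", "+")
  grp <- sample(names(config$groupFractions), n, replace = TRUE,
                prob = config$groupFractions)

  sp <- config$geneSpacingBp
  gstart <- sp + cumsum(c(0, glen[-n] + sp))
  gend <- gstart + glen - 1
  chromLen <- gend[n] + sp
  if (!is.null(config$chromLen)) {
    if (config$chromLen < chromLen)
      stop("genes do not fit on the chromosome (need ", chromLen,
           " bp); increase chromLen or reduce nGenes")
    chromLen <- config$chromLen
  }
  chrom <- config$chromName
  tssPos <- ifelse(strand == "+", gstart, gend)

  # region intervals, strand-aware (5'UTR at the TSS end)
  plus <- strand == "+"
  u5s <- ifelse(plus, gstart, gend - u5 + 1)
  u5e <- ifelse(plus, gstart + u5 - 1, gend)
  cdsS <- ifelse(plus, gstart + u5, gstart + u3)
  cdsE <- cdsS + cd - 1
  u3s <- ifelse(plus, gend - u3 + 1, gstart)
  u3e <- ifelse(plus, gend, gstart + u3 - 1)

  spansGr <- GRanges(chrom, IRanges(gstart, gend), strand = strand)
  names(spansGr) <- ids
  mcols(spansGr)$transcript_id <- paste0(ids, ".1")
  mcols(spansGr)$tss <- tssPos
  asList <- function(s, e) {
    g <- GRanges(chrom, IRanges(s, e), strand = strand)
    split(g, factor(ids, levels = ids))
  }
  catalog <- GeneCatalog(spansGr, asList(u5s, u5e), asList(cdsS, cdsE),
                         asList(u3s, u3e),
                         stats::setNames(chromLen, chrom))

  # m6A peaks: one per designated UTR, summit uniform inside the region
  has5 <- grp %in% c("5only", "53")
  has3 <- grp %in% c("3only", "53")
  fe5 <- rep(NA_real_, n)
  fe3 <- rep(NA_real_, n)
  # truncated log-normal: emitted peaks already passed the caller's
  # fold-enrichment threshold, like real thresholded peak files
  rfe <- function(m) {
    pLo <- stats::pnorm((log(config$feMin) - config$feMeanlog) / config$feSdlog)
    z <- stats::qnorm(pLo + stats::runif(m) * (1 - pLo))
    exp(config$feMeanlog + config$feSdlog * z)
  }
  fe5[has5] <- rfe(sum(has5))
  fe3[has3] <- rfe(sum(has3))
  unif <- function(a, b) a + floor(stats::runif(length(a)) * (b - a + 1))
  s5 <- unif(u5s, u5e)
  s3 <- unif(u3s, u3e)
  mk <- function(idx, summit, fe, tag) {
    if (!length(idx)) return(NULL)
    data.frame(gene = ids[idx], summit = summit[idx], fe = fe[idx],
               q = 1e-6, tag = tag, stringsAsFactors = FALSE)
  }
  pk <- rbind(mk(which(has5), s5, fe5, "utr5"),
              mk(which(has3), s3, fe3, "utr3"))
  if (config$decoyFraction > 0) {
    nd <- round(config$decoyFraction * nrow(pk))
    if (nd > 0) {
      gi <- sample(n, nd, replace = TRUE)
      pk <- rbind(pk, data.frame(gene = ids[gi], summit = unif(cdsS, cdsE)[gi],
                                 fe = 1.2, q = 0.5, tag = "decoy",
                                 stringsAsFactors = FALSE))
    }
  }
  peakGr <- GRanges(chrom,
                    IRanges(pmax(1, pk$summit - 75),
                            pmin(chromLen, pk$summit + 75)),
                    name = sprintf("m6a_%s_%s", pk$tag, pk$gene),
                    summit = pk$summit, foldEnrichment = pk$fe,
                    qvalue = pk$q)
  m6aPeaks <- PeakSet(peakGr, "m6a_synthetic")

  # H3K4me3 bump centre: base offset, plus enrichment coupling for genes
  # methylated in the 5'UTR, plus jitter; clipped inside the gene
  offset <- config$baseSummitBp +
    ifelse(has5, config$shiftBeta * log2(fe5), 0) +
    stats::rnorm(n, 0, config$noiseSdBp)
  offset <- pmin(pmax(round(offset), 1), glen - 1)
  centre <- ifelse(plus, tssPos + offset, tssPos - offset)
  amp <- stats::rlnorm(n, config$bumpAmpMeanlog, config$bumpAmpSdlog)

  h3kGr <- GRanges(chrom,
                   IRanges(pmax(1, centre - 150), pmin(chromLen, centre + 150)),
                   name = sprintf("h3k4me3_%s", ids),
                   summit = centre, foldEnrichment = amp / config$background,
                   qvalue = 1e-6)
  h3k4me3 <- PeakSet(h3kGr, "h3k4me3_synthetic")

  coverage <- NULL
  if (makeCoverage) {
    vec <- rep(config$background, chromLen)
    half <- ceiling(4 * config$bumpSd)
    for (k in seq_len(n)) {
      xs <- max(1, centre[k] - half):min(chromLen, centre[k] + half)
      vec[xs] <- vec[xs] +
        amp[k] * exp(-0.5 * ((xs - centre[k]) / config$bumpSd)^2)
    }
    covRle <- RleList(Rle(vec))
    names(covRle) <- chrom
    coverage <- new("CoverageTrack", cov = covRle, librarySize = sum(vec))
  }

  exprLog2 <- config$exprMu +
    ifelse(has5, config$exprBeta * log2(fe5), 0) +
    stats::rnorm(n, 0, config$exprNoiseSd)
  expression <- stats::setNames(2^exprLog2, ids)

  manifest <- list(
    generator = "m6Ashift synthetic-data module",
    config = unclass(config),
    seed = config$seed,
    chrom = chrom, chrom_len = chromLen,
    planted_shift_bp = plantedShift(config),
    shift_beta = config$shiftBeta, expr_beta = config$exprBeta,
    base_summit_bp = config$baseSummitBp,
    library_size = if (makeCoverage) coverage@librarySize else NA,
    genes = data.frame(
      gene_id = ids, strand = strand, group = grp,
      length_bp = glen,
      fe_utr5 = fe5, fe_utr3 = fe3,
      true_summit_offset_bp = offset,
      bump_amplitude = amp,
      true_rpkm = unname(expression),
      stringsAsFactors = FALSE))

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- stats::setNames(file.path(dir, .simFileNames),
                             names(.simFileNames))
    writeAnnotation(catalog, files["annotation"])
    writeNarrowPeak(m6aPeaks, files["m6a"])
    writeNarrowPeak(h3k4me3, files["h3k4me3"])
    if (makeCoverage) writeBedGraph(coverage, files["coverage"])
    else files <- files[names(files) != "coverage"]
    writeExpression(expression, files["expression"])
    jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  list(catalog = catalog, m6a = m6aPeaks, h3k4me3 = h3k4me3,
       coverage = coverage, expression = expression, manifest = manifest,
       files = files)
}

#' Cross-check an emitted dataset against its truth manifest
#'
#' Re-reads the standard files of a written dataset with the package's
#' own readers and verifies, per manifest gene: presence in the GFF3;
#' m6A group membership after the default peak filter; recorded fold
#' enrichments, expression values, and the H3K4me3 summit offset from the
#' TSS. An empty character vector means the dataset is consistent.
#'
#' @param dir Directory written by [simulateDataset()].
#' @param manifest Optional manifest list; defaults to the one in `dir`.
#' @return Character vector of inconsistency messages (empty = pass).
#' @export
verifyManifest <- function(dir, manifest = NULL) {
  need <- .simFileNames[names(.simFileNames) != "coverage"]
  paths <- stats::setNames(file.path(dir, need), names(need))
  for (p in paths)
    if (!file.exists(p)) stop("missing dataset file: ", p)
  if (is.null(manifest))
    manifest <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
  tryRead <- function(f, path, ...) {
    tryCatch(f(path, ...),
             error = function(e) stop("failed to read ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  catalog <- tryRead(loadAnnotation, paths["annotation"])
  m6a <- filterPeaks(tryRead(readPeaks, paths["m6a"]))
  h3k <- tryRead(readPeaks, paths["h3k4me3"])
  expr <- tryRead(readExpression, paths["expression"])
  covPath <- file.path(dir, .simFileNames["coverage"])
  if (file.exists(covPath)) tryRead(readCoverage, covPath)

  issues <- character()
  gt <- buildGroups(m6a, catalog)
  pg <- perGeneRegions(gt)
  g <- manifest$genes
  relDiff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  for (k in seq_len(nrow(g))) {
    gid <- g$gene_id[k]
    if (!gid %in% geneIds(catalog)) {
      issues <- c(issues, sprintf("%s: missing from annotation", gid))
      next
    }
    inG <- vapply(.GROUP_LABELS, function(l) gid %in% groupGenes(gt, l),
                  logical(1))
    expect <- switch(g$group[k],
      "5only" = inG[["G_5only"]],
      "3only" = inG[["G_3only"]],
      "53" = inG[["G_53"]],
      "none" = !inG[["G_m6A"]])
    if (!isTRUE(expect))
      issues <- c(issues, sprintf("%s: group '%s' not recovered from peaks",
                                  gid, g$group[k]))
    if (!is.na(g$fe_utr5[k])) {
      fe <- pg$best_utr5_fe[match(gid, pg$gene_id)]
      if (is.na(fe) || relDiff(fe, g$fe_utr5[k]) > 1e-3)
        issues <- c(issues, sprintf("%s: 5'UTR fold enrichment mismatch", gid))
    }
    if (!gid %in% names(expr) ||
        relDiff(expr[[gid]], g$true_rpkm[k]) > 1e-4)
      issues <- c(issues, sprintf("%s: expression mismatch", gid))
  }
  # H3K4me3 summit offsets (vectorized by peak name)
  hk <- peaks(h3k)
  hnames <- sub("^h3k4me3_", "", mcols(hk)$name)
  for (k in seq_len(nrow(g))) {
    gid <- g$gene_id[k]
    j <- match(gid, hnames)
    if (is.na(j)) {
      issues <- c(issues, sprintf("%s: missing H3K4me3 peak", gid))
    } else if (gid %in% geneIds(catalog)) {
      off <- tssOffset(catalog, gid, mcols(hk)$summit[j])
      if (off != g$true_summit_offset_bp[k])
        issues <- c(issues, sprintf("%s: H3K4me3 summit offset mismatch", gid))
    }
  }
  issues
}
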