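#' Construct a PeakSet from a GRanges
#'
#' @param gr GRanges with metadata columns `name`, `summit` (genomic bp),
#'   `foldEnrichment`, `qvalue`. Sorted on construction.
#' @param sampleLabel Single string.
#' @return A [PeakSet-class].
#' @export
PeakSet <- function(gr, sampleLabel = "sample") {
  o <- order(as.character(seqnames(gr)), start(gr))
  new("PeakSet", peaks = gr[o], sampleLabel = sampleLabel)
}

#' Read peak calls from narrowPeak or BED
#'
#' A 10-column file is read as ENCODE narrowPeak: the summit is
#' `start + column 10`, fold enrichment is column 7 (signalValue) and the
#' q-value is `10^-column 9` (the column holds -log10 FDR, per the format
#' standard; negative sentinel values map to q = 1). Files with 6-9 or 12
#' columns are read as BED: the summit defaults to the interval midpoint,
#' fold enrichment to 1 and q-value to 0. Reads are gzip-transparent.
#' Coordinates are converted from 0-based half-open to the package's
#' 1-based closed convention.
#'
#' @param source Path to a narrowPeak/BED file.
#' @param label Sample label stored in the result.
#' @return A [PeakSet-class].
#' @export
readPeaks <- function(source, label = basename(source)) {
  lines <- .readLinesAny(source)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines))
    return(PeakSet(GRanges(NULL, name = character(), summit = integer(),
                           foldEnrichment = numeric(), qvalue = numeric()),
                   label))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(f))
  if (length(ncol) != 1L || !ncol %in% c(6:10, 12))
    stop("peak format error: expected 6-10 or 12 tab-separated columns, found ",
         paste(sort(unique(lengths(f))), collapse = "/"))
  m <- do.call(rbind, f)
  chrom <- m[, 1]
  start0 <- as.numeric(m[, 2])
  end0 <- as.numeric(m[, 3])
  name <- m[, 4]
  if (ncol == 10L) {
    fe <- as.numeric(m[, 7])
    qv <- pmin(1, 10^-as.numeric(m[, 9]))
    off <- as.numeric(m[, 10])
    bad <- off >= (end0 - start0) | off < 0
    if (any(bad))
      stop("peak value error: summit offset outside peak for: ",
           paste(head(name[bad], 3), collapse = ", "))
    summit0 <- start0 + off
  } else {
    fe <- rep(1, nrow(m))
    qv <- rep(0, nrow(m))
    summit0 <- floor((start0 + end0) / 2)  # midpoint, 0-based
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0),
                name = name, summit = as.integer(summit0 + 1),
                foldEnrichment = fe, qvalue = qv)
  PeakSet(gr, label)
}

#' Filter peaks on FDR and fold enrichment
#'
#' Retains peaks with `qvalue < maxFdr` AND `foldEnrichment > minFe`
#' (both strict, matching the MACS2 thresholds "FDR less than 0.01, fold
#' enrichment more than 1.5" used for meRIP-seq peak sets). Order is
#' preserved; the operation is idempotent and monotone in the thresholds.
#'
#' @param p A `PeakSet`.
#' @param maxFdr FDR cutoff (default 0.01).
#' @param minFe Fold-enrichment cutoff (default 1.5).
#' @return A filtered [PeakSet-class].
#' @export
filterPeaks <- function(p, maxFdr = 0.01, minFe = 1.5) {
  stopifnot(is(p, "PeakSet"), maxFdr >= 0, minFe >= 0)
  g <- p@peaks
  keep <- mcols(g)$qvalue < maxFdr & mcols(g)$foldEnrichment > minFe
  new("PeakSet", peaks = g[keep], sampleLabel = p@sampleLabel)
}

#' Construct a CoverageTrack from scored ranges
#'
#' @param gr GRanges with a `score` column of non-negative signal values;
#'   ranges must not overlap.
#' @param genomeSizes Optional named numeric vector of chromosome lengths;
#'   defaults to the maximal covered coordinate per chromosome.
#' @return A [CoverageTrack-class].
#' @export
CoverageTrack <- function(gr, genomeSizes = NULL) {
  sc <- mcols(gr)$score
  if (any(sc < 0)) stop("coverage value error: negative signal value")
  red <- IRanges::reduce(gr, ignore.strand = TRUE)
  if (sum(width(red)) != sum(width(gr)))
    stop("coverage format error: overlapping runs")
  if (is.null(genomeSizes)) {
    genomeSizes <- tapply(end(gr), as.character(seqnames(gr)), max)
    genomeSizes <- stats::setNames(as.numeric(genomeSizes), names(genomeSizes))
  }
  gr <- GenomeInfoDb::keepSeqlevels(gr, names(genomeSizes),
                                    pruning.mode = "coarse")
  seqlengths(gr) <- as.integer(genomeSizes[seqlevels(gr)])
  cov <- coverage(gr, weight = "score")
  new("CoverageTrack", cov = cov,
      librarySize = sum(as.numeric(width(gr)) * sc))
}

#' Read a bedGraph coverage track
#'
#' Four-column bedGraph (0-based half-open), gzip-transparent. Rows are
#' sorted on load; overlapping runs are a format error; negative values a
#' value error. The library size is `sum(value * run length)`.
#'
#' @param source Path to a bedGraph file.
#' @param genomeSizes Optional named numeric chromosome lengths.
#' @return A [CoverageTrack-class].
#' @export
readCoverage <- function(source, genomeSizes = NULL) {
  gr <- rtracklayer::import(source, format = "bedGraph")
  CoverageTrack(gr, genomeSizes)
}

#' Read a gene expression table
#'
#' Two-column TSV (gene_id, RPKM), optional header, gzip-transparent.
#' When `minRpkm` is given, genes with `RPKM <= minRpkm` are dropped (the
#' DEG-style "RPKM larger than 1" filter); by default no filter is applied.
#'
#' @param source Path to the TSV.
#' @param minRpkm Optional strict lower RPKM cutoff.
#' @return Named numeric vector of RPKM values.
#' @export
readExpression <- function(source, minRpkm = NULL) {
  lines <- .readLinesAny(source)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L))
    stop("expression parse error at line ", which(lengths(f) < 2L)[1],
         ": expected two tab-separated columns")
  first <- suppressWarnings(as.numeric(f[[1]][2]))
  if (is.na(first)) { f <- f[-1]; lineOff <- 1L } else lineOff <- 0L
  ids <- vapply(f, `[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 2L)))
  if (anyNA(vals))
    stop("expression parse error at line ", which(is.na(vals))[1] + lineOff,
         ": non-numeric RPKM")
  if (anyDuplicated(ids))
    stop("duplicate gene id in expression table: ",
         ids[duplicated(ids)][1])
  if (any(vals < 0)) stop("negative RPKM values are not allowed")
  expr <- stats::setNames(vals, ids)
  if (!is.null(minRpkm)) expr <- expr[expr > minRpkm]
  expr
}

#' Write an expression table
#' @param expr Named numeric vector of RPKM values.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeExpression <- function(expr, path) {
  writeLines(c("gene_id\trpkm",
               sprintf("%s\t%s", names(expr), formatC(expr, digits = 6,
                                                      format = "g"))),
             path)
  invisible(path)
}
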