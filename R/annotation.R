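#' Construct a GeneCatalog
#'
#' Low-level constructor used by [loadAnnotation()] and the synthetic-data
#' generator. Most users will call [loadAnnotation()] instead.
#'
#' @param spans GRanges of representative-transcript spans, named by gene
#'   id, with a `transcript_id` metadata column (`tss` is derived from the
#'   strand if absent).
#' @param utr5,cds,utr3 GRangesList named like `spans` (possibly with
#'   empty elements).
#' @param genomeSizes Named numeric vector of chromosome lengths.
#' @return A [GeneCatalog-class] object.
#' @export
GeneCatalog <- function(spans, utr5, cds, utr3, genomeSizes) {
  if (is.null(mcols(spans)$tss)) {
    plus <- as.character(strand(spans)) == "+"
    mcols(spans)$tss <- ifelse(plus, start(spans), end(spans))
  }
  new("GeneCatalog", spans = spans, utr5 = utr5, cds = cds, utr3 = utr3,
      genomeSizes = genomeSizes)
}

.openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.readLinesAny <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# GTF attribute columns look like: gene_id "AT1G01010"; GFF3 like ID=...
.sniffAnnotationFormat <- function(attrCol) {
  if (any(grepl("\\w+ +\"", attrCol))) "gtf" else "gff3"
}

.validateAnnotationLines <- function(lines) {
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(body)
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("annotation parse error at line %d: expected 9 tab-separated fields, found %d",
                   i, length(f)), call. = FALSE)
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop(sprintf("annotation parse error at line %d: invalid coordinates '%s'-'%s'",
                   i, f[4], f[5]), call. = FALSE)
    if (!f[7] %in% c("+", "-", ".", "?"))
      stop(sprintf("annotation parse error at line %d: invalid strand '%s'",
                   i, f[7]), call. = FALSE)
  }
  idx
}

.pragmaSizes <- function(lines) {
  pr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(pr)) return(numeric())
  f <- strsplit(trimws(pr), "[ \t]+")
  stats::setNames(vapply(f, function(x) as.numeric(x[4]), numeric(1)),
                  vapply(f, function(x) x[2], character(1)))
}

.regionKind <- function(type) {
  type <- tolower(type)
  out <- rep(NA_character_, length(type))
  out[type %in% c("five_prime_utr", "5utr")] <- "utr5"
  out[type == "cds"] <- "cds"
  out[type %in% c("three_prime_utr", "3utr")] <- "utr3"
  out
}

#' Select the representative isoform of a gene
#'
#' The representative transcript is the isoform with the longest genomic
#' span; ties are broken by the lexicographically smallest transcript id.
#'
#' @param transcriptIds Character vector of isoform ids (one gene).
#' @param spanWidths Numeric vector of span lengths (bp), aligned with
#'   `transcriptIds`.
#' @return The chosen transcript id.
#' @examples
#' selectModelTranscript(c("AT1G01010.1", "AT1G01010.2"), c(900, 1200))
#' @export
selectModelTranscript <- function(transcriptIds, spanWidths) {
  if (!length(transcriptIds)) stop("no isoforms supplied")
  stopifnot(length(transcriptIds) == length(spanWidths))
  best <- spanWidths == max(spanWidths)
  sort(transcriptIds[best], method = "radix")[1L]
}

#' Load a gene annotation into a GeneCatalog
#'
#' Reads GFF3 or GTF (auto-detected from the attribute syntax,
#' gzip-transparent), builds one transcript model per transcript from its
#' `five_prime_UTR`/`CDS`/`three_prime_UTR` features, and keeps one
#' representative transcript per gene (see [selectModelTranscript()]).
#' Genes lacking one or both UTRs are retained in the catalog but excluded
#' from the [allGenes()] universe.
#'
#' @param source Path to a GFF3 or GTF file (optionally gzipped).
#' @param chromSizes Optional chromosome sizes: a named numeric vector or
#'   the path to a two-column TSV (chrom, length). When absent, sizes come
#'   from `##sequence-region` pragmas, falling back to the maximal
#'   annotated coordinate per chromosome.
#' @return A [GeneCatalog-class].
#' @export
loadAnnotation <- function(source, chromSizes = NULL) {
  lines <- .readLinesAny(source)
  idx <- .validateAnnotationLines(lines)
  if (!length(idx)) stop("annotation contains no feature lines")
  attrCol <- vapply(strsplit(lines[idx], "\t", fixed = TRUE), `[`, character(1), 9L)
  fmt <- .sniffAnnotationFormat(attrCol)
  gr <- rtracklayer::import(source, format = fmt)
  type <- tolower(as.character(mcols(gr)$type))
  kind <- .regionKind(as.character(mcols(gr)$type))
  isTx <- type %in% c("mrna", "transcript")

  if (fmt == "gff3") {
    parent1 <- vapply(as.list(mcols(gr)$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    txId <- ifelse(isTx, mcols(gr)$ID, NA_character_)
    geneOfTx <- ifelse(is.na(parent1[isTx]), mcols(gr)$ID[isTx], parent1[isTx])
    regTx <- parent1
  } else {
    txId <- ifelse(isTx, mcols(gr)$transcript_id, NA_character_)
    geneOfTx <- mcols(gr)$gene_id[isTx]
    regTx <- mcols(gr)$transcript_id
  }

  txTab <- data.frame(
    transcript_id = txId[isTx], gene_id = geneOfTx,
    chrom = as.character(seqnames(gr))[isTx],
    start = start(gr)[isTx], end = end(gr)[isTx],
    strand = as.character(strand(gr))[isTx],
    stringsAsFactors = FALSE)
  if (anyDuplicated(txTab$transcript_id))
    stop("duplicate transcript id in annotation: ",
         txTab$transcript_id[duplicated(txTab$transcript_id)][1])

  isReg <- !is.na(kind) & !is.na(regTx)
  regTab <- data.frame(
    transcript_id = regTx[isReg], kind = kind[isReg],
    chrom = as.character(seqnames(gr))[isReg],
    start = start(gr)[isReg], end = end(gr)[isReg],
    strand = as.character(strand(gr))[isReg],
    stringsAsFactors = FALSE)
  # transcripts only implied by their features (bare GTFs)
  orphan <- setdiff(unique(regTab$transcript_id), txTab$transcript_id)
  if (length(orphan)) {
    gid <- if (fmt == "gtf") {
      stats::setNames(mcols(gr)$gene_id[isReg], regTx[isReg])[orphan]
    } else orphan
    o <- regTab[regTab$transcript_id %in% orphan, ]
    agg <- do.call(rbind, lapply(split(o, o$transcript_id), function(d)
      data.frame(transcript_id = d$transcript_id[1],
                 gene_id = NA_character_, chrom = d$chrom[1],
                 start = min(d$start), end = max(d$end),
                 strand = d$strand[1], stringsAsFactors = FALSE)))
    agg$gene_id <- unname(gid[agg$transcript_id])
    txTab <- rbind(txTab, agg)
  }

  # annotation consistency: regions must not overlap within a transcript
  for (tid in unique(regTab$transcript_id)) {
    d <- regTab[regTab$transcript_id == tid, ]
    ir <- IRanges(d$start, d$end)
    if (sum(width(IRanges::reduce(ir))) != sum(width(ir)))
      stop("annotation-consistency error: overlapping CDS/UTR features in transcript ",
           tid)
    tx <- txTab[txTab$transcript_id == tid, ]
    if (nrow(tx) && (any(d$chrom != tx$chrom) ||
                     any(d$strand != tx$strand) ||
                     any(d$start < tx$start) || any(d$end > tx$end)))
      stop("annotation-consistency error: feature outside transcript span in ",
           tid)
  }

  # one representative transcript per gene: longest span, ties by id
  keep <- vapply(split(txTab, txTab$gene_id), function(d)
    selectModelTranscript(d$transcript_id, d$end - d$start + 1), character(1))
  rep <- txTab[match(keep, txTab$transcript_id), ]
  ord <- order(rep$chrom, rep$start, rep$gene_id)
  rep <- rep[ord, ]

  spansGr <- GRanges(rep$chrom, IRanges(rep$start, rep$end),
                     strand = rep$strand)
  names(spansGr) <- rep$gene_id
  mcols(spansGr)$transcript_id <- rep$transcript_id
  mcols(spansGr)$tss <- ifelse(rep$strand == "+", rep$start, rep$end)

  reg <- regTab[regTab$transcript_id %in% rep$transcript_id, ]
  reg$gene_id <- rep$gene_id[match(reg$transcript_id, rep$transcript_id)]
  lev <- factor(character(), levels = rep$gene_id)
  regionList <- function(k) {
    d <- reg[reg$kind == k, ]
    d <- d[order(d$chrom, d$start), ]
    g <- GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand)
    split(g, factor(d$gene_id, levels = rep$gene_id))
  }

  sizes <- .pragmaSizes(lines)
  if (!is.null(chromSizes)) {
    if (is.character(chromSizes) && length(chromSizes) == 1L) {
      cs <- utils::read.table(chromSizes, sep = "\t", header = FALSE,
                              col.names = c("chrom", "size"),
                              stringsAsFactors = FALSE)
      sizes <- stats::setNames(as.numeric(cs$size), cs$chrom)
    } else sizes <- chromSizes
  }
  maxEnd <- tapply(c(txTab$end, regTab$end), c(txTab$chrom, regTab$chrom), max)
  for (ch in names(maxEnd))
    if (!ch %in% names(sizes)) sizes[ch] <- as.numeric(maxEnd[[ch]])

  GeneCatalog(spansGr, regionList("utr5"), regionList("cds"),
              regionList("utr3"), sizes[sort(names(sizes))])
}

#' Write a GeneCatalog back to GFF3
#'
#' Emits `##sequence-region` pragmas plus gene/mRNA/UTR/CDS features.
#' Re-loading the written file with [loadAnnotation()] reproduces the
#' catalog (I/O round trip).
#'
#' @param catalog A `GeneCatalog`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeAnnotation <- function(catalog, path) {
  stopifnot(is(catalog, "GeneCatalog"))
  sizes <- genomeSizes(catalog)
  out <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(sizes),
                   as.integer(sizes)))
  sp <- spans(catalog)
  featLines <- function(gr, type, attr) {
    if (!length(gr)) return(character())
    sprintf("%s\tm6Ashift\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(seqnames(gr)), type, start(gr), end(gr),
            as.character(strand(gr)), attr)
  }
  for (i in seq_along(sp)) {
    g <- names(sp)[i]
    txid <- mcols(sp)$transcript_id[i]
    out <- c(out,
      featLines(sp[i], "gene", sprintf("ID=%s", g)),
      featLines(sp[i], "mRNA", sprintf("ID=%s;Parent=%s", txid, g)),
      featLines(catalog@utr5[[g]], "five_prime_UTR", sprintf("Parent=%s", txid)),
      featLines(catalog@cds[[g]], "CDS", sprintf("Parent=%s", txid)),
      featLines(catalog@utr3[[g]], "three_prime_UTR", sprintf("Parent=%s", txid)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Strand-aware offset from a gene's TSS
#'
#' Positive offsets point downstream in the direction of transcription:
#' `pos - tss` on the plus strand and `tss - pos` on the minus strand.
#' Offsets outside the gene are legal and signed.
#'
#' @param catalog A `GeneCatalog`.
#' @param geneId Single gene id.
#' @param pos Numeric vector of genomic coordinates on the gene's
#'   chromosome.
#' @return Numeric vector of signed offsets (bp).
#' @examples
#' \dontrun{tssOffset(catalog, "g1", c(1000, 1060))}
#' @export
tssOffset <- function(catalog, geneId, pos) {
  stopifnot(is(catalog, "GeneCatalog"), length(geneId) == 1L)
  i <- match(geneId, geneIds(catalog))
  if (is.na(i)) stop("unknown gene id: ", geneId)
  t0 <- mcols(catalog@spans)$tss[i]
  if (as.character(strand(catalog@spans))[i] == "+") pos - t0 else t0 - pos
}
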