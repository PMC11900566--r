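# Decode-once cache: per-bp numeric signal per chromosome, so repeated
# window extraction is plain vector indexing.
.covCache <- function(track) {
  cache <- new.env(parent = emptyenv())
  function(chrom) {
    if (!chrom %in% names(track@cov))
      stop("chromosome not covered by track: ", chrom)
    if (is.null(cache[[chrom]])) cache[[chrom]] <- as.numeric(track@cov[[chrom]])
    cache[[chrom]]
  }
}

# Extract per-bp signal over [start, end] (genomic, 1-based closed) with NA
# outside the chromosome bounds, so off-chromosome bp never count as zeros.
.chromVec <- function(getChrom, chrom, start, end) {
  v <- getChrom(chrom)
  len <- length(v)
  n <- end - start + 1
  out <- rep(NA_real_, n)
  qs <- max(1, start); qe <- min(len, end)
  if (qs <= qe) out[(qs - start + 1):(qe - start + 1)] <- v[qs:qe]
  out
}

.binMeans <- function(vec, binBp) {
  m <- matrix(vec, nrow = binBp)
  out <- colMeans(m, na.rm = TRUE)
  out[colSums(!is.na(m)) == 0L] <- NA_real_
  out
}

# Per-gene binned coverage downstream of the TSS, oriented with
# transcription. Bins beyond the gene's TES (or chromosome edge) are NA.
.tssBinMatrix <- function(track, genes, catalog, windowBp, binBp) {
  sp <- spans(catalog)
  i <- match(genes, names(sp))
  if (anyNA(i)) stop("genes not in catalog: ",
                     paste(head(genes[is.na(i)], 3), collapse = ", "))
  nbins <- windowBp %/% binBp
  M <- matrix(NA_real_, length(genes), nbins, dimnames = list(genes, NULL))
  chrom <- as.character(seqnames(sp))[i]
  st <- as.character(strand(sp))[i]
  t0 <- mcols(sp)$tss[i]
  glen <- width(sp)[i]
  getChrom <- .covCache(track)
  for (k in seq_along(genes)) {
    vec <- if (st[k] == "+") {
      .chromVec(getChrom, chrom[k], t0[k], t0[k] + windowBp - 1)
    } else {
      rev(.chromVec(getChrom, chrom[k], t0[k] - windowBp + 1, t0[k]))
    }
    usable <- min(windowBp, glen[k])
    if (usable < windowBp) vec[(usable + 1):windowBp] <- NA_real_
    M[k, ] <- .binMeans(vec, binBp)
  }
  M
}

.profileFromMatrix <- function(M, binEdges, mode, binBp, librarySize,
                               metadata) {
  nPer <- colSums(!is.na(M))
  vals <- colMeans(M, na.rm = TRUE) * 1e6 / librarySize
  vals[nPer == 0L] <- NA_real_
  new("Profile", mode = mode, binEdges = binEdges, values = unname(vals),
      nGenesPerBin = unname(as.integer(nPer)), nGenes = nrow(M),
      binBp = binBp, metadata = metadata)
}

#' TSS-anchored metagene profile at fixed bp resolution
#'
#' For every gene, the mean coverage in each strand-aware bin
#' `[k*binBp, (k+1)*binBp)` downstream of the TSS is computed, normalized
#' to signal-per-million of the track's library size; the profile is the
#' across-gene mean per bin. Genes shorter than the window contribute only
#' the bins they cover (per-bin gene counts are kept in the object).
#'
#' @param track A `CoverageTrack`.
#' @param genes Character vector of gene ids (non-empty).
#' @param catalog A `GeneCatalog`.
#' @param windowBp Window downstream of the TSS (default 1000); must be a
#'   multiple of `binBp`.
#' @param binBp Bin width in bp (default 10).
#' @param smoothBins Odd moving-average width in bins applied to the
#'   aggregate profile; 1 (the default) applies no smoothing. The value
#'   used is recorded in the profile metadata.
#' @return A [Profile-class] with `mode = "TSS_ANCHORED"`.
#' @seealso [groupSummit()], [groupShift()]
#' @export
tssProfile <- function(track, genes, catalog, windowBp = 1000, binBp = 10,
                       smoothBins = 1) {
  stopifnot(is(track, "CoverageTrack"), is(catalog, "GeneCatalog"))
  if (!length(genes)) stop("empty gene set")
  if (windowBp %% binBp != 0) stop("windowBp must be a multiple of binBp")
  if (smoothBins %% 2 != 1) stop("smoothBins must be odd")
  M <- .tssBinMatrix(track, genes, catalog, windowBp, binBp)
  p <- .profileFromMatrix(M, seq(0, windowBp, by = binBp), "TSS_ANCHORED",
                          binBp, librarySize(track),
                          list(window_bp = windowBp, bin_bp = binBp,
                               normalization = "per_million",
                               library_size = librarySize(track),
                               smooth_bins = smoothBins))
  if (smoothBins > 1) {
    k <- (smoothBins - 1) / 2
    v <- p@values
    p@values <- vapply(seq_along(v), function(i) {
      w <- v[max(1, i - k):min(length(v), i + k)]
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, numeric(1))
  }
  p
}

#' Minimal profile-to-SVG helper
#'
#' Writes a bare polyline rendering of a profile, for quick visual
#' inspection; figure aesthetics are out of scope.
#'
#' @param profile A `Profile`.
#' @param path Output SVG path.
#' @param width,height Canvas size in px.
#' @return Invisibly, `path`.
#' @export
profileToSvg <- function(profile, path, width = 640, height = 240) {
  stopifnot(is(profile, "Profile"))
  v <- profileValues(profile)
  v[is.na(v)] <- 0
  top <- max(v, 1e-12)
  xs <- seq(10, width - 10, length.out = length(v))
  ys <- height - 10 - (v / top) * (height - 20)
  pts <- paste(sprintf("%.1f,%.1f", xs, ys), collapse = " ")
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<polyline fill="none" stroke="black" points="%s"/>', pts),
    "</svg>"), path)
  invisible(path)
}

#' Gene-body-scaled metagene profile with fixed-width flanks
#'
#' Each gene body (TSS to TES) is rescaled to `nBodyBins` equal fractions;
#' upstream and downstream flanks are binned at fixed width. Per-gene
#' normalization and across-gene averaging follow [tssProfile()]. Genes
#' shorter than `nBodyBins` bp are skipped with a warning and counted in
#' the profile metadata.
#'
#' The composite bin-edge axis is: negative bp for the upstream flank,
#' `[0, nBodyBins]` (one unit per body bin) for the body, and
#' `nBodyBins + bp` for the downstream flank.
#'
#' @param track A `CoverageTrack`.
#' @param genes Character vector of gene ids.
#' @param catalog A `GeneCatalog`.
#' @param nBodyBins Number of body bins (default 100).
#' @param flankBp Flank size in bp (default 1000).
#' @param flankBinBp Flank bin width (default 50); must divide `flankBp`.
#' @return A [Profile-class] with `mode = "BODY_SCALED"`.
#' @export
bodyProfile <- function(track, genes, catalog, nBodyBins = 100,
                        flankBp = 1000, flankBinBp = 50) {
  stopifnot(is(track, "CoverageTrack"), is(catalog, "GeneCatalog"))
  if (!length(genes)) stop("empty gene set")
  if (flankBp %% flankBinBp != 0) stop("flankBp must be a multiple of flankBinBp")
  nf <- flankBp %/% flankBinBp
  sp <- spans(catalog)
  i <- match(genes, names(sp))
  if (anyNA(i)) stop("genes not in catalog: ",
                     paste(head(genes[is.na(i)], 3), collapse = ", "))
  chrom <- as.character(seqnames(sp))[i]
  st <- as.character(strand(sp))[i]
  gs <- start(sp)[i]; ge <- end(sp)[i]
  keep <- (ge - gs + 1) >= nBodyBins
  skipped <- genes[!keep]
  if (length(skipped)) {
    warning(length(skipped), " gene(s) shorter than ", nBodyBins,
            " bp skipped in body profile")
    genes <- genes[keep]; chrom <- chrom[keep]; st <- st[keep]
    gs <- gs[keep]; ge <- ge[keep]
    if (!length(genes)) stop("all genes shorter than nBodyBins")
  }
  M <- matrix(NA_real_, length(genes), nf + nBodyBins + nf,
              dimnames = list(genes, NULL))
  getChrom <- .covCache(track)
  for (k in seq_along(genes)) {
    if (st[k] == "+") {
      up <- .chromVec(getChrom, chrom[k], gs[k] - flankBp, gs[k] - 1)
      body <- .chromVec(getChrom, chrom[k], gs[k], ge[k])
      dn <- .chromVec(getChrom, chrom[k], ge[k] + 1, ge[k] + flankBp)
    } else {
      up <- rev(.chromVec(getChrom, chrom[k], ge[k] + 1, ge[k] + flankBp))
      body <- rev(.chromVec(getChrom, chrom[k], gs[k], ge[k]))
      dn <- rev(.chromVec(getChrom, chrom[k], gs[k] - flankBp, gs[k] - 1))
    }
    b <- floor(seq(0, length(body), length.out = nBodyBins + 1))
    bodyBins <- vapply(seq_len(nBodyBins), function(j) {
      v <- body[(b[j] + 1):b[j + 1]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    M[k, ] <- c(.binMeans(up, flankBinBp), bodyBins, .binMeans(dn, flankBinBp))
  }
  edges <- c(seq(-flankBp, -flankBinBp, by = flankBinBp),
             seq(0, nBodyBins),
             nBodyBins + seq(flankBinBp, flankBp, by = flankBinBp))
  .profileFromMatrix(M, edges, "BODY_SCALED", flankBinBp, librarySize(track),
                     list(n_body_bins = nBodyBins, flank_bp = flankBp,
                          flank_bin_bp = flankBinBp,
                          normalization = "per_million",
                          library_size = librarySize(track),
                          n_skipped = length(skipped),
                          skipped_genes = skipped))
}

#' Write a Profile as TSV (plus JSON metadata)
#'
#' @param profile A `Profile`.
#' @param path Output TSV path; metadata is written next to it as
#'   `<path>.meta.json`.
#' @return Invisibly, `path`.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "Profile"))
  e <- binEdges(profile)
  df <- data.frame(bin_start = e[-length(e)], bin_end = e[-1],
                   mean_signal = profileValues(profile),
                   n_genes_contributing = profile@nGenesPerBin)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(mode = profile@mode, n_genes = profile@nGenes,
                 bin_bp = profile@binBp), profile@metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
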