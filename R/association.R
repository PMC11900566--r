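#' Pearson correlation with a two-sided t-test p-value
#'
#' Standard product-moment correlation; the p-value comes from the
#' t-transform with `n - 2` degrees of freedom (two-sided), as returned
#' by [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, each with
#'   nonzero variance.
#' @return An object of class `"CorrelationResult"`: list with `pcc`,
#'   `p_value`, `n`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("degenerate input: non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(pcc = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, two-sided p = %.3g)\n",
              x$pcc, x$n, x$p_value))
  invisible(x)
}

#' Correlation of 5'UTR m6A enrichment with mRNA abundance
#'
#' For every gene of the chosen group with an expression value, pairs
#' `x = log2(strongest 5'UTR m6A fold enrichment)` with
#' `y = log2(RPKM + 1)` and returns their Pearson correlation; a negative
#' coefficient reproduces the repressive association between 5'UTR
#' methylation and transcript abundance.
#'
#' @param groups A `GroupTable` built by [buildGroups()].
#' @param expr Named numeric RPKM vector (see [readExpression()]).
#' @param group Group to correlate within (default `"G_5only"`).
#' @param log2Transform Use log2 scales (default TRUE); raw scale
#'   otherwise.
#' @return A `"CorrelationResult"` (see [pearsonCor()]).
#' @export
enrichmentExpressionCorr <- function(groups, expr, group = "G_5only",
                                     log2Transform = TRUE) {
  d <- enrichmentExpressionData(groups, expr, group)
  if (nrow(d) < 3)
    stop("fewer than 3 genes with both 5'UTR enrichment and expression")
  if (log2Transform) pearsonCor(log2(d$fold_enrichment), log2(d$rpkm + 1))
  else pearsonCor(d$fold_enrichment, d$rpkm)
}

#' Per-gene scatter data behind the enrichment-expression correlation
#'
#' @param groups A `GroupTable`.
#' @param expr Named numeric RPKM vector.
#' @param group Group to extract (default `"G_5only"`).
#' @return data.frame (gene_id, fold_enrichment, rpkm), one row per gene
#'   of the group with both values.
#' @export
enrichmentExpressionData <- function(groups, expr, group = "G_5only") {
  stopifnot(is(groups, "GroupTable"))
  ids <- groupGenes(groups, group)
  pg <- perGeneRegions(groups)
  fe <- pg$best_utr5_fe[match(ids, pg$gene_id)]
  keep <- !is.na(fe) & ids %in% names(expr)
  data.frame(gene_id = ids[keep], fold_enrichment = fe[keep],
             rpkm = unname(expr[ids[keep]]), stringsAsFactors = FALSE)
}

#' Correlation of 5'UTR m6A enrichment with the H3K4me3 summit distance
#'
#' Pairs `x = log2(fold enrichment)` with `y = TSS-to-summit distance`
#' from [geneSummitDistance()]; a positive coefficient reproduces the
#' association of stronger 5'UTR methylation with larger downstream
#' H3K4me3 shifts.
#'
#' @param distances data.frame from [geneSummitDistance()] with columns
#'   `distance_bp` and `m6a_fold_enrichment` (>= 3 complete rows).
#' @return A `"CorrelationResult"`.
#' @export
enrichmentShiftCorr <- function(distances) {
  d <- distances[!is.na(distances$m6a_fold_enrichment), , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 genes with enrichment and distance")
  pearsonCor(log2(d$m6a_fold_enrichment), d$distance_bp)
}

.sigMark <- function(p) {
  ifelse(is.na(p), "untestable",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Pairwise group comparison of expression levels
#'
#' Two-sided Welch t-tests on `log2(RPKM + 1)` between every pair of the
#' six m6A-location groups, with the conventional significance marks
#' (`**` for p < 0.01, `*` for p < 0.05, `NS` otherwise). Pairs in which
#' either group has fewer than 2 expressed genes are marked untestable.
#' Set `welch = FALSE` for the classic equal-variance Student flavor.
#' Raw p-values are reported; `adjust = "BH"` adds a Benjamini-Hochberg
#' adjusted column (marks stay keyed to the raw p-values).
#'
#' @param groups A `GroupTable`.
#' @param expr Named numeric RPKM vector.
#' @param welch Use the unequal-variance test (default TRUE).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame (group1, group2, n1, n2, t_statistic, p_value,
#'   mark, and p_adjusted when requested).
#' @export
compareGroupExpression <- function(groups, expr, welch = TRUE,
                                   adjust = c("none", "BH")) {
  stopifnot(is(groups, "GroupTable"))
  adjust <- match.arg(adjust)
  vals <- lapply(.GROUP_LABELS, function(l) {
    ids <- intersect(groupGenes(groups, l), names(expr))
    log2(unname(expr[ids]) + 1)
  })
  names(vals) <- .GROUP_LABELS
  pairs <- utils::combn(.GROUP_LABELS, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- vals[[a]]; vb <- vals[[b]]
    if (length(va) < 2 || length(vb) < 2) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      # both constant: t.test is undefined; identical means carry no evidence
      tt <- list(statistic = if (mean(va) == mean(vb)) 0 else Inf,
                 p.value = if (mean(va) == mean(vb)) 1 else 0)
    } else {
      h <- stats::t.test(va, vb, var.equal = !welch,
                         alternative = "two.sided")
      tt <- list(statistic = unname(h$statistic), p.value = h$p.value)
    }
    data.frame(group1 = a, group2 = b,
               n1 = length(va), n2 = length(vb),
               t_statistic = tt$statistic, p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mark <- .sigMark(out$p_value)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
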