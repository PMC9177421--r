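# TCR dissimilarity index: mean pairwise sequence distance among the most
# expanded CDR3beta clonotypes. Low values indicate convergent clonal
# expansion (the biggest clones share similar receptors), a correlate of
# antigen-driven T cell activity.

# Global alignment distance between two CDR3beta sequences under a
# BLOSUM62-derived residue cost: cost 0 for identical residues, otherwise
# (max BLOSUM62 self-score - pair score); gaps cost the maximum residue
# cost. Dynamic programming, minimizing.
.blosumCostMatrices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b62 <- .blosum62()
      cost <- max(diag(b62)) - b62
      cost[row(cost) == col(cost)] <- 0
      cache <<- list(cost = cost, gap = max(cost))
    }
    cache
  }
})

.alignmentDistance <- function(s1, s2, metric = c("blosum", "edit")) {
  metric <- match.arg(metric)
  if (metric == "edit")
    return(as.numeric(utils::adist(s1, s2)))
  cm <- .blosumCostMatrices()
  a <- .splitAA(s1); b <- .splitAA(s2)
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- (0:n) * cm$gap
  D[1L, ] <- (0:m) * cm$gap
  for (i in seq_len(n)) {
    subCosts <- cm$cost[a[i], b]
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + subCosts[j],
                               D[i, j + 1L] + cm$gap,
                               D[i + 1L, j] + cm$gap)
    }
  }
  D[n + 1L, m + 1L]
}

#' Pairwise CDR3 distance
#'
#' Length-normalized distance between two CDR3beta sequences: the global
#' alignment cost (see package vignette) divided by the mean of the two
#' lengths. \code{metric = "edit"} uses plain Levenshtein distance instead
#' of the BLOSUM62-derived cost.
#'
#' @param s1,s2 CDR3beta amino-acid sequences.
#' @param metric \code{"blosum"} (default) or \code{"edit"}.
#' @return Non-negative distance; 0 iff the sequences are identical.
#' @export
cdr3Distance <- function(s1, s2, metric = c("blosum", "edit")) {
  metric <- match.arg(metric)
  .alignmentDistance(toupper(s1), toupper(s2), metric) /
    mean(c(nchar(s1), nchar(s2)))
}

#' Most expanded clonotypes of a repertoire
#'
#' @param repertoire A [TcrRepertoire-class].
#' @param k Number of clonotypes; count ties are broken by CDR3beta
#'   lexicographic order.
#' @return data.frame of the top clonotypes.
#' @export
topClonotypes <- function(repertoire, k) {
  cl <- clonotypes(repertoire)
  ord <- order(-cl$count, cl$cdr3b)
  cl[ord[seq_len(min(k, nrow(cl)))], , drop = FALSE]
}

#' TCR dissimilarity index
#'
#' Mean pairwise length-normalized distance among the k most expanded
#' CDR3beta clonotypes. The index is 0 iff the top clonotypes are all
#' identical, is invariant to uniform count rescaling (selection is
#' rank-based) and to clonotype input order.
#'
#' @param repertoire A [TcrRepertoire-class] with at least 2 clonotypes.
#' @param k Number of top clonotypes to compare (default 10).
#' @param metric Distance metric, \code{"blosum"} or \code{"edit"} (see
#'   [cdr3Distance()]).
#' @return One-row data.frame: \code{sample_id, index, k_used, metric}.
#' @export
dissimilarityIndex <- function(repertoire, k = 10L,
                               metric = c("blosum", "edit")) {
  metric <- match.arg(metric)
  cl <- clonotypes(repertoire)
  if (nrow(cl) == 1L && cl$count >= 2L) {
    # a fully convergent expansion: every top clonotype is the same sequence
    return(data.frame(sample_id = repertoire@sampleId, index = 0,
                      k_used = min(k, cl$count), metric = metric,
                      row.names = NULL))
  }
  if (nrow(cl) < 2L) stop("need at least 2 clonotypes")
  top <- topClonotypes(repertoire, k)
  seqs <- top$cdr3b
  pairs <- utils::combn(length(seqs), 2L)
  d <- vapply(seq_len(ncol(pairs)), function(i)
    cdr3Distance(seqs[pairs[1, i]], seqs[pairs[2, i]], metric), 0)
  data.frame(sample_id = repertoire@sampleId, index = mean(d),
             k_used = length(seqs), metric = metric, row.names = NULL)
}

#' Correlate repertoire convergence with immune fitness cost
#'
#' Two-tailed Pearson correlation (and linear-fit slope) between per-sample
#' TCR dissimilarity indices and mean immune fitness costs: convergent
#' expansion (low index) in more highly edited tumours (low cost) shows as a
#' positive correlation.
#'
#' @param cohort data.frame with columns \code{index} and
#'   \code{mean_immune_cost}, one row per sample (>= 3 rows).
#' @return List with \code{r}, \code{p} and \code{slope}.
#' @export
expansionVsEditing <- function(cohort) {
  stopifnot(all(c("index", "mean_immune_cost") %in% names(cohort)))
  ok <- is.finite(cohort$index) & is.finite(cohort$mean_immune_cost)
  x <- cohort$index[ok]; y <- cohort$mean_immune_cost[ok]
  if (length(x) < 3L) stop("need at least 3 samples with both quantities")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in index or immune cost")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]))
}
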