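# Tumour- and cohort-level immunoediting statistics: clonal entropy, burden
# deltas between paired primary/recurrent tumours, depletion distributions
# and the substitution-frequency regression against the matrix distance.

#' Shannon entropy of a clone frequency distribution
#'
#' S = -sum x log x in nats (0 log 0 = 0); frequencies are renormalized to
#' sum 1 first.
#'
#' @param frequencies Non-negative frequencies, at least one positive.
#' @param base Logarithm base: \code{"nats"} (natural, default) or
#'   \code{"bits"} (log2 display).
#' @return Entropy (scalar).
#' @examples
#' shannonEntropy(rep(0.25, 4))  # log(4)
#' @export
shannonEntropy <- function(frequencies, base = c("nats", "bits")) {
  base <- match.arg(base)
  if (any(frequencies < 0)) stop("negative frequencies")
  s <- sum(frequencies)
  if (s == 0) stop("all frequencies are zero")
  x <- frequencies[frequencies > 0] / s
  h <- -sum(x * log(x))
  if (base == "bits") h / log(2) else h
}

# Mutations present in a sample: carried by any clone whose frequency
# exceeds the presence threshold.
.presentMutations <- function(tree, sample, presenceThreshold) {
  x <- cloneFrequencies(tree, sample)
  present <- names(x)[x > presenceThreshold]
  unique(unlist(lapply(present, function(cl) cloneGenotype(tree, cl))))
}

#' Summarize one tumour sample
#'
#' Computes the clonal Shannon entropy, the tumour mutational burden (TMB:
#' non-synonymous mutations carried by any clone above the presence
#' threshold), the neoantigen count (records whose mutant Kd passes the
#' binder threshold and whose mutation is present), the count of distinct
#' neoantigen-generating mutations, and the mean immune fitness cost
#' (frequency-weighted mean of per-clone F_I by default).
#'
#' @param tree A [CloneTree-class].
#' @param sample Sample id in the tree.
#' @param mutations Mutation data.frame (\code{mutation_id, effect}).
#' @param neoantigens Neoantigen data.frame (\code{mutation_id, kd_mt}).
#' @param qualities Named per-mutation quality vector (for F_I); may be
#'   \code{NULL} to skip the immune-cost column.
#' @param presenceThreshold Clone frequency above which a clone counts as
#'   present (default 0.01, the sampling noise floor).
#' @param binderThreshold Mutant Kd (nM) at or below which a peptide counts
#'   as an MHC-I binder (default 500 nM, the conventional cutoff).
#' @param weighted Frequency-weight the immune-cost mean (default TRUE);
#'   FALSE averages F_I over present clones unweighted.
#' @return One-row data.frame: \code{tumor_id, role, shannon_entropy, tmb,
#'   na_count, na_mut_count, mean_immune_cost}.
#' @export
summarizeTumor <- function(tree, sample, mutations, neoantigens,
                           qualities = NULL, presenceThreshold = 0.01,
                           binderThreshold = 500, weighted = TRUE) {
  x <- cloneFrequencies(tree, sample)
  entropy <- shannonEntropy(x)
  present <- .presentMutations(tree, sample, presenceThreshold)

  nonSyn <- mutations$mutation_id[mutations$effect %in%
                                    c("missense", "nonsense")]
  tmb <- length(intersect(present, nonSyn))

  na <- neoantigens[neoantigens$mutation_id %in% present &
                      neoantigens$kd_mt <= binderThreshold, , drop = FALSE]
  naCount <- nrow(na)
  naMutCount <- length(unique(na$mutation_id))

  meanCost <- NA_real_
  if (!is.null(qualities)) {
    ids <- cloneIds(tree)
    fi <- vapply(ids, function(cl) immuneFitnessCost(tree, cl, qualities), 0)
    presentClones <- x > presenceThreshold
    if (any(presentClones)) {
      meanCost <- if (weighted) {
        sum(x[presentClones] * fi[presentClones]) / sum(x[presentClones])
      } else {
        mean(fi[presentClones])
      }
    }
  }
  data.frame(tumor_id = sample,
             role = unname(sampleRoles(tree)[sample]),
             shannon_entropy = entropy, tmb = tmb, na_count = naCount,
             na_mut_count = naMutCount, mean_immune_cost = meanCost,
             row.names = NULL)
}

#' Paired primary/recurrent deltas for one patient
#'
#' All deltas are recurrent minus primary. New clones are clones above the
#' presence threshold in the recurrent sample but not in the primary; the
#' percentage of new neoantigens is the share of recurrent neoantigens whose
#' mutation is private to new clones. When the recurrent tumour carries no
#' neoantigens the percentage is 0 and \code{no_recurrent_neoantigens} is
#' flagged.
#'
#' @inheritParams summarizeTumor
#' @param primarySample,recurrentSample Sample ids in the tree.
#' @return One-row data.frame of deltas plus \code{pct_new_neoantigens} and
#'   \code{new_clone_mean_immune_cost}.
#' @export
pairedDeltas <- function(tree, primarySample, recurrentSample, mutations,
                         neoantigens, qualities = NULL,
                         presenceThreshold = 0.01, binderThreshold = 500,
                         weighted = TRUE) {
  sPrim <- summarizeTumor(tree, primarySample, mutations, neoantigens,
                          qualities, presenceThreshold, binderThreshold,
                          weighted)
  sRec <- summarizeTumor(tree, recurrentSample, mutations, neoantigens,
                         qualities, presenceThreshold, binderThreshold,
                         weighted)
  xPrim <- cloneFrequencies(tree, primarySample)
  xRec <- cloneFrequencies(tree, recurrentSample)
  newClones <- names(xRec)[xRec > presenceThreshold &
                             xPrim <= presenceThreshold]
  oldPresent <- names(xRec)[xRec > presenceThreshold &
                              xPrim > presenceThreshold]

  recMuts <- .presentMutations(tree, recurrentSample, presenceThreshold)
  recNa <- neoantigens[neoantigens$mutation_id %in% recMuts &
                         neoantigens$kd_mt <= binderThreshold, , drop = FALSE]
  newMuts <- unique(unlist(lapply(newClones, function(cl)
    cloneGenotype(tree, cl))))
  oldMuts <- unique(unlist(lapply(oldPresent, function(cl)
    cloneGenotype(tree, cl))))
  privateNew <- setdiff(newMuts, oldMuts)
  noRecNa <- nrow(recNa) == 0L
  pctNew <- if (noRecNa) 0 else
    100 * sum(recNa$mutation_id %in% privateNew) / nrow(recNa)

  newCost <- NA_real_
  if (!is.null(qualities) && length(newClones) > 0) {
    fi <- vapply(newClones, function(cl)
      immuneFitnessCost(tree, cl, qualities), 0)
    wts <- xRec[newClones]
    newCost <- if (weighted) sum(wts * fi) / sum(wts) else mean(fi)
  }
  data.frame(delta_entropy = sRec$shannon_entropy - sPrim$shannon_entropy,
             delta_tmb = sRec$tmb - sPrim$tmb,
             delta_na = sRec$na_count - sPrim$na_count,
             delta_na_mut = sRec$na_mut_count - sPrim$na_mut_count,
             n_new_clones = length(newClones),
             pct_new_neoantigens = pctNew,
             no_recurrent_neoantigens = noRecNa,
             new_clone_mean_immune_cost = newCost,
             row.names = NULL)
}

#' Depletion analysis: compare logC and D distributions between groups
#'
#' Empirical CDFs of the cross-reactivity distance log C and the
#' self-discrimination D for two groups of scored neoantigens, with
#' two-sided Kolmogorov-Smirnov tests per statistic.
#'
#' @param groupA,groupB data.frames of scored neoantigens (needs columns
#'   \code{log_c} and \code{D}, as from [neoantigenQuality()]).
#' @param statistics Columns to compare (default \code{c("log_c", "D")}).
#' @return Named list per statistic: \code{ecdf_a}, \code{ecdf_b} (functions),
#'   \code{ks_statistic}, \code{p_value}.
#' @export
depletionAnalysis <- function(groupA, groupB,
                              statistics = c("log_c", "D")) {
  out <- list()
  for (st in statistics) {
    a <- groupA[[st]]; b <- groupB[[st]]
    if (is.null(a) || is.null(b) || sum(is.finite(a)) < 2L ||
        sum(is.finite(b)) < 2L)
      stop(sprintf("need at least 2 finite values per group for %s", st))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    ks <- suppressWarnings(
      stats::ks.test(a, b, alternative = "two.sided"))
    out[[st]] <- list(ecdf_a = stats::ecdf(a), ecdf_b = stats::ecdf(b),
                      ks_statistic = unname(ks$statistic),
                      p_value = ks$p.value)
  }
  out
}

#' Regression of observed substitution frequency on matrix distance
#'
#' Normalizes observed substitution counts to proportions and regresses them
#' on the substitution-matrix distance M[wt, mt]; immunoediting predicts
#' fewer observed substitutions at larger antigenic distance (negative
#' slope).
#'
#' @param counts data.frame with \code{wt_residue, mt_residue, count}.
#' @param model A [CrossReactModel-class] (or 20 x 20 named matrix).
#' @return List with \code{slope}, \code{r} (two-tailed Pearson),
#'   \code{p} and the per-substitution \code{table}.
#' @export
substitutionFrequencyRegression <- function(counts, model) {
  M <- if (methods::is(model, "CrossReactModel")) model@matrix else model
  stopifnot(all(c("wt_residue", "mt_residue", "count") %in% names(counts)))
  counts <- counts[counts$wt_residue != counts$mt_residue, , drop = FALSE]
  if (nrow(counts) < 3L)
    stop("need at least 3 distinct substitution types")
  prop <- counts$count / sum(counts$count)
  dist <- M[cbind(counts$wt_residue, counts$mt_residue)]
  if (stats::sd(dist) == 0) stop("no variance in matrix distance")
  fit <- stats::lm(prop ~ dist)
  ct <- stats::cor.test(prop, dist, method = "pearson",
                        alternative = "two.sided")
  list(slope = unname(stats::coef(fit)[2]), r = unname(ct$estimate),
       p = ct$p.value,
       table = data.frame(wt_residue = counts$wt_residue,
                          mt_residue = counts$mt_residue,
                          proportion = prop, m_distance = dist,
                          row.names = NULL))
}

#' Two-tailed Mann-Whitney U comparison of two groups
#'
#' Convenience wrapper used for cohort-level group contrasts (e.g. entropy
#' or burden deltas between survivor groups).
#'
#' @param x,y Numeric vectors.
#' @return List with \code{statistic} (U), \code{p}, and the group medians.
#' @export
compareGroups <- function(x, y) {
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_x = stats::median(x), median_y = stats::median(y))
}
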