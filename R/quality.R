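# Neoantigen quality Q = R x D.
#
# R (recognition potential): how similar the mutant peptide is to known
# immunogenic epitopes, aggregated through a logistic partition over gapless
# alignment scores — a proxy for lying inside the recognition space of the
# TCR repertoire.
# D (self-discrimination): (1-w) log(Kd^WT/Kd^MT) + w log(EC50^MT/EC50^WT),
# combining differential MHC presentation (amplitude A) with the TCR
# cross-reactivity distance C — a proxy for lying outside the toleration
# space. Natural logs throughout.

#' Best gapless alignment score between two peptides
#'
#' Slides the shorter sequence over the longer at every full-overlap offset
#' and sums BLOSUM62 residue scores; the maximum window score is returned.
#' No gaps are opened.
#'
#' @param x,y Amino-acid sequences (uppercase).
#' @return Integer alignment score.
#' @export
gaplessAlignmentScore <- function(x, y) {
  b62 <- .blosum62()
  a <- .splitAA(toupper(x)); b <- .splitAA(toupper(y))
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  ns <- length(a); nl <- length(b)
  best <- -Inf
  for (off in 0:(nl - ns)) {
    sc <- sum(b62[cbind(a, b[seq_len(ns) + off])])
    if (sc > best) best <- sc
  }
  best
}

# Alignment scores of one peptide against every epitope in the set.
.epitopeScores <- function(peptide, epitopes) {
  seqs <- as.character(epitopeSequences(epitopes))
  vapply(seqs, function(e) gaplessAlignmentScore(peptide, e), 0)
}

#' Recognition potential of a mutant neopeptide
#'
#' R = Z^-1 sum_e exp(-k (a - s_e)) with Z = 1 + sum_e exp(-k (a - s_e)),
#' where s_e is the best gapless BLOSUM62 alignment score of the peptide
#' against epitope e. R lies in [0, 1) and saturates towards 1 as alignment
#' scores exceed the displacement a.
#'
#' @param pMt Mutant peptide sequence.
#' @param params A [QualityParams-class] (supplies a, k and the epitope set).
#' @param scores Optional precomputed alignment scores (named by epitope id)
#'   to avoid re-aligning across a parameter grid.
#' @return List with \code{R} and \code{bestEpitope} (id of the top-scoring
#'   epitope, \code{NA} for an empty set). An empty epitope set gives R = 0
#'   with a warning.
#' @export
recognitionPotential <- function(pMt, params, scores = NULL) {
  stopifnot(methods::is(params, "QualityParams"))
  if (is.null(scores)) {
    if (length(params@epitopes) == 0L) {
      warning("empty epitope set: recognition potential is 0")
      return(list(R = 0, bestEpitope = NA_character_))
    }
    scores <- .epitopeScores(pMt, params@epitopes)
    names(scores) <- epitopeIds(params@epitopes)
  }
  if (length(scores) == 0L) return(list(R = 0, bestEpitope = NA_character_))
  terms <- exp(-params@k * (params@a - scores))
  s <- sum(terms)
  list(R = s / (1 + s), bestEpitope = names(scores)[which.max(scores)])
}

#' Self-discrimination of a neoantigenic substitution
#'
#' D = (1 - w) log(Kd^WT / Kd^MT) + w logC, where the first term is the MHC
#' amplitude (differential presentation of mutant vs wild-type peptide) and
#' logC is the predicted TCR cross-reactivity distance. Natural logs.
#'
#' @param pWt,pMt Wild-type and mutant peptides (equal length).
#' @param kdWt,kdMt Dissociation constants in nM (> 0).
#' @param model A [CrossReactModel-class] used to predict logC.
#' @param w Weight in [0, 1] between the two terms.
#' @return List with \code{logA}, \code{logC} and \code{D}.
#' @export
selfDiscrimination <- function(pWt, pMt, kdWt, kdMt, model, w) {
  stopifnot(kdWt > 0, kdMt > 0, w >= 0, w <= 1)
  logA <- log(kdWt / kdMt)
  logC <- predictLogC(pWt, pMt, model)
  list(logA = logA, logC = logC, D = (1 - w) * logA + w * logC)
}

#' Score neoantigen quality for a table of records
#'
#' Computes, per record, the recognition potential R, the MHC amplitude
#' log A, the predicted cross-reactivity distance log C, self-discrimination
#' D and quality Q = R x D.
#'
#' @param records data.frame as returned by [readNeoantigenTable()] (needs
#'   \code{p_wt, p_mt, kd_wt, kd_mt}).
#' @param params A [QualityParams-class].
#' @param model A [CrossReactModel-class].
#' @return The input data.frame with columns \code{R, best_epitope, log_a,
#'   log_c, D, Q} appended.
#' @export
neoantigenQuality <- function(records, params, model) {
  stopifnot(is.data.frame(records),
            all(c("p_wt", "p_mt", "kd_wt", "kd_mt") %in% names(records)))
  n <- nrow(records)
  R <- numeric(n); best <- character(n)
  logA <- numeric(n); logC <- numeric(n)
  emptySet <- length(params@epitopes) == 0L
  if (emptySet && n > 0)
    warning("empty epitope set: recognition potential is 0 for all records")
  for (i in seq_len(n)) {
    if (emptySet) {
      R[i] <- 0; best[i] <- NA_character_
    } else {
      rp <- recognitionPotential(records$p_mt[i], params)
      R[i] <- rp$R; best[i] <- rp$bestEpitope
    }
    sd <- selfDiscrimination(records$p_wt[i], records$p_mt[i],
                             records$kd_wt[i], records$kd_mt[i],
                             model, params@w)
    logA[i] <- sd$logA; logC[i] <- sd$logC
  }
  D <- (1 - params@w) * logA + params@w * logC
  out <- records
  out$R <- R
  out$best_epitope <- best
  out$log_a <- logA
  out$log_c <- logC
  out$D <- D
  out$Q <- R * D
  out
}

#' Write quality scores as TSV
#' @param scored data.frame from [neoantigenQuality()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeQualityTable <- function(scored, path) {
  .atomicWrite(path, function(tmp)
    utils::write.table(scored, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Select quality-model parameters by log-rank score
#'
#' For every grid point (w, a, k), scores all neoantigens, summarizes each
#' patient (max Q by default, mirroring the clone-level max of the fitness
#' model), splits the cohort at the median of the summary, and computes the
#' two-sided log-rank statistic between the arms. Returns the grid point
#' maximizing the statistic; ties are broken by smallest (w, a, k) in
#' lexicographic order. Grid points giving a degenerate split (an empty arm)
#' score -Inf. Alignment scores are computed once per record and reused
#' across the grid.
#'
#' @param records Neoantigen data.frame (needs \code{patient_id, p_wt, p_mt,
#'   kd_wt, kd_mt}).
#' @param survivalData data.frame with \code{patient_id, time, event}
#'   (event: 1 = death observed, 0 = censored).
#' @param epitopes An [EpitopeSet-class].
#' @param model A [CrossReactModel-class].
#' @param grid data.frame with columns \code{w, a, k}.
#' @param summary Per-patient aggregation of Q: \code{"max"} or
#'   \code{"mean"}.
#' @return List with \code{best} (a [QualityParams-class]), \code{scores}
#'   (the grid with a \code{logrank} column) and \code{summaryFun}.
#' @export
selectParamsByLogrank <- function(records, survivalData, epitopes, model,
                                  grid, summary = c("max", "mean")) {
  summary <- match.arg(summary)
  stopifnot(all(c("w", "a", "k") %in% names(grid)), nrow(grid) >= 1L,
            all(c("patient_id", "time", "event") %in% names(survivalData)))
  if (sum(survivalData$event) == 0L)
    stop("all-censored cohort: log-rank statistic undefined")
  patients <- survivalData$patient_id
  if (length(patients) < 4L)
    stop("need at least 2 patients per arm")

  scoresList <- lapply(records$p_mt, .epitopeScores, epitopes = epitopes)
  logA <- log(records$kd_wt / records$kd_mt)
  logC <- mapply(predictLogC, records$p_wt, records$p_mt,
                 MoreArgs = list(model = model))
  aggFun <- if (summary == "max") max else mean

  grid <- grid[order(grid$w, grid$a, grid$k), , drop = FALSE]
  stat <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    wg <- grid$w[g]; ag <- grid$a[g]; kg <- grid$k[g]
    R <- vapply(scoresList, function(s) {
      z <- sum(exp(-kg * (ag - s))); z / (1 + z)
    }, 0)
    Q <- R * ((1 - wg) * logA + wg * logC)
    perPatient <- tapply(Q, records$patient_id, aggFun)
    v <- perPatient[as.character(patients)]
    v[is.na(v)] <- 0  # patients without neoantigens
    split <- v > stats::median(v)
    if (length(unique(split)) < 2L) { stat[g] <- -Inf; next }
    sd <- survival::survdiff(
      survival::Surv(survivalData$time, survivalData$event) ~ split)
    stat[g] <- sd$chisq
  }
  bestIdx <- which.max(stat)  # grid pre-sorted: first max = lexicographic min
  list(best = QualityParams(grid$w[bestIdx], grid$a[bestIdx], grid$k[bestIdx],
                            epitopes = epitopes),
       scores = cbind(grid, logrank = stat),
       summaryFun = summary)
}
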