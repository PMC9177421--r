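# Learning the substitution matrix M and position-weight profile from EC50
# scans, and predicting cross-reactivity distance for arbitrary
# single-substitution peptide pairs.
#
# Model: log C(i, a -> b) = w_i * M[a, b]. The decomposition is fitted by
# alternating least squares over the position weights and the matrix cells;
# the scale degeneracy (w * M vs cw * M/c) is resolved by normalizing the
# interior position weights to mean 1.

#' Learn a cross-reactivity model from logC observations
#'
#' Pools observations across TCRs (each an observed natural-log EC50 ratio
#' for a single substitution) and decomposes them into a per-position weight
#' profile and a 20 x 20 residue matrix by alternating minimization, iterated
#' until the relative change in residual sum of squares falls below
#' \code{tol} (or \code{maxIter} sweeps). Identity cells are pinned to 0.
#' Off-diagonal cells with no observations are imputed from the mean of
#' observed cells within the same wild-type/mutant biochemical family pair,
#' falling back to the global off-diagonal observed mean; their support is
#' recorded as 0 so they can be filtered downstream.
#'
#' @param observations data.frame with columns \code{position} (1-based),
#'   \code{wt_residue}, \code{mt_residue} and \code{log_c} (finite), e.g.
#'   from [fitScan()].
#' @param peptideLength Length of the scanned peptide(s); defaults to the
#'   largest observed position.
#' @param tol Relative RSS convergence tolerance.
#' @param maxIter Maximum alternating sweeps.
#' @return A [CrossReactModel-class].
#' @export
buildCrossReactModel <- function(observations,
                                 peptideLength = max(observations$position),
                                 tol = 1e-8, maxIter = 200L) {
  required <- c("position", "wt_residue", "mt_residue", "log_c")
  stopifnot(all(required %in% names(observations)))
  obs <- observations[observations$wt_residue != observations$mt_residue, ,
                      drop = FALSE]
  if (nrow(obs) == 0L) stop("no non-identity observations")
  if (any(!is.finite(obs$log_c))) stop("log_c must be finite")
  if (!all(obs$wt_residue %in% .AA20) || !all(obs$mt_residue %in% .AA20))
    stop("residues must be standard one-letter amino-acid codes")
  L <- as.integer(peptideLength)
  if (any(obs$position < 1L | obs$position > L))
    stop("observation positions outside the peptide length")

  pos <- obs$position
  y <- obs$log_c
  cell <- paste0(obs$wt_residue, obs$mt_residue)
  cells <- unique(cell)
  cellIdx <- split(seq_along(y), cell)

  singlePosition <- length(unique(pos)) < 2L
  if (singlePosition)
    warning("observations cover a single position; profile fixed to all ones")

  w <- rep(1, L)
  m <- stats::setNames(rep(0, length(cells)), cells)
  rssOld <- Inf
  for (iter in seq_len(maxIter)) {
    # matrix cells given weights
    for (cl in cells) {
      i <- cellIdx[[cl]]
      denom <- sum(w[pos[i]]^2)
      m[cl] <- if (denom > 0) sum(w[pos[i]] * y[i]) / denom else 0
    }
    # weights given matrix cells
    if (!singlePosition) {
      mObs <- m[cell]
      for (p in unique(pos)) {
        i <- which(pos == p)
        denom <- sum(mObs[i]^2)
        if (denom > 0) w[p] <- sum(mObs[i] * y[i]) / denom
      }
      w <- pmax(w, 0)
    }
    rss <- sum((y - w[pos] * m[cell])^2)
    if (is.finite(rssOld) &&
        abs(rssOld - rss) <= tol * max(rssOld, .Machine$double.eps)) break
    rssOld <- rss
  }

  # resolve scale: interior positions average to weight 1
  interior <- if (L > 2L) 2:(L - 1L) else seq_len(L)
  s <- mean(w[interior])
  if (s > 0) { w <- w / s; m <- m * s }

  M <- matrix(0, 20, 20, dimnames = list(.AA20, .AA20))
  support <- matrix(0L, 20, 20, dimnames = list(.AA20, .AA20))
  for (cl in cells) {
    a <- substr(cl, 1, 1); b <- substr(cl, 2, 2)
    M[a, b] <- m[cl]
    support[a, b] <- length(cellIdx[[cl]])
  }

  # impute unobserved off-diagonal cells
  offdiag <- row(M) != col(M)
  observedCells <- support > 0
  globalMean <- mean(M[offdiag & observedCells])
  if (!is.finite(globalMean)) globalMean <- 0
  famOf <- vapply(.AA20, .aaFamily, "")
  for (a in .AA20) for (b in .AA20) {
    if (a == b || support[a, b] > 0) next
    sameFam <- observedCells & offdiag &
      outer(famOf == famOf[a], famOf == famOf[b], "&")
    M[a, b] <- if (any(sameFam)) mean(M[sameFam]) else globalMean
  }
  diag(M) <- 0

  methods::new("CrossReactModel", matrix = M, support = support,
               weights = w, combiner = "multiplicative")
}

#' Predict the log cross-reactivity distance of a peptide pair
#'
#' For a single substitution at position i, log C = w(i) * M[wt, mt], where
#' w(i) is the position weight (linearly interpolated over normalized
#' position when the peptide length differs from the training length).
#' Identity pairs return 0; multi-substitution pairs return the sum of
#' per-substitution terms (an extension beyond single-substitution scans).
#'
#' @param pWt,pMt Equal-length peptides (uppercase amino acids).
#' @param model A [CrossReactModel-class].
#' @return Natural-log cross-reactivity distance (numeric scalar).
#' @examples
#' \dontrun{predictLogC("NLVPMVATV", "NLVPKVATV", model)}
#' @export
predictLogC <- function(pWt, pMt, model) {
  stopifnot(methods::is(model, "CrossReactModel"))
  pWt <- toupper(pWt); pMt <- toupper(pMt)
  if (nchar(pWt) != nchar(pMt))
    stop("peptides must have equal length")
  if (!.validAASeq(pWt) || !.validAASeq(pMt))
    stop("invalid amino-acid characters")
  a <- .splitAA(pWt); b <- .splitAA(pMt)
  subs <- which(a != b)
  if (length(subs) == 0L) return(0)
  n <- length(a)
  sum(vapply(subs, function(i) {
    .positionWeight(model@weights, i, n) * model@matrix[a[i], b[i]]
  }, 0))
}

# Weight at position i of an n-mer: exact when n equals the training length,
# otherwise linear interpolation over normalized position (0 = N-terminus).
.positionWeight <- function(weights, i, n) {
  L <- length(weights)
  if (n == L) return(weights[i])
  xTrain <- if (L > 1L) (seq_len(L) - 1) / (L - 1) else 0.5
  xq <- if (n > 1L) (i - 1) / (n - 1) else 0.5
  if (L == 1L) return(weights[1])
  stats::approx(xTrain, weights, xout = xq, rule = 2)$y
}

#' Agglomerative clustering of residues from the substitution matrix
#'
#' Clusters the 20 residues by average linkage on the Euclidean distance
#' between rows of the symmetrized matrix (M + t(M))/2, so residues with
#' identical substitution behaviour merge at height 0. Leaf labels follow
#' alphabetical input order, making the dendrogram deterministic.
#'
#' @param x A [CrossReactModel-class] or a 20 x 20 named matrix.
#' @return List with \code{hclust} (the tree) and \code{order} (leaf labels
#'   left to right).
#' @export
clusterResidues <- function(x) {
  M <- if (methods::is(x, "CrossReactModel")) x@matrix else x
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(is.finite(M)))
  msym <- (M + t(M)) / 2
  hc <- stats::hclust(stats::dist(msym), method = "average")
  list(hclust = hc, order = rownames(msym)[hc$order])
}

#' Serialize a cross-reactivity model to JSON
#' @param model A [CrossReactModel-class].
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeCrossReactModel <- function(model, path) {
  rowsOf <- function(m) lapply(seq_len(nrow(m)),
                               function(i) unname(as.numeric(m[i, ])))
  obj <- list(combiner = model@combiner,
              residues = .AA20,
              matrix = rowsOf(model@matrix),
              support = rowsOf(model@support),
              weights = model@weights,
              provenance = list(n_observations = sum(model@support)))
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
}

#' Read a cross-reactivity model from JSON
#' @param path Path written by [writeCrossReactModel()].
#' @return A [CrossReactModel-class].
#' @export
readCrossReactModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  toMat <- function(x, mode) {
    mm <- if (is.matrix(x)) {
      x
    } else if (is.data.frame(x)) {
      as.matrix(x)
    } else {
      matrix(unlist(x), 20, 20, byrow = TRUE)
    }
    storage.mode(mm) <- mode
    dimnames(mm) <- list(obj$residues, obj$residues)
    mm
  }
  M <- toMat(obj$matrix, "double")
  support <- toMat(obj$support, "integer")
  methods::new("CrossReactModel", matrix = M[.AA20, .AA20],
               support = support[.AA20, .AA20],
               weights = as.numeric(obj$weights), combiner = obj$combiner)
}

#' Export the substitution matrix as TSV (for plotting)
#' @param model A [CrossReactModel-class].
#' @param path Output TSV path; rows = wild-type residue, columns = mutant.
#' @return Invisibly, \code{path}.
#' @export
exportSubstitutionMatrix <- function(model, path) {
  df <- data.frame(wt_residue = rownames(model@matrix), model@matrix,
                   check.names = FALSE)
  .atomicWrite(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}
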