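# Generics, accessors and show methods.

#' @rdname EpitopeSet-class
#' @param object An object.
#' @export
setGeneric("epitopeIds", function(object) standardGeneric("epitopeIds"))

#' @rdname EpitopeSet-class
#' @export
setMethod("epitopeIds", "EpitopeSet", function(object) names(object@sequences))

#' @rdname EpitopeSet-class
#' @export
setGeneric("epitopeSequences",
           function(object) standardGeneric("epitopeSequences"))

#' @rdname EpitopeSet-class
#' @export
setMethod("epitopeSequences", "EpitopeSet",
          function(object) object@sequences)

setMethod("show", "EpitopeSet", function(object) {
  cat(sprintf("EpitopeSet with %d epitope(s)\n", length(object@sequences)))
  if (length(object@sequences) > 0) {
    n <- min(3L, length(object@sequences))
    for (i in seq_len(n))
      cat(sprintf("  %s: %s\n", names(object@sequences)[i],
                  as.character(object@sequences[[i]])))
    if (length(object@sequences) > n) cat("  ...\n")
  }
})

#' @rdname EpitopeSet-class
#' @param x An \code{EpitopeSet}.
#' @export
setMethod("length", "EpitopeSet", function(x) length(x@sequences))

#' @rdname CloneTree-class
#' @param object An object.
#' @export
setGeneric("cloneIds", function(object) standardGeneric("cloneIds"))

#' @rdname CloneTree-class
#' @export
setMethod("cloneIds", "CloneTree", function(object) object@cloneIds)

#' @rdname CloneTree-class
#' @export
setGeneric("parentIds", function(object) standardGeneric("parentIds"))

#' @rdname CloneTree-class
#' @export
setMethod("parentIds", "CloneTree",
          function(object) stats::setNames(object@parentIds, object@cloneIds))

#' @rdname CloneTree-class
#' @export
setGeneric("cloneFrequencies",
           function(object, sample) standardGeneric("cloneFrequencies"))

#' Clone frequencies of one sample (or the full matrix)
#' @rdname CloneTree-class
#' @param sample Sample id; if missing, the full clones x samples matrix.
#' @export
setMethod("cloneFrequencies", "CloneTree", function(object, sample) {
  if (missing(sample)) return(object@frequencies)
  if (!sample %in% colnames(object@frequencies))
    stop(sprintf("sample '%s' not in tree (has: %s)", sample,
                 paste(colnames(object@frequencies), collapse = ", ")))
  object@frequencies[, sample]
})

#' @rdname CloneTree-class
#' @export
setGeneric("sampleRoles", function(object) standardGeneric("sampleRoles"))

#' @rdname CloneTree-class
#' @export
setMethod("sampleRoles", "CloneTree", function(object)
  object@sampleRoles[colnames(object@frequencies)])

#' @rdname CloneTree-class
#' @export
setGeneric("ownMutations", function(object) standardGeneric("ownMutations"))

#' @rdname CloneTree-class
#' @export
setMethod("ownMutations", "CloneTree",
          function(object) object@ownMutations[object@cloneIds])

#' Genotype of a clone: own mutations plus all inherited ones
#'
#' @param object A [CloneTree-class].
#' @param cloneId Clone identifier.
#' @return Character vector of mutation ids along the root path.
#' @export
setGeneric("cloneGenotype",
           function(object, cloneId) standardGeneric("cloneGenotype"))

#' @rdname cloneGenotype
#' @export
setMethod("cloneGenotype", "CloneTree", function(object, cloneId) {
  if (!cloneId %in% object@cloneIds)
    stop(sprintf("clone '%s' not in tree", cloneId))
  idx <- stats::setNames(seq_along(object@cloneIds), object@cloneIds)
  muts <- character(0)
  j <- idx[[cloneId]]
  repeat {
    muts <- c(muts, object@ownMutations[[object@cloneIds[j]]])
    p <- object@parentIds[j]
    if (is.na(p)) break
    j <- idx[[p]]
  }
  unique(muts)
})

setMethod("show", "CloneTree", function(object) {
  roles <- sampleRoles(object)
  cat(sprintf("CloneTree: %d clones, %d sample(s) [%s]\n",
              length(object@cloneIds), ncol(object@frequencies),
              paste(sprintf("%s=%s", names(roles), roles), collapse = ", ")))
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf(
    "HillFit: EC50 = %.3g M, h = %.2f, emax = %.3g, baseline = %.3g%s\n",
    object@ec50, object@hill, object@emax, object@baseline,
    if (object@censored) " [censored]" else ""))
})

setMethod("show", "CrossReactModel", function(object) {
  off <- object@matrix[row(object@matrix) != col(object@matrix)]
  cat(sprintf(paste0(
    "CrossReactModel (multiplicative position x residue decomposition)\n",
    "  peptide length: %d; observed cells: %d/380; mean |off-diag M|: %.3f\n"),
    length(object@weights), sum(object@support > 0) - 0L, mean(abs(off))))
})

setMethod("show", "SelectionFit", function(object) {
  cat(sprintf(paste0(
    "SelectionFit over %d clones (n_eff = %g)\n",
    "  sigma_I = %.4g, sigma_P = %.4g, logL = %.4g\n",
    "  BIC: full = %.4g, oncogenic = %.4g, neutral = %.4g -> preferred: %s\n"),
    object@nClones, object@nEff, object@sigmaI, object@sigmaP,
    object@logLik, object@bicFull, object@bicOncogenic, object@bicNeutral,
    object@preferredModel))
})

setMethod("show", "TcrRepertoire", function(object) {
  cat(sprintf("TcrRepertoire '%s': %d clonotypes, %d total counts\n",
              object@sampleId, nrow(object@clonotypes),
              sum(object@clonotypes$count)))
})

setMethod("show", "QualityParams", function(object) {
  cat(sprintf(
    "QualityParams: w = %.3g, a = %.3g, k = %.3g; %d epitope(s)\n",
    object@w, object@a, object@k, length(object@epitopes@sequences)))
})

#' @rdname SelectionFit-class
#' @param object An object.
#' @export
setGeneric("preferredModel",
           function(object) standardGeneric("preferredModel"))

#' @rdname SelectionFit-class
#' @export
setMethod("preferredModel", "SelectionFit",
          function(object) object@preferredModel)

#' @rdname SelectionFit-class
#' @export
setGeneric("selectionParams",
           function(object) standardGeneric("selectionParams"))

#' @rdname SelectionFit-class
#' @export
setMethod("selectionParams", "SelectionFit", function(object)
  c(sigma_I = object@sigmaI, sigma_P = object@sigmaP))

#' @rdname CrossReactModel-class
#' @param object An object.
#' @export
setGeneric("substitutionMatrix",
           function(object) standardGeneric("substitutionMatrix"))

#' @rdname CrossReactModel-class
#' @export
setMethod("substitutionMatrix", "CrossReactModel",
          function(object) object@matrix)

#' @rdname CrossReactModel-class
#' @export
setGeneric("positionWeights",
           function(object) standardGeneric("positionWeights"))

#' @rdname CrossReactModel-class
#' @export
setMethod("positionWeights", "CrossReactModel",
          function(object) object@weights)

#' @rdname CrossReactModel-class
#' @export
setGeneric("matrixSupport", function(object) standardGeneric("matrixSupport"))

#' @rdname CrossReactModel-class
#' @export
setMethod("matrixSupport", "CrossReactModel", function(object) object@support)

#' @rdname TcrRepertoire-class
#' @param object An object.
#' @export
setGeneric("clonotypes", function(object) standardGeneric("clonotypes"))

#' @rdname TcrRepertoire-class
#' @export
setMethod("clonotypes", "TcrRepertoire", function(object) object@clonotypes)
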