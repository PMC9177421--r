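#' @import methods
NULL

#' Set of known immunogenic epitopes
#'
#' Container for the reference epitopes against which the recognition
#' potential of a mutant neopeptide is scored. Wraps a
#' \link[Biostrings]{AAStringSet}; entry names are epitope identifiers and
#' must be unique.
#'
#' @slot sequences An \code{AAStringSet} of uppercase amino-acid sequences
#'   over the 20-letter alphabet.
#' @seealso [readEpitopeFasta()], [recognitionPotential()]
#' @export
setClass("EpitopeSet", slots = c(sequences = "AAStringSet"))

setValidity("EpitopeSet", function(object) {
  seqs <- as.character(object@sequences)
  ids <- names(object@sequences)
  if (length(seqs) == 0L) return(TRUE)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    return("all epitopes must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate epitope ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad <- !.validAASeq(seqs)
  if (any(bad))
    return(sprintf("invalid amino-acid characters in epitope(s): %s",
                   paste(ids[bad], collapse = ", ")))
  TRUE
})

#' Single TCR-peptide dose-response curve
#'
#' Activation readout of one T cell receptor against one peptide across a
#' log-spaced concentration gradient. The unsubstituted reference peptide of
#' a scan carries \code{NA} in \code{position}.
#'
#' @slot tcrId TCR identifier.
#' @slot peptide Amino-acid sequence of the tested peptide.
#' @slot position 1-based substituted position, \code{NA} for the reference.
#' @slot wtResidue,mtResidue Wild-type and mutant residues at that position.
#' @slot concentrations Molar concentrations, strictly increasing, length
#'   at least 4.
#' @slot responses Non-negative, finite activation readouts.
#' @seealso [fitHill()]
#' @export
setClass("DoseResponseCurve",
         slots = c(tcrId = "character", peptide = "character",
                   position = "integer", wtResidue = "character",
                   mtResidue = "character", concentrations = "numeric",
                   responses = "numeric"))

setValidity("DoseResponseCurve", function(object) {
  if (length(object@concentrations) < 4L)
    return("a dose-response curve needs at least 4 points")
  if (length(object@responses) != length(object@concentrations))
    return("concentrations and responses differ in length")
  if (any(diff(object@concentrations) <= 0))
    return("concentrations must be strictly increasing")
  if (any(!is.finite(object@responses)))
    return("responses must be finite")
  if (any(object@concentrations <= 0))
    return("concentrations must be positive")
  if (!.validAASeq(object@peptide))
    return("peptide contains invalid amino-acid characters")
  TRUE
})

#' Hill fit of a dose-response curve
#'
#' Four-parameter Hill model \code{response = baseline + emax / (1 +
#' (ec50/conc)^h)} fitted by bounded least squares in log10-concentration
#' space. A peptide that never activates the TCR within the tested range is
#' censored: its EC50 is set to the highest tested concentration times the
#' censor factor so downstream log-ratios stay finite but capped.
#'
#' @slot ec50 Half-maximal effective concentration, molar.
#' @slot hill Hill coefficient (dimensionless).
#' @slot emax Fitted response amplitude.
#' @slot baseline Fitted baseline response.
#' @slot censored TRUE when the peptide did not activate within range.
#' @slot rss Residual sum of squares of the fit.
#' @slot nPoints Number of points fitted.
#' @slot concRange Lowest and highest tested concentration (molar).
#' @export
setClass("HillFit",
         slots = c(ec50 = "numeric", hill = "numeric", emax = "numeric",
                   baseline = "numeric", censored = "logical",
                   rss = "numeric", nPoints = "integer",
                   concRange = "numeric"))

setValidity("HillFit", function(object) {
  if (length(object@ec50) != 1L || !is.finite(object@ec50) || object@ec50 <= 0)
    return("ec50 must be a single positive number")
  if (length(object@concRange) != 2L || any(object@concRange <= 0))
    return("concRange must be two positive concentrations")
  TRUE
})

#' Cross-reactivity model: substitution matrix with a position profile
#'
#' Predicts the log cross-reactivity distance log C = log(EC50^MT/EC50^WT)
#' of a single amino-acid substitution as the product of a per-position
#' weight and a 20 x 20 residue substitution term: log C(i, a -> b) =
#' w_i * M[a, b]. Identity cells of M are 0 by construction. The scale
#' degeneracy of the product is resolved by normalizing the mean of the
#' interior position weights to 1.
#'
#' @slot matrix 20 x 20 numeric matrix M of log-distance values, rows =
#'   wild-type residue, columns = mutant residue, alphabetical one-letter
#'   order; asymmetric in general.
#' @slot support 20 x 20 integer matrix of observation counts per cell; 0
#'   marks imputed cells.
#' @slot weights Per-position multipliers (length = training peptide length).
#' @slot combiner How position and residue terms combine; only
#'   \code{"multiplicative"} is defined.
#' @seealso [buildCrossReactModel()], [predictLogC()]
#' @export
setClass("CrossReactModel",
         slots = c(matrix = "matrix", support = "matrix",
                   weights = "numeric", combiner = "character"))

setValidity("CrossReactModel", function(object) {
  M <- object@matrix
  if (!identical(dim(M), c(20L, 20L)))
    return("matrix must be 20 x 20")
  if (!identical(rownames(M), .AA20) || !identical(colnames(M), .AA20))
    return("matrix must be named by the 20 amino acids in alphabetical order")
  if (any(!is.finite(M)))
    return("matrix entries must be finite")
  if (any(abs(diag(M)) > 1e-12))
    return("identity substitutions must have distance 0")
  if (!identical(dim(object@support), c(20L, 20L)))
    return("support must be 20 x 20")
  w <- object@weights
  if (length(w) < 1L || any(!is.finite(w)) || any(w < 0))
    return("position weights must be finite and non-negative")
  interior <- if (length(w) > 2L) w[2:(length(w) - 1L)] else w
  if (mean(interior) > 0 && abs(mean(interior) - 1) > 1e-6)
    return("interior position weights must average 1")
  if (!identical(object@combiner, "multiplicative"))
    return("combiner must be 'multiplicative'")
  TRUE
})

#' Multisample clone tree
#'
#' Joint clonal structure of all tumours of one patient: a rooted tree of
#' clones, each carrying its own (newly acquired) mutations, with observed
#' clone frequencies per sample. A clone's genotype is the union of its own
#' mutations with those of all ancestors. Per-sample frequencies may sum to
#' less than 1 (residual mass is normal-cell contamination); all model
#' arithmetic renormalizes over clones.
#'
#' @slot cloneIds Character vector of clone identifiers.
#' @slot parentIds Parent of each clone; \code{NA} for the single root.
#' @slot ownMutations Named list: mutation ids newly acquired by each clone.
#' @slot frequencies Numeric matrix, clones x samples, entries in [0, 1],
#'   column sums at most 1 (+1e-6 tolerance).
#' @slot sampleRoles Named character, \code{"primary"} or \code{"recurrent"}
#'   per sample.
#' @seealso [readCloneTree()], [predictRecurrentFrequencies()]
#' @export
setClass("CloneTree",
         slots = c(cloneIds = "character", parentIds = "character",
                   ownMutations = "list", frequencies = "matrix",
                   sampleRoles = "character"))

setValidity("CloneTree", function(object) {
  ids <- object@cloneIds
  par <- object@parentIds
  if (length(ids) == 0L) return("clone tree has no clones")
  if (anyDuplicated(ids)) return("duplicate clone ids")
  if (length(par) != length(ids)) return("parentIds length mismatch")
  roots <- which(is.na(par))
  if (length(roots) != 1L) return("tree must have exactly one root")
  orphan <- !is.na(par) & !(par %in% ids)
  if (any(orphan))
    return(sprintf("parent id(s) not in tree: %s",
                   paste(unique(par[orphan]), collapse = ", ")))
  # cycle check: walk each clone to the root
  idx <- stats::setNames(seq_along(ids), ids)
  for (i in seq_along(ids)) {
    seen <- logical(length(ids))
    j <- i
    while (!is.na(par[j])) {
      if (seen[j]) return("cycle detected in clone tree")
      seen[j] <- TRUE
      j <- idx[[par[j]]]
    }
  }
  fr <- object@frequencies
  if (nrow(fr) != length(ids) || !identical(rownames(fr), ids))
    return("frequency matrix rows must match clone ids")
  if (any(fr < 0)) return("negative clone frequencies")
  if (any(fr > 1 + 1e-6)) return("clone frequencies exceed 1")
  sums <- colSums(fr)
  if (any(sums > 1 + 1e-6))
    return(sprintf("frequencies in sample(s) %s sum to more than 1",
                   paste(colnames(fr)[sums > 1 + 1e-6], collapse = ", ")))
  if (!identical(sort(names(object@sampleRoles)), sort(colnames(fr))))
    return("sampleRoles must name every frequency column")
  if (!all(object@sampleRoles %in% c("primary", "recurrent")))
    return("sample roles must be 'primary' or 'recurrent'")
  if (!identical(sort(names(object@ownMutations)), sort(ids)))
    return("ownMutations must be named by clone ids")
  TRUE
})

#' Maximum-likelihood selection fit for one primary-recurrent tumour pair
#'
#' Point estimates of the immune amplitude sigma_I and oncogenic amplitude
#' sigma_P of the clone fitness model, with the log-likelihood at the
#' optimum and BIC values for the full (2-parameter), oncogene-only
#' (1-parameter) and neutral (0-parameter) models.
#'
#' @slot sigmaI,sigmaP Non-negative selection amplitudes.
#' @slot logLik Maximized log-likelihood of the full model.
#' @slot bicFull,bicOncogenic,bicNeutral BIC = k ln(n) - 2 ln L per model.
#' @slot preferredModel \code{"full"}, \code{"oncogenic"} or \code{"neutral"}
#'   (argmin BIC).
#' @slot nClones Number of clones entering the likelihood.
#' @slot nEff Effective multinomial sample size used.
#' @seealso [fitSelectionParams()]
#' @export
setClass("SelectionFit",
         slots = c(sigmaI = "numeric", sigmaP = "numeric", logLik = "numeric",
                   bicFull = "numeric", bicOncogenic = "numeric",
                   bicNeutral = "numeric", preferredModel = "character",
                   nClones = "integer", nEff = "numeric"))

setValidity("SelectionFit", function(object) {
  if (object@sigmaI < 0 || object@sigmaP < 0)
    return("selection amplitudes must be non-negative")
  bics <- c(full = object@bicFull, oncogenic = object@bicOncogenic,
            neutral = object@bicNeutral)
  if (any(!is.finite(bics))) return("BIC values must be finite")
  if (!object@preferredModel %in% names(bics))
    return("preferredModel must be one of full, oncogenic, neutral")
  if (bics[object@preferredModel] > min(bics) + 1e-9)
    return("preferredModel must be a BIC-minimizing model")
  TRUE
})

#' TCR repertoire of one sample
#'
#' CDR3beta clonotypes with read/cell counts, aggregated so each CDR3beta
#' sequence appears once.
#'
#' @slot sampleId Sample identifier.
#' @slot clonotypes data.frame with columns \code{cdr3b} (amino-acid
#'   sequence) and \code{count} (positive integer).
#' @seealso [readAirrRepertoire()], [dissimilarityIndex()]
#' @export
setClass("TcrRepertoire",
         slots = c(sampleId = "character", clonotypes = "data.frame"))

setValidity("TcrRepertoire", function(object) {
  cl <- object@clonotypes
  if (!all(c("cdr3b", "count") %in% names(cl)))
    return("clonotypes must have columns cdr3b and count")
  if (nrow(cl) > 0) {
    if (any(!.validAASeq(cl$cdr3b)))
      return("invalid amino-acid characters in cdr3b")
    if (any(cl$count < 1) || any(cl$count != round(cl$count)))
      return("counts must be positive integers")
    if (anyDuplicated(cl$cdr3b))
      return("clonotypes must be aggregated (unique cdr3b)")
  }
  TRUE
})

#' Parameters of the neoantigen quality model
#'
#' The quality of a neoantigen is Q = R x D, where R is the recognition
#' potential of the mutant peptide against a set of known epitopes and
#' D = (1-w) log(Kd^WT/Kd^MT) + w log(EC50^MT/EC50^WT) is self-discrimination.
#'
#' @slot w Weight in [0, 1] between the MHC-amplitude and cross-reactivity
#'   terms of D.
#' @slot a Horizontal displacement of the recognition logistic, in alignment
#'   score units.
#' @slot k Steepness of the recognition logistic (> 0), inverse score units.
#' @slot epitopes An [EpitopeSet-class] of known immunogenic epitopes.
#' @seealso [neoantigenQuality()], [defaultQualityParams()]
#' @export
setClass("QualityParams",
         slots = c(w = "numeric", a = "numeric", k = "numeric",
                   epitopes = "EpitopeSet"))

setValidity("QualityParams", function(object) {
  if (length(object@w) != 1L || object@w < 0 || object@w > 1)
    return("w must be in [0, 1]")
  if (length(object@k) != 1L || object@k <= 0)
    return("k must be positive")
  if (length(object@a) != 1L || !is.finite(object@a))
    return("a must be finite")
  TRUE
})
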