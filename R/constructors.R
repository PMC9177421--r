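# User-facing constructors.

#' Construct an EpitopeSet
#'
#' @param sequences Named character vector or \code{AAStringSet} of epitope
#'   sequences; lowercase input is uppercased.
#' @return An [EpitopeSet-class].
#' @examples
#' EpitopeSet(c(NLV = "NLVPMVATV", GIL = "GILGFVFTL"))
#' @export
EpitopeSet <- function(sequences = character(0)) {
  if (is.character(sequences)) {
    sequences <- Biostrings::AAStringSet(toupper(sequences))
  }
  methods::new("EpitopeSet", sequences = sequences)
}

#' Construct a DoseResponseCurve
#'
#' @param tcrId TCR identifier.
#' @param peptide Peptide sequence tested.
#' @param concentrations Strictly increasing molar concentrations (>= 4).
#' @param responses Activation readouts, same length.
#' @param position 1-based substituted position; \code{NA} for the
#'   unsubstituted reference peptide.
#' @param wtResidue,mtResidue Residues swapped at \code{position}.
#' @return A [DoseResponseCurve-class].
#' @export
DoseResponseCurve <- function(tcrId, peptide, concentrations, responses,
                              position = NA_integer_,
                              wtResidue = NA_character_,
                              mtResidue = NA_character_) {
  methods::new("DoseResponseCurve", tcrId = as.character(tcrId),
               peptide = toupper(peptide),
               position = as.integer(position),
               wtResidue = as.character(wtResidue),
               mtResidue = as.character(mtResidue),
               concentrations = as.numeric(concentrations),
               responses = as.numeric(responses))
}

#' Construct a CloneTree
#'
#' @param cloneIds Clone identifiers.
#' @param parentIds Parent of each clone (\code{NA} for the root).
#' @param frequencies Clones x samples matrix of clone fractions (row names
#'   are matched/assigned from \code{cloneIds}).
#' @param sampleRoles Named character vector mapping each sample to
#'   \code{"primary"} or \code{"recurrent"}.
#' @param ownMutations Named list of mutation ids newly acquired per clone;
#'   defaults to empty sets.
#' @return A [CloneTree-class].
#' @examples
#' CloneTree(c("c1", "c2"), c(NA, "c1"),
#'           matrix(c(0.6, 0.4), 2, 1, dimnames = list(NULL, "prim")),
#'           c(prim = "primary"))
#' @export
CloneTree <- function(cloneIds, parentIds, frequencies, sampleRoles,
                      ownMutations = NULL) {
  cloneIds <- as.character(cloneIds)
  frequencies <- as.matrix(frequencies)
  rownames(frequencies) <- cloneIds
  if (is.null(ownMutations)) {
    ownMutations <- stats::setNames(
      rep(list(character(0)), length(cloneIds)), cloneIds)
  }
  methods::new("CloneTree", cloneIds = cloneIds,
               parentIds = as.character(parentIds),
               ownMutations = ownMutations,
               frequencies = frequencies, sampleRoles = sampleRoles)
}

#' Construct a TcrRepertoire
#'
#' Rows with identical CDR3beta sequences are aggregated (counts summed).
#'
#' @param sampleId Sample identifier.
#' @param cdr3b CDR3beta amino-acid sequences.
#' @param count Clonotype counts (positive integers), recycled if length 1.
#' @return A [TcrRepertoire-class].
#' @export
TcrRepertoire <- function(sampleId, cdr3b, count = 1L) {
  df <- data.frame(cdr3b = toupper(as.character(cdr3b)),
                   count = as.integer(count))
  agg <- stats::aggregate(count ~ cdr3b, data = df, FUN = sum)
  agg <- agg[order(agg$cdr3b), , drop = FALSE]
  rownames(agg) <- NULL
  methods::new("TcrRepertoire", sampleId = as.character(sampleId),
               clonotypes = agg)
}

#' Construct quality-model parameters
#'
#' @param w Weight in [0, 1] between the MHC-amplitude and cross-reactivity
#'   terms of self-discrimination D.
#' @param a Displacement of the recognition logistic (alignment score units).
#' @param k Steepness of the recognition logistic (inverse score units).
#' @param epitopes An [EpitopeSet-class].
#' @return A [QualityParams-class].
#' @export
QualityParams <- function(w, a, k, epitopes = EpitopeSet()) {
  methods::new("QualityParams", w = as.numeric(w), a = as.numeric(a),
               k = as.numeric(k), epitopes = epitopes)
}

#' Default quality-model parameters
#'
#' Ships explicit defaults (w = 0.5, a = 22, k = 1) that the user is expected
#' to confirm or refit for their cohort with [selectParamsByLogrank()]: the
#' displacement \code{a} sits near typical best self-alignment scores of
#' 9-mers under BLOSUM62 and \code{k = 1} gives a logistic spanning a few
#' score units; \code{w = 0.5} weighs MHC amplitude and cross-reactivity
#' equally.
#'
#' @param epitopes An [EpitopeSet-class].
#' @return A [QualityParams-class].
#' @export
defaultQualityParams <- function(epitopes = EpitopeSet()) {
  QualityParams(w = 0.5, a = 22, k = 1, epitopes = epitopes)
}
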