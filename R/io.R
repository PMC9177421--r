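# Readers and writers for the external file formats: FASTA epitope sets,
# TSV neoantigen/mutation tables, JSON clone trees, AIRR clonotype tables
# and dose-response CSVs. Readers validate and reject invalid rows with
# row-numbered messages rather than silently coercing. TSV/CSV paths may be
# gzip-compressed.

.readTable <- function(path, sep) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read an epitope FASTA file
#'
#' @param path Path to a FASTA file of known immunogenic epitopes.
#' @return An [EpitopeSet-class]. Sequences are uppercased on read; duplicate
#'   ids or non-amino-acid characters are errors; an empty file yields an
#'   empty set with a warning.
#' @export
readEpitopeFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning(sprintf("no epitopes in %s: returning an empty set", path))
    return(EpitopeSet())
  }
  # FASTA headers may carry descriptions; the id is the first word
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  chr <- toupper(as.character(seqs))
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate epitope id(s) in %s: %s", path,
                 paste(unique(names(seqs)[duplicated(names(seqs))]),
                       collapse = ", ")))
  bad <- !.validAASeq(chr)
  if (any(bad))
    stop(sprintf("non-amino-acid characters in record(s): %s",
                 paste(names(seqs)[bad], collapse = ", ")))
  EpitopeSet(stats::setNames(chr, names(seqs)))
}

#' Write an epitope FASTA file
#'
#' @param epitopes An [EpitopeSet-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeEpitopeFasta <- function(epitopes, path) {
  .atomicWrite(path, function(tmp)
    Biostrings::writeXStringSet(epitopeSequences(epitopes), tmp))
}

# Infer (position, wt, mt) substitutions between two equal-length peptides.
.substitutionDiff <- function(pWt, pMt) {
  a <- .splitAA(pWt); b <- .splitAA(pMt)
  pos <- which(a != b)
  list(n = length(pos),
       position = if (length(pos) == 1L) pos else NA_integer_,
       wt = if (length(pos) == 1L) a[pos] else NA_character_,
       mt = if (length(pos) == 1L) b[pos] else NA_character_)
}

.KD_UNIT_TO_NM <- c(pM = 1e-3, nM = 1, uM = 1e3, mM = 1e6, M = 1e9)

#' Read a neoantigen table
#'
#' Expects a TSV with header columns \code{patient_id, tumor_id, clone_id,
#' gene, mutation_id, p_wt, p_mt, hla, kd_wt, kd_mt}. Substitution columns
#' (\code{position, wt_residue, mt_residue}) are inferred from
#' \code{p_wt}/\code{p_mt} when absent; positions are 1-based over the
#' peptide. Rows violating the record invariants (length mismatch,
#' non-positive Kd, invalid residues, zero substitutions, or a stated
#' substitution inconsistent with the peptides) are rejected with a
#' row-numbered warning.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param kdUnit Unit of the Kd columns on disk, one of
#'   \code{"pM","nM","uM","mM","M"}; values are converted to nM on read.
#' @return data.frame of validated records, Kd in nM, with inferred
#'   substitution columns.
#' @export
readNeoantigenTable <- function(path, kdUnit = "nM") {
  kdUnit <- match.arg(kdUnit, names(.KD_UNIT_TO_NM))
  df <- .readTable(path, sep = "\t")
  required <- c("patient_id", "tumor_id", "clone_id", "gene", "mutation_id",
                "p_wt", "p_mt", "hla", "kd_wt", "kd_mt")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("missing column(s) %s; header has: %s",
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  df$p_wt <- toupper(df$p_wt)
  df$p_mt <- toupper(df$p_mt)
  df$kd_wt <- as.numeric(df$kd_wt) * .KD_UNIT_TO_NM[[kdUnit]]
  df$kd_mt <- as.numeric(df$kd_mt) * .KD_UNIT_TO_NM[[kdUnit]]

  reasons <- character(0)
  keep <- logical(nrow(df))
  pos <- integer(nrow(df)); wtr <- character(nrow(df))
  mtr <- character(nrow(df)); nsub <- integer(nrow(df))
  hasStated <- all(c("position", "wt_residue", "mt_residue") %in% names(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    reject <- function(why) reasons <<- c(reasons, sprintf("row %d: %s", i, why))
    if (!.validAASeq(r$p_wt) || !.validAASeq(r$p_mt)) {
      reject("invalid amino-acid character"); next
    }
    if (nchar(r$p_wt) != nchar(r$p_mt)) {
      reject("p_wt and p_mt lengths differ"); next
    }
    if (!is.finite(r$kd_wt) || !is.finite(r$kd_mt) ||
        r$kd_wt <= 0 || r$kd_mt <= 0) {
      reject("non-positive Kd"); next
    }
    d <- .substitutionDiff(r$p_wt, r$p_mt)
    if (d$n == 0L) { reject("zero substitutions (p_wt == p_mt)"); next }
    if (hasStated && d$n == 1L) {
      stated <- as.integer(r$position)
      if (!is.na(stated) &&
          (stated != d$position ||
           !identical(as.character(r$wt_residue), d$wt) ||
           !identical(as.character(r$mt_residue), d$mt))) {
        reject("stated substitution inconsistent with peptides"); next
      }
    }
    keep[i] <- TRUE
    pos[i] <- d$position; wtr[i] <- d$wt; mtr[i] <- d$mt; nsub[i] <- d$n
  }
  if (length(reasons) > 0)
    warning(sprintf("rejected %d row(s) in %s:\n  %s", length(reasons), path,
                    paste(reasons, collapse = "\n  ")))
  out <- df[keep, required, drop = FALSE]
  out$position <- pos[keep]
  out$wt_residue <- wtr[keep]
  out$mt_residue <- mtr[keep]
  out$n_substitutions <- nsub[keep]
  rownames(out) <- NULL
  out
}

#' Write a neoantigen table
#' @param records data.frame as returned by [readNeoantigenTable()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeNeoantigenTable <- function(records, path) {
  .atomicWrite(path, function(tmp)
    utils::write.table(records, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Read a mutation table
#'
#' TSV with columns \code{patient_id, tumor_id, clone_id, mutation_id, gene,
#' effect, generates_neoantigen}; \code{effect} must be one of
#' \code{missense, nonsense, synonymous, other}.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return Validated data.frame.
#' @export
readMutationTable <- function(path) {
  df <- .readTable(path, sep = "\t")
  required <- c("patient_id", "tumor_id", "clone_id", "mutation_id", "gene",
                "effect", "generates_neoantigen")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("missing column(s) %s; header has: %s",
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  bad <- !df$effect %in% c("missense", "nonsense", "synonymous", "other")
  if (any(bad))
    stop(sprintf("unknown mutation effect(s) at row(s) %s",
                 paste(which(bad), collapse = ", ")))
  df$generates_neoantigen <- as.logical(df$generates_neoantigen)
  df
}

#' Write a mutation table
#' @param mutations data.frame as returned by [readMutationTable()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeMutationTable <- function(mutations, path) {
  .atomicWrite(path, function(tmp)
    utils::write.table(mutations, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Read a clone tree from JSON
#'
#' Schema: \code{{"samples": {sample_id: role, ...}, "nodes": [{"clone_id":
#' ..., "parent_id": null|id, "mutations": [ids], "frequencies":
#' {sample_id: fraction}}]}}. Per-sample frequencies must be non-negative
#' and sum to at most 1 (+1e-6); the residual mass is normal-cell
#' contamination. Cycles, orphan parents and negative frequencies are errors.
#'
#' @param path Path to the JSON file.
#' @return A [CloneTree-class].
#' @export
readCloneTree <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$nodes) || length(obj$nodes) == 0L)
    stop(sprintf("no clone nodes in %s", path))
  ids <- vapply(obj$nodes, function(n) as.character(n$clone_id), "")
  par <- vapply(obj$nodes, function(n)
    if (is.null(n$parent_id)) NA_character_ else as.character(n$parent_id), "")
  muts <- stats::setNames(lapply(obj$nodes, function(n)
    as.character(unlist(n$mutations))), ids)
  sampleIds <- unique(unlist(lapply(obj$nodes,
                                    function(n) names(n$frequencies))))
  if (length(sampleIds) == 0L) stop("clone tree has no sample frequencies")
  fr <- matrix(0, length(ids), length(sampleIds),
               dimnames = list(ids, sampleIds))
  for (n in obj$nodes) {
    for (s in names(n$frequencies))
      fr[as.character(n$clone_id), s] <- as.numeric(n$frequencies[[s]])
  }
  roles <- if (!is.null(obj$samples)) {
    vapply(obj$samples, as.character, "")
  } else {
    # default: first sample primary, the rest recurrent
    stats::setNames(c("primary", rep("recurrent", length(sampleIds) - 1L)),
                    sampleIds)
  }
  CloneTree(ids, par, fr, roles, muts)
}

#' Write a clone tree to JSON
#' @param tree A [CloneTree-class].
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeCloneTree <- function(tree, path) {
  nodes <- lapply(seq_along(tree@cloneIds), function(i) {
    list(clone_id = tree@cloneIds[i],
         parent_id = if (is.na(tree@parentIds[i])) NULL else tree@parentIds[i],
         mutations = as.list(tree@ownMutations[[tree@cloneIds[i]]]),
         frequencies = as.list(tree@frequencies[i, , drop = TRUE]))
  })
  obj <- list(samples = as.list(sampleRoles(tree)), nodes = nodes)
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE))
}

#' Read an AIRR-style TCR repertoire table
#'
#' TSV with a CDR3beta amino-acid column and a count column (AIRR names
#' \code{junction_aa} and \code{duplicate_count} by default). Rows whose
#' CDR3beta contains characters outside the 20-letter alphabet (stop
#' \code{*}, frameshift \code{_}, ambiguous \code{X}) are dropped with a
#' row-numbered warning; remaining rows are aggregated by identical CDR3beta.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param sampleId Sample identifier to attach; defaults to the file stem.
#' @param cdr3Col,countCol Column names holding the CDR3beta sequence and
#'   clonotype count.
#' @return A [TcrRepertoire-class].
#' @export
readAirrRepertoire <- function(path, sampleId = NULL,
                               cdr3Col = "junction_aa",
                               countCol = "duplicate_count") {
  df <- .readTable(path, sep = "\t")
  missing <- setdiff(c(cdr3Col, countCol), names(df))
  if (length(missing) > 0)
    stop(sprintf("missing column(s) %s; header has: %s",
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  if (is.null(sampleId))
    sampleId <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  cdr3 <- toupper(as.character(df[[cdr3Col]]))
  cnt <- as.integer(df[[countCol]])
  bad <- !.validAASeq(cdr3) | is.na(cnt) | cnt < 1
  if (any(bad))
    warning(sprintf("dropped %d row(s) with invalid CDR3 or count (row %s)",
                    sum(bad), paste(which(bad), collapse = ", ")))
  cdr3 <- cdr3[!bad]; cnt <- cnt[!bad]
  if (length(cdr3) == 0L) stop(sprintf("no clonotypes in %s", path))
  TcrRepertoire(sampleId, cdr3, cnt)
}

#' Write a TCR repertoire as AIRR-style TSV
#' @param repertoire A [TcrRepertoire-class].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeAirrRepertoire <- function(repertoire, path) {
  df <- data.frame(junction_aa = repertoire@clonotypes$cdr3b,
                   duplicate_count = repertoire@clonotypes$count)
  .atomicWrite(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Read dose-response activation scans
#'
#' CSV with columns \code{tcr_id, peptide, position, wt_residue, mt_residue,
#' concentration_molar, response}; one row per concentration point. The
#' reference (unsubstituted) peptide of a scan has an empty/NA position.
#'
#' @param path Path to the CSV (optionally gzipped).
#' @return List of [DoseResponseCurve-class], one per (tcr_id, peptide).
#' @export
readDoseResponse <- function(path) {
  df <- .readTable(path, sep = ",")
  required <- c("tcr_id", "peptide", "position", "wt_residue", "mt_residue",
                "concentration_molar", "response")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("missing column(s) %s; header has: %s",
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  key <- paste(df$tcr_id, df$peptide, sep = "\r")
  lapply(split(df, key)[unique(key)], function(g) {
    g <- g[order(g$concentration_molar), , drop = FALSE]
    DoseResponseCurve(
      tcrId = g$tcr_id[1], peptide = g$peptide[1],
      concentrations = g$concentration_molar, responses = g$response,
      position = suppressWarnings(as.integer(g$position[1])),
      wtResidue = as.character(g$wt_residue[1]),
      mtResidue = as.character(g$mt_residue[1]))
  })
}

#' Write dose-response curves as CSV
#' @param curves List of [DoseResponseCurve-class].
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeDoseResponse <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(tcr_id = cv@tcrId, peptide = cv@peptide,
               position = cv@position, wt_residue = cv@wtResidue,
               mt_residue = cv@mtResidue,
               concentration_molar = cv@concentrations,
               response = cv@responses)
  }))
  .atomicWrite(path, function(tmp)
    utils::write.csv(rows, tmp, quote = FALSE, row.names = FALSE))
}
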