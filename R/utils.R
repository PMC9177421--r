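# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter order.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Coarse biochemical families used only to impute unobserved substitution
# cells; grouping by size/hydrophobicity/charge.
.AA_FAMILIES <- list(
  aliphatic = c("A", "V", "L", "I", "M", "C"),
  aromatic  = c("F", "W", "Y"),
  polar     = c("S", "T", "N", "Q"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  special   = c("G", "P")
)

.aaFamily <- function(aa) {
  for (fam in names(.AA_FAMILIES)) {
    if (aa %in% .AA_FAMILIES[[fam]]) return(fam)
  }
  NA_character_
}

.validAASeq <- function(x) {
  nzchar(x) & !grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), x)
}

# BLOSUM62 restricted to the 20 standard residues, cached per session.
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62[.AA20, .AA20]
    }
    cache
  }
})

.splitAA <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Write a file atomically: render into a temp file in the target directory,
# then rename over the destination.
.atomicWrite <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tmp-", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Derive a per-subtask seed from a root seed so that adding subtasks does not
# perturb earlier ones. Kept inside 32-bit integer range.
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483646L) + 1L
}
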