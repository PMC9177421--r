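# Shared fixture builders. Everything is constructed in code; no files are
# shipped.

# Tiny hand-set cross-reactivity model: 3 positions with weights
# (0.5, 1, 1.5) (interior weight 1 satisfies the normalization) and a single
# informative cell M[A, G] = 2.
toyModel <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  M <- matrix(0, 20, 20, dimnames = list(aa, aa))
  M["A", "G"] <- 2
  support <- matrix(1L, 20, 20, dimnames = list(aa, aa))
  methods::new("CrossReactModel", matrix = M, support = support,
               weights = c(0.5, 1, 1.5), combiner = "multiplicative")
}

# Three-clone linear chain c1 -> c2 -> c3 with driver and passenger
# mutations; frequencies for a primary and a recurrent sample.
chainTree <- function(xPrim = c(0.5, 0.3, 0.2), xRec = c(0.2, 0.3, 0.5)) {
  fr <- cbind(prim = xPrim, rec = xRec)
  CloneTree(cloneIds = c("c1", "c2", "c3"),
            parentIds = c(NA, "c1", "c2"),
            frequencies = fr,
            sampleRoles = c(prim = "primary", rec = "recurrent"),
            ownMutations = list(c1 = c("m1", "m2", "m3"),
                                c2 = "m4", c3 = "m5"))
}

chainMutations <- function() {
  data.frame(patient_id = "P1", tumor_id = "prim",
             clone_id = c("c1", "c1", "c1", "c2", "c3"),
             mutation_id = paste0("m", 1:5),
             gene = c("KRAS", "TP53", "SMAD4", "CDKN2A", "GENE1"),
             effect = c("missense", "missense", "nonsense", "missense",
                        "synonymous"),
             generates_neoantigen = c(FALSE, FALSE, FALSE, FALSE, FALSE))
}

writeTempTable <- function(df, sep = "\t", ext = ".tsv") {
  f <- tempfile(fileext = ext)
  utils::write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

# Independent Pearson correlation from first principles.
oraclePearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Scan design whose wild-type residues connect all nine positions (shared
# residues across peptides), making the position x residue decomposition
# identifiable up to one global scale.
connectedScanPeptides <- function() c("NLVPMVATV", "ITDQVPFSV", "VATLQDKHE")
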