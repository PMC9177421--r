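# Readers, writers and type invariants for the external formats.

test_that("neoantigen reader infers substitutions and round-trips", {
  df <- data.frame(patient_id = "P1", tumor_id = "T1", clone_id = "c1",
                   gene = c("G1", "G2", "G3"),
                   mutation_id = c("m1", "m2", "m3"),
                   p_wt = c("NLVPMVATV", "GILGFVFTL", "KVAELVHFL"),
                   p_mt = c("NLVPKVATV", "GILGFVFTM", "KVAELVHHL"),
                   hla = "HLA-A*02:01",
                   kd_wt = c(50, 200, 1000), kd_mt = c(40, 100, 30))
  rec <- readNeoantigenTable(writeTempTable(df))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$position[1], 5L)
  expect_equal(rec$wt_residue[1], "M")
  expect_equal(rec$mt_residue[1], "K")
  expect_equal(rec$n_substitutions, rep(1L, 3))

  f2 <- tempfile(fileext = ".tsv")
  writeNeoantigenTable(rec, f2)
  expect_equal(readNeoantigenTable(f2), rec)
})

test_that("invalid neoantigen rows are rejected with row numbers", {
  df <- data.frame(patient_id = "P1", tumor_id = "T1", clone_id = "c1",
                   gene = "G", mutation_id = c("m1", "m2", "m3", "m4"),
                   p_wt = c("NLVPMVATV", "NLVPMVATV", "NLVPMVAT", "NLVPMVATV"),
                   p_mt = c("NLVPKVATV", "NLVPMVATV", "NLVPKVATV", "NLVPKVATV"),
                   hla = "A", kd_wt = c(50, 50, 50, -1), kd_mt = 40)
  f <- writeTempTable(df)
  expect_warning(rec <- readNeoantigenTable(f), "row 2")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$mutation_id, "m1")
  w <- tryCatch(readNeoantigenTable(f), warning = conditionMessage)
  expect_match(w, "zero substitutions")
  expect_match(w, "row 3: .*lengths differ")
  expect_match(w, "row 4: non-positive Kd")
})

test_that("kd unit conversion rescales to nM on read", {
  df <- data.frame(patient_id = "P", tumor_id = "T", clone_id = "c",
                   gene = "G", mutation_id = "m1", p_wt = "NLVPMVATV",
                   p_mt = "NLVPKVATV", hla = "A", kd_wt = 0.05, kd_mt = 0.04)
  rec <- readNeoantigenTable(writeTempTable(df), kdUnit = "uM")
  expect_equal(rec$kd_wt, 50)
  expect_equal(rec$kd_mt, 40)
})

test_that("epitope FASTA reading validates and normalizes", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">e1 first", "NLVPMVATV", ">e2", "gilgfvftl"), f)
  es <- readEpitopeFasta(f)
  expect_s4_class(es, "EpitopeSet")
  expect_equal(length(es), 2L)
  expect_equal(epitopeIds(es), c("e1", "e2"))
  expect_equal(as.character(epitopeSequences(es)[["e2"]]), "GILGFVFTL")

  writeLines(c(">dup", "ACDEF", ">dup", "ACDEG"), f)
  expect_error(readEpitopeFasta(f), "duplicate")
  writeLines(c(">bad", "ACDEB"), f)
  expect_error(readEpitopeFasta(f), "bad")

  f2 <- tempfile(fileext = ".fasta")
  writeEpitopeFasta(es, f2)
  expect_equal(as.character(epitopeSequences(readEpitopeFasta(f2))),
               as.character(epitopeSequences(es)))
})

test_that("clone tree JSON validates structure and round-trips", {
  tree <- chainTree()
  expect_equal(sort(cloneGenotype(tree, "c3")), paste0("m", 1:5))
  expect_equal(sort(cloneGenotype(tree, "c1")), c("m1", "m2", "m3"))

  f <- tempfile(fileext = ".json")
  writeCloneTree(tree, f)
  tree2 <- readCloneTree(f)
  expect_equal(cloneIds(tree2), cloneIds(tree))
  expect_equal(unname(parentIds(tree2)), unname(parentIds(tree)))
  expect_equal(cloneFrequencies(tree2), cloneFrequencies(tree))
  expect_equal(sampleRoles(tree2), sampleRoles(tree))
  expect_equal(ownMutations(tree2), ownMutations(tree))

  # frequencies above 1 are rejected
  bad <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  bad$nodes[[1]]$frequencies$prim <- 1.2
  jsonlite::write_json(bad, f, auto_unbox = TRUE, null = "null")
  expect_error(readCloneTree(f), "exceed 1|more than 1")

  # orphan parents and cycles are rejected
  expect_error(CloneTree(c("c1", "c2"), c(NA, "zz"),
                         matrix(c(0.5, 0.5), 2, 1,
                                dimnames = list(NULL, "s")),
                         c(s = "primary")),
               "parent id")
  expect_error(CloneTree(c("c1", "c2", "c3"), c(NA, "c3", "c2"),
                         matrix(0.3, 3, 1, dimnames = list(NULL, "s")),
                         c(s = "primary")),
               "cycle")
})

test_that("AIRR repertoire reader aggregates and filters clonotypes", {
  df <- data.frame(junction_aa = c("CASSL", "CASSF", "CASSL", "CATTG"),
                   duplicate_count = c(3L, 2L, 4L, 1L))
  rep <- readAirrRepertoire(writeTempTable(df), sampleId = "s1")
  cl <- clonotypes(rep)
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$count[cl$cdr3b == "CASSL"], 7L)

  # stop-codon characters are dropped with a warning
  df2 <- rbind(df, data.frame(junction_aa = "CAS*L", duplicate_count = 5L))
  expect_warning(rep2 <- readAirrRepertoire(writeTempTable(df2), "s1"),
                 "row 5")
  expect_equal(sum(clonotypes(rep2)$count), 10L)

  # missing columns report the found header
  df3 <- data.frame(cdr3 = "CASSL", n = 1L)
  expect_error(readAirrRepertoire(writeTempTable(df3), "s1"),
               "junction_aa.*cdr3, n")

  # all rows invalid -> no clonotypes
  df4 <- data.frame(junction_aa = "CAS*L", duplicate_count = 1L)
  expect_error(suppressWarnings(
    readAirrRepertoire(writeTempTable(df4), "s1")), "no clonotypes")

  f5 <- tempfile(fileext = ".tsv")
  writeAirrRepertoire(rep, f5)
  expect_equal(clonotypes(readAirrRepertoire(f5, "s1")), cl)
})

test_that("dose-response CSV round-trips curve sets", {
  curves <- simulateSubstitutionScan("ACDE", 1L, trueCrossReactModel(4L),
                                     seed = 3L)
  f <- tempfile(fileext = ".csv")
  writeDoseResponse(curves, f)
  back <- readDoseResponse(f)
  expect_equal(length(back), length(curves))
  ref <- curves[[1]]; refBack <- back[[paste(ref@tcrId, ref@peptide,
                                             sep = "\r")]]
  expect_equal(refBack@concentrations, ref@concentrations)
  expect_equal(refBack@responses, ref@responses)
  expect_true(is.na(refBack@position))
})

test_that("dose-response curves enforce their invariants", {
  expect_error(DoseResponseCurve("t", "ACDE", c(1e-9, 1e-8, 1e-7), 1:3),
               "at least 4")
  expect_error(DoseResponseCurve("t", "ACDE", c(1e-9, 1e-8, 1e-8, 1e-7),
                                 1:4), "strictly increasing")
  expect_error(DoseResponseCurve("t", "ACDE", 10^seq(-9, -6), c(1, 2, NA, 4)),
               "finite")
})
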