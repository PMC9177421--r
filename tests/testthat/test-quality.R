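# Recognition potential, self-discrimination, quality and parameter
# selection by log-rank score.

# Independent brute-force recognition potential: enumerate every gapless
# window of the shorter sequence against the longer, sum BLOSUM62 scores,
# and evaluate the logistic partition directly.
oracleRecognition <- function(pMt, epitopeSeqs, a, k) {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                envir = env)
  b62 <- env$BLOSUM62
  best <- function(x, y) {
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    if (length(xs) > length(ys)) { tmp <- xs; xs <- ys; ys <- tmp }
    scores <- sapply(0:(length(ys) - length(xs)), function(off)
      sum(sapply(seq_along(xs), function(i) b62[xs[i], ys[i + off]])))
    max(scores)
  }
  s <- vapply(epitopeSeqs, function(e) best(pMt, e), 0)
  z <- sum(exp(-k * (a - s)))
  z / (1 + z)
}

test_that("recognition potential matches a brute-force oracle", {
  epi <- EpitopeSet(c(e1 = "NLVPMVATV", e2 = "GILGF", e3 = "KVAELVHFLAM"))
  params <- QualityParams(w = 0.5, a = 10, k = 1, epitopes = epi)
  for (p in c("NLVPMVATV", "ACDEFGHIK", "GILGY")) {
    rp <- recognitionPotential(p, params)
    expect_equal(rp$R,
                 oracleRecognition(p, c("NLVPMVATV", "GILGF", "KVAELVHFLAM"),
                                   a = 10, k = 1),
                 tolerance = 1e-12)
  }
})

test_that("recognition potential saturates and degrades as defined", {
  p <- "NLVPMVATV"
  s <- gaplessAlignmentScore(p, p)
  params <- QualityParams(w = 0.5, a = s - 10, k = 1,
                          epitopes = EpitopeSet(c(self = p)))
  expect_gt(recognitionPotential(p, params)$R, 0.99)
  expect_lt(recognitionPotential(p, params)$R, 1)

  # empty set: R = 0 with a warning
  empty <- QualityParams(w = 0.5, a = 10, k = 1, epitopes = EpitopeSet())
  expect_warning(rp <- recognitionPotential(p, empty), "empty epitope set")
  expect_identical(rp$R, 0)

  # monotone in each alignment score via the displacement a
  pars1 <- QualityParams(0.5, a = 20, k = 1, epitopes = EpitopeSet(c(x = p)))
  pars2 <- QualityParams(0.5, a = 25, k = 1, epitopes = EpitopeSet(c(x = p)))
  expect_gt(recognitionPotential(p, pars1)$R,
            recognitionPotential(p, pars2)$R)
})

test_that("self-discrimination follows its closed form", {
  model <- toyModel()
  # w = 0: MHC amplitude only
  sd0 <- selfDiscrimination("CCA", "CCG", kdWt = 500, kdMt = 50, model, w = 0)
  expect_equal(sd0$D, log(10))
  expect_equal(sd0$logA, log(10))
  # w = 1, identity pair: D = 0
  sd1 <- selfDiscrimination("CCA", "CCA", 500, 50, model, w = 1)
  expect_identical(sd1$D, 0)
  # w = 0.5, kd ratio 1, toy logC: position 2 weight 1, M[A,G] = 2
  sd2 <- selfDiscrimination("CAC", "CGC", 100, 100, model, w = 0.5)
  expect_equal(sd2$logC, 2)
  expect_equal(sd2$D, 1)
})

test_that("quality is the product R x D with zero annihilation", {
  epi <- EpitopeSet(c(e1 = "NLVPMVATV", e2 = "GILGF", e3 = "KVAELVHFLAM"))
  params <- QualityParams(w = 0.5, a = 10, k = 1, epitopes = epi)
  model <- trueCrossReactModel(9L)
  rec <- data.frame(patient_id = "P", mutation_id = "m1",
                    p_wt = "NLVPMVATV", p_mt = "NLVPKVATV",
                    kd_wt = 500, kd_mt = 50)
  sc <- neoantigenQuality(rec, params, model)
  rp <- recognitionPotential("NLVPKVATV", params)
  sdd <- selfDiscrimination("NLVPMVATV", "NLVPKVATV", 500, 50, model, 0.5)
  expect_equal(sc$Q, rp$R * sdd$D, tolerance = 1e-12)
  expect_equal(sc$R, rp$R, tolerance = 1e-12)
  expect_equal(sc$best_epitope, "e1")

  # D = 0 (w = 1 and kd ratio irrelevant, identity-substitution logC = 0)
  params1 <- QualityParams(w = 1, a = 10, k = 1, epitopes = epi)
  recId <- rec; recId$p_mt <- "NLVPMVATW"  # M[V,W] may be nonzero; use toy
  model0 <- toyModel()
  sc2 <- neoantigenQuality(data.frame(patient_id = "P", mutation_id = "m",
                                      p_wt = "CCC", p_mt = "CCA",
                                      kd_wt = 500, kd_mt = 50),
                           params1, model0)
  expect_identical(sc2$D, 0)  # M[C, A] = 0 in the toy matrix
  expect_identical(sc2$Q, 0)

  # R = 0 (empty epitope set): Q = 0 regardless of D
  paramsE <- QualityParams(w = 0, a = 10, k = 1, epitopes = EpitopeSet())
  expect_warning(sc3 <- neoantigenQuality(rec, paramsE, model))
  expect_identical(sc3$Q, 0)
  expect_equal(sc3$D, log(10))

  # pure function: identical inputs, identical outputs
  expect_identical(neoantigenQuality(rec, params, model),
                   neoantigenQuality(rec, params, model))
})

test_that("log-rank selection honours grid contract and tie rules", {
  model <- trueCrossReactModel(9L)
  epi <- EpitopeSet(c(e = "NLVPMVATV"))
  # 20 patients, one neoantigen each, kd_wt = kd_mt (logA = 0): quality
  # ranking is driven entirely by logC
  set.seed(7)
  strong <- c("NLVPWVATV", "NLVPYVATV")   # disruptive central substitution
  weak <- c("NLVPMVATI", "NLVPMVATL")     # conservative terminal one
  pmt <- c(sample(strong, 10, TRUE), sample(weak, 10, TRUE))
  rec <- data.frame(patient_id = sprintf("P%02d", 1:20),
                    mutation_id = sprintf("m%02d", 1:20),
                    p_wt = "NLVPMVATV", p_mt = pmt,
                    kd_wt = 100, kd_mt = 100)
  survd <- data.frame(patient_id = rec$patient_id,
                      time = c(rnorm(10, 12, 1), rnorm(10, 60, 2)),
                      event = 1L)

  # single-point grid returns that point
  g1 <- data.frame(w = 0.4, a = 15, k = 1)
  sel1 <- selectParamsByLogrank(rec, survd, epi, model, g1)
  expect_equal(sel1$best@w, 0.4)

  # w = 0 collapses all qualities to 0 (degenerate split, -Inf); w = 0.5 and
  # w = 1 give the same ranking, so they tie and the smaller w wins
  g <- data.frame(w = c(0, 0.5, 1), a = 15, k = 1)
  sel <- selectParamsByLogrank(rec, survd, epi, model, g)
  expect_equal(sel$best@w, 0.5)
  expect_equal(sel$scores$logrank[sel$scores$w == 0], -Inf)
  expect_equal(sel$scores$logrank[sel$scores$w == 0.5],
               sel$scores$logrank[sel$scores$w == 1])
  expect_gt(sel$scores$logrank[sel$scores$w == 0.5], 10)

  # the displacement a cannot reorder a D > 0 cohort: scores tie across a
  # and the lexicographically smallest grid point is returned
  ga <- data.frame(w = 0.5, a = c(12, 18, 24), k = 1)
  sela <- selectParamsByLogrank(rec, survd, epi, model, ga)
  expect_equal(sela$best@a, 12)
  expect_equal(length(unique(round(sela$scores$logrank, 8))), 1L)

  # all-censored cohorts are rejected
  survc <- survd; survc$event <- 0L
  expect_error(selectParamsByLogrank(rec, survc, epi, model, g1),
               "all-censored")
})
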