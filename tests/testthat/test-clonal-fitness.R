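# Clone fitness components, frequency propagation, ML fitting and
# frequency-change evaluation.

test_that("driver fitness counts missense driver mutations cumulatively", {
  tree <- chainTree()
  mut <- chainMutations()
  # root: KRAS missense + TP53 missense; SMAD4 nonsense excluded
  expect_equal(driverFitness(tree, "c1", mut), 2L)
  # child adds CDKN2A missense
  expect_equal(driverFitness(tree, "c2", mut), 3L)
  expect_equal(driverFitness(tree, "c3", mut), 3L)  # synonymous ignored
  # empty genotype
  t0 <- CloneTree("c1", NA_character_,
                  matrix(1, 1, 1, dimnames = list(NULL, "s")),
                  c(s = "primary"))
  expect_equal(driverFitness(t0, "c1", mut), 0L)
})

test_that("immune fitness cost is the max quality along the lineage", {
  tree <- chainTree()
  q <- c(m1 = 0.2, m2 = 1.7, m4 = 0.9)
  expect_equal(immuneFitnessCost(tree, "c1", q), 1.7)
  expect_equal(immuneFitnessCost(tree, "c2", q), 1.7)   # inherits parent max
  expect_equal(immuneFitnessCost(tree, "c3", q), 1.7)
  q2 <- c(m1 = 0.2, m4 = 2.5)
  expect_equal(immuneFitnessCost(tree, "c2", q2), 2.5)  # child exceeds parent
  expect_identical(immuneFitnessCost(tree, "c1", c(zz = 1)), 0)
})

test_that("clone fitness combines the components linearly", {
  tree <- chainTree()
  mut <- chainMutations()
  q <- c(m1 = 2)  # F_I = 2 for every clone
  ft <- cloneFitnessTable(tree, sigmaI = 1, sigmaP = 0.5, q, mut)
  expect_equal(ft$F[ft$clone_id == "c1"], -1 * 2 + 0.5 * 2)
  ft0 <- cloneFitnessTable(tree, 0, 0, q, mut)
  expect_true(all(ft0$F == 0))
  # with sigma_P = 0, fitness strictly decreases in F_I
  ftI <- cloneFitnessTable(tree, 2, 0, c(m1 = 1, m4 = 3), mut)
  expect_true(all(diff(ftI$F[order(ftI$F_I)]) <= 0))
})

test_that("frequency propagation matches closed forms and conserves mass", {
  # neutral: predictions equal primary frequencies exactly
  x <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(predictRecurrentFrequencies(x, 0), x)
  # two clones, F = (0, ln 2): (1/3, 2/3)
  expect_equal(predictRecurrentFrequencies(c(a = 0.5, b = 0.5),
                                           c(0, log(2))),
               c(a = 1 / 3, b = 2 / 3), tolerance = 1e-15)
  # single clone: 1 regardless of fitness
  expect_equal(unname(predictRecurrentFrequencies(c(x = 0.4), 17)), 1)
  # zero-frequency clones do not perturb the rest
  x2 <- c(a = 0.5, b = 0.5, z = 0)
  p2 <- predictRecurrentFrequencies(x2, c(0, log(2), 5))
  expect_equal(p2[c("a", "b")], c(a = 1 / 3, b = 2 / 3), tolerance = 1e-15)
  expect_identical(unname(p2["z"]), 0)
  # relabeling invariance
  x3 <- c(q = 0.3, r = 0.7)
  expect_equal(unname(predictRecurrentFrequencies(x3, c(1, -1))),
               unname(predictRecurrentFrequencies(rev(x3), c(-1, 1))[2:1]))
  # conservation across random parameter points
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:15, 1)
    xr <- rgamma(n, 1); xr <- xr / sum(xr)
    f <- rnorm(n, 0, 3)
    expect_lt(abs(sum(predictRecurrentFrequencies(xr, f)) - 1), 1e-12)
  }
  expect_error(predictRecurrentFrequencies(c(0, 0), c(1, 1)), "zero")
})

test_that("noiseless selection data return the generating parameters", {
  cfg <- simConfig(seed = 42, nPatients = 1, nEff = Inf,
                   sigmaI = 1.2, sigmaP = 0.6)
  co <- simulateCohort(cfg, withSurvival = FALSE)
  p <- co$patients[[1]]
  fit <- fitSelectionParams(p$tree, p$qualities, p$mutations, nEff = 100)
  expect_lt(abs(fit@sigmaI - 1.2), 1e-5)
  expect_lt(abs(fit@sigmaP - 0.6), 1e-5)
  expect_s4_class(fit, "SelectionFit")
  expect_equal(preferredModel(fit),
               names(which.min(c(full = fit@bicFull,
                                 oncogenic = fit@bicOncogenic,
                                 neutral = fit@bicNeutral))))
  # likelihood at truth is at least the neutral likelihood
  expect_gte(fit@logLik, (fit@bicNeutral / -2))
})

test_that("a single usable clone yields a neutral fit with a warning", {
  fr <- cbind(prim = c(1, 0), rec = c(0.6, 0.4))
  tree <- CloneTree(c("c1", "c2"), c(NA, "c1"), fr,
                    c(prim = "primary", rec = "recurrent"),
                    list(c1 = "m1", c2 = "m2"))
  mut <- data.frame(patient_id = "P", tumor_id = "T",
                    clone_id = c("c1", "c2"), mutation_id = c("m1", "m2"),
                    gene = "G", effect = "missense",
                    generates_neoantigen = FALSE)
  expect_warning(fit <- fitSelectionParams(tree, c(m1 = 1), mut),
                 "single usable clone")
  expect_equal(preferredModel(fit), "neutral")
  expect_equal(selectionParams(fit), c(sigma_I = 0, sigma_P = 0))
})

test_that("frequency-change evaluation matches oracles and tie rules", {
  # observed equals predicted: perfect agreement and rank correlation
  xPrim <- c(c1 = 0.4, c2 = 0.35, c3 = 0.25)
  f <- c(0.3, -0.5, 0.8)
  xhat <- predictRecurrentFrequencies(xPrim, f)
  tree <- CloneTree(names(xPrim), c(NA, "c1", "c1"),
                    cbind(prim = xPrim, rec = xhat),
                    c(prim = "primary", rec = "recurrent"))
  ev <- evaluateFrequencyChanges(tree, f)
  expect_equal(ev$directionAgreement, 1)
  expect_equal(ev$rho, 1)

  # neutral fitness with unchanged frequencies: all ratios tie at 1 and the
  # agreement denominator is empty
  tree0 <- CloneTree(names(xPrim), c(NA, "c1", "c1"),
                     cbind(prim = xPrim, rec = xPrim),
                     c(prim = "primary", rec = "recurrent"))
  ev0 <- evaluateFrequencyChanges(tree0, rep(0, 3))
  expect_true(all(ev0$table$observed_ratio == 1))
  expect_true(is.na(ev0$directionAgreement))

  # Spearman statistic equals an independent rank-based computation
  set.seed(9)
  n <- 8
  xp <- rgamma(n, 1); xp <- xp / sum(xp)
  # keep all clones above the 3% threshold to avoid pseudocount branches
  xp <- 0.03 + xp * (1 - 0.03 * n); xp <- xp / sum(xp)
  fr <- rnorm(n)
  xr <- rgamma(n, 1); xr <- xr / sum(xr)
  ids <- sprintf("k%d", 1:n)
  treeR <- CloneTree(ids, c(NA, rep("k1", n - 1)),
                     cbind(prim = xp, rec = xr),
                     c(prim = "primary", rec = "recurrent"))
  evR <- evaluateFrequencyChanges(treeR, fr)
  lro <- log(evR$table$observed_ratio)
  lrf <- log(evR$table$fitted_ratio)
  expect_equal(evR$rho, oraclePearson(rank(lro), rank(lrf)),
               tolerance = 1e-12)

  # sub-threshold frequencies are replaced by the pseudocount
  xs <- c(c1 = 0.9, c2 = 0.09, c3 = 0.01)
  treeS <- CloneTree(names(xs), c(NA, "c1", "c1"),
                     cbind(prim = xs, rec = c(0.985, 0.005, 0.01)),
                     c(prim = "primary", rec = "recurrent"))
  evS <- evaluateFrequencyChanges(treeS, rep(0, 3), threshold = 0.03,
                                  pseudocount = 0.015)
  r2 <- evS$table[evS$table$clone_id == "c2", ]
  expect_equal(r2$observed_ratio, 0.015 / 0.09)
  expect_error(evaluateFrequencyChanges(treeS, rep(0, 3), threshold = 0.95),
               "no clones above")
})

test_that("cohort-level joint fit pools tumours under shared amplitudes", {
  cfg <- simConfig(seed = 77, nPatients = 3, nEff = 200,
                   sigmaI = 1.0, sigmaP = 0.5)
  co <- simulateCohort(cfg, withSurvival = FALSE)
  fit <- fitSelectionCohort(co$patients, nEff = 200)
  expect_s4_class(fit, "SelectionFit")
  expect_equal(fit@nClones,
               sum(vapply(co$patients, function(p)
                 sum(cloneFrequencies(p$tree)[, 1] > 0), 0L)))
  expect_lt(abs(fit@sigmaI - 1.0), 0.5)
})
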