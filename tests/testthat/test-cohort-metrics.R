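# Entropy, tumour summaries, paired deltas, depletion tests and the
# substitution-frequency regression.

test_that("Shannon entropy matches closed forms and invariants", {
  expect_equal(shannonEntropy(rep(0.25, 4)), log(4))
  expect_identical(shannonEntropy(1), 0)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)),
               0.5 * log(2) + 0.5 * log(4))
  # invariant to zero padding and to scale
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25, 0, 0)),
               shannonEntropy(c(2, 1, 1)))
  # maximal iff uniform
  expect_lt(shannonEntropy(c(0.4, 0.3, 0.2, 0.1)), log(4))
  expect_equal(shannonEntropy(rep(0.25, 4), base = "bits"), 2)
  expect_error(shannonEntropy(c(0, 0)), "zero")
  expect_error(shannonEntropy(c(0.5, -0.1)), "negative")
})

.metricsFixture <- function() {
  # two clones; primary dominated by c1, recurrent adds c2
  fr <- cbind(prim = c(0.7, 0.005), rec = c(0.45, 0.4))
  tree <- CloneTree(c("c1", "c2"), c(NA, "c1"), fr,
                    c(prim = "primary", rec = "recurrent"),
                    list(c1 = paste0("m", 1:7), c2 = paste0("m", 8:10)))
  mut <- data.frame(patient_id = "P", tumor_id = "T",
                    clone_id = rep(c("c1", "c2"), c(7, 3)),
                    mutation_id = paste0("m", 1:10),
                    gene = "G",
                    effect = c(rep("missense", 5), "synonymous", "synonymous",
                               "missense", "missense", "nonsense"),
                    generates_neoantigen = FALSE)
  neo <- data.frame(patient_id = "P", tumor_id = "T",
                    clone_id = c("c1", "c1", "c1", "c2", "c2"),
                    mutation_id = c("m1", "m2", "m3", "m8", "m9"),
                    p_wt = "NLVPMVATV", p_mt = "NLVPKVATV", hla = "A",
                    kd_wt = 100, kd_mt = c(50, 400, 800, 120, 90))
  list(tree = tree, mut = mut, neo = neo)
}

test_that("tumour summaries count what they claim to count", {
  fx <- .metricsFixture()
  q <- c(m1 = 1.2, m8 = 2.0)
  sPrim <- summarizeTumor(fx$tree, "prim", fx$mut, fx$neo, q)
  # c2 below presence threshold in primary: only c1's mutations count
  expect_equal(sPrim$tmb, 5L)  # 5 missense among m1..m7, synonymous excluded
  expect_equal(sPrim$na_count, 2L)  # kd_mt 50 and 400 pass 500 nM; 800 fails
  expect_equal(sPrim$na_mut_count, 2L)
  expect_equal(sPrim$mean_immune_cost, 1.2)  # single present clone
  expect_equal(sPrim$shannon_entropy, shannonEntropy(c(0.7, 0.005)))

  sRec <- summarizeTumor(fx$tree, "rec", fx$mut, fx$neo, q)
  expect_equal(sRec$tmb, 5L + 3L)  # c2 adds m8, m9 missense + m10 nonsense
  expect_equal(sRec$na_count, 4L)
  # frequency-weighted immune cost over both clones
  expect_equal(sRec$mean_immune_cost,
               (0.45 * 1.2 + 0.4 * 2.0) / 0.85)
  # unweighted variant
  sRecU <- summarizeTumor(fx$tree, "rec", fx$mut, fx$neo, q,
                          weighted = FALSE)
  expect_equal(sRecU$mean_immune_cost, mean(c(1.2, 2.0)))
  expect_error(summarizeTumor(fx$tree, "nope", fx$mut, fx$neo, q),
               "not in tree")
})

test_that("paired deltas are recurrent minus primary with new-clone shares", {
  fx <- .metricsFixture()
  q <- c(m1 = 1.2, m8 = 2.0)
  d <- pairedDeltas(fx$tree, "prim", "rec", fx$mut, fx$neo, q)
  sPrim <- summarizeTumor(fx$tree, "prim", fx$mut, fx$neo, q)
  sRec <- summarizeTumor(fx$tree, "rec", fx$mut, fx$neo, q)
  expect_equal(d$delta_tmb, sRec$tmb - sPrim$tmb)
  expect_equal(d$delta_na, sRec$na_count - sPrim$na_count)
  expect_equal(d$delta_entropy,
               sRec$shannon_entropy - sPrim$shannon_entropy)
  expect_equal(d$n_new_clones, 1L)
  # c2 is new; of the 4 recurrent neoantigens, m8 and m9 are private to it
  expect_equal(d$pct_new_neoantigens, 100 * 2 / 4)
  expect_equal(d$new_clone_mean_immune_cost, 2.0)
  expect_false(d$no_recurrent_neoantigens)

  # identical primary and recurrent: all deltas 0, no new clones
  fr <- cbind(a = c(0.6, 0.3), b = c(0.6, 0.3))
  t2 <- CloneTree(c("c1", "c2"), c(NA, "c1"), fr,
                  c(a = "primary", b = "recurrent"),
                  list(c1 = "m1", c2 = "m2"))
  mut2 <- fx$mut[1:2, ]; mut2$clone_id <- c("c1", "c2")
  mut2$mutation_id <- c("m1", "m2")
  d2 <- pairedDeltas(t2, "a", "b", mut2, fx$neo[0, ], q)
  expect_equal(d2$delta_tmb, 0L)
  expect_equal(d2$n_new_clones, 0L)
  expect_true(d2$no_recurrent_neoantigens)
  expect_equal(d2$pct_new_neoantigens, 0)

  # antisymmetry under role swap
  dSwap <- pairedDeltas(fx$tree, "rec", "prim", fx$mut, fx$neo, q)
  expect_equal(dSwap$delta_tmb, -d$delta_tmb)
  expect_equal(dSwap$delta_entropy, -d$delta_entropy)
  expect_equal(dSwap$delta_na, -d$delta_na)
})

test_that("paired deltas agree with a brute-force recount on simulated data", {
  cfg <- simConfig(seed = 31, nPatients = 1)
  co <- simulateCohort(cfg, withSurvival = FALSE)
  p <- co$patients[[1]]
  samples <- colnames(cloneFrequencies(p$tree))
  d <- pairedDeltas(p$tree, samples[1], samples[2], p$mutations,
                    p$neoantigens, p$qualities)
  # independent recount of delta_tmb from first principles
  recount <- function(sample) {
    x <- cloneFrequencies(p$tree, sample)
    present <- unique(unlist(lapply(names(x)[x > 0.01], function(cl)
      cloneGenotype(p$tree, cl))))
    ns <- p$mutations$mutation_id[p$mutations$effect %in%
                                    c("missense", "nonsense")]
    length(intersect(present, ns))
  }
  expect_equal(d$delta_tmb, recount(samples[2]) - recount(samples[1]))
})

test_that("depletion analysis reproduces KS statistics from first principles", {
  set.seed(3)
  a <- data.frame(log_c = rnorm(40), D = rnorm(40))
  b <- data.frame(log_c = rnorm(45, 0.4), D = rnorm(45, 0.8))
  res <- depletionAnalysis(a, b)
  for (st in c("log_c", "D")) {
    grid <- sort(c(a[[st]], b[[st]]))
    oracle <- max(abs(ecdf(a[[st]])(grid) - ecdf(b[[st]])(grid)))
    expect_equal(res[[st]]$ks_statistic, oracle, tolerance = 1e-12)
  }
  # identical groups: statistic 0, p = 1
  same <- suppressWarnings(depletionAnalysis(a, a))
  expect_equal(same$log_c$ks_statistic, 0)
  expect_equal(same$log_c$p_value, 1)
  # a clear shift is detected at n = 200
  set.seed(4)
  g1 <- data.frame(log_c = rnorm(200), D = rnorm(200))
  g2 <- data.frame(log_c = g1$log_c, D = g1$D + 1)
  shift <- depletionAnalysis(g1, g2, statistics = "D")
  expect_lt(shift$D$p_value, 0.01)
  expect_error(depletionAnalysis(data.frame(log_c = 1, D = 1), a),
               "at least 2")
})

test_that("substitution-frequency regression matches closed-form least squares", {
  model <- trueCrossReactModel(9L)
  M <- substitutionMatrix(model)
  subs <- data.frame(wt_residue = c("A", "A", "L", "F", "K", "D"),
                     mt_residue = c("G", "V", "I", "Y", "R", "E"))
  d <- M[cbind(subs$wt_residue, subs$mt_residue)]
  # counts exactly linear (decreasing) in matrix distance
  subs$count <- round(1000 * (max(d) + 0.5 - d))
  res <- substitutionFrequencyRegression(subs, model)
  expect_equal(res$r, -1, tolerance = 1e-6)
  # oracle: closed-form simple regression
  prop <- subs$count / sum(subs$count)
  slopeOracle <- sum((d - mean(d)) * (prop - mean(prop))) /
    sum((d - mean(d))^2)
  expect_equal(res$slope, slopeOracle, tolerance = 1e-12)
  expect_equal(res$r, oraclePearson(prop, d), tolerance = 1e-12)
  expect_error(substitutionFrequencyRegression(subs[1:2, ], model),
               "at least 3")

  # permuted counts decorrelate
  set.seed(5)
  rs <- replicate(100, {
    subs$count <- sample(subs$count)
    substitutionFrequencyRegression(subs, model)$r
  })
  expect_lt(abs(median(rs)), 0.5)
})
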