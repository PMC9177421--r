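# Clone fitness model and recurrent-tumour frequency prediction.
#
# Each clone alpha carries a fitness F = -sigma_I * F_I + sigma_P * F_P:
# a negative cost from immune recognition of its best (highest-quality)
# neoantigen and a positive gain from accumulated driver missense mutations.
# Primary clone frequencies are propagated to the recurrent tumour as
# xhat_rec = x_prim * exp(F) / Z, with Z ensuring normalization. The
# selection amplitudes are fitted by maximum likelihood (multinomial over
# observed recurrent fractions with effective sample size n_eff) and
# compared against oncogene-only and neutral models by BIC.

#' Canonical PDAC driver genes
#'
#' Default driver-gene set used by the oncogenic fitness component.
#' @return Character vector of gene symbols.
#' @export
pdacDriverGenes <- function() c("KRAS", "TP53", "CDKN2A", "SMAD4")

#' Oncogenic fitness component of a clone
#'
#' Counts missense mutations in driver genes within the clone genotype
#' (inherited mutations included).
#'
#' @param tree A [CloneTree-class].
#' @param cloneId Clone identifier.
#' @param mutations Mutation data.frame (needs \code{mutation_id, gene,
#'   effect}).
#' @param driverGenes Driver gene symbols; defaults to [pdacDriverGenes()].
#' @return Integer count F_P.
#' @export
driverFitness <- function(tree, cloneId, mutations,
                          driverGenes = pdacDriverGenes()) {
  geno <- cloneGenotype(tree, cloneId)
  if (length(geno) == 0L) return(0L)
  rows <- mutations[mutations$mutation_id %in% geno, , drop = FALSE]
  sum(rows$effect == "missense" & rows$gene %in% driverGenes)
}

#' Immune fitness cost of a clone
#'
#' F_I = maximum neoantigen quality Q over the clone genotype; 0 for a
#' neoantigen-free clone.
#'
#' @param tree A [CloneTree-class].
#' @param cloneId Clone identifier.
#' @param qualities Named numeric vector of per-mutation neoantigen
#'   qualities (names are mutation ids; for mutations with several
#'   neoantigens, supply the per-mutation maximum).
#' @return Numeric F_I.
#' @export
immuneFitnessCost <- function(tree, cloneId, qualities) {
  geno <- cloneGenotype(tree, cloneId)
  hit <- intersect(geno, names(qualities))
  if (length(hit) == 0L) return(0)
  max(qualities[hit])
}

#' Fitness table of all clones in a tree
#'
#' @param tree A [CloneTree-class].
#' @param sigmaI,sigmaP Non-negative selection amplitudes.
#' @param qualities Named numeric vector of per-mutation qualities.
#' @param mutations Mutation data.frame (see [driverFitness()]).
#' @param driverGenes Driver gene symbols.
#' @return data.frame with \code{clone_id, F_I, F_P, F} where
#'   \code{F = -sigmaI * F_I + sigmaP * F_P}.
#' @export
cloneFitnessTable <- function(tree, sigmaI, sigmaP, qualities, mutations,
                              driverGenes = pdacDriverGenes()) {
  stopifnot(sigmaI >= 0, sigmaP >= 0)
  ids <- cloneIds(tree)
  fi <- vapply(ids, function(cl) immuneFitnessCost(tree, cl, qualities), 0)
  fp <- vapply(ids, function(cl)
    as.numeric(driverFitness(tree, cl, mutations, driverGenes)), 0)
  data.frame(clone_id = ids, F_I = fi, F_P = fp,
             F = -sigmaI * fi + sigmaP * fp, row.names = NULL)
}

#' Predict recurrent clone frequencies from primary frequencies
#'
#' xhat_rec = x_prim * exp(F) / Z with Z = sum_beta x_prim^beta exp(F^beta).
#' Primary frequencies are renormalized over clones first (tumour purity),
#' and the output sums to 1 (to 1e-12).
#'
#' @param xPrim Named numeric vector of primary clone frequencies (>= 0, at
#'   least one positive).
#' @param fitness Numeric vector of clone fitness values F, aligned with
#'   \code{xPrim} (recycled if scalar).
#' @return Named numeric vector of predicted recurrent frequencies.
#' @examples
#' predictRecurrentFrequencies(c(a = 0.5, b = 0.5), c(0, log(2)))
#' @export
predictRecurrentFrequencies <- function(xPrim, fitness) {
  if (all(xPrim == 0)) stop("all primary frequencies are zero")
  if (any(xPrim < 0)) stop("negative primary frequencies")
  if (length(fitness) == 1L) fitness <- rep(fitness, length(xPrim))
  stopifnot(length(fitness) == length(xPrim))
  x <- xPrim / sum(xPrim)
  # subtract the max fitness for numerical stability of exp()
  zterm <- x * exp(fitness - max(fitness[x > 0]))
  zterm / sum(zterm)
}

# Multinomial log-likelihood of observed recurrent fractions under the
# propagation model: L = n_eff * sum_alpha xobs * log(xhat).
.propagationLogLik <- function(xPrim, xObs, fi, fp, sigmaI, sigmaP, nEff) {
  xhat <- predictRecurrentFrequencies(xPrim, -sigmaI * fi + sigmaP * fp)
  nEff * sum(xObs[xObs > 0] * log(xhat[xObs > 0]))
}

#' Fit selection amplitudes by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of the observed recurrent clone
#' fractions under the frequency-propagation model over sigma_I, sigma_P >= 0
#' (bounded quasi-Newton with multi-start from \{0, 1, 10\} per axis).
#' Clones absent from the primary tumour are excluded (the propagation
#' equation carries primary clones only) and observed recurrent fractions
#' are renormalized over the propagated clones. BIC = k ln(n) - 2 L is
#' reported for the full model (k = 2), the oncogene-only model
#' F = sigma_P F_P (k = 1) and the neutral model (k = 0); the preferred
#' model minimizes BIC.
#'
#' @param tree A [CloneTree-class] with one primary and one recurrent sample.
#' @param qualities Named numeric vector of per-mutation qualities.
#' @param mutations Mutation data.frame (see [driverFitness()]).
#' @param primarySample,recurrentSample Sample ids; default to the first
#'   sample with the matching role.
#' @param nEff Effective multinomial sample size (default 100).
#' @param driverGenes Driver gene symbols.
#' @param sigmaUpper Upper optimization bound on both amplitudes.
#' @return A [SelectionFit-class].
#' @export
fitSelectionParams <- function(tree, qualities, mutations,
                               primarySample = NULL, recurrentSample = NULL,
                               nEff = 100, driverGenes = pdacDriverGenes(),
                               sigmaUpper = 50) {
  roles <- sampleRoles(tree)
  if (is.null(primarySample))
    primarySample <- names(roles)[roles == "primary"][1]
  if (is.null(recurrentSample))
    recurrentSample <- names(roles)[roles == "recurrent"][1]
  if (is.na(primarySample) || is.na(recurrentSample))
    stop("tree must carry one primary and one recurrent sample")

  xPrimAll <- cloneFrequencies(tree, primarySample)
  xRecAll <- cloneFrequencies(tree, recurrentSample)
  keep <- xPrimAll > 0
  if (sum(keep) < 1L) stop("all primary frequencies are zero")
  ft <- cloneFitnessTable(tree, 0, 0, qualities, mutations, driverGenes)
  fi <- ft$F_I[keep]; fp <- ft$F_P[keep]
  xPrim <- xPrimAll[keep] / sum(xPrimAll[keep])
  if (sum(xRecAll[keep]) == 0)
    stop("no propagated clone observed in the recurrent sample")
  xObs <- xRecAll[keep] / sum(xRecAll[keep])
  n <- sum(keep)

  neutralLL <- nEff * sum(xObs[xObs > 0] * log(xPrim[xObs > 0]))

  if (n < 2L) {
    warning("single usable clone: likelihood is flat, returning neutral fit")
    return(methods::new("SelectionFit", sigmaI = 0, sigmaP = 0,
                        logLik = neutralLL, bicFull = -2 * neutralLL,
                        bicOncogenic = -2 * neutralLL,
                        bicNeutral = -2 * neutralLL,
                        preferredModel = "neutral", nClones = as.integer(n),
                        nEff = nEff))
  }

  negLL <- function(sig) -.propagationLogLik(xPrim, xObs, fi, fp,
                                             sig[1], sig[2], nEff)
  starts <- as.matrix(expand.grid(sI = c(0, 1, 10), sP = c(0, 1, 10)))
  bestFull <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[r, ], negLL, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(sigmaUpper, sigmaUpper),
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(bestFull) || fit$value < bestFull$value))
      bestFull <- fit
  }
  if (is.null(bestFull)) stop("full-model optimization failed at every start")

  negLLOnco <- function(sp) negLL(c(0, sp))
  bestOnco <- NULL
  for (s0 in c(0, 1, 10)) {
    fit <- tryCatch(
      stats::optim(s0, negLLOnco, method = "L-BFGS-B", lower = 0,
                   upper = sigmaUpper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(bestOnco) || fit$value < bestOnco$value))
      bestOnco <- fit
  }
  oncoLL <- if (is.null(bestOnco)) neutralLL else -bestOnco$value

  fullLL <- -bestFull$value
  bics <- c(full = 2 * log(n) - 2 * fullLL,
            oncogenic = 1 * log(n) - 2 * oncoLL,
            neutral = 0 - 2 * neutralLL)
  methods::new("SelectionFit",
               sigmaI = unname(bestFull$par[1]),
               sigmaP = unname(bestFull$par[2]),
               logLik = fullLL,
               bicFull = unname(bics["full"]),
               bicOncogenic = unname(bics["oncogenic"]),
               bicNeutral = unname(bics["neutral"]),
               preferredModel = names(bics)[which.min(bics)],
               nClones = as.integer(n), nEff = nEff)
}

# Per-tumour data needed by the likelihood: renormalized primary and
# observed recurrent fractions plus fitness components of propagated clones.
.tumorLikData <- function(tree, qualities, mutations,
                          primarySample = NULL, recurrentSample = NULL,
                          driverGenes = pdacDriverGenes()) {
  roles <- sampleRoles(tree)
  if (is.null(primarySample))
    primarySample <- names(roles)[roles == "primary"][1]
  if (is.null(recurrentSample))
    recurrentSample <- names(roles)[roles == "recurrent"][1]
  xPrimAll <- cloneFrequencies(tree, primarySample)
  xRecAll <- cloneFrequencies(tree, recurrentSample)
  keep <- xPrimAll > 0
  if (sum(keep) < 1L || sum(xRecAll[keep]) == 0) return(NULL)
  ft <- cloneFitnessTable(tree, 0, 0, qualities, mutations, driverGenes)
  list(xPrim = xPrimAll[keep] / sum(xPrimAll[keep]),
       xObs = xRecAll[keep] / sum(xRecAll[keep]),
       fi = ft$F_I[keep], fp = ft$F_P[keep], n = sum(keep))
}

#' Fit shared selection amplitudes across a cohort by joint ML
#'
#' Maximizes the sum of per-tumour multinomial log-likelihoods under shared
#' (sigma_I, sigma_P), for cohorts whose tumours evolved under a common
#' selection regime. BIC uses the total number of clones entering the joint
#' likelihood.
#'
#' @param patients List of per-patient lists, each with elements \code{tree}
#'   ([CloneTree-class]), \code{qualities} (named per-mutation quality
#'   vector) and \code{mutations} (data.frame) — the shape returned by
#'   [simulateCohort()].
#' @param nEff Effective multinomial sample size per tumour (default 100).
#' @param driverGenes Driver gene symbols.
#' @param sigmaUpper Upper optimization bound on both amplitudes.
#' @return A [SelectionFit-class].
#' @export
fitSelectionCohort <- function(patients, nEff = 100,
                               driverGenes = pdacDriverGenes(),
                               sigmaUpper = 50) {
  dat <- Filter(Negate(is.null), lapply(patients, function(p)
    .tumorLikData(p$tree, p$qualities, p$mutations,
                  driverGenes = driverGenes)))
  if (length(dat) == 0L) stop("no usable tumours in cohort")
  nTotal <- sum(vapply(dat, function(d) d$n, 0L))

  cohortLL <- function(sigmaI, sigmaP) {
    sum(vapply(dat, function(d)
      .propagationLogLik(d$xPrim, d$xObs, d$fi, d$fp, sigmaI, sigmaP, nEff),
      0))
  }
  neutralLL <- cohortLL(0, 0)

  negLL <- function(sig) -cohortLL(sig[1], sig[2])
  starts <- as.matrix(expand.grid(sI = c(0, 1, 10), sP = c(0, 1, 10)))
  bestFull <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[r, ], negLL, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(sigmaUpper, sigmaUpper),
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(bestFull) || fit$value < bestFull$value))
      bestFull <- fit
  }
  if (is.null(bestFull)) stop("cohort optimization failed at every start")
  bestOnco <- NULL
  for (s0 in c(0, 1, 10)) {
    fit <- tryCatch(
      stats::optim(s0, function(sp) negLL(c(0, sp)), method = "L-BFGS-B",
                   lower = 0, upper = sigmaUpper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(bestOnco) || fit$value < bestOnco$value))
      bestOnco <- fit
  }
  oncoLL <- if (is.null(bestOnco)) neutralLL else -bestOnco$value
  fullLL <- -bestFull$value
  bics <- c(full = 2 * log(nTotal) - 2 * fullLL,
            oncogenic = 1 * log(nTotal) - 2 * oncoLL,
            neutral = 0 - 2 * neutralLL)
  methods::new("SelectionFit",
               sigmaI = unname(bestFull$par[1]),
               sigmaP = unname(bestFull$par[2]),
               logLik = fullLL,
               bicFull = unname(bics["full"]),
               bicOncogenic = unname(bics["oncogenic"]),
               bicNeutral = unname(bics["neutral"]),
               preferredModel = names(bics)[which.min(bics)],
               nClones = as.integer(nTotal), nEff = nEff)
}

#' Evaluate observed versus predicted clone frequency changes
#'
#' Restricted to clones with primary frequency above \code{threshold}
#' (reliably predictable clones), compares observed recurrent/primary
#' frequency ratios with model-predicted ratios. Frequencies below the
#' sampling threshold are substituted by \code{pseudocount} in the ratios so
#' vanished clones keep finite log-ratios. Reports the fraction of clones
#' whose frequency-change direction (sign of the log-ratio) is predicted
#' correctly — ties (log-ratio exactly 0 on either side) are excluded from
#' the denominator — and the two-tailed Spearman rank correlation between
#' observed and predicted log-ratios.
#'
#' @param tree A [CloneTree-class].
#' @param fitness Named or plain numeric vector of clone fitness values F
#'   aligned with \code{cloneIds(tree)}.
#' @param primarySample,recurrentSample Sample ids; default to roles.
#' @param threshold Primary-frequency inclusion threshold (default 0.03).
#' @param pseudocount Substitute for sub-threshold frequencies (default
#'   \code{threshold / 2}).
#' @return List with \code{table} (per-clone observed/predicted ratios),
#'   \code{directionAgreement}, \code{rho} and \code{p} (Spearman test;
#'   \code{NA} when fewer than 3 clones).
#' @export
evaluateFrequencyChanges <- function(tree, fitness,
                                     primarySample = NULL,
                                     recurrentSample = NULL,
                                     threshold = 0.03,
                                     pseudocount = threshold / 2) {
  roles <- sampleRoles(tree)
  if (is.null(primarySample))
    primarySample <- names(roles)[roles == "primary"][1]
  if (is.null(recurrentSample))
    recurrentSample <- names(roles)[roles == "recurrent"][1]
  xPrimAll <- cloneFrequencies(tree, primarySample)
  xRecAll <- cloneFrequencies(tree, recurrentSample)
  stopifnot(length(fitness) == length(xPrimAll))

  keep <- xPrimAll > 0
  xPrim <- xPrimAll / sum(xPrimAll[keep])
  xRec <- xRecAll / max(sum(xRecAll[keep]), .Machine$double.eps)
  xhat <- rep(0, length(xPrimAll))
  names(xhat) <- names(xPrimAll)
  xhat[keep] <- predictRecurrentFrequencies(xPrimAll[keep], fitness[keep])

  sel <- which(xPrim > threshold)
  if (length(sel) == 0L)
    stop(sprintf("no clones above the %g primary-frequency threshold",
                 threshold))
  sub <- function(x) ifelse(x < threshold, pseudocount, x)
  obsRatio <- sub(xRec[sel]) / sub(xPrim[sel])
  fitRatio <- sub(xhat[sel]) / sub(xPrim[sel])
  lro <- log(obsRatio); lrf <- log(fitRatio)

  decided <- lro != 0 & lrf != 0
  agreement <- if (any(decided)) {
    mean(sign(lro[decided]) == sign(lrf[decided]))
  } else NA_real_
  if (length(sel) >= 3L && stats::sd(lro) > 0 && stats::sd(lrf) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(lro, lrf, method = "spearman", alternative = "two.sided"))
    rho <- unname(ct$estimate); pval <- ct$p.value
  } else {
    rho <- suppressWarnings(stats::cor(lro, lrf, method = "spearman"))
    pval <- NA_real_
  }
  list(table = data.frame(clone_id = cloneIds(tree)[sel],
                          x_prim = unname(xPrim[sel]),
                          x_rec = unname(xRec[sel]),
                          x_rec_hat = unname(xhat[sel]),
                          observed_ratio = unname(obsRatio),
                          fitted_ratio = unname(fitRatio),
                          row.names = NULL),
       directionAgreement = agreement, rho = rho, p = pval)
}

#' Write a selection fit report as JSON
#' @param fit A [SelectionFit-class].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the report (e.g. the
#'   per-clone table from [evaluateFrequencyChanges()]).
#' @return Invisibly, \code{path}.
#' @export
writeSelectionFit <- function(fit, path, extra = list()) {
  obj <- c(list(sigma_I = fit@sigmaI, sigma_P = fit@sigmaP,
                log_likelihood = fit@logLik,
                bic = list(full = fit@bicFull, oncogenic = fit@bicOncogenic,
                           neutral = fit@bicNeutral),
                preferred_model = fit@preferredModel,
                n_clones = fit@nClones, n_eff = fit@nEff), extra)
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
}
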