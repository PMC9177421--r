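# Seeded generators for every input class: substitution scans (dose-response
# curves), logC observation tables, patient cohorts evolved under known
# selection amplitudes, TCR repertoires with controlled convergence, and a
# coherent on-disk fixture bundle. All generators are pure functions of
# (config, seed); per-subtask seeds are derived from the root seed so adding
# patients or TCRs does not perturb earlier draws.

#' Simulation configuration
#'
#' Bundles the generative settings shared by the cohort and scan simulators.
#' Defaults emulate resected pancreatic cancer cohorts: 8-15 clones per
#' tumour, ~35 neoantigens per tumour arising on passenger mutations,
#' clonal driver missense mutations with occasional later driver gains,
#' 9-mer peptides, and moderate multinomial sampling depth.
#'
#' @param seed Integer seed (mandatory).
#' @param nPatients Number of patients.
#' @param cloneRange Range (min, max) of clones per tumour.
#' @param peptideLength Peptide length (default 9).
#' @param nEpitopes Size of the known-epitope reference set.
#' @param sigmaI,sigmaP Generative selection amplitudes.
#' @param nEff Multinomial sampling depth for observed recurrent
#'   frequencies; \code{Inf} for noiseless propagation.
#' @param noiseSd Gaussian response noise of simulated dose-response points.
#' @param logCNoiseSd Gaussian noise on simulated logC observations.
#' @param pNeoantigen Probability that a passenger mutation generates a
#'   neoantigen.
#' @param pHomologous Probability that a neopeptide is a mutated copy of a
#'   known epitope (high recognition potential) rather than random.
#' @param pLateDriver Probability that a non-root clone acquires an extra
#'   driver missense mutation.
#' @param rootDrivers Range of clonal (root) driver missense mutations.
#' @param passengersPerClone Range of passenger mutations per clone.
#' @param survBeta Log-hazard increase per unit of tumour max quality when
#'   generating survival times.
#' @param survMedianMonths Baseline median overall survival, months.
#' @param censorHorizon Administrative censoring time, months.
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed, nPatients = 6L, cloneRange = c(8L, 15L),
                      peptideLength = 9L, nEpitopes = 50L,
                      sigmaI = 1.0, sigmaP = 0.5, nEff = 100,
                      noiseSd = 0.05, logCNoiseSd = 0.2,
                      pNeoantigen = 0.6, pHomologous = 0.5,
                      pLateDriver = 0.35, rootDrivers = c(1L, 2L),
                      passengersPerClone = c(1L, 4L),
                      survBeta = 0.5, survMedianMonths = 24,
                      censorHorizon = 120) {
  stopifnot(!missing(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(length(cloneRange) == 2L, cloneRange[1] >= 1,
            cloneRange[2] >= cloneRange[1])
  structure(list(seed = as.integer(seed), nPatients = as.integer(nPatients),
                 cloneRange = as.integer(cloneRange),
                 peptideLength = as.integer(peptideLength),
                 nEpitopes = as.integer(nEpitopes), sigmaI = sigmaI,
                 sigmaP = sigmaP, nEff = nEff, noiseSd = noiseSd,
                 logCNoiseSd = logCNoiseSd, pNeoantigen = pNeoantigen,
                 pHomologous = pHomologous, pLateDriver = pLateDriver,
                 rootDrivers = as.integer(rootDrivers),
                 passengersPerClone = as.integer(passengersPerClone),
                 survBeta = survBeta, survMedianMonths = survMedianMonths,
                 censorHorizon = censorHorizon),
            class = "simConfig")
}

.randomPeptide <- function(len) paste(sample(.AA20, len, TRUE), collapse = "")

.mutatePeptide <- function(peptide, nSubs) {
  aa <- .splitAA(peptide)
  pos <- sample(length(aa), min(nSubs, length(aa)))
  for (i in pos) aa[i] <- sample(setdiff(.AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

#' A ground-truth cross-reactivity model for simulations
#'
#' Builds a generative truth: a bell-shaped position profile (termini more
#' cross-reactive, i.e. smaller weights at positions 1 and L) and a residue
#' matrix derived from BLOSUM62 dissimilarity (within-family substitutions
#' closer), normalized to the package's scale convention.
#'
#' @param peptideLength Profile length (default 9).
#' @return A [CrossReactModel-class] usable as simulation truth.
#' @export
trueCrossReactModel <- function(peptideLength = 9L) {
  L <- as.integer(peptideLength)
  x <- (seq_len(L) - 1) / (L - 1)
  w <- 0.3 + 1.1 * sin(pi * x)  # low at termini, peak centrally
  interior <- if (L > 2L) 2:(L - 1L) else seq_len(L)
  w <- w / mean(w[interior])
  b62 <- .blosum62()
  self <- (outer(diag(b62), diag(b62), "+")) / 2
  # scale: disruptive substitutions at central positions reach logC ~ 7-8
  # (EC50 ratios of 10^3-fold), matching scans that span a 10,000-fold
  # concentration range; conservative within-family swaps stay near logC ~ 1
  M <- (self - b62) / 2
  diag(M) <- 0
  dimnames(M) <- list(.AA20, .AA20)
  support <- matrix(1L, 20, 20, dimnames = list(.AA20, .AA20))
  diag(support) <- 0L
  methods::new("CrossReactModel", matrix = M, support = support,
               weights = w, combiner = "multiplicative")
}

#' Simulate logC observations from a substitution scan design
#'
#' For each TCR, emits one observation per single-substitution variant of
#' the reference peptide (19 residues x length positions) with
#' logC = w_i * M[wt, mt] + Gaussian noise. This is the post-curve-fitting
#' view of a scan, used directly for matrix-recovery studies.
#'
#' @param peptide Reference peptide.
#' @param nTcrs Number of TCRs scanned against this peptide.
#' @param model A [CrossReactModel-class] truth (e.g.
#'   [trueCrossReactModel()]).
#' @param noiseSd Gaussian noise on logC.
#' @param seed Integer seed.
#' @param tcrPrefix Prefix for TCR identifiers.
#' @return data.frame with \code{tcr_id, position, wt_residue, mt_residue,
#'   log_c}.
#' @export
simulateLogCObservations <- function(peptide, nTcrs, model, noiseSd = 0,
                                     seed, tcrPrefix = "tcr") {
  set.seed(seed)
  aa <- .splitAA(toupper(peptide))
  L <- length(aa)
  rows <- list()
  for (t in seq_len(nTcrs)) {
    for (i in seq_len(L)) {
      for (b in setdiff(.AA20, aa[i])) {
        lc <- .positionWeight(model@weights, i, L) * model@matrix[aa[i], b] +
          stats::rnorm(1, 0, noiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          tcr_id = sprintf("%s%d", tcrPrefix, t), position = i,
          wt_residue = aa[i], mt_residue = b, log_c = lc)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full substitution scan as dose-response curves
#'
#' For each reference peptide x TCR, emits the reference activation curve
#' plus all 19 x length single-substitution variant curves. Variant EC50s
#' follow the truth model: log(EC50^MT/EC50^WT) = w_i * M[wt, mt] plus
#' Gaussian noise of sd \code{logCNoiseSd}; responses are Hill curves with
#' optional Gaussian response noise. Deterministic under a fixed seed.
#'
#' @param peptides Character vector of reference peptides.
#' @param tcrsPerPeptide Number of TCRs scanned per peptide (recycled).
#' @param model Truth [CrossReactModel-class].
#' @param seed Integer seed.
#' @param ec50Wt Reference EC50 (molar).
#' @param concentrations Molar test concentrations (log-spaced grid).
#' @param hill,emax,baseline True Hill parameters of every curve.
#' @param responseNoiseSd Gaussian noise added to responses.
#' @param logCNoiseSd Gaussian noise added to variant log EC50 ratios.
#' @return List of [DoseResponseCurve-class].
#' @export
simulateSubstitutionScan <- function(peptides, tcrsPerPeptide, model, seed,
                                     ec50Wt = 1e-9,
                                     concentrations = 10^seq(-12, -5,
                                                             length.out = 8),
                                     hill = 1, emax = 1, baseline = 0,
                                     responseNoiseSd = 0, logCNoiseSd = 0) {
  tcrsPerPeptide <- rep_len(as.integer(tcrsPerPeptide), length(peptides))
  curves <- list()
  lc <- log10(concentrations)
  makeCurve <- function(tcrId, pep, ec50, pos, wt, mt) {
    y <- .hillResponse(lc, log10(ec50), hill, emax, baseline)
    if (responseNoiseSd > 0) y <- y + stats::rnorm(length(y), 0,
                                                   responseNoiseSd)
    DoseResponseCurve(tcrId, pep, concentrations, pmax(y, 0),
                      position = pos, wtResidue = wt, mtResidue = mt)
  }
  for (p in seq_along(peptides)) {
    pep <- toupper(peptides[p])
    aa <- .splitAA(pep)
    L <- length(aa)
    for (t in seq_len(tcrsPerPeptide[p])) {
      set.seed(.deriveSeed(seed, p * 1000L + t))
      tcrId <- sprintf("pep%d_tcr%d", p, t)
      curves[[length(curves) + 1L]] <-
        makeCurve(tcrId, pep, ec50Wt, NA_integer_, NA_character_,
                  NA_character_)
      for (i in seq_len(L)) {
        for (b in setdiff(.AA20, aa[i])) {
          logC <- .positionWeight(model@weights, i, L) *
            model@matrix[aa[i], b]
          if (logCNoiseSd > 0) logC <- logC + stats::rnorm(1, 0, logCNoiseSd)
          mtPep <- pep
          substr(mtPep, i, i) <- b
          curves[[length(curves) + 1L]] <-
            makeCurve(tcrId, mtPep, ec50Wt * exp(logC), i, aa[i], b)
        }
      }
    }
  }
  curves
}

#' Simulate a random epitope set
#'
#' @param n Number of epitopes.
#' @param length Peptide length.
#' @param seed Integer seed.
#' @return An [EpitopeSet-class] with ids \code{E1..En}.
#' @export
simulateEpitopeSet <- function(n, length = 9L, seed) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) .randomPeptide(length), "")
  EpitopeSet(stats::setNames(seqs, sprintf("E%d", seq_len(n))))
}

# Random rooted clone tree by uniform attachment.
.simulateTreeTopology <- function(nClones, patientId) {
  ids <- sprintf("%s_c%d", patientId, seq_len(nClones))
  parents <- c(NA_character_,
               if (nClones > 1)
                 ids[vapply(2:nClones, function(j)
                   sample.int(j - 1L, 1L), 0L)])
  list(ids = ids, parents = parents)
}

#' Simulate a patient cohort under known selection
#'
#' Generates, per patient: a random clone tree (uniform attachment) with
#' Dirichlet primary frequencies; clonal driver missense mutations at the
#' root with occasional later driver gains in subclones; passenger mutations
#' per clone, a fraction of which generate neoantigens (random 9-mer
#' wild-type peptides with a single substitution, or mutated copies of known
#' epitopes, with lognormal Kd pairs); neoantigen qualities under the
#' supplied quality model; recurrent frequencies propagated at
#' (sigma_I, sigma_P) followed by multinomial sampling at depth n_eff; and
#' optional survival times with hazard increasing in the tumour's maximum
#' quality.
#'
#' @param config A [simConfig()].
#' @param params A [QualityParams-class] (its epitope set is used); if
#'   \code{NULL}, a fresh epitope set is simulated and default parameters
#'   used.
#' @param model A [CrossReactModel-class]; defaults to
#'   [trueCrossReactModel()].
#' @param withSurvival Generate survival times (default TRUE).
#' @return List with \code{patients} (per patient: \code{patientId, tree,
#'   neoantigens, mutations, qualities}), \code{survival} (data.frame),
#'   \code{params}, \code{model} and \code{config}.
#' @export
simulateCohort <- function(config, params = NULL, model = NULL,
                           withSurvival = TRUE) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(model)) model <- trueCrossReactModel(config$peptideLength)
  if (is.null(params)) {
    epi <- simulateEpitopeSet(config$nEpitopes, config$peptideLength,
                              seed = .deriveSeed(config$seed, 0L))
    params <- defaultQualityParams(epi)
  }
  drivers <- pdacDriverGenes()
  patients <- vector("list", config$nPatients)
  surv <- data.frame(patient_id = character(0), time = numeric(0),
                     event = integer(0))
  for (pIdx in seq_len(config$nPatients)) {
    set.seed(.deriveSeed(config$seed, pIdx))
    pid <- sprintf("P%02d", pIdx)
    nClones <- sample(seq(config$cloneRange[1], config$cloneRange[2]), 1L)
    topo <- .simulateTreeTopology(nClones, pid)

    mutRows <- list(); neoRows <- list()
    ownMuts <- stats::setNames(rep(list(character(0)), nClones), topo$ids)
    mutCounter <- 0L
    addMutation <- function(cloneId, gene, effect, genNeo) {
      mutCounter <<- mutCounter + 1L
      mid <- sprintf("%s_m%d", pid, mutCounter)
      ownMuts[[cloneId]] <<- c(ownMuts[[cloneId]], mid)
      mutRows[[length(mutRows) + 1L]] <<- data.frame(
        patient_id = pid, tumor_id = paste0(pid, "_prim"),
        clone_id = cloneId, mutation_id = mid, gene = gene, effect = effect,
        generates_neoantigen = genNeo)
      mid
    }
    addNeoantigen <- function(cloneId, mid, gene) {
      if (stats::runif(1) < config$pHomologous &&
          length(params@epitopes) > 0) {
        src <- as.character(epitopeSequences(params@epitopes)[[
          sample.int(length(params@epitopes), 1L)]])
        pWt <- .mutatePeptide(src, sample(2:3, 1L))
      } else {
        pWt <- .randomPeptide(config$peptideLength)
      }
      pMt <- .mutatePeptide(pWt, 1L)
      kdWt <- exp(stats::runif(1, log(50), log(5000)))
      kdMt <- kdWt * exp(stats::rnorm(1, -0.7, 1.0))  # mutants often bind better
      neoRows[[length(neoRows) + 1L]] <<- data.frame(
        patient_id = pid, tumor_id = paste0(pid, "_prim"),
        clone_id = cloneId, gene = gene, mutation_id = mid,
        p_wt = pWt, p_mt = pMt, hla = "HLA-A*02:01",
        kd_wt = kdWt, kd_mt = kdMt)
    }

    # clonal drivers at the root, later driver gains in subclones
    nRoot <- sample(seq(config$rootDrivers[1], config$rootDrivers[2]), 1L)
    for (g in sample(drivers, nRoot))
      addMutation(topo$ids[1], g, "missense", FALSE)
    if (nClones > 1) {
      for (cl in topo$ids[-1]) {
        if (stats::runif(1) < config$pLateDriver)
          addMutation(cl, sample(drivers, 1L), "missense", FALSE)
      }
    }
    # passengers, some neoantigenic
    for (cl in topo$ids) {
      nPass <- sample(seq(config$passengersPerClone[1],
                          config$passengersPerClone[2]), 1L)
      for (j in seq_len(nPass)) {
        effect <- sample(c("missense", "synonymous"), 1L, prob = c(0.75, 0.25))
        genNeo <- effect == "missense" && stats::runif(1) < config$pNeoantigen
        gene <- sprintf("GENE%d", sample.int(5000L, 1L))
        mid <- addMutation(cl, gene, effect, genNeo)
        if (genNeo) addNeoantigen(cl, mid, gene)
      }
    }
    mutations <- do.call(rbind, mutRows)
    neoantigens <- if (length(neoRows) > 0) do.call(rbind, neoRows) else
      data.frame(patient_id = character(0), tumor_id = character(0),
                 clone_id = character(0), gene = character(0),
                 mutation_id = character(0), p_wt = character(0),
                 p_mt = character(0), hla = character(0),
                 kd_wt = numeric(0), kd_mt = numeric(0))

    scored <- if (nrow(neoantigens) > 0)
      neoantigenQuality(neoantigens, params, model) else NULL
    qualities <- if (!is.null(scored) && nrow(scored) > 0) {
      tapply(scored$Q, scored$mutation_id, max)
    } else stats::setNames(numeric(0), character(0))
    qualities <- stats::setNames(as.numeric(qualities), names(qualities))

    # primary frequencies: flat Dirichlet
    gam <- stats::rgamma(nClones, shape = 1)
    xPrim <- gam / sum(gam)

    primName <- paste0(pid, "_prim"); recName <- paste0(pid, "_rec")
    fr0 <- matrix(c(xPrim, rep(0, nClones)), nClones, 2,
                  dimnames = list(topo$ids, c(primName, recName)))
    tree0 <- CloneTree(topo$ids, topo$parents, fr0,
                       stats::setNames(c("primary", "recurrent"),
                                       c(primName, recName)), ownMuts)
    ft <- cloneFitnessTable(tree0, config$sigmaI, config$sigmaP, qualities,
                            mutations)
    xhat <- predictRecurrentFrequencies(xPrim, ft$F)
    xRec <- if (is.finite(config$nEff)) {
      as.numeric(stats::rmultinom(1, config$nEff, xhat)) / config$nEff
    } else xhat
    fr <- fr0
    fr[, recName] <- xRec
    tree <- CloneTree(topo$ids, topo$parents, fr,
                      stats::setNames(c("primary", "recurrent"),
                                      c(primName, recName)), ownMuts)

    if (withSurvival) {
      maxQ <- if (length(qualities) > 0) max(qualities) else 0
      rate0 <- log(2) / config$survMedianMonths
      t <- stats::rexp(1, rate0 * exp(config$survBeta * maxQ))
      surv <- rbind(surv, data.frame(
        patient_id = pid, time = min(t, config$censorHorizon),
        event = as.integer(t <= config$censorHorizon)))
    }
    patients[[pIdx]] <- list(patientId = pid, tree = tree,
                             neoantigens = if (is.null(scored))
                               neoantigens else scored,
                             mutations = mutations, qualities = qualities)
  }
  list(patients = patients, survival = if (withSurvival) surv else NULL,
       params = params, model = model, config = config)
}

#' Simulate a TCR repertoire with controlled convergence
#'
#' Top clonotypes are mutated copies of a seed CDR3beta with per-residue
#' mutation probability (1 - convergence); counts are geometric. At
#' convergence 1 all top clonotypes are identical (dissimilarity index 0).
#'
#' @param sampleId Sample identifier.
#' @param convergence Number in [0, 1].
#' @param nClonotypes Number of clonotypes to draw.
#' @param cdr3Length Length of the seed CDR3beta.
#' @param seed Integer seed.
#' @return A [TcrRepertoire-class].
#' @export
simulateRepertoire <- function(sampleId, convergence, nClonotypes = 50L,
                               cdr3Length = 14L, seed) {
  stopifnot(convergence >= 0, convergence <= 1)
  set.seed(seed)
  seedCdr3 <- .randomPeptide(cdr3Length)
  cdr3 <- vapply(seq_len(nClonotypes), function(i) {
    aa <- .splitAA(seedCdr3)
    flip <- stats::runif(cdr3Length) < (1 - convergence)
    for (j in which(flip)) aa[j] <- sample(setdiff(.AA20, aa[j]), 1L)
    paste(aa, collapse = "")
  }, "")
  counts <- sort(stats::rgeom(nClonotypes, prob = 0.2) + 1L,
                 decreasing = TRUE)
  TcrRepertoire(sampleId, cdr3, counts)
}

#' Write a coherent mini-cohort fixture bundle to disk
#'
#' Writes every input format the package reads: an epitope FASTA, one clone
#' tree JSON per patient, pooled neoantigen and mutation TSVs, a
#' dose-response CSV (one small scan), per-sample AIRR repertoire TSVs, the
#' truth cross-reactivity model JSON and the configuration YAML. Regenerated
#' with the same seed, the bundle is byte-identical.
#'
#' @param outdir Output directory.
#' @param config A [simConfig()].
#' @param force Overwrite a non-empty directory (default FALSE: error).
#' @return Invisibly, a named character vector of the files written.
#' @export
makeFixtureBundle <- function(outdir, config, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force)
    stop(sprintf("directory %s is not empty (use force = TRUE)", outdir))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  model <- trueCrossReactModel(config$peptideLength)
  epi <- simulateEpitopeSet(config$nEpitopes, config$peptideLength,
                            seed = .deriveSeed(config$seed, 0L))
  params <- defaultQualityParams(epi)
  cohort <- simulateCohort(config, params, model)

  files <- c(epitopes = file.path(outdir, "epitopes.fasta"))
  writeEpitopeFasta(epi, files[["epitopes"]])

  neo <- do.call(rbind, lapply(cohort$patients, function(p) {
    cols <- c("patient_id", "tumor_id", "clone_id", "gene", "mutation_id",
              "p_wt", "p_mt", "hla", "kd_wt", "kd_mt")
    p$neoantigens[, cols[cols %in% names(p$neoantigens)], drop = FALSE]
  }))
  mut <- do.call(rbind, lapply(cohort$patients, function(p) p$mutations))
  files[["neoantigens"]] <- file.path(outdir, "neoantigens.tsv")
  writeNeoantigenTable(neo, files[["neoantigens"]])
  files[["mutations"]] <- file.path(outdir, "mutations.tsv")
  writeMutationTable(mut, files[["mutations"]])

  sampleCounter <- 0L
  for (p in cohort$patients) {
    f <- file.path(outdir, sprintf("clone_tree_%s.json", p$patientId))
    files[[paste0("tree_", p$patientId)]] <- f
    writeCloneTree(p$tree, f)
    for (s in colnames(cloneFrequencies(p$tree))) {
      sampleCounter <- sampleCounter + 1L
      rep <- simulateRepertoire(s, convergence = 0.7, nClonotypes = 30L,
                                seed = .deriveSeed(config$seed,
                                                   10000L + sampleCounter))
      f <- file.path(outdir, sprintf("repertoire_%s.tsv", s))
      files[[paste0("repertoire_", s)]] <- f
      writeAirrRepertoire(rep, f)
    }
  }

  scan <- simulateSubstitutionScan("NLVPMVATV", 1L, model,
                                   seed = .deriveSeed(config$seed, 99L),
                                   responseNoiseSd = config$noiseSd,
                                   logCNoiseSd = config$logCNoiseSd)
  files[["dose_response"]] <- file.path(outdir, "dose_response.csv")
  writeDoseResponse(scan, files[["dose_response"]])

  files[["model"]] <- file.path(outdir, "model.json")
  writeCrossReactModel(model, files[["model"]])

  files[["survival"]] <- file.path(outdir, "survival.tsv")
  .atomicWrite(files[["survival"]], function(tmp)
    utils::write.table(cohort$survival, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  cfg <- unclass(config)
  cfg$quality <- list(w = params@w, a = params@a, k = params@k)
  files[["config"]] <- file.path(outdir, "config.yaml")
  .atomicWrite(files[["config"]], function(tmp)
    yaml::write_yaml(cfg, tmp))
  invisible(files)
}
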