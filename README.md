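# neoquality

Neoantigen quality scoring and clonal selection inference for longitudinal
tumour cohorts.

Cancer immunoediting predicts that T cells preferentially eliminate tumour
clones carrying immunogenic neoantigens, so recurrent tumours should be
depleted of them — most visibly in patients under strong immune pressure.
`neoquality` implements the quantitative machinery needed to test this in
paired primary/recurrent cohorts:

* **Neoantigen quality** `Q = R × D`, where `R` is the recognition
  potential of the mutant peptide **p**^MT (a logistic partition over
  gapless BLOSUM62 alignment scores against known immunogenic epitopes) and
  `D = (1−w)·log(Kd^WT/Kd^MT) + w·log(EC50^MT/EC50^WT)` is
  self-discrimination: differential MHC presentation (amplitude *A*) plus
  the TCR cross-reactivity distance *C* between mutant and wild-type
  peptide.
* **Cross-reactivity from experiments**: Hill fits of TCR activation
  titrations (`fitHill`), EC50 ratios (`crossReactivityRatio`), and a
  position-weighted 20×20 substitution matrix learned from substitution
  scans by alternating least squares (`buildCrossReactModel`), with residue
  clustering (`clusterResidues`) and prediction for arbitrary pairs
  (`predictLogC`).
* **Clone fitness and prediction**: `F^α = −σ_I·max Q + σ_P·F_P^α` per
  clone (immune cost vs driver-missense gain), recurrent frequency
  propagation `x̂_rec^α = x_prim^α e^{F^α}/Z`, maximum-likelihood fitting
  of (σ_I, σ_P) with BIC comparison against oncogene-only and neutral
  models (`fitSelectionParams`, `fitSelectionCohort`), and observed-vs-
  predicted frequency-change evaluation with pseudocounts
  (`evaluateFrequencyChanges`).
* **Cohort immunoediting metrics**: clonal Shannon entropy, TMB/neoantigen
  deltas, new-clone statistics, KS depletion tests,
  substitution-frequency regression, and the TCR dissimilarity index with
  its correlation to immune fitness cost.
* **Seeded simulators** for every input format (epitope FASTA, neoantigen
  and mutation TSVs, clone-tree JSON, dose-response CSV, AIRR repertoire
  TSV), including cohorts evolved under known selection amplitudes for
  recovery studies.

## Worked example

```r
library(neoquality)

# 1. learn a cross-reactivity model from a (simulated) substitution scan
truth <- trueCrossReactModel()
obs <- simulateLogCObservations("NLVPMVATV", nTcrs = 3, truth,
                                noiseSd = 0.2, seed = 11)
model <- buildCrossReactModel(obs, peptideLength = 9)
model
#> CrossReactModel (multiplicative position x residue decomposition)
#>   peptide length: 9; observed cells: 133/380; mean |off-diag M|: 3.113

# 2. score a neoantigen
epitopes <- EpitopeSet(c(CMV_NLV = "NLVPMVATV", FLU_GIL = "GILGFVFTL"))
params <- defaultQualityParams(epitopes)
rec <- data.frame(patient_id = "P01", mutation_id = "m1",
                  p_wt = "NLVPMVATV", p_mt = "NLVPKVATV",
                  kd_wt = 480, kd_mt = 38)
round(neoantigenQuality(rec, params, model)[, c("R","log_a","log_c","D","Q")], 3)
#>   R log_a log_c     D     Q
#> 1 1 2.536 3.946 3.241 3.241

# 3. simulate a cohort under known selection and refit the amplitudes
cfg <- simConfig(seed = 7, nPatients = 6, nEff = 200,
                 sigmaI = 1, sigmaP = 0.5)
cohort <- simulateCohort(cfg, withSurvival = FALSE)
fit <- fitSelectionCohort(cohort$patients, nEff = 200)
fit
#> SelectionFit over 71 clones (n_eff = 200)
#>   sigma_I = 0.9578, sigma_P = 0.5002, logL = -2356
#>   BIC: full = 4720, oncogenic = 5063, neutral = 5080 -> preferred: full

# 4. per-tumour frequency-change prediction
p1 <- cohort$patients[[1]]
ft <- cloneFitnessTable(p1$tree, fit@sigmaI, fit@sigmaP,
                        p1$qualities, p1$mutations)
ev <- evaluateFrequencyChanges(p1$tree, ft$F)
sprintf("direction agreement %.2f, Spearman rho %.2f",
        ev$directionAgreement, ev$rho)
#> "direction agreement 1.00, Spearman rho 0.86"
```

Reading the output: the mutant peptide is one substitution away from a
known strong epitope, so `R ≈ 1`; it binds MHC ~13-fold better than its
wild-type counterpart (`log_a = 2.5`) and the substitution is predicted
poorly cross-reactive (`log_c = 3.9`), giving a high quality `Q = 3.2`.
The cohort refit recovers the generating amplitudes (1.0, 0.5) to within a
few percent and BIC prefers the full model over oncogene-only and neutral
alternatives; per tumour, the fitted model predicts the direction of every
clone frequency change above the 3% threshold.

## Command line

A thin wrapper over the same functions
(`inst/scripts/neoquality <subcommand>`): `simulate`, `fit-curves`,
`build-xreact`, `quality`, `fit-fitness`, `predict`, `metrics`, `tcr`.
Every run writes a `manifest.json` with option values and input/output md5
hashes; exit codes are 0 (success), 2 (validation), 1 (runtime).

```sh
Rscript inst/scripts/neoquality simulate --seed 7 --out demo/
Rscript inst/scripts/neoquality quality \
  --neoantigens demo/neoantigens.tsv --epitopes demo/epitopes.fasta \
  --model demo/model.json --out demo/scored/
```

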