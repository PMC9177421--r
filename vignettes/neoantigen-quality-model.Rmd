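---
title: "Neoantigen quality and clonal selection: models and methods"
author: "neoquality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen quality and clonal selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoquality)
```

# The problem

Cancer immunoediting predicts that T cells preferentially kill tumour cell
clones carrying immunogenic mutant peptides (neoantigens), so that less
immunogenic clones come to dominate over time. Testing this in longitudinal
human cohorts requires (i) a per-neoantigen immunogenicity ("quality")
score, (ii) a clone-level fitness model that converts qualities and driver
mutations into predicted clonal dynamics between a primary tumour and its
recurrence, and (iii) cohort-level statistics that detect depletion of
high-quality neoantigens. This package implements all three layers plus
seeded simulators for every input class, so the full pipeline is testable
without access to protected patient data.

# Neoantigen quality

A neoantigen is a wild-type/mutant peptide pair (p^WT, p^MT) with MHC-I
dissociation constants Kd^WT and Kd^MT (nM, supplied as inputs — binding
prediction is out of scope). Its quality is

  Q = R x D,

with natural logarithms throughout (a display option converts to log10; the
fitness exponentials below pair naturally with ln).

**Recognition potential R** measures whether p^MT resembles epitopes the
TCR repertoire can already recognize. For each epitope e in a reference set,
s_e is the best gapless alignment score of p^MT against e (every full-overlap
window of the shorter sequence against the longer, BLOSUM62 residue scores,
no gaps). These enter a logistic partition

  R = Z^-1 * sum_e exp(-k (a - s_e)),  Z = 1 + sum_e exp(-k (a - s_e)),

so R is in [0, 1), increases with every s_e, and saturates once scores
exceed the displacement `a` (score units) at steepness `k` (inverse score
units). The aggregation over the whole set (rather than only the best hit)
is kept behind a single function so alternatives can be swapped; the sum lets
several moderate hits add up rather than crediting only the best one.

**Self-discrimination D** measures how different p^MT is from its own
wild-type counterpart, i.e. how hard it is for tolerance mechanisms to
confuse the two:

  D = (1 - w) log(Kd^WT / Kd^MT) + w log(EC50^MT / EC50^WT).

The first term is the MHC amplitude A (differential presentation: a poorly
presented wild-type peptide leaves more peptide-specific T cells in the
periphery). The second is the cross-reactivity distance C, the fold-change
in peptide concentration a TCR needs to respond to the mutant versus the
wild-type peptide. The weight `w` in [0, 1] balances the two.

**Parameters (w, a, k).** These ship as explicit defaults (w = 0.5, a = 22,
k = 1) that users should confirm or refit for their cohort:
`a` sits near typical best self-alignment scores of 9-mers under BLOSUM62,
`k = 1` spans a few score units, and `w = 0.5` weighs the two D terms
equally. `selectParamsByLogrank()` implements the refitting procedure: for
each grid point, patients are summarized (max Q by default, mirroring the
clone-level max of the fitness model), split at the cohort median, and
scored by the two-sided log-rank statistic; ties break to the smallest
(w, a, k) lexicographically. One caveat discovered while validating the
procedure: for fixed k the displacement `a` rescales every patient's
recognition sum by the same factor, which is a monotone transformation of
the per-patient ranking whenever D > 0 dominates, so the median split — and
with it the log-rank score — is typically invariant in `a`. In that regime
`a` must be fixed on external grounds (e.g. the score scale of the epitope
set); the grid search genuinely discriminates `w` and, weakly, `k`.

# Cross-reactivity from activation scans

`fitHill()` fits each TCR-peptide dose-response curve with the increasing
4-parameter Hill form

  response(c) = baseline + emax / (1 + (EC50 / c)^h),

by bounded least squares in log10 concentration: h in [0.5, 5], EC50 within
the tested range widened 100-fold either side, three EC50 starting points
with best-RSS selection. Unbounded sigmoid fits on sparse titration grids
diverge, hence the boxes; multi-start guards against the initialization
sensitivity of sigmoids. Peptides that never activate (flat curves, failed
fits, or fitted amplitude below `activationFloor` = 0.1 of the same-TCR
reference amplitude) are *censored*: EC50 is set to the highest tested
concentration x 10, keeping log C finite but capped so poorly
cross-reactive substitutions still inform the model rather than vanishing.

`buildCrossReactModel()` pools log C observations across TCRs and fits the
multiplicative decomposition

  log C(i, a -> b) = w_i * M[a, b]

by alternating least squares (converged when the relative RSS change falls
below 1e-8, at most 200 sweeps). M is a 20 x 20 matrix over wild-type ->
mutant residues, asymmetric because EC50 ratios are directional; identity
cells are pinned at 0. The scale degeneracy between the profile and the
matrix is resolved by normalizing the interior position weights to mean 1.
Cells never observed are imputed from observed cells within the same
biochemical family pair (aliphatic, aromatic, polar, positive, negative,
glycine/proline), falling back to the global off-diagonal mean, and carry
`support = 0` so downstream users can filter them.

**Identifiability caveat.** Positions are coupled only through shared
wild-type residues: scanning a single reference peptide leaves the
(position, cell) observation graph disconnected, and the relative scale of
each component is then arbitrary — exact recovery is impossible no matter
how clean the data. Scan panels should therefore combine reference peptides
whose wild-type residues connect all positions; the package's test design
uses three 9-mers (NLVPMVATV, ITDQVPFSV, VATLQDKHE) that form a single
connected component, under which noiseless recovery is exact up to the
normalization convention.

`clusterResidues()` reproduces the residue dendrogram: average-linkage
agglomerative clustering on the Euclidean distance between rows of the
symmetrized matrix (M + t(M))/2, so residues with identical substitution
behaviour merge at height 0. `predictLogC()` maps a substitution at
position i of an n-mer through the profile (linear interpolation over
normalized position when n differs from the training length) and sums terms
for multi-substitution pairs — an extension beyond the single-substitution
scans the model is trained on, flagged as such.

# Clone fitness and recurrent-tumour prediction

Clone trees are inputs (joint multisample phylogenies reconstructed
upstream); each clone's genotype is the union of its own mutations and its
ancestors'. Per-sample clone frequencies may sum to less than 1 (tumour
purity); all model arithmetic renormalizes over clones.

Each clone alpha has fitness

  F = -sigma_I * F_I + sigma_P * F_P,

where F_I is the maximum quality Q over neoantigens in the clone genotype
(0 for neoantigen-free clones) and F_P counts missense mutations in the
canonical PDAC driver genes (KRAS, TP53, CDKN2A, SMAD4 by default). Both
amplitudes are constrained non-negative, matching the signs in the model.
Primary frequencies propagate to the recurrence as

  xhat_rec = x_prim * exp(F) / Z,

with Z the normalizing constant; the prediction conserves mass to 1e-12 by
construction.

**Likelihood.** The propagation equation fixes the predicted composition
but not an error model; this package adopts a multinomial over
observed recurrent clone fractions with a configurable effective sample
size n_eff (default 100), L = n_eff * sum_alpha x_rec * log xhat_rec,
maximized by bounded quasi-Newton (L-BFGS-B) from a 3 x 3 multi-start grid
{0, 1, 10} per amplitude. Clones absent from the primary tumour are
excluded from propagation (new clones are handled by the cohort metrics)
and observed recurrent fractions are renormalized over propagated clones.
Model choice uses BIC = kappa ln(n) - 2 L for the full (kappa = 2),
oncogene-only (kappa = 1) and neutral (kappa = 0) models, with n the number
of clones entering the likelihood (reported in the fit object).
`fitSelectionParams()` fits one primary-recurrent pair;
`fitSelectionCohort()` fits shared amplitudes across a cohort by summing
per-tumour log-likelihoods, which is how the parameter-recovery studies are
run.

`evaluateFrequencyChanges()` compares observed and fitted frequency ratios
for reliably predictable clones (primary frequency above 3%); frequencies
below that sampling threshold are replaced by a pseudocount (threshold/2 =
0.015 by default; any sub-threshold estimate is sampling noise, and half the
threshold is the neutral stand-in) so vanished clones keep finite
log-ratios. It reports the fraction
of clones whose change direction is predicted correctly (exact ties are
excluded from the denominator) and the two-tailed Spearman correlation of
the log-ratios.

# Cohort metrics and the TCR repertoire

Per-tumour summaries: clonal Shannon entropy (nats, with a log2 display
option); TMB as non-synonymous mutations carried by any clone above the
presence threshold (0.01, a sampling noise floor distinct from the 3%
prediction threshold); neoantigen counts filtered at the conventional
MHC-I binder cutoff of 500 nM on the mutant Kd (both thresholds are
arguments); and the mean immune fitness cost, frequency-weighted by default
(weighting by clone frequency reflects what the tumour presents in
aggregate; the unweighted per-clone mean is available as an option). Paired primary/recurrent deltas are always
recurrent minus primary; new clones are those above the presence threshold
only in the recurrence, and the percentage of new neoantigens is the share
of recurrent neoantigens private to new clones. Depletion analyses compare
log C and D distributions between groups with two-sided Kolmogorov-Smirnov
tests; group contrasts use two-tailed Mann-Whitney U; the
substitution-frequency regression relates observed substitution proportions
to the matrix distance M with a two-tailed Pearson test.

The TCR dissimilarity index is the mean pairwise length-normalized distance
among the k most expanded CDR3beta clonotypes (k = 10 by default; count
ties break lexicographically). The default distance is a global alignment
cost with residue cost max(BLOSUM62 self-score) - pair score (0 for
identical residues) and gap cost equal to the maximum residue cost,
normalized by the mean pair length; a plain normalized edit distance is
available behind the same interface so results can be checked against a
metric with no substitution model. Low index = convergent expansion.
`expansionVsEditing()` correlates the index with the mean immune fitness
cost (two-tailed Pearson).

# Synthetic data: what it emulates and what it does not

All generators are pure functions of (config, seed); per-subtask seeds are
derived from the root seed so adding patients or TCRs never perturbs
earlier draws.

* `simulateSubstitutionScan()` reproduces the experimental design of a
  substitution scan — for each reference peptide x TCR, the reference curve
  plus all 19 x length single-substitution variants (two 9-mers x 3 TCRs
  give 1,026 variant pairs; adding one 9-mer x 1 TCR gives 1,197) — with
  Hill-curve responses whose EC50 ratios follow a ground-truth
  position x residue model plus optional noise.
* `trueCrossReactModel()` is that ground truth: a bell-shaped position
  profile (termini more cross-reactive) and a matrix derived from BLOSUM62
  dissimilarity scaled so disruptive central substitutions reach
  log C of about 7-8 (EC50 ratios of 10^3-10^4, consistent with scans that
  span a 10,000-fold concentration range), while within-family swaps stay
  near log C of 1.
* `simulateCohort()` draws, per patient: a uniform-attachment clone tree
  with 8-15 clones and flat-Dirichlet primary frequencies; 1-2 clonal
  driver missense mutations at the root plus later driver gains in
  subclones with probability 0.35 (drivers are mostly clonal in this
  disease, but strictly constant driver counts would cancel out of the
  propagation equation and make sigma_P unidentifiable — the cumulative
  per-clone driver count the fitness model uses presumes such variation);
  passenger mutations of which ~60% of missense ones generate neoantigens
  (9-mers, single substitution, lognormal Kd pairs, half homologous to a
  known epitope so recognition potentials span (0, 1)); recurrent
  frequencies propagated at the configured (sigma_I, sigma_P) and sampled
  multinomially at depth n_eff; and optional survival times from an
  exponential model with hazard log(2)/24 months x exp(0.5 x max Q), i.e.
  baseline median survival of 24 months, as for resected pancreatic cancer.
* `simulateRepertoire()` draws top clonotypes as mutated copies of a seed
  CDR3beta with per-residue mutation probability (1 - convergence) and
  geometric counts.

The simulators emulate the *structure* of real inputs, not their biology:
no mutational signatures, no read-level noise, no HLA restriction in the
peptide draws, no clonal interference during recurrence. Passing recovery
tests therefore shows the estimators are correct and well calibrated under
the model family, not that the model fits any particular cohort.

# Numerical choices and degenerate inputs

* Alternating minimization: convergence at relative RSS change < 1e-8 or
  200 sweeps; all-zero observations are a fixed point (zero matrix,
  all-ones profile); single-position scans pin the profile to 1 with a
  warning; negative profile weights are clamped at 0.
* Hill fits: flat curves are censored, not errors; curves with fewer than
  4 points are rejected at construction.
* Propagation: exp() is stabilized by subtracting the maximum fitness among
  clones with positive primary frequency.
* Likelihood optimization: L-BFGS-B with factr = 1e4; noiseless
  selection-generated data return the generating amplitudes to ~1e-6.
* A tumour pair with a single usable clone has a flat likelihood: the fit
  warns and returns the neutral model.
* Median splits with an empty arm score -Inf in the log-rank grid search;
  all-censored cohorts are errors.

# Study sizes used by the validation suites

The packaged tests and the acceptance script use: 50 cohorts x 6 patients
(n_eff = 200) for selection-amplitude recovery and model choice, 100 seeds
for noisy EC50 recovery, the 1,197-observation three-peptide design for
matrix recovery, and 1,000 random parameter points for the conservation
property. These sizes give stable medians and proportions while keeping the
whole suite to a few minutes on one CPU.

One honest negative result is retained: with Gaussian response noise of
0.05 on 8-point titrations, the median relative EC50 error of the
4-parameter fit is ~16%, and no estimator can do much better — a
one-parameter oracle with the other Hill parameters known already has a
~14% median error (the Fisher information in 8 points at that noise caps
log10-EC50 precision at about 0.08). Recovery to within 10% at this design
requires either denser titrations or replicate curves.

# Known limitations

* The defaults for (w, a, k) are starting points, not fitted truths;
  refitting on the user's cohort is expected.
* The multiplicative position x residue form is the minimal model in
  which cross-reactivity depends on the substituted position and residue;
  the combiner is an enum so richer forms can be added.
* Multi-substitution log C sums per-substitution terms — an extrapolation.
* The multinomial likelihood's n_eff is a modelling choice, not an
  estimate of sequencing depth; BIC rankings are invariant to applying the
  same n_eff across models but absolute likelihoods are not interpretable.
* The TCR dissimilarity metric is one reasonable choice among several;
  it is isolated behind an interface for exactly that reason.
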