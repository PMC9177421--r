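Package: neoquality
Title: Neoantigen Quality, T Cell Cross-Reactivity and Clonal Selection in
    Longitudinal Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores tumour neoantigens by a quality model combining a
    recognition potential (similarity of the mutant peptide to known
    immunogenic epitopes) with self-discrimination (differential MHC
    presentation and TCR cross-reactivity between mutant and wild-type
    peptides). Fits Hill dose-response curves to TCR activation scans to
    estimate EC50-based cross-reactivity distances, learns a position-weighted
    amino-acid substitution matrix from them, propagates clone frequencies
    from primary to recurrent tumours under an immune-cost/oncogenic-gain
    fitness model, fits the selection amplitudes by maximum likelihood with
    BIC model comparison, and computes cohort-level immunoediting statistics
    (clonal entropy, mutation and neoantigen burden deltas, depletion tests,
    TCR repertoire convergence). Includes seeded simulators for every input
    class so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    survival
VignetteBuilder: knitr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
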