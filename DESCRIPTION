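Package: mitonet
Title: Residue Interaction Analysis for the Mitochondrial Respiratory Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study interactions among residues of the thirteen
    mitochondrially encoded respiratory-chain subunits. Screens ortholog
    protein alignments for compensated pathogenic deviations (human
    pathogenic residues fixed in healthy mammals with conserved flanks),
    scores co-varying column pairs with weighted mutual information
    (average-product corrected) and mean-field direct coupling analysis,
    classifies single and paired free-energy changes into disruptive and
    compensatory calls, enumerates every nonsynonymous single-nucleotide
    substitution of the mtDNA protein genes under the vertebrate
    mitochondrial code, and summarises molecular-dynamics trajectories
    (superposition RMSD, per-atom RMSF, essential-dynamics PCA). Includes
    simulators that plant known signal in alignments, free-energy tables
    and trajectories so every analysis can be validated against ground
    truth, plus a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
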