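---
title: "Residue interaction analysis for the mitochondrial respiratory chain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue interaction analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

# The problem

The thirteen proteins encoded by the human mitochondrial genome are subunits
of the OXPHOS complexes I, III, IV and V. Their residues interact — within a
subunit, across subunits, and with nuclear-encoded partners — and those
interactions leave three kinds of statistical and energetic footprints that
this package quantifies:

1. **Compensated pathogenic deviations (CPDs).** An amino acid that is
   pathogenic in humans sometimes occurs as the normal, fixed residue in a
   healthy non-human mammal. Such a deviation is presumed *compensated* by
   residues elsewhere, so cataloguing CPDs points at epistatic partners.
2. **Residue co-variation.** Compensation implies correlated substitution
   histories. Column pairs of ortholog alignments that co-vary across the
   mammalian phylogeny are candidate interacting sites.
3. **Energetic compensation.** For a candidate pair, free-energy changes upon
   mutation (ΔΔG, kcal/mol) of the single mutants and the double mutant tell
   whether the second substitution cancels the destabilisation caused by the
   first. Molecular-dynamics trajectory statistics (RMSD, RMSF, essential
   dynamics) probe the same question dynamically.

The package implements each step behind plain functions, a file-level
command-line interface (`inst/cli/mitonet`), and simulators that plant known
signal so every claim the analyses make can be checked against ground truth.

# CPD calling

`read_alignment()` loads an aligned FASTA of mammalian orthologs with a
designated human reference row. Ortholog quality control follows a
dissimilarity screen: `dissimilarity()` is the fraction of differing columns,
where a column gapped in both sequences leaves the denominator and a gap
aligned to a residue counts as a difference (the common percent-identity
convention; stated explicitly because the choice moves borderline sequences).
`filter_orthologs()` discards sequences *strictly* above the threshold —
0.5 by default, with 0.3 the appropriate choice for the short and fast-evolving
MT-ATP8 — never re-aligning afterwards, and always retaining the reference.

A variant (gene, human protein position, reference and alternative residue)
is a CPD when at least one non-human ortholog carries the alternative residue
at the variant's alignment column **and** at least 7 of the 10 surrounding
human residues (5 per side) are identical in that ortholog. Three conventions
matter and are fixed as follows:

* The flank window is anchored to *human ungapped positions*, not raw
  alignment columns, so insertions private to an ortholog do not shift the
  window; a gap in the ortholog at a flank column counts as non-identical.
* Window slots beyond a protein terminus count as non-identical, keeping the
  7-of-10 rule meaningfully strict near the ends.
* "Non-human" means the species string differs from the reference species
  (default `"Homo sapiens"`).

`cpd_prevalence()` reports the fraction of *all* non-human orthologs carrying
the alternative residue, regardless of flank quality — prevalence answers
"how widespread is the deviation", while the flank rule answers "is this a
trustworthy ortholog call".

# Co-variation scoring

Both scorers consume the same alignment object, optionally concatenated
across proteins by `concatenate_alignments()` (species-matched, one row per
species, duplicates resolved toward the row closest to human). Sequence
redundancy is corrected by `sequence_weights()`: a record's weight is the
reciprocal of the number of records within 80% identity of it, and
\(M_{\mathrm{eff}} = \sum_s w_s\) is the effective depth. Both scorers ignore
columns gapped in the human reference when ranking, so every reported pair
maps to a human protein position.

**MI-APC.** Weighted mutual information in bits over the 21-symbol alphabet
(20 residues + gap) with a uniform pseudocount, followed by the
average-product correction
\(MI_p(i,j) = MI(i,j) - \bar{MI}(i)\,\bar{MI}(j)/\bar{MI}\), which removes
the entropic/phylogenetic background each column carries into every pair.
The package deliberately uses a *pairwise* MI statistic as its MI-family
score: cumulative mutual information is a per-residue quantity and cannot
rank pairs, which the TOP-N selection requires.

**mfDCA.** Mean-field direct coupling analysis in its standard formulation:
weighted single and pair frequencies with pseudocount weight 0.5 (half the
probability mass uniform), the connected-correlation matrix over 20 states
per column — the gap is the removed reference state, the usual gauge —
inverted to give couplings, and each pair scored by the direct information
(DI, in nats) of a two-site model whose fields are fit so the direct
distribution reproduces the single-site marginals. DI is a Kullback–Leibler
divergence and therefore non-negative. Unlike MI, DCA separates *direct*
couplings from correlations propagated through intermediate sites.

A caution that the tests make explicit: at shallow alignment depth the
mean-field inversion amplifies sampling noise, and background DI on perfectly
independent columns is *not* negligible (measured here: max background DI
≈ 0.55 at \(M_{\mathrm{eff}} = 150\), falling to ≈ 0.07 at 1000 sequences,
against an independently written reference implementation that agrees to
12 decimals). DI values are rank scores, not calibrated probabilities;
conclusions should rest on ranks, as the TOP-N selection does.

**Selection and filtering.** `top_pairs()` takes the N highest-scoring
distinct column pairs (N = 500 by default) with a deterministic positional
tie-break. Because one protein (MT-ND1 in the published setting) is
concatenated to every partner, `filter_inter()` keeps only cross-protein
pairs, while `filter_intra()` keeps same-protein pairs lying entirely outside
the concatenated carrier. `combine_methods()` forms the union of the two
methods' lists — kept as one row per method, so the union size is the sum of
the list sizes — and flags pairs common to both. Raw matrices produced by
external co-variation servers can be ingested through `read_icoms_matrix()`
(square labelled matrix, labels `protein_position`), and
`reproduce_icoms_counts()` re-runs the TOP-N/filter/union pipeline over a
directory of such matrices.

# Energetic compensation

ΔΔG values arrive as tables (replica columns are averaged by row;
`mean_replicas()` is the one-liner it sounds like). Two strict thresholds do
all the work:

* `classify_single()`: a single mutant is **disruptive** iff |ΔΔG| *exceeds*
  0.61 kcal/mol — the published FoldX significance cutoff; 0.61 itself is
  tolerated.
* `classify_pair()`: a double mutant is **compensatory** iff |ΔΔG| is
  *strictly below* 0.1 kcal/mol.

`compensation_screen()` joins each double mutant to its constituent singles
(unmatched constituents are a hard error listing the missing variants) and
reports a **compensation event** when at least one constituent is disruptive
and the pair is compensatory. Whether the partner variant must itself be
tolerated is left to the consumer — both single calls are reported, so either
convention is a one-line filter. Pairs are partitioned into `interface`
(both positions in a user-supplied interface set), `inter` (different
proteins) and `intra`; the pair ΔΔG is used as supplied rather than as a sum
of singles, with `epistasis = ΔΔG_pair − ΔΔG_a − ΔΔG_b` emitted as a
diagnostic.

# Trajectory summaries

`kabsch_superpose()` is the standard SVD least-squares rigid fit with the
determinant correction that forbids reflections. `rmsd_series()` fits every
frame to a reference frame; `rmsf()` and `essential_dynamics()` fit all
frames to the *average* structure, recompute the average and refit until the
average stops moving (capped at 30 passes, tolerance 1e-12). Conventions
differ across MD packages here; iteration to convergence was chosen because
a fixed two-pass refinement leaves a residual dependence (~1e-5) on
per-frame rigid motions, whereas the converged fit makes RMSF and PCA
eigenvalues invariant to arbitrary rigid motion of every frame to better
than 1e-8 — an invariance the test suite asserts. Mass weighting is off
(uniform weights); the atom subset is an argument, since which atoms
(Cα, backbone, heavy) enter RMSD/RMSF is a modelling choice, not something
the package should guess.

Essential dynamics is the eigendecomposition of the 3N-dimensional positional
covariance of the superposed frames (computed via SVD, so eigenvalues are
non-negative by construction and sum to the total positional variance — an
identity asserted to 1e-8 in the tests). A known artefact is documented
rather than hidden: the least-squares fit removes six rigid degrees of
freedom and, with them, a sliver of any planted motion that overlaps that
subspace; tests therefore bound leakage relatively (e.g. third eigenvalue
< 1e-3 of the first for a two-mode trajectory).

# What the simulators emulate — and what they do not

`simulate_alignment()` evolves tips independently from the human (ancestral)
row on a star phylogeny: each column substitutes with probability
\(1 - e^{-d}\) for divergence \(d\) (expected substitutions per site), to a
uniformly drawn different residue. Planted signal is constructed, not
sampled, so truth is unambiguous:

* **Coupled pairs** co-substitute with probability `strength`; the partner
  column is a fixed random residue bijection of the first (anchored so the
  ancestral pair is consistent), so `strength = 1` gives a deterministic
  residue map between the two columns.
* **CPD carriers** receive the alternative residue with exactly
  `round(10 × flank_conservation)` flank slots held identical to human and
  the rest forced different; non-carriers never show the alternative. Recall
  and decoy rejection on these fixtures are therefore exact (1.0/1.0), by
  construction.

`simulate_ddg_table()` builds exactly `round(fraction × n)` compensation
events with margins (0.30 kcal/mol on the single threshold, 0.05 on the pair
threshold) that replica noise cannot cross — replicas are recentred so their
mean equals the drawn ΔΔG exactly, and a `noise_sd` incompatible with the
margins is a contract error. `simulate_trajectory()` plants harmonic motion
along orthonormal *internal* modes — drawn orthogonal to the six rigid-body
degrees of freedom, as physical collective modes are — with integer cycle
counts, so each mode's sampled variance is exactly its squared amplitude and
the planted eigenvalue spectrum is well defined even under per-frame rigid
drift.

What passing these tests shows is that the statistics are implemented
correctly and recover unambiguous signal under the stated conditions. What
they do not show: real ortholog alignments are tree-structured (not
star-shaped), carry alignment errors, indels and hydrophobicity-biased
substitution processes; real ΔΔG estimates carry model error far beyond
replica noise; real trajectories are not harmonic. Conclusions about real
data inherit those caveats, exactly as they do for the published analysis.

# Study conditions and problem sizes

The package's own validation runs use: coupled-pair recovery on 300 sequences
× 40 columns at divergence 0.6 with coupling strength 0.9 (star tree, so all
weights are 1 and \(M_{\mathrm{eff}} ≈ 300\)), where both scorers are
required to rank 4 planted pairs with AUC ≥ 0.9; CPD recovery on 120 × 70
alignments with 6 carriers (full flanks) and 6 decoy carriers (5-of-10
flanks); ΔΔG screens of 200 pairs at planted fraction 0.25; trajectories of
200 frames × 40 atoms with amplitudes 2 and 1 Å (eigenvalue ratio 4,
recovered within 5%). These sizes keep the full validation suite under a
minute of compute while leaving all conclusions unchanged at larger sizes.

# The mtDNA variant enumeration

`load_genes()` takes any single-record genome plus a gene coordinate table
(1-based inclusive, `+`/`−` strand); minus-strand genes are
reverse-complemented and features ending mid-codon are completed with `A`s —
the mitochondrial polyadenylation convention — and flagged. Every gene must
translate without internal stop codons under NCBI table 2 (TGA = Trp,
ATA = Met, AGA/AGG = stop), or loading fails.

`enumerate_nonsyn()` applies all nine single-nucleotide substitutions to
every complete codon and emits those that change the encoded residue. The
**stop policy** matters to the headline count and is therefore explicit,
logged in the CLI run manifest, and configurable: by default, substitutions
whose reference *or* alternative codon is a stop are excluded — the total
then counts amino-acid-to-amino-acid changes only — and bases added by stop
completion are never enumerated. Start codons are translated plainly (ATT at
position 1 is isoleucine), with no initiator-methionine override. Overlapping
genes (MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4) are enumerated independently, so one
genomic substitution can appear once per gene.

`human_mtdna_genes()` makes the enumeration self-contained: it reads the
human mitochondrial genome record that ships with the seqinr package
(NC_001807.4, 16,571 bp) together with a CDS coordinate table verified for
that record (each of the 13 genes is the unique clean open reading frame of
the expected protein length near its canonical position; on this record all
13 sit exactly one base downstream of their rCRS coordinates). On this
record the default policy yields **24,203** nonsynonymous variants over
3,789 codons. The rCRS (NC_012920.1) differs from NC_001807.4 at a few dozen
positions, ~20 of them inside coding sequence, which shifts the total by a
handful of counts; to enumerate on the rCRS itself, pass that genome and its
annotation to `load_genes()` — the rCRS coordinate offsets are −1 relative
to the bundled table.

# Numerical choices, degenerate inputs, tie-breaks

* MI pseudocount defaults to 0.01 (0 gives exact small-sample arithmetic for
  hand-checkable cases); mfDCA pseudocount weight defaults to 0.5 and a
  numerically singular correlation matrix raises an error advising a larger
  pseudocount.
* The DI two-site fixed point iterates to 1e-9 (cap 2000); looser tolerances
  visibly break the column-permutation equivariance of the scores.
* `top_pairs()` breaks score ties by (protein, position, position), proteins
  in segment order, so outputs are reproducible across platforms.
* Single-column alignments, empty FASTA files, ragged records, unknown
  reference identifiers, positions past the reference length, <3-atom or
  collinear superposition inputs, and single-frame RMSF are all hard errors
  with messages naming the offender.
* `dissimilarity()` of two all-gap sequences is NaN (no comparable columns)
  rather than an arbitrary 0 or 1.

# Known limitations

* The MI-family score is pairwise MI with APC, not the cumulative-MI variant
  used by some co-variation servers; rankings from the two will differ, which
  is precisely why externally produced matrices can be ingested as-is.
* Sequence weighting is the only phylogenetic correction; deep tree structure
  beyond redundancy is not modelled (the star-tree simulator cannot expose
  such effects either).
* ΔΔG values are inputs; the package neither runs a stability predictor nor
  models the membrane environment. Interface residue sets are likewise
  inputs.
* Trajectory I/O is plain text (frame, atom, x, y, z); binary MD formats are
  out of scope.
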