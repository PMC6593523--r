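---
title: "Inferring a transcription-factor regulon from a two-condition bacterial transcriptome"
author: "regulonScout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a transcription-factor regulon from a two-condition bacterial transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonScout)
```

## The problem

Actinobacteria that degrade steroids (for example the mycobacteria used
industrially to convert phytosterol into 9α-hydroxyandrostenedione) switch on
large gene sets when sterols are present. Two TetR-family repressors, KstR
and KstR2, are the canonical regulators, but a substantial fraction of
sterol-induced genes carry neither operator in their promoters — pointing to
additional, uncharacterised regulators whose binding motifs can be found
computationally.

regulonScout implements that computational route as a reusable pipeline:

1. **Differential expression.** From a two-condition (control vs induced),
   replicated RNA-seq count matrix, genes are selected that change at least
   3-fold at a Benjamini–Hochberg FDR (q) of at most 0.01 — both boundaries
   inclusive.
2. **Promoter windows.** For each gene, 500 bp upstream plus 50 bp
   downstream of the first base of the start codon (550 bp total when not
   truncated by a contig edge); minus-strand windows are
   reverse-complemented so motifs are always read 5′→3′ of the gene.
3. **Motif discovery.** Over-represented motifs of width 8–50 bp are sought
   in the up-regulated promoters by seeded expectation-maximisation under a
   ZOOPS occurrence model, and the top motifs are screened against three
   candidacy criteria: E ≤ 10⁻⁵, contains a palindrome, and is not a simple
   repeat.
4. **Site scanning.** Candidate PWMs are scanned over all promoters with two
   schemes — exact p-values with an FDR cut (FIMO-style) and a
   fraction-of-maximum score rule (UGENE-style, 85%) — and merged: a site is
   kept when both schemes find it, or when one scheme finds it upstream of
   an up-regulated operon.
5. **Regulon assembly.** A site before the first gene of an operon is taken
   to regulate every gene of the operon; reports include per-operon mean
   fold changes, co-occurrence with other TFs' sites, and an autoregulation
   flag (a site in the promoter of the regulator's own operon).
6. **Side analyses.** ddCq fold changes from qPCR Cq tables
   (fold = 2^−ΔΔCq with reference-gene normalisation), and substitution
   counting over per-residue conservation ranks (1 = most conserved … 9 =
   least) for enzyme orthologue comparisons.

Every stage runs on synthetic data with known ground truth, generated by the
package itself, so the whole pipeline is testable end to end.

## The statistical pieces and their assumptions

### Negative-binomial differential expression

Counts are normalised with median-of-ratios size factors. Per-gene
dispersion is estimated by method of moments and shrunk toward a lowess
mean–dispersion trend; with the default prior weight (prior df 20 against
the residual df of the design, which is 2 in a 2 + 2 experiment) the trend
dominates, which is the right regime for two replicates. The test is an
exact-style conditional test: within each gene the two condition sums are
compared conditional on their total under a common-mean negative-binomial
model, summing the probabilities of all outcomes no more likely than the
observed one. A dispersion floor of 10⁻⁴ avoids the Poisson degeneracy.
All-zero genes get p = 1. The null calibration and power of this test are
checked by simulation in the test suite (type-I error within [0.03, 0.07]
at α = 0.05; sensitivity ≥ 0.9 at true fold 5 with the 3-fold/q ≤ 0.01
rule).

Fold changes are `(mean induced + 0.5) / (mean control + 0.5)` on
normalised counts; the pseudo-count keeps ratios finite and is
configurable.

### Exact PWM p-values

A PWM hit's p-value is `P(score(W) ≥ s)` for a random background word,
computed exactly by dynamic programming over the per-column score
distributions discretised at 10⁻³ bits. Because each column's score is
rounded to a bin, a word's total can be displaced by up to half a bin per
column; lookups therefore shift by that slack so p-values are never
understated (`p(min score) = 1` holds exactly). The DP agrees with
exhaustive enumeration over all 4^w words for w ≤ 6 within the
discretisation tolerance — this is an acceptance-level check. The scanning
background is, by default, the 0-order composition of the promoter set
being scanned.

One practical consequence of correcting across the whole scan (all
positions of all promoters, both orientations — the package's BH universe)
is that very short motifs cannot reach significance alone: a unique
width-12 consensus has a best possible p of 4⁻¹², which across ~6.5×10⁵
scored positions already gives q ≈ 0.04. Motifs of width 14 and up, the
realistic size for TetR-family operators, do clear the cut.

### Motif discovery and the E-value

Discovery is seeded EM: the most over-represented exact 8-mers (observed /
expected under the background, both strands) are extended to each trial
width on a coarse grid (8, 11, 15, 21, 29, 39, 50), evaluated with two EM
iterations, and the best seed per width is refined to convergence
(penalised log-likelihood change < 10⁻⁴, at most 200 iterations). The
ZOOPS model allows zero or one occurrence per sequence on either strand;
the EM objective (including the Dirichlet pseudo-count prior) is
non-decreasing by construction and asserted per iteration in tests. After
a motif is reported, its maximum-posterior occurrences (posterior ≥ 0.5)
are masked so subsequent motifs are disjoint.

Significance is defined by permutation: the observed log-likelihood ratio
is compared with the best same-width LLR found on base-shuffled copies of
the promoter set. Because an add-one permutation estimate cannot resolve
p below 1/(n+1), a Gaussian tail fitted to the null sample supplies the
far-tail bound, and the p-value is the smaller of the two; the E-value
multiplies by the effective number of motifs examined (widths × seeds).
This E is monotone decreasing in the observed LLR. Two engineering choices
keep the null affordable: a small pilot null (6 replicates per width) ranks
candidate widths, and the full null (40 replicates by default) is computed
only for the selected motif's width; null fits use a lighter EM protocol
(2 seeds, 30 iterations), which biases the null slightly downward — the
5-plus-sigma distance required for E ≤ 10⁻⁵ dwarfs that bias. Both nulls
are drawn from the original (unmasked) promoters and cached across the
report rounds; masking removes well under 1% of the sequence, so the
approximation is benign.

### Candidacy criteria

* **Palindromicity** is the best, over contiguous sub-windows of at least
  8 columns, of the mean per-column Pearson correlation between the
  sub-PWM and its own reverse complement, mapped to [0, 1]; "contains a
  palindrome" means a score of at least 0.8. A perfect palindrome scores
  1; an A-homopolymer scores 1/3 (the correlation between the A and T
  indicator columns is −1/3, not −1 — a 4-letter bookkeeping fact worth
  recording).
* **Simple repeats** are flagged when the consensus matches itself under a
  shift of 1–3 at ≥ 80% of positions and the motif carries at least 1 bit
  per column on average (so degenerate motifs are not flagged).

### Motif–motif comparison

Motifs are compared by aligning probability columns at every ungapped
offset with at least 4 overlapping columns, in both orientations. The
per-column Pearson correlations are averaged **over all query columns**,
with non-overlapping columns contributing zero. Averaging only over the
overlap — the more obvious definition — turns out to have a badly behaved
null: a column-shuffled target very often aligns 4 columns almost
perfectly, so even a recovered planted motif compared with its source
failed to look significant. Query-width normalisation (in the spirit of
TOMTOM's complete-query scoring) makes a full-width match dominate and
restores discrimination. The null is column permutation of the target with
add-one correction; across a target collection the p-values get BH
q-values.

### The two scanning schemes and the consensus rule

Scheme A keeps hits at q ≤ 0.01 after BH over all scored positions of the
run; overlapping same-motif hits in a promoter collapse to the best-scoring
(ties: leftmost, then forward strand). Scheme B keeps positions whose
normalised score fraction `(score − min)/(max − min)` is at least 0.85 —
the normalised form is used because raw score/max is ill-defined for
negative log-odds scores. A and B hits pair when they overlap by at least
half the motif width on the same orientation (support `both`); unpaired
hits survive only upstream of up-regulated operons. Because a palindromic
motif hits both orientations at the same position in scheme B, singletons
that overlap an already-accepted site on any strand are treated as
redundant rather than reported twice.

### Conservation ranks

ConSurf's Bayesian, phylogeny-aware ranks are an *input* here: the
reproducible analytical step is the stratified substitution count (query
vs majority consensus or a named homolog, gap columns excluded). The
bundled rank estimator — relative entropy of each column against
background amino-acid frequencies, binned into 9 equal-quantile grades —
exists so the counting logic can be tested with known truth; it is
explicitly not ConSurf and is labelled as such.

## The synthetic-data generator

`sim_config()` fixes the simulated study: ~300 genes laid out in operons of
1–3 genes (same strand, intra-operon gaps ≤ 100 bp, ≥ 600 bp of intergenic
space before each operon's first gene), a 14-bp palindromic operator
(consensus `AAGTACGCGTACTT`; consensus probability 0.9, ≈ 19 bits — typical
for a TetR-family site) planted 40–80 bp upstream of the start codons of 30
regulon operons on the coding strand, and counts that are negative-binomial
(dispersion 0.02) with per-gene base means drawn uniformly from 200–1000,
log-normal(0, 0.1) library-size factors, and a 5-fold induction of regulon
genes in two conditions × two replicates — the study design the pipeline
targets. Discovery benchmarks use a softer variant of the same motif
(consensus probability 0.8, ≈ 13.5 bits) planted in 60 of 300 stand-alone
promoter windows, which is the interesting signal-to-noise regime for EM.

What the generator does **not** emulate: sequencing-level artefacts (no
reads, no rRNA carry-over, no positional coverage bias), overlapping genes,
horizontally co-regulated operon pairs, genome-scale GC heterogeneity, or
binding sites inside coding sequence. Passing tests therefore demonstrate
the correctness and calibration of the algorithms under the stated model,
not robustness to every artefact of real RNA-seq.

## Numerical and design choices worth knowing

* Coordinates are 1-based inclusive on disk (GFF3) and in all user-facing
  tables; BED output is 0-based half-open with score = 100 × log-odds.
* The 550-bp window counts the start-codon base as the first downstream
  base (+1); the boundary is configurable.
* The operon caller is a gap rule (≤ 100 bp, same strand, same contig,
  consecutive in genome order) with an optional co-expression veto
  (Pearson r ≥ 0.7); it replaces external operon servers with an explicit,
  testable rule.
* Overlapping upstream genes do not truncate promoter windows — fixed
  regions are scanned regardless of neighbours.
* Ambiguity codes in promoters are replaced by random bases with a
  warning; PWMs reject non-ACGT input outright.
* EM seeds: 20 starting points per width, fixed default RNG seed 1817;
  identical seeds give byte-identical outputs everywhere in the package.
* Per-operon fold change is the arithmetic mean over member genes
  (geometric would be defensible; arithmetic is exposed and documented).
* "Near the start codon" for autoregulation means: inside the promoter
  window of the first gene of the TF's own operon.
* Problem sizes used by the automated checks (300 promoters / 60 planted
  for discovery; ~300-gene genomes with 30 regulon operons end-to-end;
  5,000 null genes for DE calibration) were chosen as the smallest sizes
  at which the statistical claims are meaningful.

## Known limitations

* The NB exact-style test is not Rockhopper's (undocumented) procedure;
  only the selection rule (≥ 3-fold, q ≤ 0.01) is reproduced exactly.
* The permutation E-value is a re-specification of MEME's analytic
  E-value; the 10⁻⁵ candidacy threshold applies to this definition.
* The Gaussian far-tail of the discovery null understates heavy tails in
  principle; the null-promoter calibration test bounds the practical
  effect.
* Scheme B's UGENE convention (whether UGENE normalises by max or by
  max − min) is not documented in the original tool; the normalised form
  is the package's choice, switchable via `f_min` semantics if needed.
* The bundled KstR/KstR2 matrices are synthetic reconstructions for
  plumbing and demos, not the published operators.
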