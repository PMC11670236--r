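---
title: "Methods: malignancy scoring and repertoire surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: malignancy scoring and repertoire surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
`clonesurveil`. The package asks whether a treatment selectively removed the
malignant, clonally expanded, highly mutated compartment of a bone-marrow
plasma-cell / B-cell population, using two coupled readouts: per-cell
gene-set malignancy scores on single-cell expression data, and clonal
structure, mutation burden and canonical-clone usage in the paired
heavy-chain BCR repertoire.

## 1. Module scoring and the dual-percentile classifier

### Model

For a gene set $S$ and a log-normalized expression matrix, the module score
of cell $c$ is

$$\mathrm{score}(c) \;=\; \frac{1}{|S|}\sum_{g \in S} x_{gc}
\;-\; \frac{1}{|C|}\sum_{g \in C} x_{gc},$$

where $C$ is a multiset of control genes: all genes are ranked by mean
expression across cells and cut into `n_bins` equal-size bins, and for each
set gene `n_ctrl` controls are sampled (seeded, without replacement,
excluding the set genes) from the gene's own bin. Matching controls on mean
expression removes the dependence of the naive set-mean on per-cell depth:
adding a constant to all genes of one cell shifts set mean and control mean
equally, so the score is exactly invariant (this is a tested property). With
one bin and all non-set genes as controls the score reduces to
(set mean − non-set mean), which the test suite uses as a closed-form
oracle.

Cells are gated as plasma cells before scoring: at least one of *Sdc1*,
*Xbp1*, *Prdm1* above threshold (default 0: any expression) and no *Cd19*
expression. Each gated cell then gets a malignant score $M$, a nonmalignant
score $N$, and a compound score $M - N$. Classification is dual-percentile:

* **malignant**: $M \ge Q_{0.8}(M)$ and $N \le Q_{0.2}(N)$;
* **nonmalignant**: $M \le Q_{0.2}(M)$ and $N \ge Q_{0.8}(N)$;
* **unclassified** otherwise.

The treated-vs-untreated comparison is a two-tailed Mann–Whitney test on
compound scores, plus per-sample malignant frequencies. Differential
expression between groups uses a per-gene tie-corrected rank-sum test with
Benjamini–Hochberg adjustment and a log2 fold change of mean normalized
expression.

### Design decisions

* **Compound-score sign.** The two natural conventions (malignant minus
  nonmalignant, or the reverse) both appear in practice. The package fixes
  `compound = M − N` (higher = more malignant) as canonical and exposes
  `compound_sign = -1` to flip it. One convention had to be canonical for
  histograms and shift tests to be comparable across runs.
* **Quantile pooling.** Classification percentiles are computed over all
  gated cells of the analysis (both arms pooled), because the downstream
  comparison is across arms: per-sample percentiles would force every sample
  to contain the same labeled fractions and erase the group effect. A
  `by_sample = TRUE` option provides the within-sample alternative.
* **Quantile definition.** Linear interpolation between order statistics
  (type 7), with inclusive (≥ / ≤) threshold comparisons — deterministic and
  exactly reproducible by the brute-force oracle in the tests.
* **Scoring layer.** Scores are computed on log-normalized values (each
  cell scaled to 10,000 counts, then log1p). Whether batch-corrected or raw
  log values are scored is recorded in the run summary
  (`scoring_layer: lognorm`); correction/integration is out of scope.
* **Histogram bins** are half-open `[k·w, (k+1)·w)` anchored at 0 with
  default width 0.2 compound-score units, and per-group frequencies are
  percentages of that group's cells.
* **Scoring defaults.** `module_score()` defaults to `n_bins = 24`,
  `n_ctrl = 100`, the common transcriptome-scale setting. The pipeline
  defaults to `n_bins = 10`, `n_ctrl = 30` because the packaged simulations
  use a few hundred genes; with 24 bins of such a matrix every bin would be
  smaller than the control sample and sampling would fall back to
  replacement (it does so with a warning, never silently).
* **DE test.** The rank-sum + BH combination is used because it is the
  default of the standard single-cell toolchain; constant genes get p = 1
  and a flag rather than an error.

## 2. Repertoire surveillance

### Clonotyping

Records are partitioned by (V gene, J gene, CDR3 amino-acid length); within
a partition, single-linkage clusters connect records whose CDR3 Hamming
identity is **at or above** 0.80. Decisions:

* Hamming identity on equal-length CDR3s (records of different CDR3 length
  never share a clone) is the common repertoire convention; a
  normalized-edit-distance reading that merges different lengths is *not*
  implemented and is flagged as a known alternative.
* Single linkage is the standard clonal-grouping choice (a clone is a
  mutational lineage, so chaining is intended); complete linkage is
  available via `linkage = "complete"`.
* The threshold comparison is inclusive: two length-10 CDR3s differing at
  exactly 2 positions (identity 0.80) share a clone.
* Clone labels are derived from sorted partition contents, so the partition
  is invariant to input row order (tested property).

### Mutation burden and the double filter

Per record, the SHM count is the number of aligned positions where sequence
and germline both hold a residue and differ; the frequency is that count
over the non-gap aligned length, in percent. A clone's mutation frequency is
the mean over its **distinct** sequence variants (each clonotype variant
counted once). The "highly mutated clonotype" filter is strict on both
sides: frequency **above** 2% and size **larger than** 10 cells, so 6
substitutions over 300 sites (exactly 2.0%) and a 10-cell clone both fail.

`mutated_clonotype_frequency()` reports three per-sample variants because
the natural denominators genuinely differ:

* `prop_mutated_clones` — mutated clones among clones > 10 cells (missing,
  not zero, when no clone qualifies);
* `prop_mutated_all` — mutated qualifying clones over all clones;
* `prop_mutated_seqs` — fraction of sequences belonging to clones mutated
  above threshold, no size filter.

The sequence-weighted variant is the one used for planted-effect recovery:
under clone-size depletion by a factor $d$ the clone-count variants jump
discontinuously as clones cross the 10-cell boundary, whereas the
sequence-weighted frequency scales smoothly (approximately as
$d(1-f)+f$ for an expanded fraction $f$).

### Canonical clone and logos

VH1-72 usage is the per-sample fraction of records carrying the canonical V
gene. W33L is read directly from the germline-annotated CDR1 window:
residue at window position 8 (1-based; the window is positions 26–33 of the
V region, so window position 8 is residue 33). No general antibody numbering
engine is implemented — the window coordinates travel with the germline
annotation, and records whose window extends past the alignment are flagged
and excluded. Carriage by arm is tested with Fisher's exact test.

The Kullback–Leibler logo weight of residue $a$ at position $i$ is
$p\,\log_2(p/q_a)$ with $p = (n_a + \kappa q_a)/(n + \kappa)$, background
$q$ (uniform over the 20 canonical residues by default) and pseudocount
$\kappa = 1$ distributed by background — the smallest smoothing that avoids
$\log 0$; the sign puts depleted residues below the axis. When observed
frequencies equal the background exactly, the pseudocount leaves them
unchanged and the logo is exactly zero (tested).

### Clone sizes

Per-clone $\log_{10}$ sizes are compared across arms by Mann–Whitney.
`min_size` (default 1) restricts the comparison; with deeply sampled naive
repertoires the all-clone comparison is dominated by singletons present
equally in both arms, so the acceptance script compares multi-member
clonotypes (`min_size = 2`).

## 3. Exact statistics

Exact p-values are computed by dynamic programming over doubled midranks
(doubling makes tied midranks integral), which enumerates the same null
space as brute force — all $\binom{n+m}{n}$ rank assignments for
Mann–Whitney, all $2^n$ sign patterns for the signed rank — in polynomial
time. Two-tailed p is twice the smaller tail, capped at 1. Defaults switch
to tie-corrected, continuity-corrected normal approximations above
`exact_limit = 12` (configurable); the report records which method produced
each p, since group sizes of 5–16 straddle the exact/approximate regimes.
Fisher's two-tailed p uses the point-probability method (sum of all
fixed-margin tables no more probable than the observed one) — stated
explicitly because two-tailed Fisher has competing definitions. Dunn's post
hoc adjustment defaults to BH (Holm available). Degenerate inputs are
reported, not hidden: all-zero differences give p = 1 with a note, a
zero-variance nonzero difference vector gives `p = NA` with a note, a
zero-margin table gives p = 1 with a note.

The test suite verifies every exact routine against independent
enumeration oracles (200 random instances each) and checks type-I
calibration under null simulation (2,000 replicates per test; 15 per group
for the rank tests, 100 per margin for Fisher, where the exact test's
discreteness is mild).

## 4. The synthetic-data generator

### What it emulates

`simulate_expression()` draws negative-binomial counts (fixed dispersion
0.5 — the simplest overdispersed single-cell model that makes binned-control
scoring behave realistically) with lognormal per-gene base abundances and
per-cell library sizes (mean 2,500 counts, sdlog 0.3). Five cell types
(plasma 30%, B 25%, T/NK 20%, granulocyte 15%, other 10%) are allocated
deterministically by largest remainder, so type counts match proportions
within rounding. Marker genes are pinned at 10× the median gene abundance
in their own type and 0.2% of median off-type: marker-based gates are
near-pure in practice, and at higher leakage the classifier's measured
precision reflects gate contamination rather than the classifier. Planted
malignant plasma cells receive `+signature_effect` (log scale, default 2,
i.e. ×e²) on the malignant signature genes; nonmalignant plasma cells the
same on the nonmalignant set. Treated samples carry the untreated malignant
fraction (0.30) divided by `depletion_factor`.

`simulate_repertoire()` builds, per sample, a naive compartment (uniform
V/J over the packaged synthetic germline set, IgM-dominant isotypes, CDR3
lengths ~N(11, 1.5) clipped to 7–16, per-site SHM 5×10⁻⁴) and an expanded
compartment (default 10% of sequences over 6 clones with power-law sizes)
whose members share (V, J, ancestor CDR3), differ from the ancestor by at
most one CDR3 substitution (so members stay within the 80% identity rule
for typical CDR3 lengths), carry class-switched isotypes and per-site SHM
0.04 (~4% mutation frequency over the 98-residue V region). Clone 1 of
every sample is the canonical VH1-72 clone; its members carry W33L in 56%
(untreated) or 10% (treated) of cases — the treated fraction is a planted
parameter because size depletion alone cannot change member composition.
Treated samples are derived by `apply_treatment()`: each expanded clone
keeps `round(size/d)` members (half-up, floor 0; deterministic and
conservative), the naive compartment is untouched.

Parameter choices worth stating:

* **Naive SHM 5×10⁻⁴ per site** (~0.05 mutations per sequence): naive
  marrow B cells are essentially unmutated; this residual rate represents
  sequencing noise. At rates a few-fold higher, the binomial tail of naive
  singletons crossing the 2% threshold dominates the treated arm's
  mutated-clonotype frequency and the planted fold is not recoverable —
  i.e. the generator would not be emulating the population it claims to.
* **Expanded fraction 0.10**: with the sequence-weighted recovery statistic
  scaling as $d(1-f)+f$, a 10% clonal compartment makes a planted sixfold
  depletion measurable as ≈5.5-fold and a tenfold VH1-72 depletion as
  ≈9-fold, matching the magnitudes the method is meant to detect.
* **The canonical V segment is excluded from the naive draw**: VH1-72 usage
  is then a clean readout of the antigen-selected clone. A large naive
  background usage would dilute any clonal fold change toward 1; the
  magnitude of observed usage folds in this setting implies background
  usage is negligible.
* The germline set (10 V, 4 J amino-acid segments, packaged as
  `germline_*_synthetic.fasta`) is synthetic, written for this package; it
  is not a curated germline database. Simulation operates at the amino-acid
  level — mutation counting is alphabet-agnostic, so all arithmetic holds,
  but nucleotide-level phenomena (codon structure, transition bias,
  indels) are not represented.

### What it does not emulate

No transcriptome-wide co-expression structure, no batch effects or
integration artifacts, no doublets, no light chains, no indel SHM, no
selection on CDR3 content beyond the planted clone structure, and naive
CDR3 length diversity deeper than typical single-cell V(D)J experiments
(which is why untreated modal CDR3 length in simulations reflects the naive
mode rather than clonal skew). Passing recovery tests therefore show the
pipeline's statistical machinery is correct and sensitive at realistic
effect sizes — not that real data meet the generator's assumptions.

## 5. Problem sizes used by tests and the acceptance script

Chosen as desk-scale reference conditions: classifier recovery uses 1,667
cells/sample (500 plasma cells) × 400 genes, one sample per arm, effects
{0, 1, 2, 3} × 10 seeds; repertoire recovery uses the full default cohort
(6 treated + 5 untreated samples × 1,200 sequences) × 10 seeds per
depletion scenario; calibration uses 2,000 null replicates per test; the
acceptance script runs the full 11-sample expression cohort once and the
two repertoire scenarios once each, with every random stream derived from
`--seed`.

## 6. Known limitations

* The CDR1-window approach to W33L requires the annotation to be correct
  for the germline in use; gapped alignments shift coordinates and such
  records are excluded rather than re-numbered.
* Clone-level mutation frequency averages distinct variants without
  phylogenetic weighting.
* The exact Mann–Whitney switches to a normal approximation above 12 total
  observations; for 13–30 observations with heavy ties the approximation
  (though tie-corrected) is less accurate than a larger enumeration
  threshold would be — `exact_limit` is exposed for users who want it.
* `differential_expression()` is a two-group screen, not a replacement for
  count-model DE frameworks; it matches the pipeline convention of
  rank-sum + BH on normalized values.
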