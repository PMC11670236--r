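# clonesurveil

Single-cell analysis of clone-directed immune surveillance in plasma-cell
malignancy. The package addresses a question that arises when a therapy is
expected to clear malignant plasma cells while sparing their healthy
neighbours: given single-cell expression profiles and paired heavy-chain
B-cell receptor (BCR) repertoires from treated and untreated bone marrow, did
treatment selectively deplete the malignant, clonally expanded, highly
mutated compartment?

It is written for immunologists and computational biologists working with
10x-style single-cell RNA + V(D)J data from mouse models of monoclonal
gammopathy / multiple myeloma (and comparable systems), and it is fully
exercisable without access to such data through a built-in synthetic-data
generator that plants known effects.

## What it computes

**Malignancy classification.** Plasma cells are gated by marker expression
(*Sdc1*, *Xbp1* or *Prdm1* positive; *Cd19* negative). Each cell receives two
gene-set module scores — for a malignancy signature and a nonmalignancy
signature — computed as

```
score(cell) = mean expr(set genes) − mean expr(expression-matched control genes)
```

with control genes drawn from expression-decile bins, so the score is
insensitive to per-cell depth. A cell is called **malignant** when its
malignant score lies in the top 20% and its nonmalignant score in the bottom
20% of the gated population (and **nonmalignant** under the mirror-image
rule). The per-cell **compound score** `M − N` summarises the malignancy
axis; its treated-vs-untreated shift is tested with a two-tailed
Mann–Whitney test.

**Repertoire surveillance.** Heavy-chain rearrangements (AIRR TSV) are
clonotyped by identical V gene, identical J gene, and CDR3 amino-acid
identity ≥ 80% (single linkage, Hamming identity on equal-length CDR3s).
Per clone the package reports size, isotype spectrum and somatic
hypermutation (SHM) burden — percent divergence of the aligned V region from
germline — and derives the frequency of highly mutated clonotypes
(> 2% SHM, clones larger than 10 cells), isotype and V-family usage, CDR3
length distributions with trapezoidal AUC, V–J pairing matrices, per-clone
log10 sizes, usage of the canonical NP-response gene VH1-72 and its
affinity-increasing W33L mutation (CDR1 window position 8), and
Kullback–Leibler sequence logos (`weight = p·log2(p/q)`, signed so depleted
residues fall below the axis).

**Exact small-sample statistics.** Two-tailed Mann–Whitney (exact by
enumeration for `n+m ≤ 12`, tie-aware), Wilcoxon matched-pairs signed rank
(exact sign-pattern enumeration), Fisher's exact (point-probability method),
paired and ratio-paired t, Kruskal–Wallis with Dunn follow-up, and
Benjamini–Hochberg FDR — each validated in the test suite against
independent brute-force enumeration oracles.

**Synthetic data.** `sim_config()` + `simulate_expression()` /
`simulate_repertoire()` generate a bone-marrow cell mixture with planted
malignant plasma cells (negative-binomial counts, signature effects on two
gene sets) and a paired repertoire mixing diverse unmutated IgM cells with
expanded, class-switched, mutated clones including a canonical VH1-72/W33L
clone; `apply_treatment()` depletes expanded clones by a configurable
factor. Every planted label is returned, so downstream recovery is testable.

## Worked example

Simulate a cohort in which treatment depletes expanded clones tenfold, then
track the canonical clone:

```r
library(clonesurveil)
library(dplyr)

cfg  <- sim_config(depletion_factor = 10, seed = 42)
rep  <- simulate_repertoire(cfg)
rearr <- assign_clonotypes(add_mutation_stats(rep$rearrangements))

vh <- vh1_72_analysis(rearr)
vh$usage |> group_by(group) |> summarise(mean_usage = mean(usage))
#> # A tibble: 2 × 2
#>   group     mean_usage
#>   <chr>          <dbl>
#> 1 treated      0.00457
#> 2 untreated    0.0408
vh$w33l
#> # A tibble: 2 × 6
#>   group         n   n_W   n_L n_other w33l_fraction
#>   <chr>     <int> <int> <int>   <int>         <dbl>
#> 1 treated      30    25     5       0         0.167
#> 2 untreated   245   104   141       0         0.576
vh$test
#> <fisher_exact> statistic = 0.147518, two-tailed p = 2.35971e-05 (exact; n = 275)
```

VH1-72 usage drops 8.9-fold in the treated arm (0.0408 → 0.00457), and W33L
carriage among surviving VH1-72 sequences falls from 58% to 17%
(Fisher's exact p = 2.4e-05) — the planted clone-specific depletion is
recovered. The frequency of sequences in highly mutated clonotypes drops
from 0.101 to 0.0128 in the same run:

```r
mutated_clonotype_frequency(rearr) |>
  group_by(group) |> summarise(freq = mean(prop_mutated_seqs))
#> 1 treated   0.0128
#> 2 untreated 0.101
```

The exact tests are available directly:

```r
mann_whitney(c(1.1, 2.0, 3.2, 4.1), c(5.3, 6.0, 7.4, 8.8))
#> <mann_whitney> statistic = 0, two-tailed p = 0.0285714 (exact; n = 4, 4)
```

`run_pipeline(cfg, out_dir = "out")` executes every stage
(simulate → QC → normalize → gate → score → classify → repertoire →
statistics) and writes the full CSV/JSON bundle; a thin command-line wrapper
with per-stage subcommands is installed at `inst/cli/clonal-surveil.R`.

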