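---
title: "Codon usage, tRNA pools and translational efficiency: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage, tRNA pools and translational efficiency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonflux)
```

# The question

Synonymous codons are decoded at rates that depend on the abundance of
their cognate (and wobble-pairing) tRNAs. If mammalian cells tuned codon
usage to cell-state-specific tRNA pools, the codon composition of a cell
type's transcriptome should agree better with its *own* anticodon pool
than with the pool of a different cell state. codonflux implements the
statistical machinery for testing this hypothesis: a resampling null for
how much gene-set codon usage can diverge from the exonic background by
sampling alone; expression-weighted translational-efficiency statistics
contrasted between matching and mismatching mRNA/tRNA condition pairs; and
a PCA decomposition showing how much of the between-gene-set codon-usage
structure is carried by GC content.

# Sequence layer

A gene's **canonical CDS** is its longest annotated coding sequence that
starts with `ATG`, ends with a stop (`TAA`/`TAG`/`TGA`) and has length
divisible by 3 (`is_valid_cds()`, `canonical_cds()`). Equal-length valid
candidates tie-break to the first in annotation order, which keeps the
choice deterministic. Codon usage is the count vector over the 61 sense
codons, in fixed lexicographic order so vectors align across modules; the
terminal stop is excluded and the initiator `ATG` is counted as an
ordinary codon (only the terminal stop can legally occur in a valid CDS,
so no other special-casing is needed). Sequences are uppercased and `U` is
read as `T`; any other character is an error rather than a silent `FALSE`,
so corrupt annotation fails loudly. During bulk canonical-CDS selection,
candidates containing ambiguity codes are treated as invalid candidates
instead, since reference annotation routinely contains a few `N`s.

Anticodons are written 5'→3' in the DNA alphabet as the reverse complement
of the codon (`AAA` ↔ `TTT`); the first letter of an anticodon is its
wobble (position 34) base. This single convention is used end to end.

# Expression layer

Size factors are Anders–Huber median-of-ratios (`estimate_size_factors()`),
estimated separately for mRNA and tRNA libraries since they come from
different assays. Expression filters follow the asymmetry of the two
assays: an mRNA gene is expressed if any replicate has a nonzero raw
count, while a tRNA gene (Pol III ChIP being noisier) needs a normalized
count of at least 10 — inclusive — in *every* replicate of at least one
condition. Both filters restrict to nuclear autosomes.

Top upregulated genes of a contrast are selected by discarding the lower
three quartiles of base-mean expression (linear-interpolation percentile;
the boundary gene is kept), requiring a positive log2 fold change with the
condition of interest as numerator, and taking the `n = 200` smallest raw
p-values; ties break by descending base mean, then gene id. Raw rather
than adjusted p is the default because BH adjustment is monotone within a
table and cannot change the selected set, only its labels.

# The resampling null

For each gene-set size of interest, `sample_null()` draws sets uniformly
without replacement from the eligible (non-mitochondrial) genes, sums
member codon counts and Spearman-correlates each set's usage with the
aggregate usage of all canonical CDSs. A term's empirical p-value is the
fraction of size-matched random sets whose correlation is *strictly*
smaller than the term's; Benjamini–Hochberg across terms gives the
divergence calls at FDR 0.05. Two numerical choices matter:

* The plain fraction can be exactly zero, and an exact zero survives any
  FDR adjustment. With $n$ null draws a random term lands below all of
  them with probability $1/(n+1)$, so screening hundreds of random terms
  at a few thousand draws each produces spurious "divergent" calls at a
  predictable rate. For calibration work we therefore use the
  $(r+1)/(n+1)$ estimator (Phipson & Smyth 2010), available via
  `add_one = TRUE`; the plain fraction remains the default because it is
  the quantity the divergence analysis is defined with.
* Each set size uses its own RNG substream derived from the master seed,
  so extending the size grid never perturbs existing draws.

Term sizes not present in the null are an error by default;
`nearest_size = TRUE` maps them to the closest sampled size for
exploratory runs.

# Translational efficiency

For a gene set $GS$ and one mRNA sample, the expression-weighted codon
usage is
$$CU_c = \sum_{g \in GS} CU_{cg} \cdot x_g / l_g,$$
with $x_g$ the size-factor-normalized count of gene $g$ in that sample and
$l_g$ its CDS length in sense codons (the same unit as the counts; any
other length unit would cancel in rank statistics but not in tAI
weighting, so the convention is fixed). Anticodon pools sum normalized
isoacceptor tRNA expression per anticodon.

Three statistics are implemented:

* **strict** — Spearman correlation between $CU$ and the pool after pairing
  each codon with its Watson–Crick anticodon; codons whose anticodon is
  absent from the pool are excluded. Rank correlation makes explicit
  normalisation of either pool unnecessary.
* **wobble** — as strict, but codons without a cognate anticodon are
  paired with their unique wobble anticodon: codon third base `T`→wobble
  base `G` (G:U pairing), `G`→`T` (U:G), `C`→`A` and `A`→`A` (inosine,
  written as its genomic `A`). The table ships as editable YAML
  (`wobble_rules()`).
* **tai** — an expression-based tRNA adaptation index. Per codon,
  $W_i = (1-s_{wc}) A_{wc(i)} + (1-s_{wob}) A_{wob(i)}$, with abundances
  from the pool rather than gene copy numbers; $w_i = W_i / \max W$, zero
  weights replaced by the geometric mean of the nonzero ones; per-gene tAI
  is the geometric mean of $w$ over the gene's codons and the set value is
  the expression-weighted mean of gene tAIs. The s-values default to the
  dos Reis et al. (2004) *initial* vector (`tai_s_values()`), because the
  optimised vector is fitted under the assumption that highly expressed
  genes have optimal codon usage — the hypothesis under test. The
  two-class rule is applied uniformly to all codons, with no
  methionine/tryptophan special cases: this keeps the closed-form
  behaviour (uniform pool and $s = 0$ give $w_i \equiv 1$ and tAI = 1)
  exact, at the cost of a small systematic difference from gene-copy-number
  tAI implementations for `ATG` and `TGG`. The initiator `ATG` is included
  by default (`exclude_start = TRUE` to drop it).

The **ramp** variant recomputes $CU$ from only the first $N$ codons of
each CDS (default 10, `ramp_codon_usage()`), with $l_g = N$; $N$ may not
exceed the shortest transcript in the set.

# Match/mismatch contrasts

`study_design()` records replicate lists per condition and an explicit,
symmetric "dissimilar" relation (e.g. healthy tissue vs each cancer line,
but not the cancer lines against each other). Match pairings cross mRNA
and tRNA replicates within a condition; mismatch pairings cross mRNA
replicates of one condition with tRNA replicates of each dissimilar
condition, in both directions. The one-tailed Mann–Whitney–Wilcoxon test
(`compare_match_mismatch()`) asks whether match TE values are
stochastically larger than mismatch values; the exact U distribution is
used when the smaller group has at most 8 values and there are no ties,
otherwise the tie-corrected normal approximation with continuity
correction. P-values are Bonferroni-multiplied over the declared family
(the number of gene-set menu entries × variants tested in the run; the
family size is reported in every result row), with significance codes
`***`/`**`/`*` at 0.001/0.01/0.05.

A caveat the synthetic experiments make explicit: TE values over all
replicate pairings are not independent — they cluster by
(mRNA condition, tRNA condition) — so the MWW test is calibrated only
when condition-level differences are absent or small relative to replicate
noise. This pseudo-replication is inherent to the all-pairings design, not
to this implementation.

# Per-term PCA and GC

`go_codon_matrix()` aggregates codon counts per catalog term;
`pca_codon_usage()` runs mean-centred, unscaled PCA on the row-normalized
frequency matrix. Frequencies are the default because term sizes span
orders of magnitude and a count-mode PC1 would be a term-size axis;
count mode stays available behind a flag. The 61 columns are commensurate
frequencies, so no column standardisation is applied. PCA sign is
arbitrary; when per-term GC is supplied, PC1 is oriented to correlate
positively with GC so outputs are deterministic (the flip is reported).
`pc1_gc_correlation()` is Spearman with average ranks and errors on
degenerate (constant-GC) input. `enriched_te_test()` compares mean
matching-condition TE of enriched vs non-enriched terms with the same
one-tailed MWW machinery.

# The synthetic-data generator

`synthetic_config()` + `generate_genome()` + `generate_expression()`
emulate the *structure* of a two-assay (RNA-seq + Pol III ChIP) liver
study entirely in code:

* **Genome** — genes with lognormal lengths (default median 350 sense
  codons, minimum 30) and per-gene target GC uniform on [0.30, 0.70].
  Codons are drawn from a GC-parameterised sense-codon distribution whose
  nucleotide parameter is root-solved so the *realized* GC matches the
  target despite the exclusion of (AT-rich) stop codons. Every emitted
  CDS is valid by construction. One percent of genes sit on `X` and half
  a percent on `MT` to exercise the autosome filters.
* **Catalog** — 100 terms of 40–200 genes; with a GC gradient configured
  (default 0.35→0.65), each term samples genes with weights centred on
  its GC target (sd 0.03), producing term-level GC that tracks the
  gradient to well within ±0.02 at realistic term sizes.
* **Expression** — three conditions (quiescent reference plus two
  proliferating lines, dissimilar only to the reference), four replicates
  per assay; the upper end of the emulated study's 2–4 replicates, chosen
  a priori because a 2-replicate design gives the exact one-sided U test
  too little resolution (the minimal achievable p with 2×2 pairings per
  side is 0.05·something too coarse for calibration work). Counts are
  negative binomial: mRNA dispersion 0.05 and tRNA dispersion 0.10,
  chosen so synthetic replicate correlations resemble bulk RNA-seq and
  ChIP replicate QC; 40% of genes are differentially expressed per
  cancer condition with |log2FC| ~ N(1, 0.5) and random sign. A
  per-condition `de_gc_bias` coefficient can couple expression changes to
  gene GC (cell-state-specific transcriptomes differing along the GC
  axis); it is zero by default.
* **Enrichment** — per cancer condition, 10 terms get a coordinated +1
  log2FC boost to member genes; these are the ground-truth enriched
  terms.
* **DE tables** — a per-gene Welch t-test on log2 normalized counts, BH
  adjusted. This is a deliberately simple stand-in that orders genes well
  enough for top-gene selection; it is not a count-model DE analysis. (A
  rank test was considered and rejected: with four replicates its p-values
  take ~70 distinct values, too granular to pick 200 genes from
  thousands.)
* **tRNA pools** — 120 tRNA genes over a 45-anticodon repertoire (all
  anticodons except the genomically A-starting ones, the classic
  inosine-related absences; the repertoire size matches mammalian pools).
  Anticodon abundances follow a geometric profile spanning 150-fold. One
  codon-usage-unrelated pool *ordering* is drawn per dataset and shared
  by every condition — tRNA pools are stable across cell states — and the
  per-condition adaptation knob α blends anticodon ranks from that shared
  ordering (α = 0) toward rank-identity with the condition's own
  expression-weighted codon usage (α = 1); abundance magnitudes are then
  assigned by the blended order. Replicate counts are negative binomial
  around the per-gene shares of each anticodon's abundance.

## What the generator does and does not emulate

It reproduces: valid coding sequences with controllable GC structure,
term catalogs with a GC gradient, overdispersed two-condition-family
counts with ground-truth DE and enrichment, realistic anticodon
repertoires and pool spreads, and a tunable, seeded degree of
codon–anticodon adaptation. It does not model: read-level artifacts
(mapping, multi-mapping reallocation), tRNA charging or base
modifications, post-transcriptional mRNA stability, amino-acid-level
constraints on codon composition, or GO-graph structure (terms are flat,
possibly overlapping sets). Passing tests therefore validate the
*statistical machinery* under the stated generative assumptions, not
biological conclusions about real tissues.

## Adaptation regimes and what the tests check

* α = 1 everywhere: matching-condition strict TE approaches 1 (observed
  ≥ 0.95 at default depth; residual loss comes from count noise on both
  assays).
* α = 0 everywhere: no true adaptation; TE is centred at zero and the
  match/mismatch test holds its size. This is the regime for type-I
  calibration — at *equal α > 0* every condition's pool genuinely
  self-adapts, the match advantage is real, and the test correctly
  rejects.
* α = 1 for one condition only: detectable only when codon usage is
  condition-specific; with GC-neutral expression a pool adapted to one
  transcriptome is equally adapted to all of them and the U statistic is
  structurally centred on its null value. The power scenario therefore
  tilts expression along GC with opposite signs (`de_gc_bias` ±2), the
  regime in which adaptation is genuinely cell-state-specific.

# Problem sizes and numerical choices

Simulation-based checks use: 500-gene genomes for per-run TE studies (200
calibration runs, 100 power runs), a 5000-gene genome with 200 random
terms and 2000 null draws per size in {40, 100, 400, 1600} (20 seeded
runs) for null calibration, a 20000-gene genome for DE-recovery precision
(the top-200 selection is proportioned to a ~20k-gene transcriptome, so
recovery is tested at that scale), and 100 GC-gradient terms over 2000
genes for the PCA/GC check. Degenerate inputs (constant GC, empty pools,
fewer than 3 codon–anticodon pairs, all-zero decoding weights, disjoint
gene universes) raise errors with actionable messages rather than
propagating NaN.

# Limitations

The TE statistics treat the anticodon pool as a proxy for decoding
capacity; Pol III occupancy does not see charging or modification state.
The MWW contrast inherits the pseudo-replication caveat above. The tAI
variant's uniform two-class wobble rule is a simplification at `ATG` and
`TGG`. The generator's GC knob moves codon usage only through composition,
not through amino-acid usage shifts, which real proteomes also exhibit.
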