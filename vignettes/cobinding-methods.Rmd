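---
title: "Quantifying transcription-factor co-occupancy with cobindseq"
author: "cobindseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-factor co-occupancy with cobindseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobindseq)
```

## The problem

Lineage-defining transcription factors rarely act alone. In tissues such
as the thyroid, several factors (a GLIS-family factor together with
NKX-, PAX-, and FOX-family partners) occupy overlapping sets of
regulatory regions near the genes they co-regulate. Given one ChIP-seq
fragment library per factor plus an input (chromatin background)
library, the analytical question is: which genomic regions are bound by
which combination of factors, which genes do those regions point at, and
how does the combination relate to expression changes across
experimental contrasts?

`cobindseq` implements this analysis as a reusable pipeline. The unit of
inference is the **collapsed region** — a merged interval formed from
pooled per-factor peaks — and the central statistic is a per-factor,
per-region **random-overlap positivity test**. Everything downstream
(co-binding signatures, gene tables, expression cross-tabulations) is
bookkeeping on top of those calls.

Coordinates are 0-based half-open everywhere the user sees them (BED
convention); `GRanges` objects carry the usual 1-based representation
internally, with conversion confined to the I/O layer.

## The pipeline and its model

### 1. Fragment extension

Single-end reads are replaced by fixed-length intervals (default 150 bp)
anchored at the 5' end and extended in strand direction, approximating
the immunoprecipitated fragment. Unstranded reads are treated as `+` and
counted in a warning; fragments are clipped at chromosome bounds.

### 2. Simplified factor peak calling

`call_peaks_factor()` scores sliding windows (300 bp every 75 bp) by
comparing the ChIP fragment count against the library-size-scaled
control count. The expected count is floored at a pseudocount of 0.5
*and* at the genome-wide uniform window rate; without the global floor,
windows where the control happens to sample zero fragments would get an
absurdly small expected value and manufacture significance out of
sampling noise (the same reason established callers use a local/global
maximum background estimate). A window is significant when

* observed / expected >= `min_fold` (8 in the stringent profile, 4 in
  the permissive one), **and**
* the Poisson upper tail `P(X >= observed | expected)` survives
  Benjamini-Hochberg correction at `fdr` (1e-5 / 1e-3).

Overlapping significant windows are merged; each merged run is reported
as one window-width peak at its maximum-count window, leftmost on ties
(determinism). This caller is deliberately simple — it is not a
reimplementation of any published caller, and externally produced peak
BEDs can be supplied to bypass it entirely.

### 3. Resizing and collapsing

Peaks are re-sized to 300 bp centered on their midpoints
(`mid = floor((start + end) / 2)`), then pooled across factors and
merged whenever the gap between intervals is at most 50 bp
(`collapse_peaksets()`, the bedtools `merge -d 50` rule). The output is
sorted, disjoint, and idempotent under re-collapsing.

### 4. The positivity statistic

For each collapsed region and each factor library,
`score_region_positivity()` asks how improbable the observed overlapping
fragment count would be if the library were placed uniformly at random
on the genome. A fragment of length $f$ overlaps a fixed region of
length $L$ with probability

$$p = \min\!\left(1, \frac{L + f - 1}{G}\right),$$

where $G$ is the summed chromosome length (no mappability correction —
none is in scope). The null count over $N$ fragments is Binomial$(N,p)$,
evaluated as its Poisson approximation $\lambda = Np$; the reported
p-value is the upper tail $P(X \ge \text{count})$, computed through the
survival function (accurate far into the tail; the test suite pins it to
a direct pmf-summation oracle at relative error $<10^{-9}$). A region is
flagged **positive** for a factor when $p < 10^{-6}$, strictly — a
cutoff excludes its own value.

At study scale ($N = 10^6$, $G = 10^8$, $L = 300$) the null mean is
$\lambda \approx 4.5$, and the $10^{-6}$ cutoff corresponds to roughly
20 fragments; scoring 10,000 random regions yields essentially zero
false flags. Each factor is scored against its own library size, not a
pooled one.

### 5. Signatures, genes, contexts

The ordered vector of per-factor flags forms the **co-binding
signature** (e.g. `G+N+P-`). Region signatures are tabulated directly;
gene-level signatures come from `assign_regions_to_genes()`: a region is
linked to a gene when the region midpoint lies within 5 kb of the TSS
(inclusive at both ends, strand-agnostic), and a gene's factor flag is
positive when *any* linked region is positive for that factor (union
semantics — per-region co-occurrence remains visible in the region
table). The midpoint rule mirrors the resize convention; the union rule
matches the question "which genes have binding of factor X nearby",
not "which genes have one region bound by everything".

Genomic context classifies each peak midpoint with precedence
TSS-proximal (1 kb upstream of the TSS) > Upstream (5-1 kb upstream) >
Genebody (TSS..TES) > Intergenic, strand-aware; precedence among the
first three is a documented, configurable choice ranked by
promoter-centrality. On the minus strand the windows mirror exactly, and
the test suite checks invariance under genome reflection.

### 6. Expression integration

`filter_de_genes()` thresholds a differential-expression table at a
minimum 1.5-fold change (inclusive; signed linear folds, log2 accepted
via a flag) and FDR < 0.05 (strict). `crosstab_binding_expression()`
partitions the genes of one signature into up / down / not-significant
per contrast, and `build_gene_binding_report()` renders the per-gene
table (fold change and FDR per contrast, `NS` where not significant,
then one `+`/`-` column per factor). Over-representation of gene lists
against GMT collections uses the upper-tail hypergeometric test with BH
correction across sets.

### 7. Histone signal

Broad marks use the same window scorer with minimum fold 2 (a
permissive broad-mark default; the stringent factor fold is
inappropriate for domains) and window/merge geometries of 500/1000 bp
(H3K4me3-like) or 1000/2500 bp (H3K27me3-like); per-sample region sets
are unified by plain interval union. Promoter signal is quantified as
the fragment count over TSS +/- 1 kb flanks, normalized by the summed
flank count over **all** annotated genes and scaled per million — the
scale constant is arbitrary (it cancels between samples) but chosen for
readable magnitudes. Group summaries are Tukey box statistics: type-7
quantiles (linear interpolation between closest ranks — stated because
quartile conventions differ), whiskers at the most extreme values within
1.5 IQR.

### 8. Motif co-occurrence

`scan_pwm()` scores both strands with summed log2 odds against a
background model (default uniform; default threshold 80% of the maximal
score); windows containing N are skipped as hard misses (conservative).
`motif_enrichment_near_anchors()` compares hit-containing anchors
against a background region set with the hypergeometric upper tail
(window of 100 bp around midpoints — configurable; "near" has no
canonical distance), and `spacing_profile()` histograms signed
hit-to-anchor distances. De novo motif discovery is out of scope;
scanning works with user-supplied PWMs (JASPAR-style text).

## The synthetic-data generator

`simulate_cobinding_study()` makes every stage testable offline with
known truth. Its defaults define the study conditions used by the test
suite and the acceptance script:

* genome: 2 chromosomes of 50 Mb (G = 1e8 bp);
* 2,000 genes on alternating strands, inter-TSS spacing at least
  2 x (site offset + 5 kb) = 18 kb so every planted site and TSS window
  is unambiguous; gene lengths uniform 5-20 kb;
* each gene draws a signature label from configured proportions
  (defaults: 25% triple-positive, 5% + 2% + 2% partial combinations
  with the first factor, 30% bound by others only, remainder unbound) —
  chosen to resemble a study in which most first-factor binding is
  shared with both partners;
* one 300 bp site per bound gene, centered uniformly within TSS
  +/- 4 kb (single site for crisp truth; multi-site genes exist in real
  data and are a config extension);
* per factor, 1e6 fragments: a calibrated fraction arises from that
  factor's occupied sites so that the site-window fragment rate exceeds
  background by `enrichment_fold` (default 20; 1 yields an exact null
  library), with 5' positions Normal(site edge, sd 40 bp) on either
  strand — sub-peak-width jitter, not a fit to any dataset; the input
  library is purely uniform;
* expression contrasts affect configured fractions of configured
  categories (defaults: an induction contrast up-regulating 10% of
  triple-positive genes, a knockout contrast down-regulating 7.7% and
  up-regulating 4.4% of them, echoing the relative magnitudes seen in
  thyroid induction/knockout designs); affected folds are log-uniform
  2-20 with FDR below 0.01, so every affected gene passes the 1.5/0.05
  filter by construction and recovery is a pure bookkeeping check;
* component seeds (annotation, sites, per-factor fragments, expression)
  are derived from the master seed by fixed offsets, so changing one
  stage's parameters does not perturb the others, and every artifact is
  byte-identical for a fixed seed.

What the generator does **not** emulate: sequencing error, duplicate
reads, mappability and GC bias, replicate variance, multi-site genes,
correlated factor occupancy beyond the planted labels. Passing the
recovery benchmark therefore demonstrates that the pipeline's logic and
statistics are correct under its stated model — not that any particular
biological dataset would yield the same numbers.

## Numerical and design notes

* Poisson and hypergeometric tails go through R's survival functions;
  the tests pin them to pmf-summation oracles.
* Merging semantics: `-d` gap merging is strict at the boundary (gap of
  exactly 50 merges, 51 does not); interval union merges book-ended
  intervals; the histone merge distance is strict (`gap < min_dist`).
* Peak summit ties break to the leftmost window; region and gene tables
  have deterministic row orders; chromosome order is normalized
  (natural sort) regardless of input order.
* Degenerate inputs: empty peak sets collapse to empty region sets and
  flow through scoring, assignment, and integration without error —
  the null benchmark exercises exactly this path.
* The pipeline writes provenance headers (package version, hash of the
  analysis parameters, timestamp); reruns on identical inputs are
  byte-identical apart from the timestamp line.
* Configuration is by R constructor (`simulation_config()`,
  `run_config()`) with fail-fast validation, rather than a bespoke
  config-file format; the `inst/exec/cobind` script exposes the same
  parameters as flags for shell use.

## Problem sizes used in the checks

The recovery benchmark runs at the generator's default scale (2,000
genes, three 1e6-fragment libraries on a 1e8 bp genome) — the same
conditions the acceptance script reports on — and completes in well
under a minute on a single core. Unit and property tests use smaller
genomes (0.5-2 Mb, 1e4-2e4 fragments) where the property under test
does not depend on scale.

## Known limitations

* The positivity null is exchangeable-uniform; regions in high-signal
  background neighborhoods are not penalized (a local-background lambda
  is a natural extension and the statistic is isolated behind one
  function).
* One TSS per gene: isoform choice must be resolved upstream.
* The simplified caller has no fragment-length estimation, no
  strand-shift model, and no duplicate handling; it exists so the
  pipeline is runnable end-to-end from raw fragments, not to compete
  with dedicated callers.
* Gene assignment ignores distal enhancers by construction (the 5 kb
  window is the analysis definition, not a claim about enhancer
  biology).
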