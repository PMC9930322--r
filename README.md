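# cobindseq

Multi-factor ChIP-seq co-occupancy analysis in R.

## What it does, and for whom

When several transcription factors regulate a tissue together (for
example a GLIS-family factor alongside NKX, PAX, and FOX partners in
the thyroid), the binding sites measured by ChIP-seq for each factor
overlap extensively. `cobindseq` is for analysts who have one ChIP
fragment library per factor plus an input (background) library and want
to answer, with calibrated statistics:

* which genomic regions are bound by which **combination** of factors;
* which genes those regions point at, and with what co-binding
  **signature** (e.g. `G+N+P-`);
* how the signatures intersect differential-expression results across
  experimental contrasts;
* how promoter histone-mark signal and known binding motifs distribute
  around those regions.

## The model at the core

Per-factor peaks (called by a simplified fold + Poisson + FDR
sliding-window caller, or supplied as BED) are re-sized to 300 bp around
their midpoints, pooled, and merged across factors whenever gaps are
at most 50 bp, giving **collapsed regions**. Each region *r* is then
scored against every factor library under a uniform-placement null: a
fragment of length *f* overlaps a region of length *L* with probability

    p = min(1, (L + f - 1) / G),      G = total genome length,

so the null overlap count for a library of *N* fragments is
Binomial(N, p), evaluated as Poisson(lambda = N p). The region is flagged
positive for that factor when the upper-tail probability
P(X >= observed) falls below 1e-6. The ordered flags form the region's
co-binding signature; genes inherit signatures from regions whose
midpoints lie within 5 kb of the TSS (union semantics over regions).
Expression tables are thresholded at a minimum 1.5-fold change and
FDR < 0.05 and cross-tabulated against the signatures.

A fully seeded synthetic-data generator (`simulate_cobinding_study()`)
plants known co-binding signatures, fragment libraries at a controlled
enrichment fold, and expression effects, so the entire pipeline is
verifiable against ground truth without any external data.

## Worked example

Simulate a small three-factor study and run the pipeline end-to-end:

```r
library(cobindseq)

cfg <- simulation_config(seed = 1, n_chroms = 1, chrom_length_bp = 2e6,
                         n_genes = 80, site_offset_bp = 2000,
                         n_fragments_per_library = 4e4,
                         input_library_size = 4e4)
study <- simulate_cobinding_study(cfg)

rc <- run_config(chip = study$libraries, input = study$input,
                 annotation = study$annotation,
                 de_tables = lapply(study$de, `[[`, "table"),
                 outdir = "demo_run")
res <- run_cobinding_pipeline(rc)

signature_summary(res$regions)
```

```
  signature n_regions
1    G+N+P+        18
2    G-N+P-        10
3    G-N+P+         7
4    G-N-P+         3
5    G+N+P-         3
6    G+N-P-         2
7    G+N-P+         2
```

Eighteen collapsed regions are bound by all three factors; the rest
carry partial signatures. Gene-level signatures and per-factor totals:

```r
tab <- tabulate_gene_signatures(res$records)
tab$counts        # genes per signature (same shape as above)
tab$factor_totals
```

```
 G  N  P
25 38 30
```

25 genes have factor G binding within 5 kb of the TSS. Intersecting the
triple-positive genes with the simulated knockout contrast:

```r
res$crosstab$counts
```

```
   contrast up down NS
1 LID_vs_ND  2    0 16
2  KO_vs_WT  1    1 16
```

of the 18 triple-positive genes, two are induced in the first contrast
and one repressed in the second, matching the planted expression truth
for this seed. All outputs are also written to `demo_run/` as TSV/BED
with provenance headers.

The same percentages reported in multi-factor binding studies drop out
of the tabulation: with gene counts 4502 / 519 / 126 / 93 for
`G+N+P+` / `G+N+P-` / `G+N-P+` / `G+N-P-`,
`tabulate_gene_signatures()` reports the triple-positive share of
G-bound genes as 85.9%.

## Command line

A thin wrapper lives at `inst/exec/cobind`:

```sh
Rscript inst/exec/cobind simulate --seed 1 --outdir sim/
Rscript inst/exec/cobind run --chip G=sim/G.fragments.bed,N=sim/N.fragments.bed,P=sim/P.fragments.bed \
    --input sim/input.fragments.bed --annotation sim/annotation.refflat.tsv \
    --chrom-sizes sim/genome.chrom.sizes --de KO_vs_WT=sim/de.KO_vs_WT.tsv --outdir run/
Rscript inst/exec/cobind benchmark --seed 1 --outdir bench/
```

## Package layout

* `R/intervals.R` — BED/refFlat/GTF I/O, fragment extension, overlap
  counting (GenomicRanges-backed)
* `R/peaks.R` — window caller, peak resizing, region collapsing
* `R/signature.R` — positivity statistic, signature matrices, density
  matrices
* `R/integrate.R` — genomic context, TSS-window gene assignment,
  DE filtering/crosstabs, over-representation tests
* `R/histone.R` — broad-mark regions, TSS-flank signal, Tukey summaries
* `R/motif.R` — PWM parsing/scanning, co-occurrence enrichment
* `R/simulate.R` — the seeded generator with ground truth
* `R/pipeline.R` — orchestration and the recovery benchmark
* `vignettes/cobinding-methods.Rmd` — the model, its assumptions, and
  design notes
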