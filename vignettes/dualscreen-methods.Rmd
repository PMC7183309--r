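---
title: "Methods: integrating high-content and transcriptome siRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating high-content and transcriptome siRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## The analysis

`dualscreen` implements the computational core of a dual siRNA screening
design used to find functional interactions between chromatin regulators
during iPSC reprogramming. Two independent read-outs are collected per
knockdown: a high-content imaging phenotype (tens of colony-level
features per well) and a transcriptome response (RNA-seq against a
non-targeting control). The central idea is that two genes acting in the
same complex or pathway produce *correlated* knockdown read-outs in both
assays, while assay-specific noise rarely correlates twice. The pipeline
therefore:

1. normalizes the screen per plate (Z-scores within each
   plate × feature group), averages replicates into one phenotype
   profile per knockdown, and computes knockdown-to-knockdown Pearson
   correlations over the feature axis;
2. derives per-knockdown differential-expression (DE) gene sets and
   log2 fold-change (log2FC) profiles, and correlates knockdowns over
   the gene axis;
3. keeps a knockdown pair as a network edge only when **both**
   correlations exceed a threshold (default 0.4, strict `>`) — the
   dual-evidence filter;
4. characterizes the shared biology with gene-set overlap statistics
   (fold enrichment and hypergeometric tails), hierarchical clustering
   of log2FC profiles, max-normalized expression trajectories, and
   ChIP-seq peak/coverage integration (promoter assignment, RPM/RPKM
   signal, summit-centered matrices).

## Models and statistics

**Plate Z-scores.** Within each (plate, feature) group,
$z = (x - \bar x)/s$ with the sample SD ($n-1$ denominator; group sizes
in screens are small). Z-scoring uses all wells of a plate by default;
a controls-only mode is deliberately not the default because negative
controls are few per plate and their SD is unstable. Any per-feature
affine distortion of the raw measurements that is common to a plate is
absorbed by this step — which is exactly why profile correlations are
reproducible across plates. Replicates are averaged *after* Z-scoring.

**DE substitute.** `simple_de()` is a documented simple stand-in for a
count-model DE engine: per gene, a two-sided Welch t-test on log2-CPM
between groups, Benjamini–Hochberg adjustment across tested genes.
log2-CPM is fixed as
$\log_2\!\big((c + 0.5)/(L + 1) \times 10^6\big)$ (prior 0.5,
library size + 1); it does not replicate edgeR's prior scaling.
External DE tables (e.g. DESeq2 output) can be ingested via
`read_de_table()` with column mapping and used everywhere a DE table is
consumed. Two calibration notions are reported for this test: the
empirical FDR of the BH-adjusted calls at `padj < 0.05`, and power as
per-test sensitivity (raw `p < 0.05` on truly changed genes). With
n = 3 vs 3 the Welch degrees of freedom are ≈ 4, so individual
p-values cannot fall far below $10^{-3}$ regardless of effect size;
per-test sensitivity is the informative power measure at this design
size, while the BH calls are what the FDR is controlled on.

**Hypergeometric overlap.** For gene sets $A$, $B$ in an explicit
universe of size $N$, the expected overlap under independence is
$|A||B|/N$, fold enrichment is observed/expected, and significance is
the upper tail $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, |A|, |B|)$, *including* $k$ (the
standard over-representation convention). Tail terms are accumulated
as log binomial coefficients (`lgamma`) combined by log-sum-exp, so
`log10_p` stays finite far below double underflow (p ~ 1e-300 and
beyond). The universe is mandatory — the default builder is the set of
all genes tested for DE — because fold enrichment is meaningless
without it. Gene symbols are uppercased before every join; mouse
datasets mix `Ncor1`/`NCOR1` casing. Raw p-values are reported for a
handful of planned comparisons; a BH flag exists for larger batteries.

**Trajectories.** Per gene, the expression vector across timepoints is
divided by its maximum (each gene peaks at 1); the per-timepoint median
across the gene set is reported with a bootstrap percentile 95% CI from
resampling genes (default 1000 resamples, seeded). The CI is clamped to
contain the observed median, so the `ci_low ≤ median ≤ ci_high`
invariant holds even in degenerate resamples. Inputs must be positive —
log-ratio matrices should be exponentiated or shifted first; the error
message says so.

**Clustering.** `hierarchical_clusters()` is `hclust` + `cutree` with
euclidean or correlation (1 − r) distances and average, complete or
Ward (D2) linkage. Labels are renumbered by decreasing cluster size
with ties broken by first row index, so partitions are deterministic
and invariant to row permutation. The cluster count k is user-chosen
(k = 3 is a common choice made by inspecting a heatmap); there is no
automatic selection.

**Genomic integration.** In-memory containers are `GRanges` (1-based,
the R/Bioconductor convention); every file boundary (BED, bedGraph)
and the `gintervals()`/`as_bed_df()` helpers speak 0-based half-open
BED coordinates, and GFF is shifted on read. The promoter window is
−2000/+500 bp around the TSS, strand-aware and clipped at chromosome
bounds — an explicit configurable choice, since "promoter" has no
single accepted width. Peak-to-gene assignment offers an exact
case-normalized symbol join and an interval mode in which the peak
*summit* must fall inside a promoter window (a summit in two
overlapping windows maps to both genes; no arbitrary tie-break).
Coverage scores are read densities in reads per bp (depth divided by
read length when built from reads), so the raw signal of a region,
$\sum \text{score} \times \text{bp}$, is a read count; RPM scales by
$10^6/\text{total reads}$ and RPKM further by
$10^3/\text{region length}$. Summit matrices bin
[summit − flank, summit + flank) into an even number of equal bins
(default ±5 kb, 100 bins), zero-padding windows that run off a
chromosome end.

## The synthetic-data generators

Every pipeline stage is exercised end to end on generated inputs with
known ground truth; nothing needs to be downloaded. All generators are
pure functions of (parameters, seed): each call seeds a private RNG
stream and restores the caller's RNG state.

- **Screen** (`generate_screen`): a latent-factor model. Each planted
  module has one loading vector over features drawn N(0, 1); every
  member's expected value is `effect_size` × loading, plus i.i.d.
  Gaussian well noise (`noise_sd`) and an additive per-(plate, feature)
  offset with SD `plate_shift` — the removable batch effect the
  per-plate Z-score exists for. Replicate r sits on plate
  ((r − 1) mod n_plates) + 1, so each knockdown occupies one well per
  (plate, replicate); with 4 replicates on 2 plates, replicates
  necessarily share plates. The Gaussian latent-factor form is a
  modeling choice: high-content feature noise has no canonical
  published distribution, so passing tests show recovery under this
  model, not under arbitrary real-screen noise (outliers, spatial
  plate gradients, segmentation failures are not emulated).
- **Counts** (`generate_expression_study`): NB with
  Var = μ + αμ², mean = baseline × 2^log2FC × library-size scale;
  α = 0 degenerates to Poisson. `generate_knockdown_studies` wires a
  whole secondary screen: module members share one DE signature
  (identical true log2FCs on a common random gene subset, SD 1.5 over
  60 of 500 genes by default), everyone else gets an independent
  signature — so transcriptome correlations, like phenotype
  correlations, carry the module signal.
- **Time course** (`generate_time_course`): each named set follows a
  relative expected-level shape across timepoints; genes are split
  evenly among the sets (a remainder becomes flat background outside
  all sets); baselines are log-normal and noise multiplicative
  (log-normal, SD 0.2 on the log scale), keeping all values positive.
- **Genome** (`generate_genomic_tracks`): genes are placed in disjoint
  slots with a 2 × flank margin, so promoter windows of distinct genes
  never overlap and the `frac_targeted = 1`, no-background limit case
  recovers exactly the target genes. Coverage is built from simulated
  fixed-length reads — uniform background plus reads concentrated
  around each summit — via `coverage_from_reads`.

The defaults the recovery checks run at are the screen's design sizes:
30 knockdowns × 27 features × 4 replicates on 2 plates, one 3-member
module at effect 2 SD and noise SD 1; 500-gene expression studies at
dispersion 0.05, baseline mean 100, n = 3 vs 3; DE calibration at
2000 genes with 10% changed at |log2FC| = 2; 100-seed (tests) or
25-seed (acceptance script) replication.

## Numerical and policy choices

- Strict inequalities at both published cutoffs: network edges need
  r > 0.4 in *both* assays; DE sets use padj < 0.05 (a gene at exactly
  0.05 is excluded).
- Negative correlations never form edges by default (the filter looks
  for highest scores); an `use_abs` option exists.
- Degenerate inputs fail loudly: zero-variance (plate, feature) groups,
  zero-variance profiles or log2FC columns, and inconsistent
  hypergeometric counts are errors naming the offender — never silent
  NaN. Constant rows in `row_zscore` are excluded with a warning.
- A gene missing from one DE table when assembling a log2FC matrix is
  either filled with 0 (default, warned) or dropped, by policy.
- `de_summary` of an empty significant set reports the fraction and
  mean as absent (`NA`), not zero.
- Ties in hit ranking break lexicographically by knockdown name; edge
  lists are canonically ordered (a < b, sorted) so exports are
  deterministic.
- `run_pipeline` validates every configured path before any stage
  runs, writes every intermediate as TSV plus a JSON manifest with
  parameters, seed and input/output MD5 checksums, and leaves a
  `FAILED` marker naming the stage on error. Identical config + seed
  gives byte-identical outputs.

## Known limitations

- The Welch-on-log2-CPM DE substitute is deliberately simple: no
  dispersion shrinkage, no count model. At n = 3 it is conservative for
  genome-wide BH discovery (see the power discussion above); for real
  studies, ingest DESeq2/edgeR tables instead.
- The 27 imaging features are treated as exchangeable; real screens
  curate a feature panel, and feature selection is exposed as a
  configurable subset rather than inferred.
- The printed headline numbers of the motivating study (counts of
  deregulated genes, specific fold enrichments) depend on deposited
  datasets and an unstated gene universe; the package reproduces the
  *procedures* and validates them on synthetic ground truth rather
  than attempting to recompute those values.
- BAM/bigWig are out of scope; coverage comes from bedGraph or a BED
  of reads, and alignment/peak calling happen upstream.

## A compact worked example

```{r example, eval = FALSE}
dir <- tempfile()
cfg <- write_demo_inputs(dir, seed = 1)   # synthetic screen + DE + genome
res <- run_pipeline(cfg)
res$network$edges                          # the planted KD001-KD003 module
read.delim(file.path(dir, "out", "enrichment.tsv"))
```
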