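---
title: "Mitotyping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitotyping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotyper)
```

## The problem

Mitochondria are not interchangeable organelles: the mitochondria of liver,
brain, muscle and immune cells run different molecular programs, and the same
cell type shifts its program with age and metabolic challenge. `mitotyper`
quantifies these "mitotypes" from ordinary bulk expression data
(RNA-seq-derived nTPM, normalized counts, or proteomics intensities) by
scoring the 149 curated mitochondrial pathways of MitoCarta3.0 and then
asking, for each sample, which pathways it *prioritizes* relative to
everything else.

Two quantities are central:

1. **MitoPathway score** — the arithmetic mean expression of a pathway's
   member genes in a sample. Simple and interpretable, but confounded: a
   tissue with more mitochondria per cell ranks high in *every* pathway, and
   scores span several orders of magnitude between pathways (mtDNA-encoded
   transcripts alone guarantee that), so absolute scores can only be
   compared within a pathway, across samples.

2. **mitoPPS** (mitochondrial Pathway Prioritization Score) — the package's
   core computation. For sample $S_i$ and pathway $P_i$, with $n'$ pathways
   and $x'$ reference samples,

   $$\mathrm{mitoPPS}(S_i, P_i) \;=\; \frac{1}{n'-1} \sum_{P_n \neq P_i}
     \frac{\mathrm{Score}(S_i,P_i)\,/\,\mathrm{Score}(S_i,P_n)}
          {\tfrac{1}{x'} \sum_{S_x} \mathrm{Score}(S_x,P_i)\,/\,\mathrm{Score}(S_x,P_n)}.$$

   Every pathway is expressed relative to every other pathway *within* the
   sample, and each such ratio is normalized by its average across the
   reference samples. A value of 1 is average priority; 2 means the sample
   invests twice the average in that pathway relative to the rest of its
   mitochondrial program.

Because the inner quantity is a within-sample ratio, any per-sample scalar —
overall mitochondrial content, library depth left over after normalization —
cancels exactly. This is the property that makes mitoPPS integrable across
samples and even datasets, and it is asserted at $10^{-12}$ in the test
suite rather than assumed.

Two algebraic consequences are worth keeping in mind:

* With the reference being all samples, each pathway's mitoPPS averages to
  exactly 1 across samples (the denominator is the arithmetic mean of the
  numerators). This is a built-in sanity check on any computed matrix.
* Raising one score strictly raises its own mitoPPS and weakly lowers the
  others in the same sample: the score is *compositional by design*. A
  planted doubling of one pathway out of twelve recovers as roughly
  $\tfrac{1}{n'-1}(1.5 + 1.33 + 9 \times 2) \approx 1.9$, not 2.0, because
  the sample's other ratios shift too.

## The pipeline around the score

**Annotations.** `load_mitocarta()` parses the MitoCarta3.0 pathway sheet
(TSV/CSV, or XLSX via `readxl`) into a three-level hierarchy keyed by the
full hierarchical path string, so duplicate short names at different levels
stay distinct. Level-2/3 pathways must have a resolvable parent; parents are
expected to carry a superset of their children's genes (violations warn, not
error, since they indicate an edited file rather than an unusable one). All
149 pathways are exposed as scoreable units; filtering by level is the
caller's choice.

**Symbol harmonization.** Two rewrite rules ship by default, both
corresponding to fixes RNA-seq exports commonly need: restoring the `MT-`
prefix on mtDNA-encoded genes (`ND1` → `MT-ND1`) when the bare stem is
absent from the gene universe, and the explicit rename `C12orf10` → `MYG1`.
Matching after rewriting is exact, with no case folding — MitoCarta symbols
are uppercase-canonical and case folding could merge distinct mouse and
human symbols. The alias table accepts user extensions and rejects chained
mappings, keeping application idempotent.

**Normalization.** Raw counts are TMM-normalized via `edgeR` (the canonical
implementation, with the canonical parameters: 30% M-trim, 5% A-trim,
precision weighting, reference column chosen by 75th-percentile count
fraction) and scaled to counts per million. Library-size corrections matter
here because mtDNA-encoded transcripts can dominate libraries unevenly
across tissues. The tests cross-check the factors against an independently
coded transcription of the published algorithm.

**Proteomics cleaning.** Intensity matrices keep missingness explicit
(`NA`, never zero). `filter_and_impute()` removes genes observed nowhere,
optionally reverses a log10 transform, and imputes each remaining gap as
half the gene's minimum observed value — a low, non-zero stand-in for
below-detection-limit abundance. The operation is idempotent.

**Scoring.** `score_pathways()` averages member genes *present in the
matrix*; pathways below 50% gene coverage (tunable) are scored but flagged,
because composite scores over a minority of members lose biological
meaning. Coverage is reported, not enforced: there is no principled
universal cutoff, so the decision is left with the analyst. A pathway with
no members present scores `NA`, never a silent zero. Parent pathways
average *genes*, not child sub-scores — with unequally sized children the
two differ, and a dedicated test documents the chosen semantics.

**Nonfinite handling in mitoPPS.** A single zero pathway score poisons
every ratio involving that sample. The default policy excludes such samples
and reports them (`finite_check()` lists sample/pathway pairs); an optional
epsilon-floor policy (smallest positive score × $10^{-3}$) is available but
off by default — exclusion keeps the reported scores free of an arbitrary
constant.

**Two reference conventions.** `compute_mitopps()` normalizes against all
samples (atlas-style mapping: what does each tissue prioritize relative to
the body?). `control_referenced_mitopps()` normalizes against a designated
control set (perturbation designs: what does treatment change relative to
untreated?). The first is the second with controls = everyone; the mean-1
invariant then holds over the reference set only. When two datasets are
integrated, each is computed against its own reference first and the
matrices concatenated — mitoPPS are unitless and internally normalized, so
no cross-dataset re-normalization is applied.

## The multivariate layer

PCA uses `stats::prcomp` (centered, unscaled by default) on whatever
transform the caller chose — z-scored gene matrices for expression-level
maps, log10 mitoPPS for prioritization maps — and records that choice in
the result. Component signs are fixed by making each loading vector's
largest-magnitude element positive, so coordinates are comparable across
runs. Hierarchical clustering is Euclidean + Ward.D2 (`hclust`), k-means is
seeded with 25 restarts, and Spearman matrices use average ranks with the
t-approximation for p-values (adequate at the n involved here).

Two-group contrasts follow a fixed decision tree: Shapiro–Wilk on each
group gates normality, Fligner–Killeen gates variance homogeneity, and the
four outcomes map to Student's t, Welch's t, Wilcoxon rank-sum, and
Brunner–Munzel respectively. The gate alpha defaults to 0.05 and is
configurable. The Brunner–Munzel test is implemented in-package (rank-based
statistic with Satterthwaite-style degrees of freedom) and verified against
an independent implementation; Hedges' g (pooled-SD Cohen's d with the
$J = 1 - 3/(4\,df - 1)$ correction) accompanies every comparison. No
multiple-testing correction is applied across pathways — contrasts are
reported singly, and this is a documented limitation.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` builds expression as

$$x_{gs} = \mathrm{base}_g \times \mathrm{scale}_s \times
  \mathrm{priority}_{\mathrm{group}(s),\,\mathrm{pathway}(g)} \times
  \varepsilon_{gs}, \qquad \varepsilon_{gs} \sim \mathrm{LogNormal}(0, \sigma),$$

over a fixed 12-pathway, 3-level mini-hierarchy whose 6 leaves partition
the genes. The default fixture is 300 genes, 24 samples in 4 groups,
log-normal per-sample scale factors (sdlog 0.5 — a severalfold spread in
mitochondrial content, of the order seen between tissues), neutral
priorities and $\sigma = 0.1$; multiplicative log-normal noise was chosen
because every downstream quantity is ratio-based, and a Poisson count mode
exercises the TMM path. These sizes keep the brute-force mitoPPS oracle
(the literal $O(n'^2 x')$ triple loop) cheap, which is what makes the
equivalence tests at $10^{-12}$ practical; the planted-recovery experiment
runs 100 replicates at 40 samples each in seconds.

The generator deliberately emulates the two confounds the method is built
to defeat — per-sample scale (content) and planted prioritization — plus
noise and missingness. It does **not** simulate gene–gene correlation
structure, full-transcriptome backgrounds, tissue heterogeneity (cell-type
mixtures), or batch structure. Passing tests therefore demonstrate the
*algebraic* correctness and recovery behavior of the pipeline, not
robustness to every artifact of real tissue data; the null model
(priorities ≡ 1) shows mitoPPS = 1 exactly, and the spread of mitoPPS
under the null shrinks monotonically with $\sigma$, which is asserted over
seeded grids.

## Numerical choices and degenerate inputs

* Fold differences between groups come in two summaries, because the
  population question ("how much higher is the group mean?") and the
  matched-donor question ("how much higher within a donor, on average?")
  differ: `ratio_of_means` is the default for unpaired contrasts,
  `mean_of_ratios` for position-paired samples, which also returns the
  per-pair range. On identical paired groups the latter is exactly 1.
* Reference-sample ties in TMM are broken by first column order;
  deterministic output was preferred over any cleverness.
* Constant genes z-score to all-zero with a warning rather than `NaN`.
* Duplicate gene or sample ids, negative expression values, duplicate
  (gene, tissue) pairs in long-format input, and GCT header/dimension
  mismatches are all hard errors at read time: silent coercions of
  identifier tables are how pathway scores go quietly wrong.
* Missing (gene, tissue) pairs in long-format consensus input become `NA`,
  not zero — zero is a claim about expression, absence is not.
* Radar-chart bounds are the data extremes padded by 10% of their
  magnitude, exposed as a utility so plots are reproducible.

## Command-line interface

The installed script (`system.file("cli", "mitotyper", package =
"mitotyper")`) wires the same functions into `simulate`, `normalize`,
`impute`, `score`, `mitopps`, `pca`, `cluster`, `compare` and `atlas`
subcommands. Every command writes a JSON run manifest (command, arguments,
version, seed, timestamp) beside its outputs, and commands are idempotent
given identical inputs and seed. The `atlas` command is the only path meant
for real downloaded data (a consensus expression table plus the MitoCarta
annotation file, both read from local paths); everything else runs on
generated fixtures.

## A worked miniature

```{r worked}
d <- generate_synthetic(synthetic_config(
  n_samples = 40, groups = rep(c("A", "B"), each = 20),
  priorities = list(A = c("MitoGroupA > PathA1 > LeafA1a" = 2)),
  sigma = 0.1, seed = 11))
scores <- score_pathways(d$expr, d$hierarchy)
pps <- compute_mitopps(scores)
a <- d$samples$sample_id[d$samples$group == "A"]
sort(rowMeans(pps[, a]), decreasing = TRUE)[1:3]
recovery_report(pps, d$truth)$detection
```

The planted leaf tops group A's prioritization (about 1.31 here), its
parents rise by the diluted share of their gene sets (about 1.12 and 1.06),
and everything else sits slightly below 1. Note the effect of the
all-sample reference: since half the samples carry the planted factor and
each pathway's mitoPPS must average 1 over *all* samples, group A sits near
1.3 and group B near 0.7 for the planted leaf. Referencing the controls
instead (`control_referenced_mitopps()`) pins the *control* group at 1 and
moves the treated group to the full compositional ~1.9.

## Known limitations

* MitoPathway scores reflect transcript or protein *programs*, not measured
  flux or capacity; prioritization of, say, fission pathways indicates
  propensity, not events.
* Pathways represented by few genes yield noisier mitoPPS; the coverage
  flag marks under-covered pathways but small pathways with full coverage
  remain intrinsically less robust.
* Cross-dataset comparability assumes similar gene coverage; the package
  reports coverage but applies no threshold.
* No multiplicity correction across the 149 pathways.
* Bulk input mixes cell types; tissue-level mitotypes understate the
  differences between pure cellular mitotypes.
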