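---
title: "Methods: genomic-block methylation analysis and silencing screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-block methylation analysis and silencing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

# Scope and model

`methylscreen` analyzes promoter CpG-island (CGI) hypermethylation in
tumor cohorts profiled on methylation beadarrays, and integrates it with
expression evidence into a screen for methylation-silenced,
drug-reactivated genes. This vignette explains the models and the design
choices behind each stage; it states no result that the package's test
suite and `scripts/acceptance.R` do not themselves compute.

## Genomic blocks

Single-CpG β values are noisy and unevenly spaced; methylation-silencing
is a property of a promoter region, not of one probe. Probes are
therefore assembled into *genomic blocks* keyed by
`(gene, TSS-relative category, CGI relation, CGI id)` — the standard
annotation axes of Infinium-style manifests — and a block's level is the
arithmetic mean β of its member probes. Averaging over the 2–5 probes of
a typical TSS200 CGI block suppresses per-probe noise and emphasizes the
densely methylated islands relevant to silencing.

Choices a manifest does not dictate:

* **Multi-gene probes.** A probe annotated to *k* genes joins one block
  per gene, because every downstream screen is gene-centric.
* **Missing β.** A block's value is the mean over available probes and is
  missing only when all probes are missing; this maximizes usable blocks
  and is deterministic.
* **Shore/shelf directionality** (N/S) is collapsed: no analysis here
  uses it.
* **Non-autosomal probes** are excluded at load time; X-inactivation and
  Y-loss would otherwise confound the tumor-vs-normal comparison.

## Three-state calling

A block is called `unmethylated`, `partial`, or `methylated`. The nominal
ranges (0–0.2, 0.2–0.4, 0.4–1.0 for tissues; 0.2–0.8 and 0.8–1.0 for
cancer cell lines) overlap at their endpoints, so the package fixes a
half-open convention: lower-bound inclusive, with the methylated class
inclusive at its threshold (β ≥ 0.4 for tissues, β ≥ 0.8 for cell lines).
This matches the "β-value ≥ 0.4" phrasing used when counting methylated
tumors. The wider partial band for cell lines reflects their clonality:
without stromal admixture, intermediate β in a cell line indicates true
allelic or subclonal heterogeneity rather than contamination, and only
near-saturated β should count as methylated.

## Aberrant methylation and cluster analysis

A block is *aberrantly methylated* when β < 0.2 in **every** normal
control and β ≥ 0.4 in at least `min_tumor_count` tumors (default 6,
operationalizing "more than 5 of 28 tumors"). The strict all-normals rule
is the most conservative reading of "unmethylated in the normal tissue"
and keeps the false-positive contribution of a single noisy normal at
zero by construction.

Sample clustering uses Euclidean distance on block-β vectors with
agglomerative linkage. Because the linkage method used by the classic R
clustering stack was its historical default, the package defaults to
`complete` and exposes `average` and `ward` (ward.D2). When more blocks
are supplied than the 20,000-element cap of that stack, a seeded uniform
subsample is drawn and the seed is recorded in the result. Blocks with
missing values among the clustered samples are dropped first (Euclidean
distance is undefined on missing cells), and samples are put in a
canonical sorted order so the tree does not depend on column order.
"Most variable blocks" ranks by sample variance (standard deviation gives
the same ranking) with ties broken by block id.

The per-sample *methylated fraction* — methylated reference blocks over
non-missing reference blocks, the reference being CGI blocks unmethylated
in all normals — summarizes CpG-island methylator load and makes
methylator phenotypes comparable across samples and cohorts.

## Expression and the silencing screen

Single-color expression arrays are scaled so the 75th percentile of all
probe signals is 1.0 per sample; percentiles use linear interpolation
between order statistics (R's type-7 quantile), a convention the package
documents because vendor software conventions differ. Gene level is the
mean over a gene's probes. "Expressed in the baseline" requires the mean
normalized signal to reach a threshold in **each** baseline cell type
(mesenchymal stem cells AND osteoblasts); the threshold is nowhere
dictated by the assay, so it is a configurable default of 0.5 on the
normalized scale, documented as arbitrary.

Induction by 5-aza-2'-deoxycytidine is measured as
`log2(treated / mock)` on values floored at 0.01 (normalized scale) to
keep ratios finite near the detection limit. The screen's description
"two-fold or more (signal log ratio > 2)" is internally inconsistent —
two-fold is log2 ≥ 1, log ratio > 2 is four-fold — so the package
defaults to the two-fold reading (`induction_log2_threshold = 1`) and
leaves the threshold configurable rather than guessing intent.

The integrated screen intersects: (i) genes with a TSS200 CGI block
unmethylated in normals and methylated in ≥ `min_tumor_count` tumors,
(ii) baseline-expressed genes, (iii) genes evaluable on the expression
platform, and then requires induction in the treated cell line. The
original three published criteria do not mention the screened cell line's
own methylation, but re-activation by a demethylating agent is only
interpretable at a methylated promoter; the package therefore requires
the cell line's block to be methylated under the cell-line scheme
(β ≥ 0.8) by default, with `require_cell_line_methylated = FALSE`
restoring the pure induction screen. A gene with several qualifying
blocks is represented by the block methylated in the most tumors (ties by
block id); output is sorted by induction, then gene symbol.

## qMSP and PMR

`PMR = [(meth/Alu)_sample / (meth/Alu)_reference] × 100`, the reference
being SssI-treated fully methylated DNA. Alu normalization makes PMR
invariant to rescaling the sample's counts (copy-number robustness, the
reason Alu is preferred over single-copy genes in aneuploid tumors).
Replicate wells are averaged on the molecule-count scale — counts are the
measured quantity — before the ratio is formed. PMR > 100 is possible
under noise and is reported with a warning rather than clamped, because
clamping would bias averages of replicates.

## Clonal versus parallel evolution

For a primary P and metastasis M, per-lesion aberrant sets are blocks
with β ≥ 0.40 within an evaluated universe of promoter blocks
(unmethylated in normals, baseline-expressed genes). The qualitative
published patterns — metastasis carrying the primary's methylation "in
addition to" its own, versus sharing "only a fraction" — need a numeric
rule to be computable. The package uses the shared fraction of the
primary, `|P ∩ M| / |P|`: clonal when ≥ 0.75 (default, configurable),
parallel when below **and** the metastasis has private methylation. A
pair with low shared fraction and no metastasis-private methylation fits
neither description (it would mean wholesale methylation loss); it is
reported as clonal with an explicit edge-case flag and warning rather
than silently forced into either class. Classification depends only on
P and M, never on universe blocks outside both.

# The synthetic-data generator

The generator (`sim_config()` and the `simulate_*` functions) emits every
input the analyses read, with planted ground truth. Its defaults are the
study conditions the package is designed around: 3 normals, 28 primary
tumors of which 10 form a high-methylation (CIMP-like) subgroup, 2,000
genes each with a TSS200 CGI block of 2–5 probes (30% of genes also carry
open-sea body probes), 2% of promoter blocks planted aberrantly
methylated, cell lines assayed mock- and 5-aza-dC-treated, baseline
expression in 7 MSC and 3 osteoblast arrays, a true 4-fold induction of
silenced genes, 10% log-normal expression noise, and qMSP counts at a
Poisson scale of 10,000 molecules.

Distributional choices:

* **β noise** is Beta-distributed per state — shapes (2, 38), (10, 10),
  (17, 3) for tissue unmethylated/partial/methylated (means ≈ 0.05 / 0.5 /
  0.85) — the standard emulation of beadarray bimodality. Cell lines use
  sharper shapes ((5, 95), (90, 10)) for their near-binary profiles.
  `noise = FALSE` replaces draws by the point masses 0.05 / 0.5 / 0.85
  for exact-recovery tests.
* **Planted aberrant blocks** each receive a carrier set of 8–28 tumors,
  so every planted block exceeds the 6-tumor call threshold by
  construction and noise-free recovery must be exact.
* **High-methylator subgroup.** The subgroup shares a "susceptible" block
  set, as CIMP-like tumors share methylated loci; sharing is also what
  makes the subgroup a cluster. `high_methylator_extra_fraction` (0.20)
  is defined as the *total* planted methylated fraction of the
  normally-unmethylated CGI reference in a high-methylator — the
  susceptible set is sized after accounting for carried planted-aberrant
  blocks — so the per-sample `methylated_fraction` estimand equals the
  configured rate.
* **Ground truth under a planted subgroup.** With 10 high-methylators,
  susceptible blocks genuinely are methylated in ≥ 6 tumors, so the
  implied aberrant truth (`true_aberrant_blocks()`) is the planted seed
  blocks plus the susceptible set; recovery is measured against that
  implied set. Cohorts without a subgroup (`n_high_methylators = 0`)
  have exactly the seed blocks as truth.
* **Silenced genes** are drawn per cell line from the aberrant genes and
  forced into the baseline-expressed set (a methylation-silenced gene is,
  by definition, expressed in the cell of origin). The treated cell-line
  array shows a planted promoter-β decrease drawn uniformly from
  [0.18, 0.51]. End-to-end screen tests plant 50 silenced genes among
  2,000; since silenced genes must be a subset of aberrant genes, those
  runs raise `aberrant_block_fraction` to 0.05.
* **Expression** is generated probe-level (1–2 probes per gene) with
  multiplicative log-normal noise and an arbitrary per-sample scale
  factor, so 75th-percentile normalization does real work.
* **Pairs.** Clonal mode: metastasis = primary ∪ extra events. Parallel
  mode: both lesions are an ancestral set plus independent private
  events. Optional call-flip noise toggles each universe block's
  membership per lesion with the configured probability, emulating
  borderline β calls near the 0.40 threshold. The default pair universe
  is 120 evaluable blocks — the scale of near-threshold promoter calls
  that actually inform the comparison; since classification ignores
  blocks outside P ∪ M, universe size matters only through this noise
  model, and flipping at a genome-wide universe would amount to
  thousands of false calls, a failure mode of the calling step, not of
  the classifier.
* **RNG discipline.** Every simulated output draws from its own named
  stream derived from the master seed, so adding one simulation never
  perturbs another; identical configuration and seed give byte-identical
  outputs.

What the generator does **not** emulate: raw two-color intensities or
IDATs, array normalization artifacts, copy-number aneuploidy bleeding
into β, probe cross-hybridization, stromal-contamination gradients, or
correlated (batch) noise. Passing recovery tests on these cohorts
demonstrates the correctness of the calling, screening and
classification logic under the stated noise model — not robustness to
the full artifact spectrum of real arrays, where upstream QC and
normalization remain the analyst's responsibility.

# Numerical choices and degenerate inputs

* Interval boundaries: half-open, methylated class closed at its lower
  bound (0.2 / 0.4 / 0.8 resolve to partial / methylated / methylated
  for the relevant material).
* Percentile convention: type-7 (linear interpolation); normalization is
  exactly idempotent under it.
* Tie-breaks: variable-block ranking by variance then block id; screen
  output by log2 induction then gene symbol; representative block per
  gene by tumor count then block id. All outputs are deterministically
  ordered.
* Degenerate inputs raise errors rather than guessing: β outside [0, 1],
  empty normal/tumor/baseline sets, a zero 75th percentile, zero Alu or
  reference counts, an empty primary aberrant set, clustering a single
  sample.
* The signal floor (0.01 normalized) bounds log2 ratios at genes near
  the detection limit; a gene below floor in both conditions has ratio 0.

# Problem sizes

The shipped tests and the acceptance script run on cohorts of 2,000
genes (≈ 2,600 blocks, ≈ 8,000 probes) × 35–39 samples, 20 replicate
seeds for the noisy recovery rates, 200 + 200 simulated pairs, and
200-replicate qMSP Monte-Carlo — sizes chosen so the full suite
completes in well under a minute while keeping every binomial margin
(e.g. recall ≥ 0.95 over 20 seeds) far from its threshold.

# Known limitations

* The block-assembly key reproduces the *structure* of published block
  counts but is not asserted to reproduce any specific manifest's count,
  since the exact assembly rule behind such counts is not public.
* The clonal/parallel rule is an interpretation; the 0.75 threshold is a
  package default, not a community standard, and should be reported with
  any result.
* With single (unreplicated) mock/treated arrays there is no variance
  estimate for induction; the screen is a fold-change filter, not a
  differential-expression test. Replicates, when supplied, are averaged.
* `eligible_gene_universe()` evaluates one tissue cohort against one
  expression platform; multi-platform reconciliation is out of scope.
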