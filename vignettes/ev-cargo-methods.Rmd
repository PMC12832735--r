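---
title: "Methods: rank-based EV cargo comparison and presence calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based EV cargo comparison and presence calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcargo)
```

## The problem

Extracellular vesicles (EVs) isolated from saliva and from blood carry
RNA cargo that reflects their tissues of origin. Comparing the two
biofluids is attractive — if neurodegeneration-associated transcripts
are well represented in salivary EVs, saliva could replace blood draws
for biomarker screening — but the two cohorts are typically profiled
under different protocols, on donors of different ages, with different
isolation chemistry. Absolute or normalized expression levels are
therefore not comparable across sources. `evcargo` implements a
comparison that never contrasts levels directly: each source's most
abundant features are identified *within* that source, and only the
composition of those top sets is compared.

## The ranking statistic

For feature $g$ with counts $x_{gi}$ over a cohort's $n$ samples,

$$\mu_g = \frac{1}{n} \sum_{i=1}^{n} \log(x_{gi} + 1).$$

The $K$ features with largest $\mu_g$ (default $K = 1000$) form the
source's highly-represented set. For a pathway of $k$ genes, the
reported quantity is $100 \cdot c / k$ where $c$ is the number of
pathway genes inside the top-$K$ set.

Choices worth recording:

- **Log base.** Natural log. The mapping $x \mapsto \log_b(x+1)$ is
  monotone for any base, so top-$K$ membership is base-invariant; the
  test suite asserts this on random matrices. Scores are reported in
  nat units.
- **Raw counts.** Raw counts enter $\mu_g$ by default. Because ranking
  happens within a source, per-sample library scaling mostly cancels;
  a `normalize` flag applies mean-library scaling for users who want
  it, as an explicit deviation.
- **Ties.** Ties at the rank-$K$ boundary are broken by lexicographic
  feature ID (C collation via radix ordering), so results are identical
  across platforms and runs. Internally the score is computed as a row
  sum divided in double precision, which makes features with identical
  count multisets tie *exactly* rather than differing by an ulp of
  floating-point noise — without this, the tie rule would silently
  never fire.
- **Denominators.** Pathway percents always use the full pathway size
  $k$, including genes never measured in a source. A per-row
  "measured members" column exposes how many pathway genes were in each
  source's feature universe, so the reader can judge the effect without
  the package guessing a restriction.
- **Display rounding** is one decimal, round-half-even (R's `round`);
  full precision is retained in the objects and JSON reports.

An exact two-sided test on the $2{\times}2$ table (pathway members
in/out of top-$K$, by source) is available as `proportion_test()`. It is
an extension beyond the descriptive comparison the design reproduces and
is off by default in reports; the implementation delegates to
`stats::fisher.test` and the test suite cross-checks it against an
independent hypergeometric enumeration.

## Identifier harmonization

Count tables from different studies rarely share a namespace.
`harmonize_ids()` strips Ensembl-style version suffixes (only when the
prefix matches an `ENS...` accession, so `hsa-miR-1.2` is untouched) and
optionally maps to gene symbols through the annotation table. IDs that
cannot be mapped are dropped *with a count and a list* — the pipeline
logs them and embeds the counts in its JSON report, never silently. The
operation is idempotent, which the tests assert.

## Composition and mapping summaries

A feature is *detected* in a sample when its count reaches
`detect_threshold` (default 1 read — the weakest defensible rule, and
configurable because detection rules are rarely stated in published
summaries). Detected features are tallied by biotype over a closed
vocabulary (protein_coding, lncRNA, pseudogene, other; unannotated
features are binned as "other" with a warning). Two cohort averages are
reported side by side: the mean of per-sample percentages and the ratio
of pooled counts. These genuinely differ — a mean of ratios is not the
ratio of means — and published summary figures do not always say which
convention they used, so the package emits both rather than arbitrating.
An all-zero sample yields `NA` percents (an explicit undefined
sentinel), never a division by zero.

Read-mapping summaries add uniquely-mapped and multi-mapped percents
into a total-mapped percent per sample and on cohort average, accepting
either percent or raw-count layouts (raw counts must be positive in
total).

## Presence calling

- **qPCR arrays.** Each assay runs in duplicate; a gene is present in a
  sample iff both replicate Ct values lie inside the dynamic range
  $[18, 35]$, bounds inclusive ("between 18 and 35" is read as a closed
  interval). A missing replicate — including "Undetermined" wells, which
  the reader maps to `NA` — forces an absent call. Widening the window
  can only add present calls; the suite asserts this monotonicity on
  1,000 random tables.
- **miRNA panels.** Hybridization panels carry negative-control probes.
  The background threshold is the per-sample control mean + 2·SD,
  averaged across samples; a miRNA is expressed when its mean count
  strictly exceeds that threshold. "Mean + 2·SD" is the package's
  default where published text says only "above background"; it is the
  standard panel convention and is configurable. The low-expression
  flag uses a strict rule as well: a mean of exactly 100 stays flagged,
  strictly above 100 clears it.

## The study simulator

`simulate_study()` generates everything the pipeline consumes, with
ground truth, so every stage is testable without any external download.
The generative model is the weakest standard one supporting rank-based
analysis of RNA-seq counts:

- gene baseline means are log-normal (`meanlog = 3`, `sdlog = 1.8`,
  spanning ~5 orders of magnitude as bulk RNA-seq does);
- counts are negative-binomial with dispersion 0.4 (variance
  $\mu + 0.4\mu^2$), a mid-range value for heterogeneous human cohorts;
- per-sample library factors are log-normal (`sdlog = 0.3`);
- cohort sizes default to 15 and 117, a small saliva cohort against a
  large public blood cohort;
- 5% of genes per source are structural zeros, drawn independently per
  source — emulating the observed pattern of genes abundant in most
  samples of one biofluid yet hardly detected in the other;
- a planted enrichment multiplies one pathway's gene means by a fold
  factor (default 8) in one source. When a fold > 1 signal is planted,
  structural zeros spare the enriched pathway's genes in the enriched
  source; with fold = 1 no protection is applied, so the null stays
  symmetric between sources.
- biotype labels are drawn at proportions 0.62 / 0.17 / 0.13 / 0.08
  (protein_coding / lncRNA / pseudogene / other), the rough composition
  of detected features in salivary EV preparations.

The qPCR generator draws present-pair Ct values from a normal law
truncated one full cycle inside the calling window, and gives absent
pairs an out-of-window or missing replicate — so planted truth is
recoverable exactly, by construction. The miRNA generator separates
expressed means (≥ 200) from the control background law (mean 20,
SD 5); its defaults mirror a human panel: 827 assayed, 286 expressed,
6 negative controls, 6 samples. Seeds are mandatory, never defaulted.

What the simulator does **not** emulate: correlated co-expression
modules, batch structure within a cohort, GC/length biases, partial
pathway overlap (simulated pathways are disjoint), or panel chemistry
artifacts. Passing tests demonstrate the pipeline's arithmetic and its
power against the planted signal model — not robustness to every
failure mode of real data.

## Problem sizes and calibration

The recovery property — with an 8-fold enrichment of a 50-gene pathway
in a 5,000-gene background (top-1000 cutoff, cohorts 15 and 117), the
enriched source shows the higher pathway percent — was calibrated at the
defaults above before the test was frozen: across seeded runs the
percent gap averages roughly 40 points and recovery is essentially
always achieved, so the ≥ 95/100 assertion has a wide margin. The suite
uses 100 simulations for this property and smaller studies (hundreds of
genes, cohorts of 3–10) elsewhere; the acceptance script uses the same
sizes.

## Known limitations

- The top-$K$ comparison is descriptive; no multiple-testing control is
  applied across pathways (`proportion_test` is provided, but a
  correction flag is future work).
- Feature level (gene vs transcript) is whatever the input matrices
  carry; the package does not aggregate transcripts to genes.
- The miRNA background rule cannot be validated against a published
  expressed-miRNA count without the raw panel data; it is a documented
  convention, not a fitted quantity.
- Harmonization is exact-match on stripped IDs or symbols; no alias
  resolution or cross-annotation liftover is attempted, and the dropped
  counts in reports are the honest record of what that loses.
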