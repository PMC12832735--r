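# evcargo

Analysis of RNA cargo in extracellular vesicles (EVs) isolated from
biofluids. EVs carry a transcriptome snapshot of their cells of origin,
which makes vesicles from accessible fluids — saliva in particular — an
attractive non-invasive source of disease biomarkers. `evcargo` implements
the statistical core of a salivary-EV (salEV) versus blood-EV (bEV) cargo
comparison for users who have feature-level count tables in hand (from
featureCounts or similar), qPCR array exports, and hybridization-panel
miRNA counts.

## What it computes

Absolute expression is not comparable between cohorts profiled under
different protocols, so the cross-source comparison is rank-based. For
feature *g* with counts *x₉ᵢ* over a cohort's *n* samples, the abundance
score is the mean log count

> μ_g = (1/n) Σᵢ log(x₉ᵢ + 1)

The *K* features with largest μ_g (default K = 1000) form the source's
highly-represented set, and for a pathway of *k* genes the quantity of
interest is the percent of those *k* genes inside each source's top-K set.
Around that core the package provides:

- **I/O with strict validation** — featureCounts-style count TSVs, GMT
  gene sets, annotation tables, duplicate-run qPCR Ct tables, miRNA count
  panels with negative-control rows, read-mapping summaries; Ensembl
  version stripping and symbol harmonization with a dropped-ID report.
- **Biotype composition** (protein_coding / lncRNA / pseudogene / other)
  per sample and cohort-averaged, plus total-mapped read summaries.
- **Presence calling** — a gene is present when its Ct lies in [18, 35]
  in both duplicate runs; summaries count genes detected in ≥ m samples.
- **miRNA background filtering** — expressed means above the
  negative-control mean + 2·SD threshold; low-expression flag at 100
  counts.
- **Per-sample top-K recurrence** — e.g. which lncRNAs sit in every
  sample's top 20.
- **A seeded study simulator** — negative-binomial counts for two cohorts
  (15 and 117 samples) with a planted pathway enrichment, plus synthetic
  Ct and miRNA panels with known ground truth, so the whole pipeline is
  testable end to end.

## Worked example

```r
library(evcargo)

cfg <- simulation_config(n_genes = 2000, fold_factor = 8, seed = 42)
sim <- simulate_study(cfg)
fit <- compare_topk(sim$counts_a, sim$counts_b, sim$genesets,
                    sim$annotation, k = 1000)
print(fit)
```

```
Top-1000 gene-set representation: salEV vs bEV
 pathway                 name salEV (%)   bEV (%) size
      P1 simulated pathway P1 43 (86.0) 29 (58.0)   50
      P2 simulated pathway P2 22 (44.0) 22 (44.0)   50
      P3 simulated pathway P3 26 (52.0) 28 (56.0)   50
```

Pathway P1 carries the planted 8-fold enrichment in the salEV cohort: 43
of its 50 genes (86.0%) reach that source's top 1000 against 29 (58.0%)
in the bEV cohort, while the two unenriched pathways differ only by
sampling noise. `summary(fit)` reports the percent gaps, `plot(fit)`
draws the paired bars, and `run_compare()` / `run_presence()` drive the
same stages from files on disk, writing TSV/JSON reports that embed the
configuration used.

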