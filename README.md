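# bmptargets

Computational pipeline for genome-wide identification of direct BMP
signaling (pSMAD1/5) target genes and the quantifications that accompany
such a study in a developmental model organism:

* **Peak calling** — a peakzilla-style sliding-window caller over paired-end
  fragment midpoints with a Poisson candidate test, summit detection, and
  per-peak scores: height *H* (fragments per million), enrichment
  *E = (H + p)/(H<sub>control</sub> + p)* over a matched input lane,
  summit-symmetry score *D = 1 − |L − R|/(L + R)*, and overall score
  *S = H·D*.
* **Cross-lane quantile normalization** of peak heights (rank *r* gets the
  across-lane mean of the *r*-th order statistic; unequal lane sizes by
  interpolation of the mean quantile function).
* **Joining and filtering** — single-linkage joining of summits across
  replicate lanes at a maximum distance of 100 bp, then the significance
  filter *Ē ≥ 10* and *S̄ ≥ 80* (inclusive).
* **Annotation** — nearest-TSS gene association within 20 kb, enhancer
  overlap (≥ 1 bp, half-open coordinates), PWM motif scanning on both
  strands.
* **Orthology** — reciprocal best BLAST hits per species pair decided by
  bit score after an e-value ≤ 1e-5 filter and `.S`/`.L` homeolog-suffix
  collapse; three-way target overlaps under both triangle-closure and
  chain-linkage rules.
* **Gradient quantification** — nuclear-arc profiles (θ = (i/N)·π),
  upper-quartile normalization, LOESS smoothing with a 99% confidence
  band; binned ventral-to-dorsal axis profiles (0.5% bins, 5% trim,
  background subtraction).
* **ChIP-qPCR statistics** — input-normalized ΔΔCt fold enrichment
  (2^−ΔΔCt) against an intergenic reference region, between-condition
  ratios with a two-tailed Welch t-test, DE-based target classification,
  and functional-category fractions versus a seeded random gene draw.

A seeded synthetic-data module generates every input the pipeline consumes
with planted ground truth (peak positions/strengths, ortholog triples,
gradient amplitudes, qPCR folds), so each stage is tested as a recovery
problem. See the methods vignette
(`vignettes/bmp-target-pipeline.Rmd`) for the models, defaults and design
decisions.

## Worked example

The analysis is organised as numbered drivers under `analysis/`; run them
in order from the repository root:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_peak_pipeline.R
Rscript analysis/03_orthology.R
Rscript analysis/04_gradient.R
Rscript analysis/05_qpcr.R
```

`01` writes the synthetic inputs (BEDPE fragment lanes for two
developmental stages on a 2 Mb toy genome, GFF3 gene models, BED
enhancers, outfmt-6 hit tables, nuclei and Ct tables) under
`results/synthetic/`. The later drivers print, for example:

```
LG: 14 + 14 lane peaks -> 10 joined (2-lane), 10 significant, 9 target genes, 4 in enhancers; 100% of joined summits within 150 bp of a planted summit
P4d: 17 + 16 lane peaks -> 13 joined (2-lane), 13 significant, 12 target genes, 10 in enhancers; 100% of joined summits within 150 bp of a planted summit
stage overlap: 9 LG genes, 12 4d-planula genes, 3 bound at both stages
```

— per stage: peaks called in each of the two replicate lanes, clusters
surviving two-lane joining, peaks passing *Ē ≥ 10* / *S̄ ≥ 80*, distinct
target genes, enhancer overlaps, and the summit-recovery rate against the
planted truth; then the between-stage target-gene overlap (three summits
were planted at both stages, and exactly those three genes come out
shared). The qPCR driver prints

```
chordin: 1.81-fold (transgenic) vs 0.14-fold (wild type), ratio 12.55, Welch p = 6.9e-05
gremlin: 0.26-fold (transgenic) vs 0.34-fold (wild type), ratio 0.77, Welch p = 0.00064
BRE targets differentially expressed: 37 of 55 (67.3%)
```

— the planted chordin folds of 1.82 and 0.15 are recovered through the
ΔΔCt computation from noisy Ct values, giving a condition ratio near the
planted 12.13; the classification summary reports the fraction of
BRE-carrying targets that are differentially expressed.

Equivalent functionality is available directly from R via the exported
functions (`call_peaks()`, `quantile_normalize_heights()`,
`join_peaks()`, `filter_significant()`, `associate_genes()`,
`compute_rbh()`, `overlap_targets()`, `loess_profile()`,
`fold_enrichment()`, `run_pipeline()`, ...).

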