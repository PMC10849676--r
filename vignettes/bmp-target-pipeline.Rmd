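---
title: "Methods: ChIP-seq target calling, orthology and gradient quantification for BMP signaling studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ChIP-seq target calling, orthology and gradient quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmptargets)
```

# Scope and overall design

`bmptargets` implements the computational core of a genome-wide search for
direct BMP signaling (pSMAD1/5) target genes of the kind performed in sea
anemone embryos, together with the quantifications that typically accompany
such a study: cross-species target conservation via reciprocal best BLAST
hits, spatial quantification of the signaling gradient from nuclear
immunofluorescence, and ChIP-qPCR fold-enrichment statistics. Sequencing,
read alignment, motif *discovery*, differential-expression model fitting and
image segmentation are out of scope: the package consumes fragment
intervals, gene models, alignment hit tables, per-nucleus intensity tables
and Ct tables, and owns everything downstream of them.

Because the real inputs are large sequencing and imaging datasets, the
package carries a first-class synthetic-data module that generates every
input it consumes with *planted ground truth* — peak positions and
strengths, ortholog triples, gradient amplitudes and qPCR fold enrichments —
so that each stage can be tested as a recovery problem with a known answer.

# The peak caller

The caller is a peakzilla-style sliding-window scan over paired-end fragment
*midpoints*, defined as `floor((start + end) / 2)` in 0-based half-open
coordinates. Windows of width $W$ (default 300 bp) advance in steps of
$W/4$; a window is a candidate when its ChIP midpoint count exceeds the
upper tail, at $p < 10^{-3}$, of a Poisson distribution whose rate is the
genome-wide ChIP midpoint rate times $W$. Overlapping and book-ended
candidate windows are merged; each merged region contributes at most one
peak.

Within a region the summit is the base position maximizing the midpoint
count in $[\mathrm{bp} - W/2, \mathrm{bp} + W/2)$. Counts are integers, so
the maximum is typically attained on a plateau of positions; the summit is
the median of the tied positions, rounded down. This keeps the summit at
the center of symmetric peaks and makes calling translation-equivariant.

Each peak carries four scores:

* height $H = 10^6 \cdot c_W / N$, the fragments-per-million (FPM) midpoint
  count $c_W$ in the summit window, normalized by the lane's library size
  $N$;
* enrichment $E = (H + p) / (H_\mathrm{control} + p)$ against the matched
  input lane, computed identically from the control's own library size,
  with pseudocount $p = 0.5$;
* distribution score $D = 1 - |L - R| / (L + R)$, where $L$ and $R$ are the
  midpoint counts left and right of the summit within the window. A
  perfectly symmetric peak has $D = 1$; a fully one-sided window
  ($D = 0$) is discarded as an artifact;
* overall score $S = H \cdot D$.

Control scaling is per-million only — there is no local-lambda background.
This is a deliberate simplification relative to callers that estimate a
local background; the synthetic inputs have spatially uniform background,
and on real data the Poisson candidate test plus the enrichment ratio
already discard diffuse pile-ups. Peaks with $E < 2$ are dropped at the
candidate stage; the biological significance filter ($E \ge 10$,
$S \ge 80$, both inclusive) is applied later, to cross-lane means.

## Quantile normalization of peak heights

Replicate lanes differ in immunoprecipitation efficiency, which shifts the
whole height distribution of a lane. Heights are therefore quantile-
normalized across lanes before joining: within each lane peaks are ranked
by $H$ and rank $r$ receives the across-lane mean of the $r$-th order
statistic. Lanes with unequal peak counts are handled by linear
interpolation of the mean quantile function evaluated on an even grid of
the largest lane size; tied heights share the mean of the values they
would have received. For equal-size lanes this reproduces the standard
matrix algorithm (the test suite cross-checks against
`limma::normalizeQuantiles`), it is idempotent, and it preserves the
pooled mean. $S$ is recomputed from the normalized $H$. Normalization is
applied to the final per-lane peak lists, after candidate filtering —
heights are only comparable across lanes once both lanes have called
actual peaks.

## Joining, filtering, annotation

Summits are joined across lanes by single-linkage clustering per
chromosome with a maximum gap of 100 bp between consecutive summits.
Summit distance (rather than span overlap) is the joining metric because
the caller's primary coordinate is the summit. A joined peak keeps the
mean $H$, $E$ and $S$ of its members and the floor of the mean summit as
its consensus. Clusters supported by fewer than `min_lanes` distinct lanes
(default 2, i.e. replicate support) are dropped and counted.

Significant joined peaks ($\bar E \ge 10$ and $\bar S \ge 80$, inclusive
at the boundary) are associated with gene models: a summit inside a gene
span is assigned to that gene (nearest TSS if several overlap), otherwise
to the nearest TSS within 20 kb, with distance ties broken toward the
lexicographically smaller gene id. Manual curation of assignments, which a
real study would add, is replaced by this deterministic rule. Reported
TSS distances are signed, negative upstream on the gene's strand.
Enhancer overlap is a $\ge 1$ bp intersection in 0-based half-open
coordinates (abutting intervals do not overlap), computed with
`GenomicRanges` and verified in the tests against an exhaustive check.

Motif presence is flagged by scanning sequences on both strands with a
position frequency matrix scored as log2 odds against a uniform 0.25
background; `N` bases score 0 bits. Only scanning with a supplied matrix
is provided — motif discovery belongs to dedicated tools.

# Orthology

Inputs are directed BLAST outfmt-6 hit tables for the three species pairs
in both directions; only query, subject, e-value and bit score are used.
Allotetraploid subgenome suffixes (`.S`/`.L`) are stripped when they
terminate a gene id, keeping the best-scoring row per collapsed pair
(highest bit score, then lowest e-value, then input order). Hits with
e-value above `1e-5` are discarded. The best hit per query is the highest
*bit score* — deliberately not the e-value, which is the tie-breaker —
and a pair is an RBH when the relation holds in both directions.

"Shared by all three species" admits two readings, and the package
reports both side by side rather than choosing: the *triangle* rule
requires all three pairwise RBH edges to close consistently, while the
*chain* rule counts connected components of the target–RBH graph that
span all three species. Chains are never fewer than triangles; on clean
one-to-one fixtures they coincide.

# Gradient quantification

For the nuclear-arc procedure, nuclei are assumed ordered from the
strongest-signal midpoint; nucleus $i$ of $N$ receives the arc coordinate
$\theta_i = (i/N)\,\pi$, so the first nucleus sits at $\pi/N$ (not 0,
because the index starts at 1) and the last exactly at $\pi$. Intensities
of one control–experiment pair are pooled across both conditions and all
replicates and divided by the pool's upper quartile (type-7 interpolated
quantile, $q = 0.75$). "Upper quantile" admits several readings; the
upper quartile is the conventional one and is configurable.

The smoothed profile is a LOESS fit — local linear regression, tricube
weights, span 0.75 — of normalized intensity on $\theta$, pooling nuclei
across embryos of a condition, evaluated on a 100-point grid up to $\pi$,
with a pointwise 99% confidence band for the mean from the t distribution
on the fit's effective degrees of freedom. Span and degree are standard
defaults; degree 1 makes the fit exact on linear data, which the tests
exploit. Pooling across embryos (rather than averaging per-embryo fits)
matches fitting one curve to all measured nuclei of a condition.

The body-axis profile averages masked pixel columns of a projected image,
maps columns to percent of the masked extent (ventral at the left),
averages them into 0.5% bins, subtracts the bin-wise mean of supplied
control profiles, and discards bins in the first and last 5% of the axis,
where few pixels make the averages unreliable — with these defaults, 180
of 200 bins remain.

# qPCR statistics

Fold enrichment uses the input-normalized $\Delta\Delta C_t$ convention:
$\Delta C_t = C_t^\mathrm{IP} - C_t^\mathrm{input}$ per region, and
$\mathrm{fold} = 2^{-(\Delta C_t^\mathrm{target} - \Delta C_t^\mathrm{ref})}$
against the intergenic reference region measured in the same condition
and replicate. Between-condition comparisons report per-condition means
and SDs, the ratio of means, and a two-tailed Welch t-test on the
per-replicate folds (pooled-variance available by flag). With four
replicates per group normality cannot meaningfully be tested; the package
mirrors that situation by warning below five replicates rather than
gating on a normality test. When both groups are constant and equal the
test is degenerate and $p = 1$ by convention.

DE-based classification is inclusive at the threshold
($p_\mathrm{adj} \le 0.05$; the inclusive reading is used where sources
are ambiguous between $\le$ and $<$), with `2xDE` additionally requiring
$|\log_2 \mathrm{FC}| \ge 1$. Functional-category fractions are compared
against a seeded uniform draw of 100 genes without replacement from the
annotation universe.

# The synthetic-data generators

All generators draw from substreams derived deterministically from one
root seed (`synth_seed()`), so outputs are byte-identical for identical
(seed, config) and adding a generator never perturbs another.

* **ChIP fragments.** Each planted peak of strength $s$ FPM receives
  $\mathrm{Poisson}(s \cdot N / 10^6)$ fragments whose midpoints are
  Normal(summit, `fragment_length_sd`); the rest of the library, and all
  input fragments, are uniform over the genome. Fragments are truncated
  symmetrically at chromosome ends so midpoints stay in place — one-sided
  clamping would pile midpoints just inside the boundary and fabricate
  edge peaks. This is a midpoint placement model, not a read simulator:
  no sequence, no sequencing error, because alignment is out of scope.
  Under a uniform background, recovery of a planted peak requires
  strengths large relative to the background rate per window; the default
  study conditions (strengths of 3000–8000 FPM over a 2 Mb genome with
  40,000-fragment lanes) put candidate windows many Poisson standard
  deviations above background, which is what makes a 20-peak recovery
  test deterministic in practice.
* **Annotation.** Genes are placed on a slot grid (three gene lengths per
  slot) so spans never overlap; requesting more genes than slots is an
  error, not a silent densification. Enhancers cover a configurable
  fraction of planted summits ($\pm 500$ bp) plus decoys.
* **Nuclei.** Intensity at arc position $\theta$ is
  $b + a\,(1 + \cos\theta)/2 + \varepsilon$ with
  $\varepsilon \sim N(0, \sigma)$, in arbitrary units. The `flattened`
  knockdown shape quarters the amplitude; `expanded` widens the high
  plateau with a $\cos(\theta/2)$ profile. Defaults ($a = 10$, $b = 1$,
  $\sigma = 0.5$, 60 nuclei per embryo, 10 embryos) give a clearly
  resolvable but noisy gradient.
* **Hit tables.** Planted triples become mutual best hits (bit score 500,
  e-value $10^{-50}$); decoys have lower bit scores but some carry
  *better* e-values (so only a bit-score rule recovers the plant) and
  some fail the e-value cutoff (so filtering is exercised); homeolog
  duplicates emit `.S`/`.L` rows from one root.
* **qPCR.** The reference region keeps a fixed IP-minus-input difference
  of 2 cycles; a target's IP Ct is set so the planted fold comes out
  exactly, then independent $N(0, 0.05)$ cycle noise is added to every
  Ct. Planted defaults are the chordin/gremlin two-condition design with
  four replicates.

What the generators do *not* emulate: GC and mappability bias, local
chromatin background, fragment-length/insert-size artifacts, many-to-many
orthology and gene family expansions, embryo-to-embryo amplitude
variation, or qPCR efficiency differences between primer pairs. Passing
recovery tests therefore demonstrates correctness of the computations
under their stated models, not robustness to every artifact of real data.

# Problem sizes and numerical choices

The tests and the analysis scripts run at deliberately desk-scale sizes:
2 Mb genomes with two chromosomes, 40,000-fragment lanes, two lanes per
stage, up to 20 planted peaks, hit tables of a few hundred rows, 600
nuclei per condition, and four qPCR replicates. These sizes keep every
recovery property sharply testable while each script finishes in seconds.
Degenerate inputs are handled explicitly: empty fragment sets pile up to
zero counts rather than erroring, a lane with no peaks passes through
normalization with a warning, empty target sets yield all-zero overlap
reports, and a constant intensity profile yields a flat LOESS fit with a
zero-width band.

# Known limitations

* The caller has no local background model and no FDR estimate by
  chip/control swapping; it is not a drop-in replacement for MACS-style
  callers on real libraries.
* Gene association is nearest-TSS within a cap; it cannot reproduce
  manually curated assignments.
* RBH is one-to-one per species pair and cannot represent paralog
  families; the homeolog collapse handles exactly the terminal-suffix
  case.
* LOESS confidence bands are pointwise, not simultaneous; comparing two
  conditions by band overlap is conservative at a single position only.
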