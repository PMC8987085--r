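---
title: "Detecting naturally occurring receptor combinations: models and methods"
author: "comberon package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting naturally occurring receptor combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Endothelial cells — and cells generally — integrate many extracellular
signals at once, and combinations of receptors, rather than single
receptors, are the natural unit of intercellular communication. This
package detects *comberons*: naturally occurring combinations of
co-expressed genes of interest (typically receptors) in a chosen cell
class, supported simultaneously by three independent lines of evidence.

The procedure, per dataset:

1. **Co-expression distances.** Within each sample $i = 1 \dots k$, and
   using only the target-class cells, a distance matrix
   $\tilde M_i$ is computed between every expressed gene (non-zero in at
   least 5% of that sample's target cells; 1% suits deeply sequenced,
   class-enriched data) and every expressed gene of interest, under a
   configurable metric. The default is the correlation distance
   $1 - r$, with $r$ the Pearson correlation of the two genes' expression
   across cells; cosine and Euclidean metrics are options. A pair whose
   correlation is undefined in a sample (zero-variance vector) is treated
   as missing in that sample.
2. **Median aggregation.** The per-sample matrices are aggregated into the
   $n \times m$ matrix $M$ by the median over non-missing values; cells
   missing everywhere are imputed with distance 1 ("no correlation") under
   the correlation/cosine metric, or with $\max M$ under the Euclidean
   metric.
3. **Dendrogram ordering.** The $m \times m$ receptor matrix $A$ holds the
   Euclidean distances between the columns of the Pearson correlation
   matrix of $M$'s columns. Ward variance-minimization linkage is applied
   to $A$ directly, and the leaves are ordered to minimize the sum of
   $A$-distances between adjacent leaves over all orders consistent with
   the tree (an exact dynamic program over subtree flips; see Numerical
   choices). The *dendrogram distance* between two genes is the absolute
   difference of their leaf indices.
4. **Three measures per gene of interest.**
   *Expression fraction* — fraction of target-class cells expressing the
   gene at a non-zero level, median (configurably mean) across samples.
   *Network enrichment* — with $S$ the top 1000 differentially expressed
   genes and $p$ the fraction of interaction-network edges touching $S$,
   a gene of interest $j$ with degree $n_j$ and $k_j$ edges into $S$
   scores $-\log_{10} P_j$ where
   $P_j = \sum_{i \ge k_j} \binom{n_j}{i} p^i (1-p)^{n_j - i}$.
   *Evolutionary conservation* — the overlap between the 50-leaf window
   centered on $j$ and the same-size window centered on $j$'s homolog in a
   second species' ordering; genes absent from either species are missing.
5. **Combination and peaks.** Each measure is scaled to unit sum, smoothed
   with a centered 21-leaf uniform moving average, summed, and smoothed
   once more. The main comberon is the contiguous run around the profile
   argmax with values at least half the apex value; secondary peaks are
   local maxima with rescaled height and prominence above 0.05, at least
   50 leaves apart, each capped at 50 members.
6. **Bootstrap.** The samples are resampled with replacement $N = 100$
   times; the whole chain (aggregation → ordering → measures → combination
   → main peak) is recomputed per resample, reusing the per-sample
   distance matrices, and each gene's *bootstrap frequency* is the
   fraction of resamples that place it in the main peak. Within a
   resample, conservation is always computed against the partner species'
   original (non-resampled) ordering. Datasets with fewer than five
   samples are pooled and split into ten pseudo-samples first.

The differential-expression contrast behind the network enrichment is a
per-sample two-sided Welch $t$-test of target against non-target cells;
genes with $p < 0.001$ are ranked by decreasing statistic, ranks are
aggregated by the median over the samples where the gene qualified, and
the top 1000 genes by median rank form $S$. A Mann-Whitney variant is
available (normal approximation with tie correction; with tens of cells
per class per sample the approximation is accurate and an exact per-gene
test would be needlessly slow). Genes must qualify in at least half of the
usable samples — the aggregation needs a majority for the median rank to
be meaningful.

## Statistical machinery

* **Known-set enrichment.** Overlaps between a detected comberon and a
  known gene set (the packaged 22 angiogenesis receptors) are scored with
  the exact hypergeometric upper tail over the expressed-gene-of-interest
  universe.
* **Permutation null.** To calibrate bootstrap frequencies, the leaf order
  is replaced by uniformly random permutations: per realization, 100
  random orders are drawn (matching the bootstrap count), the combination
  and main-peak membership are recomputed per order, and the maximum
  per-gene inclusion frequency is recorded. The distribution of maxima
  over many realizations yields a non-parametric tail estimate for any
  frequency threshold, reported with a Clopper-Pearson interval. The
  default is $10^4$ realizations; bounding very small tail probabilities
  (order $10^{-7}$) requires proportionally more.
  Because normalization is order-invariant and the smoothing is linear,
  the combination of permuted tracks equals the double moving average of
  the permuted pre-summed vector; the loop runs in compiled code.
* **Dendrogram-distance test.** Whether known genes concentrate near an
  anchor (e.g. KDR) is tested by a likelihood-ratio comparison of a
  logistic regression of known-gene status on dendrogram distance to the
  anchor (intercept + linear term) against an intercept-only null, with a
  $\chi^2_1$ survival p value. The linear alternative is the simplest
  monotone model; perfect separation is reported at the machine floor
  with a warning.
* **Split-half and cross-dataset comparisons.** Two frequency sets are
  compared by the Pearson correlation over shared genes and the
  hypergeometric tail of the overlap of their above-threshold sets.
* **Peak grouping.** All peaks across resamples form a binary
  receptor-by-peak membership matrix; both axes are Ward-clustered
  (Euclidean) and cut into at most 15 groups (never more than the number
  of distinct profiles), and receptor-by-peak blocks with density at
  least 0.5 are reported with their mean height and mean inclusion
  frequency.

## The two-axis extension

Intercellular communication between two cell types is scored on a
ligand-by-receptor grid. Each axis is a full single-axis run (the ligand
axis contrasts the ligand-producing class against the rest). The grid
combines (a) the mean of the two min-max scaled combination profiles and
(b) the number of known ligand-receptor pairs joining the two genes'
bootstrap-stable dendrogram neighborhoods — a neighbor counts when it
falls in the 50-leaf window in more than 30% of resamples. The display
value is the mean of (a) and the min-max scaled (b); cells at or below
0.5 are masked. Agreement between the two components is reported with
Pearson and Spearman correlations. The hotspot box is the bounding
rectangle of the highest-mean DBSCAN cluster of shown cells
(eps = 3 cells, minPts = 5 by default). Scaling the neighborhood count to
[0, 1] before averaging is this package's convention, as is the equal
weighting.

## Numerical choices

* **Optimal leaf ordering.** The exact dynamic program over subtree
  orientations: for a node with children $L, R$,
  $\mathrm{cost}(u, w) = \min_{v \in L,\, z \in R}
  \mathrm{cost}_L(u, v) + A_{vz} + \mathrm{cost}_R(z, w)$, evaluated as
  two min-plus products, $O(m^3)$ overall. Ties break toward the first
  candidate in index order, and of the two reversals of the optimum the
  lexicographically smaller gene sequence is returned, so bootstrap
  frequencies are bit-reproducible. Validated against exhaustive
  enumeration of all tree-consistent orders for $m \le 8$.
* **Edge smoothing.** The moving average truncates its window at the
  profile edges and renormalizes by the actual width. Constants are
  preserved exactly and interior-supported signals conserve mass exactly;
  a consequence worth knowing is that an isolated spike within half a
  window of an edge is locally *amplified* (fewer neighbors dilute it).
* **Even windows.** A window of even size $w$ takes $w/2$ positions to the
  left and $w/2 - 1$ to the right of the center (so the 50-leaf
  conservation window spans positions $j - 25 \dots j + 24$, clipped at
  the boundaries, with the gene itself counted). Under an exact reversal
  of one species' order an interior gene therefore overlaps in 49 of 50
  positions, not 50 — the one-position asymmetry is inherent to any even
  window.
* **Peak thresholds.** Height and prominence cutoffs (0.05, strict) act
  on the min-max rescaled profile, because the raw combination scales as
  $1/m$ and absolute thresholds would be axis-length dependent.
  Prominence is the standard vertical distance to the lowest contour not
  enclosing a higher peak. Argmax ties resolve to the leftmost position.
  "Immediate proximity" of a peak is operationalized as the maximal
  contiguous half-height run around its apex.
* **Underflow.** Binomial and hypergeometric tails are computed in log
  space; the enrichment measure is capped at 320.
* **Degenerate inputs.** Constant receptor columns of $M$ are dropped with
  a warning before building $A$; samples with fewer than 10 target cells
  are skipped; an all-zero combination profile is an error; a resample
  failure is tolerated up to 10% of the plan, then the run aborts.

## What the synthetic generator emulates

`generateComberonData()` builds a two-species bundle with a planted
answer: (1) per-gene baselines and dropout with the strongly right-skewed
expressing-fraction distribution (Beta(0.25, 2)) of real log-normalized
single-cell data — most genes of interest are expressed in few cells, and
roughly a third fall below the 5% cutoff, as in real receptor universes;
(2) a planted module whose members share a per-cell latent factor in
target cells only (pairwise Pearson $r \approx 0.5$ at the default
loading); (3) differentially expressed genes up-shifted in target cells
and kept well expressed, as detectably DE genes are in practice; (4) a
power-law-ish interaction network in which each planted receptor is wired
to 30% of the DE genes; (5) a small fraction of non-planted genes of
interest whose network neighbors are drawn entirely from the DE set in
equal numbers — their enrichment values tie at a common large value,
mimicking the handful of saturated enrichment scores real composite
networks produce and preventing any single gene from dominating the
combination; and (6) a second species mirroring the planted module
through the homolog map, with `conservationScramble` controlling how much
of the module alignment survives. `generateNullData()` keeps every
marginal feature — baselines, dropout, class DE, network degree structure,
the tied strong-wired genes — and removes the couplings: no latent factor,
no preferential planted wiring, no cross-species alignment.

What the generator does **not** emulate: UMI count noise, batch and
platform effects, doublets, correlated gene programs beyond the planted
module, and biologically structured conservation. Passing tests therefore
demonstrate that the machinery recovers the statistical structure the
method is designed for, not that any particular biological dataset will
behave as cleanly.

### Operating regime and problem sizes

The fixed window parameters (21-leaf smoothing, 50-leaf conservation and
separation windows) presume an axis of several hundred genes of interest,
as in real receptor universes (~900 expressed receptors). On much shorter
axes the double smoothing flattens the combination until the half-height
run spans most of the dendrogram, and neighborhood windows lose meaning —
a regime the method was not designed for. The package's experiments
therefore use:

* default generator scale (1500 genes, 450 genes of interest of which
  ~300 expressed, 10 samples × 120 cells) for bootstrap-heavy experiments
  — planted-module recovery and split-half stability;
* receptor-universe scale (3000 genes, 1400 genes of interest, ~900
  expressed) for the permutation-null study, where the tail behavior of
  the maximum frequency is precisely what depends on the axis length;
* a reduced scale (400 genes, 80 genes of interest, 5 samples) for the
  200-replicate calibration of the distance test, where only the original
  ordering is needed.

One related observation, documented here deliberately: on *null* data the
bootstrap itself is not a significance calibration. Resamples share the
per-sample distance matrices, so stable noise structure yields repeated
spurious peaks and null bootstrap frequencies well above 0.5. That is
precisely why the permutation test — which destroys the ordering rather
than resampling it — is the calibration instrument, and the package
treats it as such.

## Known limitations

* Measures are combined with equal weights after unit-sum normalization;
  fitting unequal weights would need external truth data.
* The optimal-leaf-ordering program stores per-node cost matrices;
  axes beyond a few thousand leaves would need a blocked implementation.
* The Mann-Whitney DE scheme uses the normal approximation; with fewer
  than ~15 cells per class per sample prefer the t-test or larger
  samples.
* Single-species runs zero the conservation track (with a warning), which
  changes the combination's scale relative to two-species runs.
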