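---
title: "Cluster-based CNV detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based CNV detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbcnv)
```

## The detection model

Depth-of-coverage CNV callers exploit the proportionality between local
read depth and local copy number. Most fit a parametric model to the
depth signal and threshold deviations from it. `cbcnv` instead takes an
outlier-detection view: in a segmented depth profile, CNV segments are a
small minority that sit away from the bulk of segments in a suitable
feature space, so they can be found *locally*, without committing to a
depth distribution.

Concretely, for one chromosome of one sample:

1. **Binning.** Fixed-width bins (default 2,000 bp, trailing partial bin
   dropped). A bin touching an `N` reference base is removed: reads never
   align to `N` runs, and keeping such bins manufactures fake deletions.

2. **GC correction.** Sequencing efficiency depends on GC content, so
   depth is rescaled stratum-by-stratum:
   \[ RD'_i = RD_i \cdot \frac{RD_m}{RD_{gc}}, \]
   with \(RD_m\) the mean depth over unmasked bins and \(RD_{gc}\) the
   mean over bins with the same GC content. GC fractions are rounded to
   the nearest 0.01 before grouping — "equal GC content" needs a
   granularity, and 1% strata are the common convention at these bin
   sizes. After correction every stratum mean equals \(RD_m\), which also
   preserves the global mean exactly. A stratum whose mean depth is zero
   cannot be rescaled; its bins are masked with a warning.

3. **Segmentation by fused lasso.** The corrected profile is denoised by
   the exact 1-D fused-lasso / total-variation fit
   \[ \min_\beta \tfrac12\sum_i (y_i-\beta_i)^2 +
      \lambda \sum_i |\beta_{i+1}-\beta_i|, \]
   solved with the direct non-iterative algorithm of Condat (2013) —
   exact, \(O(n)\) in practice, and fast enough that a 20,000-bin
   chromosome fits in well under a second. Maximal runs of equal fitted
   values are the read-depth segments \(RDS\). At \(\lambda = 0\)
   nothing is fused and every bin is its own segment; as
   \(\lambda \to \infty\) the fit collapses to the global mean.

4. **Feature embedding.** Each segment maps to a 2-D point:
   * \(CN_i = 2\,RDS_i/RDS_m\) — a copy-number estimate, the global,
     "vertical" view (diploid segments sit at 2);
   * \(RDSD_i\) — the mean absolute difference between the segment's
     depth ratio \(RDSR_i = RDS_i/RDS_m\) and its windowed neighbors
     (half-width \(L\)), the local, "horizontal" view. The window has
     five positional cases (first element, left margin, interior, right
     margin, last element); the right-margin case excludes the final
     element by its printed definition, and we implement it verbatim.
     Both features are invariant to rescaling the depth profile by a
     positive constant.

5. **Cluster-based abnormal scores.** k-means partitions the points;
   clusters sorted by descending size are split into *large* and *small*
   at boundary \(\theta\): the smallest \(\theta\) whose large clusters
   hold at least a fraction \(x\) of all segments **and** whose smallest
   large cluster is at least \(y\) times the largest small cluster. The
   score of a segment is its Euclidean distance to the governing
   large-cluster center (its own center if it is in a large cluster, the
   nearest large center otherwise). Scores are translation invariant and
   zero exactly on a large-cluster center.

6. **Tukey's fences calling.** With quartiles \(Q_1, Q_3\) of the score
   profile, segments scoring strictly above \(T = Q_3 + w\,(Q_3-Q_1)\)
   are CNVs (ties are normal). Runs of adjacent flagged segments merge
   into one call. A call is a **gain** when its bin-weighted mean depth
   is at or above the mean depth of the uncalled segments, a **loss**
   otherwise. Tumor and normal are processed independently; a tumor call
   with at least 50% reciprocal overlap with a normal-sample call is
   **germline**, else **somatic**.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `bin_size` | 2000 | bp | depth resolution vs. noise per bin |
| `lambda` | \(2\hat\sigma\sqrt{\log n}\) | depth units | fusion penalty; \(\hat\sigma\) = MAD of first differences / \(\sqrt2\) |
| `L` | 10 (bounded to [5, 20]) | segments | neighborhood half-width of RDSD |
| `k` | 5 | clusters | k-means granularity |
| `x` | 0.9 | fraction | large-cluster cumulative mass |
| `y` | 5 | ratio | large/small size gap |
| `w` | 1.5 | — | fence width; calls are non-increasing in `w` |
| `seed` | 0 | — | k-means restarts (runs are deterministic) |

The defaults for `bin_size`, `L`, `k`, `x`, `y`, `w` are the method's
standard settings; `lambda` has no canonical value, so the default is a
universal-threshold style rule that scales with the noise level of the
profile (robust \(\hat\sigma\) from first differences, which are
insensitive to the piecewise-constant signal). It is exposed for
override in `cbcnv()` and the CLI.

## Numerical and design choices

* **\(RDS_m\) weighting.** "The mean across all read-depth segments" is
  ambiguous: equal-weight over segments, or weighted by segment length?
  We default to the bin-weighted mean (equal to the mean of the fitted
  bin values) because it is invariant to arbitrarily splitting a segment
  in two; the segment-weighted variant is available
  (`rds_m_weighting = "segment"`).
* **Short profiles.** The RDSD window cases assume \(n > 2L\); for
  shorter profiles the windows are clipped to existing indices and
  denominators count the actual neighbor terms, with case precedence in
  the order listed above.
* **Large/small split.** The mass rule and the size-gap rule can be
  jointly unsatisfiable for any \(\theta < k\) (e.g. sizes
  50/30/10/5/5 with \(x=0.9, y=5\)). We then fall back to the mass rule
  alone, mirroring the either-condition semantics of the original
  cluster-based outlier-factor formulation; `strict = TRUE` errors
  instead. Ties between equal-size clusters sort stably by cluster id.
* **k-means.** `stats::kmeans` (Hartigan–Wong) with 10 random restarts
  under a fixed seed: a deterministic, locally optimal partition. On
  tiny instances the within-cluster SSE is checked against exhaustive
  enumeration in the tests. If fewer distinct points than `k` exist,
  `k` is lowered with a warning.
* **Quartile convention.** Linear interpolation between order statistics
  (`stats::quantile` type 7), stated because the fence value depends on
  it; it is the most widespread convention.
* **Strictness and ties.** Calls require CBAS strictly greater than
  \(T\); a call whose depth equals the normal baseline types as gain
  ("greater than or equal"); truth matching in the evaluator requires
  strictly more than 50% of the truth region covered.
* **Degenerate inputs.** Fewer than 4 segments leave the quartiles
  undefined: the affected sample yields no calls (with a warning) in the
  pipeline wrapper, while `tukey_threshold()` itself errors with
  guidance. A fully-called profile has no normal baseline and
  `assign_gain_loss()` refuses it.
* **Evaluation matching.** A truth region counts as detected when some
  call covers more than half of it; a call is a false positive when it
  detects no truth region. Several calls may detect the same truth
  region (they are not false positives for doing so); metrics are
  order-independent.

## The simulator and what it does (not) emulate

`simulate_pair()` generates the matched pair the caller expects, with
known truth: a single synthetic chromosome (default 40 Mb), per-bin
expected depth \(\lambda = \text{coverage} \cdot \text{bin\_size} /
\text{read\_length}\) (200 reads/bin at the 10×, 2 kb, 100 bp defaults),
22 embedded CNV regions per tumor sample — 12 gains (copy numbers drawn
uniformly from 3–6), 4 heterozygous losses (copy 1), 6 homozygous losses
(copy 0) — with lengths drawn from the six levels 2, 6, 10, 30, 50 and
100 kb, disjoint and bin-aligned with at least one diploid bin between
regions. Inside a region the tumor's expected depth scales by the purity
mixture \((p\,c + 2(1-p))/2\). Counts are negative binomial
(size 100, ~12% CV at depth 200; `nb_size = Inf` for Poisson) — real
WGS bin counts are overdispersed relative to Poisson, and the size is
chosen to keep that overdispersion moderate. GC varies smoothly in
[0.3, 0.6] with a quadratic depth response peaked near 0.45, so the GC
correction step is exercised non-trivially (a flat profile would make it
untestable).

Not emulated: read-level artifacts (the simulator draws bin counts, not
reads), mappability bias, germline CNVs in the normal, subclonal
heterogeneity, and replication-timing waves. Passing the recovery tests
therefore shows the pipeline recovers purity-diluted depth shifts under
realistic count noise and GC bias — not that it is robust to alignment
artifacts or to germline contamination of the baseline.

## Problem sizes used in tests and the acceptance script

Unit tests run on profiles of tens to hundreds of bins with brute-force
oracles (double-loop RDSD, explicit-loop scoring, a dual box-QP fused
lasso solver, per-base overlap counting, exhaustive k-means partitions
at n = 8). The recovery checks and the acceptance script use the full
protocol scale — 40 Mb / 20,000 bins per sample, 10 samples per purity —
which one pipeline run covers in well under a second, so the whole suite
stays interactive.

## Known limitations

* Single-chromosome processing; no joint segmentation across chromosomes.
* Copy number is estimated relative to the profile mean; no explicit
  purity/ploidy estimation, so `CN` values are diluted at low purity.
* Calls are bin-resolution; breakpoints are not refined below `bin_size`.
* `k` is fixed by the user; no automatic model selection.
* At purity 0.2–0.3, events of 1–5 bins (2–10 kb) usually stay below the
  fence — visible in the per-length evaluation breakdown — because a
  single bin's depth shift is comparable to the count noise.
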