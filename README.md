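# cbcnv — cluster-based CNV detection from tumor–normal read depth

`cbcnv` detects copy number variations (CNVs) in whole-genome sequencing
data of tumor–normal matched samples, working from binned read-depth
profiles. It is aimed at cancer genomics analyses where both gains and
losses of different lengths must be found at low tumor purity, without
assuming a parametric distribution for the read-depth signal.

## Method

Given per-bin read counts for one chromosome of one sample, the pipeline is:

1. **Binning & masking.** The genome is divided into contiguous,
   non-overlapping bins (default 2,000 bp); bins containing ambiguous
   `N` reference bases are filtered out. Bin depth is the mean read count
   RD_i.
2. **GC correction.** `RD'_i = RD_i · RD_m / RD_gc`, where `RD_m` is the
   mean depth over all bins and `RD_gc` the mean over bins with the same
   (1%-rounded) GC content.
3. **Segmentation.** The corrected profile is denoised by an exact 1-D
   fused-lasso fit, `min ½Σ(y_i−β_i)² + λΣ|β_{i+1}−β_i|`, giving a
   piecewise-constant read-depth segment profile RDS.
4. **2-D embedding.** Each segment becomes the point
   `(CN_i, RDSD_i)`: a copy-number estimate `CN_i = 2·RDS_i/RDS_m` and the
   mean absolute difference of its depth ratio to its `L = 10` windowed
   neighbors.
5. **Cluster-based abnormal scores (CBAS).** k-means (`k = 5`) partitions
   the points; clusters are sorted by size and split into *large* and
   *small* at the boundary θ (cumulative mass ratio `x = 0.9`, size-gap
   multiple `y = 5`). A point in a small cluster scores its distance to
   the nearest large-cluster center; a point in a large cluster scores
   the distance to its own center.
6. **Calling.** Tukey's fences on the score profile:
   `T = Q3 + w·(Q3−Q1)` with `w = 1.5`. Segments scoring above `T` are
   CNVs; each call is typed **gain** if its depth is at or above the mean
   depth of the uncalled segments, else **loss**; a tumor call reproduced
   in the matched normal (≥50% reciprocal overlap) is **germline**,
   otherwise **somatic**.

The package also ships a purity/coverage-aware tumor–normal read-depth
simulator with BED truth output, and an evaluation harness (50%-overlap
matching; sensitivity, FDR, precision/recall/F1; overlapping density
score `ODS = O_m · O_r`).

## Worked example

Simulate a matched pair at tumor purity 0.3, coverage 10× (22 embedded
CNVs: 12 gains, 4 heterozygous + 6 homozygous losses, 2–100 kb), call
CNVs with the default parameters, and score the calls:

```r
library(cbcnv)

sim <- simulate_pair(sim_config(purity = 0.3, coverage = 10), seed = 7)
fit <- cbcnv(sim$tumor, sim$normal, gc = sim$gc, seed = 0)
summary(fit)
#> Cluster-based CNV detection — summary
#>   segments: 417; large/small boundary theta = 2
#>   score fence: Q1 0.02083, Q3 0.0452, w 1.50 -> T 0.08177
#>   20 CNV calls:
#>  chrom    start      end type  origin       cbas
#>   chrS  1102000  1132000 gain somatic 0.08923159
#>   chrS  5634000  5656000 loss somatic 0.21699186
#>   chrS  7708000  7758000 gain somatic 0.55026669
#>   ...

evaluate_calls(cnv_calls(fit), sim$truth)
#> CNV call evaluation: 20 calls vs 22 truth regions
#>   sensitivity 0.591  FDR 0.400  precision 0.600  recall 0.591  F1 0.595
#>   by length (bp):
#>  length n_truth n_called sensitivity       fdr
#>   2e+03       3        4   0.0000000 1.0000000
#>   6e+03       5        1   0.0000000 1.0000000
#>   1e+04       3        2   0.0000000 1.0000000
#>   3e+04       2        3   0.5000000 0.0000000
#>   5e+04       6        6   0.6666667 0.1666667
#>   1e+05       3        4   1.0000000 0.0000000
```

The 417 depth segments are scored; 20 clear the fence `T = 0.082` and
become calls, all correctly somatic since the simulated normal is
diploid. As expected at purity 0.3, long CNVs (≥30 kb) are recovered
reliably while 2–10 kb events — a single bin to five bins at a 15–30%
depth shift — mostly stay below the fence; `plot(fit)` displays the
corrected depth profile with segments and shaded calls.

A thin command-line front end over the same functions is installed at
`inst/cli/cbcnv.R` with `simulate`, `call` and `evaluate` subcommands.

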