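# mzadapt

Resolution-adaptive m/z binning and multi-batch integration for Orbitrap
shotgun mass spectrometry.

## The problem

Untargeted shotgun MS (direct infusion, DESI imaging) turns every scan or
pixel into a centroided peak list. To compare thousands of scans — and to
train models on them — the continuous m/z axis must be discretized into
*buckets* so that the same chemical feature lands in the same column
everywhere. The two conventional choices both break down somewhere:

* **Constant-Da grids** (0.1 / 0.01 / 0.001 Da, as in fixed-grid
  preprocessing tools): too coarse at low mass (distinct features are
  *aggregated* into one bucket), too fine at high mass (one feature's
  centroids are *clipped* across a bin boundary once batches drift by a few
  ppm).
* **Dynamic ppm buckets** (5 / 10 ppm): a constant *relative* width, which
  still ignores how the analyzer's resolving power actually changes with
  m/z.

On Orbitrap analyzers, resolving power follows a power law

```
R(m/z) = C · (m/z)^k ,   k ≈ −0.5
```

so the narrowest credible bucket at m/z is the peak width the instrument can
resolve there:

```
w(m/z) = m/z / R(m/z)
```

`mzadapt` implements this resolution-adaptive strategy as a three-stage
protocol: (1) predict `R` at each candidate feature apex from a fitted
curve, (2) open a bucket `[apex − w/2, apex + w/2)`, (3) fuse overlapping
buckets to absorb ppm-scale mass shifts between scans, batches and
platforms. Cross-batch integration reuses stage 3: per-batch bucket sets
are concatenated and fused, and every spectrum is re-binned against the
unified feature space — no apex matching, no imputation.

The package also provides the competitor binning schemes, a ground-truth
recovery benchmark (per-feature `recovered` / `aggregated` / `clipped` /
`missed` taxonomy), binary classification metrics (F1, MCC, recall,
precision, weighted F1), a synthetic multi-batch scan generator with known
ground truth, mzML/CSV I/O, and a command-line interface.

## Worked example

Fit the resolution curve from observed (m/z, resolving power) points — here
simulated from a 70,000 @ m/z 200 instrument with 1% noise:

```r
library(mzadapt)

pts <- simulate_resolution_points(orbitrap_curve(70000), n = 200,
                                  rel_noise = 0.01, seed = 1)
fit <- fit_resolution_curve(pts)
fit
#> <resolution_curve>
#>   R(m/z) = 996299 * (m/z)^-0.5010
#>   R(200) = 70074
#>   fitted on 200 points, R^2 = 0.9989
```

The fitted exponent (−0.501) and scale recover the generating instrument
model; `tidy()`/`glance()` give the broom-style views and `autoplot(fit)`
draws the curve over the points.

Simulate a two-batch experiment (20 features in 100–500 Th, +3 ppm shift in
batch 2, the default noise floor of 50 noise peaks/Da/scan, 5% dropout —
~400,000 centroid peaks in total), then benchmark recovery:

```r
cfg <- sim_config(n_features = 20, mz_range = c(100, 500),
                  n_scans_per_batch = 10, seed = 42)
truth <- simulate_ground_truth(cfg)
peaks <- simulate_scans(truth, cfg)

benchmark_recovery(peaks, truth, bin_scheme("adaptive", curve = cfg$curve))
#> <recovery_report>
#>   20 ground-truth features, matched at +/-5 ppm
#>   recovered    20  (100.0%)
#>   aggregated    0  (0.0%)
#>   clipped       0  (0.0%)
#>   missed        0  (0.0%)
#>   recovery rate: 100.0%
```

Every feature maps one-to-one onto a unified bucket despite the inter-batch
mass shift and the dense noise. A 0.1 Da grid on the same data aggregates
almost all of them — co-binned noise drags each bucket's measured apex away
from the true feature m/z:

```r
glance(benchmark_recovery(peaks, truth,
  bin_scheme("constant", width_da = 0.1, mz_min = 100, mz_max = 500)))
#> # A tibble: 1 × 7
#>   recovery_rate recovered aggregated clipped missed n_features match_tol_ppm
#>           <dbl>     <int>      <int>   <int>  <int>      <int>         <dbl>
#> 1           0.1         2         18       0      0         20             5
```

The integrated feature matrix is an ordinary tibble, one column per unified
bucket named by apex m/z (here 7221 columns: the 20 features plus recurrent
noise candidates, as in any real untargeted feature table):

```r
integrate_spectra(peaks, bin_scheme("adaptive", curve = cfg$curve))
#> <feature_matrix> 20 observations x 7221 buckets (2 batches)
#> # A tibble: 20 × 7224
#>   observation_id batch_id label `115.9287` `118.3205` `120.0845` ...
```

The command-line interface wraps the same stages:

```sh
inst/exec/mzadapt simulate --out-dir sim/ --seed 7
inst/exec/mzadapt fit --input points.csv --output curve.json
inst/exec/mzadapt integrate --batch sim/batch1.mzML --batch sim/batch2.mzML \
    --scheme adaptive --curve sim/curve.json --output matrix.csv
inst/exec/mzadapt evaluate --scheme adaptive --curve sim/curve.json \
    --input all.csv --truth sim/truth.csv --output report.json
```

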