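# pcflow

Simulation and quantification of time-resolved phase-contrast (4D flow)
MRI in small vessels, built for studying how spatial resolution and
compressed-sensing acceleration shape flow measurements.

## The problem

Phase-contrast MRI encodes velocity into signal phase
(φ = π·v/venc), which lets 4D flow acquisitions quantify flow in any
vessel — but intracranial arteries are only 2–5 mm across, so few voxels
span the lumen. A voxel straddling the vessel wall mixes flowing and
static spins, and the scanner averages *complex signal*, not velocity: the
voxel phase is the signal-weighted argument of that mixture. Counting such
voxels at full area inside a region of interest biases the integrated
flow. The error scales with the number of boundary voxels,
N_boundary ≈ π·D/Δx, i.e. inversely with the number of voxels per vessel
diameter, **nROI = D/Δx** — the resolution-normalized quantity this
package is organized around.

`pcflow` provides:

* **Analytic phantoms** — pulsatile parabolic (Poiseuille) and Womersley
  tube flow with exact closed-form flow curves; an idealized vortex cavity
  with a known speed distribution.
* **A phase-contrast forward model** — balanced four-point (Hadamard)
  velocity encoding, complex box-average voxelization (partial volume and
  phase wrapping emerge from the model), complex Gaussian noise, and
  single-coil compressed-sensing emulation (variable-density Cartesian
  masks + iterative soft-threshold reconstruction with data consistency).
* **The quantification chain** — eddy-current background-phase plane
  correction, magnitude-threshold lumen masking, neighborhood-median
  aliasing correction, circle/spline ROI rasterization, ROI flow curves in
  mL/s averaged over stations.
* **Metrics and statistics** — percentage flow difference, normalized RMS,
  repeatability coefficient RC = 1.96·√2·SD/mean·100%, velocity-magnitude
  maps and histograms, Reynolds number, and a tidy nonparametric test
  battery (Shapiro–Wilk, Spearman, OLS fit, signed-rank, Kruskal–Wallis,
  rank-sum).

Everything user-facing takes and returns tibbles where the data are
tabular (flow curves, comparisons, test results, battery reports) and
chains with the pipe; `ggplot2` helpers (`plot_flow_curves()`,
`plot_nroi_error()`, `autoplot()`) cover the standard figures. Datasets
round-trip as NIfTI volumes with a JSON sidecar (`write_dataset()` /
`read_dataset()`).

## Worked example

Simulate a 3 mm tube (mean flow 1.2 mL/s, peak 60 cm/s, venc 60 cm/s,
24 phases / 800 ms) at three voxels per diameter, quantify it, and compare
against the analytic reference:

```r
library(pcflow)

ds  <- simulate_tube_dataset(id_mm = 3, mean_flow_ml_s = 1.2,
                             voxel_mm = 1.0, snr = Inf, seed = 1)
rec <- quantify_tube_flow(ds)                    # correct, mask, unwrap, ROI A-C
ref <- analytic_flow_curve(attr(ds, "field"), times_ms = ds$times_ms)

flow_comparison(rec, ref, diameter_mm = 3, voxel_size_mm = 1.0)
#> # A tibble: 1 x 5
#>   test_label  ref_label median_diff_pct   rms n_roi
#>   <chr>       <chr>               <dbl> <dbl> <dbl>
#> 1 mean(A,B,C) analytic             8.87 0.110     3
```

At three voxels per diameter the recovered flow overestimates the true
flow by ~9% (median over the cardiac cycle) with a normalized RMS of 0.11;
rerunning at `voxel_mm = 3/10` drops the median difference below 1%. The
resolution battery automates exactly this sweep:

```r
pv <- partial_volume_battery(2:10, battery_config(seed = 1))
dplyr::group_by(pv, n_roi) |>
  dplyr::summarise(median_diff_pct = median(median_diff_pct))
#>    n_roi median_diff_pct
#>        2          12.9
#>        3           9.01
#>        4           4.92
#>        5           1.79
#>        6           2.45
#>        7           1.49
#>        8           0.237
#>        9           1.12
#>       10           1.00
plot_nroi_error(pv)
```

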