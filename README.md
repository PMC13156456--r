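# hplvpool

Quantification of the left-ventricular (LV) blood-pool hyperpolarized
[1-13C]pyruvate signal in dynamic cardiac 13C spectroscopic imaging, for
researchers normalizing downstream metabolic readouts (myocardial lactate +
bicarbonate) by delivered pyruvate.

## The method

The summed pyruvate image (`SUMPyr`, voxel-wise sum over all dynamic
frames, flip-angle corrected by `1/sin(theta)`) is restricted to the
endocardial ROI and its `N` voxel intensities are sorted descending,
`I_max = I_1 >= ... >= I_N = I_min`. The profile is fitted with a
single-parameter exponential rank-decay model

```
I_j = I_max * exp(-B * (j - 1)),     j = 1..N
```

whose decay constant `B` summarizes how concentrated (large `B`) or diffuse
(small `B`) the blood-pool signal is. A study-adaptive threshold

```
SUMPyr >= (alpha/100) * I_max + I_min,   1 <= alpha <= floor(min alpha_max),
alpha_max = (I_max - I_min) / I_max * 100
```

retains the high-delivery core; `Pyr(alpha%)` is the trapezoidal area under
the mean SNR time curve of the retained voxels. Per-study normalized
delivery metrics — `B/Pyr(alpha%)` (numerical-fitting model),
`I_max/Pyr(alpha%)` (peak-intensity baseline), `B/Pyr(T%)` (top-`T%`
percentile baseline) — are swept across the threshold grid at the cohort
level and Pearson-correlated against the metabolic outcome (lactate +
bicarbonate SNR AUC in the mid-myocardium). The optimum is the most
negative correlation; the sweep labels noise-dominated, optimal-window and
plateau regimes. A synthetic phantom module generates single studies and
cohorts with the reported cohort structure (decay constants
0.0105 ± 0.0036, amplitudes 126–5577, ROI sizes 151–315, gamma-variate
bolus, noise-only baseline frames, planted negative metric–outcome
association) so the entire pipeline is testable without patient data.

## Worked example

```r
library(hplvpool)

spec  <- phantom_spec(seed = 7)          # 100x100 grid, 44 pyruvate frames
study <- make_study(spec)                # planted B = 0.0105, Imax = 1286
m <- compute_study_metrics(study, alpha_grid = c(1, 13, 20, 63),
                           T_grid = c(10, 50, 100))
round(c(B = m$b_value, R2 = m$r2, Imax = m$i_max, N = m$n), 4)
#>         B        R2      Imax         N
#>    0.0114    0.9812 1450.5006  216.0000
round(m$pyr_alpha, 1)
#>     1    13    20    63
#> 229.5 292.1 330.2 503.1
m$n_retained_alpha
#>   1  13  20  63
#> 212 148 117  26
```

The fitted decay constant recovers the planted 0.0105 within the 10%
spatial-heterogeneity noise; `R^2 = 0.98` matches the reported cohort fit
quality (97 ± 3%). As the threshold `alpha` rises from 1% to 63%, the
retained count falls (212 → 26 of 216) while the mean-SNR delivery term
`Pyr(alpha%)` rises (229.5 → 503.1), the same trend as the reported cohort
table (197.9 → 467.3 a.u.). `m$metric_numfit`, `m$metric_peak` and
`m$metric_percentile` hold the three normalized metrics, and `m$lac_bic`
the metabolic outcome (44.2 here).

A cohort sweep with a planted association:

```r
co <- make_cohort(20, seed = 1, grid_size = 32, keep_studies = FALSE)
sw <- sweep_metric(metrics_matrix(co, "numfit"), co$outcome$lac_bic,
                   grid = co$alpha_grid)
sw
#> <sweep_result> 63 grid points; min corr -0.718 at 2; window [1, 4]
round(sw$corr[13], 3)    # realized correlation at the planted alpha* = 13
#> [1] -0.698
```

The planted negative association is realized (about −0.6 at `alpha* = 13`
for large cohorts), but note that in this synthetic world the correlation
profile is nearly flat across thresholds, so the argmin location is
sampling noise — the methods vignette discusses why.

File-based pipelines use `write_study()`/`run_study()`/`run_cohort()`
(NIfTI-1 stacks + JSON sidecars, CSV/JSON outputs), or the CLI:

```sh
Rscript inst/cli/hp-lvpool.R phantom --out cohort_dir --n 8 --seed 1
Rscript inst/cli/hp-lvpool.R cohort --manifest cohort_dir/manifest.txt --out results_dir
```

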