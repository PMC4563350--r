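# gradsig

Signal extraction for noisy one-dimensional morphogen gradient profiles.

Quantified expression profiles of the *Drosophila* morphogen **Bicoid** —
fluorescence intensity versus position along the anterior–posterior (AP)
axis, in percent egg length (%EL) — are highly volatile: nucleus-level
measurement noise rides on a smooth underlying gradient. The classical
synthesis–diffusion–degradation (SDD) description predicts an exponential
gradient at steady state,

    B(x) = A · exp(−x / λ),   λ = √(D · τ_p),

with amplitude `A` at the anterior, length constant `λ`, diffusion
constant `D` and protein lifetime `τ_p`. `gradsig` asks the operational
question: given a noisy profile, which method best recovers the underlying
signal — the naive SDD fit itself (amplitude read at the anterior, λ from
the 1/e crossing), or generic signal-processing extractors?

The package provides, behind one common interface
(`extract_signal()` → `signal + residual = observed`):

* **singular spectrum analysis (SSA)** — Hankel trajectory-matrix SVD,
  eigentriple grouping, diagonal averaging, and w-correlation
  separability diagnostics (the package's principal method);
* **SDD fits** — the anterior-1/e benchmark and a nonlinear
  least-squares alternative;
* **ARIMA** with KPSS-based differencing and AIC order selection,
  **ARFIMA** with stepwise fractional-order estimation, **ETS**
  state-space exponential smoothing, and a **feed-forward neural
  autoregression** with restart averaging;
* a reproducible **Monte-Carlo benchmark** (`run_simulation_study()`)
  scoring every method against a known truth curve with RMSE / MAE /
  MAPE, relative RMSE against the SDD benchmark, Wilcoxon rank-sum
  comparisons, and residual diagnostics (ADF, Ljung–Box,
  signal–noise correlations).

## Worked example

Simulate one noisy gradient under the default study conditions
(`A = 100`, `λ = 20 %EL`, 101 grid points, segment noise σ = 8/12/8 AU),
crop to the 20–80 %EL analysis window, and extract the signal by SSA:

```r
library(gradsig)

spec <- simulation_spec(seed = 42)        # the default study conditions
rep0 <- generate_replicate(spec, 0)
noisy <- crop_to_ap_window(rep0$noisy, 20, 80)

ex <- extract_signal_ssa(noisy)
ex
#> <signal_extraction> method = ssa, N = 61
#>   residual sd = 10.2 AU

rmse(ex$signal, crop_to_ap_window(rep0$truth, 20, 80)$intensities)
#> [1] 0.7758563
w_correlation(ex$signal, ex$residual, ex$meta$window_length_L)
#> [1] 0.01049547
```

The extracted trend misses the truth by ~0.8 AU where the raw
observations miss it by ~10.3 AU, and the near-zero w-correlation says the
retained eigentriple and the discarded residual are essentially
w-orthogonal — signal and noise separate cleanly.

The full benchmark compares six methods on common replicates:

```r
study <- run_simulation_study(spec, n_reps = 100)
study
#> <study_result> 100 replicate(s), benchmark = sdd_anterior_efold
#>               model  rmse  mape   mae  rrmse min_rmse max_rmse
#>                 ssa 2.075 27.77 1.802 0.3247   0.4959    5.005
#>  sdd_anterior_efold 6.392 62.62 5.568 1.0000   1.6280   13.870
#>               arima 5.011 69.36 4.115 0.7840   2.9680    8.161
#>              arfima 5.923 72.58 4.627 0.9266   2.9740    8.748
#>                 ets 2.175 30.86 1.864 0.3403   0.4463    4.948
#>                  nn 6.396 73.23 4.929 1.0010   4.2180   10.370
```

Mean RMSE is each method's average distance from the true curve over 100
replicates; `rrmse` divides it by the SDD benchmark's (below 1 =
outperforms the benchmark); `min`/`max` bound the per-replicate spread.
SSA extracts the most accurate signal (RRMSE 0.32, i.e. a ~68%
improvement over the naive SDD fit), with ETS close behind; the one-step
trackers (ARIMA, ARFIMA, and the overfitting-prone neural autoregression)
retain a noise fraction and sit near the benchmark. `render_report()`
writes these tables plus a JSON manifest that re-runs to the identical
summary.

Real profiles are read with `read_profile()` (two-column CSV or
whitespace-delimited exports), windowed with `crop_to_ap_window()`, and
diagnosed with `residual_diagnostics()` and
`signal_noise_correlations()`; no external data ships with the package.

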