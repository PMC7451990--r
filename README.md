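# dynstok

Adaptive estimation of **time-varying directed connectivity** from
multi-trial neural time-series. `dynstok` implements the **Self-Tuning
Optimized Kalman filter (STOK)** — an adaptive least-squares filter with
damped-SVD regularization and a self-tuning memory decay — alongside the
classical general linear Kalman filter (KF), for fitting time-varying
multivariate autoregressive (tvMVAR) models

    Y_t = Σ_{k=1..p} A_{k,t} Y_{t-k} + ε_t

to epoched recordings (trials × channels × time). From the fitted
coefficients it derives frequency-resolved measures — squared
row-normalized partial directed coherence (PDC) and parametric power
spectral density — and ships the full validation harness used to benchmark
the filters: a regime-switching surrogate-network simulator, noise and
spatial-mixing corruption operators, and quantile-criterion ROC/AUC
scoring against ground truth.

The package is for researchers analyzing event-related M/EEG, LFP or
source-reconstructed time courses who need sub-second network dynamics
rather than static or sliding-window connectivity.

## The estimators in one paragraph

The KF baseline uses an identity state transition, replaces the process
noise with a rate-of-change term `c²I` and the measurement noise with the
trace of a recursively updated innovation covariance; a single adaptation
constant `c` governs the speed/smoothness trade-off and must be chosen
(`tune_kf_c()` implements the relative-error-variance criterion). STOK
removes the noise modeling entirely: the state update is an exponential
moving average between the previous state and a regularized least-squares
solution, `x_t = (x_{t-1} + c_t H̃⁺ z_t) / (1 + c_t)`, where `H̃⁺` is a
damped-SVD pseudo-inverse retaining ≥ 99% of design variance and the
weight `c_t ∈ [0.05, 0.95]` is recalibrated every sample from the ratio of
innovation-residual traces in two consecutive windows of length `p` — so
tracking accelerates exactly at connectivity transitions, with no free
parameter beyond the model order.

## Worked example

```r
library(dynstok)

# canonical two-node demonstration: AR(1) self-coefficients 0.9, a directed
# coupling A[1,2] = 0.5 switched on for samples 401-600 (of 1000, 200 Hz,
# 200 trials)
demo <- bivariate_demo(seed = 42)
est  <- stok_filter(demo$Y, p = 1)

mean(est$coefficients[403:598, 1, 1, 2])   # coupling inside the window
#> [1] 0.4869
mean(est$coefficients[51:1000, 1, 1, 1])   # self-coefficient, node 1
#> [1] 0.8989
range(est$c_trajectory)                    # self-tuned memory decay
#> [1] 0.0500 0.6244
which.max(est$c_trajectory)                # tracking speed peaks at the onset
#> [1] 402

# frequency-resolved directed influence 2 -> 1
pd <- pdc(est)                             # 1-100 Hz by default
round(pd$values[1, 2, c(10, 50), 500], 3)  # at 10 and 50 Hz, mid-window
#> [1] 0.701 0.112
```

The estimated coupling recovers the imposed 0.5 to within a few percent,
the self-coefficients recover 0.9, and the memory decay `c_t` rests near
its baseline 0.05 during stationary stretches while spiking at the onset
and offset of the imposed connection — the transition sensitivity that
distinguishes STOK from a fixed-`c` filter.

A full benchmark against ground truth:

```r
cfg <- experiment_config(sim = sim_config(d = 10), n_realizations = 3, seed = 1)
run_experiment(cfg)$auc
#>   realization seed filter       auc       n
#> 1           1    2     kf 0.9487984 3546000
#> 2           1    2   stok 0.9642200 3546000
#> ...
```

## Package layout

- `R/mvts.R`, `R/tvmvar-core.R` — data containers, lag-matrix and
  state/coefficient conversions, FPE order selection
- `R/kalman.R`, `R/stok.R` — the two filters
- `R/spectral.R` — PDC, parametric PSD, innovation-covariance summary
- `R/simulator.R` — surrogate networks, two-node demo, corruption operators
- `R/evaluation.R` — ROC/AUC, summed flows, baseline z-scoring, bootstrap
- `R/pipeline.R` — seeded end-to-end experiments
- `vignettes/stok-tvmvar.Rmd` — the methods vignette (model, design
  decisions, simulator scope, limitations)
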