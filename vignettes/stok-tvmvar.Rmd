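---
title: "Tracking time-varying brain networks with the self-tuning optimized Kalman filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking time-varying brain networks with the self-tuning optimized Kalman filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstok)
```

## The modeling problem

Event-related neural recordings — EEG epochs, LFPs, source time courses —
are non-stationary at the scale of tens of milliseconds, and the directed
interactions between channels reorganize just as quickly. `dynstok` models a
multi-trial recording `Y` (`N` trials × `d` channels × `T` samples) as a
time-varying multivariate autoregressive (tvMVAR) process,

$$Y_t = \sum_{k=1}^{p} A_{k,t}\, Y_{t-k} + \varepsilon_t,$$

where the `d × d` coefficient matrices `A_{k,t}` change over time and
`ε_t` is white innovation noise. All frequency-resolved quantities — the
squared row-normalized partial directed coherence (PDC) and the parametric
power spectral density — derive from the estimated `A_{k,t}`, so the whole
analysis stands or falls with how well the coefficient trajectory is
tracked.

Two estimators are provided, sharing the same lag-matrix formulation
(`build_lag_matrix()`): at each time the observed samples `z_t` (trials as
rows) are regressed on the `p` previous samples
`H_t = (Y_{t-1}, …, Y_{t-p})`.

## The classical filter and its free parameter

`kf_filter()` implements the general linear Kalman filter adapted to
multi-trial physiological data: identity state transition (a random walk on
the coefficients), process noise replaced by a rate-of-change inflation
`C²I` of the predicted error covariance, and measurement noise replaced by
the trace of an innovation covariance `R̂_t` updated recursively with gain
`c`:

$$\hat R_t = \hat R_{t-1} + c\,(E^\top E/(N-1) - \hat R_{t-1}), \qquad
K_t = P_t^- H_t^\top \big(H_t P_t^- H_t^\top + \mathrm{tr}(\hat R_t) I_N\big)^{-1}.$$

The two constants are tied (`C = c`) by default; a config override exists
but is off. Everything about this filter's behaviour hinges on `c ∈ (0, 1]`:
small values smooth but lag behind genuine transitions, large values track
fast but inject noise. `tune_kf_c()` implements the relative-error-variance
criterion (normalized one-step prediction error) for choosing `c` on a grid;
ties resolve to the smaller, smoother value. The package default `c = 0.02`
is the benchmark value used throughout the validation experiments.

## STOK: least squares, damped SVD, self-tuning memory

`stok_filter()` replaces the noise-covariance machinery with a regularized
least-squares gain. The update is an exponential moving average between the
previous state and the instantaneous least-squares solution,

$$\hat x_t = \frac{\hat x_{t-1} + c_t\, \tilde H_t^{+} z_t}{1 + c_t},$$

with two data-driven ingredients:

**Damped-SVD pseudo-inverse** (`damped_pinv()`). `H_t = U S V^\top`; each
singular component is weighted by the filter factor `s/(s² + λ)`. The
damping `λ` is set at each time step to the squared first singular value
*excluded* from the smallest component set explaining at least `θ = 0.99`
of the total energy (`λ = 0` when everything is retained). This mapping is
monotone and parameter-free, reduces to the exact pseudo-inverse for
concentrated spectra, and shrinks rather than truncates weak components.
Variance is accounted in squared singular values (energy), the conventional
reading of "explained variance". `θ = 1` disables regularization — the
ablation variant used in the noise-robustness comparisons.

**Self-tuning memory decay** (`self_tuning_c()`). The averaging weight is
recalibrated at every sample from the proportional change of innovation
residuals between two consecutive non-overlapping segments of length `p`
(NEW: `t-p … t`, OLD: `t-2p … t-p-1`):

$$c_t = \min\!\Big(b + \frac{|\mathrm{tr}\hat\Sigma^{new} - \mathrm{tr}\hat\Sigma^{old}|}{\mathrm{tr}\hat\Sigma^{old}},\; 1-b\Big), \qquad b = 0.05,$$

so `c_t ∈ [0.05, 0.95]`. When a model carried over from the immediate past
stops predicting incoming data, `c_t` rises and the filter learns faster;
in stable stretches it relaxes toward the baseline `b`.

### Design choices that were genuinely open

* *Segment residuals.* Two readings of "residuals from independent past
  models" are implemented. The default (`tuning = "innovation"`) uses the
  filter's one-step prediction residuals `z_s − H_s x_{s-1}`: these spike
  exactly when the underlying coefficients change, which is what makes
  `c_t` a usable state-transition indicator. The alternative
  (`tuning = "ls"`) fits every sample by its own instantaneous regularized
  least squares; that statistic is filter-independent but reacts only to
  changes in signal variance, not to coefficient transitions (each sample's
  own fit absorbs the new coefficients immediately), and measurably blunts
  the transition response. Both are exposed; the innovation reading is the
  default because the transition-sensitivity of `c_t` is the documented
  point of the mechanism.
* *Warm-up.* `c_t = b` until every OLD-segment sample has a full lag window
  (`t ≤ 3p`), and the first valid coefficient output is at `t = p + 1`
  (earlier samples are NaN-masked, never zero-padded). Long pre-stimulus
  baselines are recommended so the adaptation stage falls outside the
  window of interest.
* *Degenerate traces.* A zero OLD trace with positive NEW trace yields
  maximal tracking (`1 − b`); zero on both sides carries no evidence of
  change and yields `b` (this covers the all-zero-input edge case).
* *State layout.* The state is a `[d·p × d]` matrix whose lag blocks hold
  `A_{k,t}^\top`; `state_to_coefficients()` /`coefficients_to_state()` are
  exact inverses and the tensor convention `[t, k, target, source]` is fixed
  package-wide so the PDC indexing reads directly.
* *Numerical safeguards.* The KF innovation matrix is solved by Cholesky
  with a pseudo-inverse fallback past condition `1e12` (correlated trials
  can make it near-singular); `P` is re-symmetrized after every update; the
  KF and STOK loops abort on non-finite states naming the offending sample.

## Frequency-domain measures

`pdc()` evaluates
`Ā(f,t) = I − Σ_k A_{k,t} e^{-i 2π f k / f_s}` and returns the squared
row-normalized PDC
`π_{lj} = |Ā_{lj}|² / Σ_m |Ā_{lm}|²`; each target row sums to one over
sources, so the measure is a relative distribution of inflows. The identity
term is included in `Ā`: without it the transfer function would be singular
for vanishing coefficients and the white-noise PSD limit would fail.
Frequencies are in Hz with `z = e^{-i2πf/f_s}`; the default grid is 1–100 Hz
in 1-Hz steps clipped to Nyquist. `psd()` inverts `Ā` into the transfer
function `B` and returns `B Σ̂ B^*` with `Σ̂` the element-wise median
innovation covariance over the last half of valid samples
(`innovation_covariance()`), which discards the filter's adaptation stage.

## What the simulator emulates — and what it does not

`surrogate_network()` generates ground-truth models mimicking large-scale
electrophysiological networks: structural links over 60–80% of ordered node
pairs, directed interactions on half of them, positive AR(2) self-dynamics
on lags 1–2 (dominant low-frequency oscillations) drawn from the magnitude
grid 0.1–0.5 in 0.01 steps, and interaction pairs with random signs at
consecutive lags with onset delay up to 5 samples (true order 6), scaled to
half magnitude. Connectivity visits three quasi-stationary regimes of
random onset with a 150 ms floor; interaction delays, signs and magnitudes
are redrawn per regime while self-dynamics stay fixed. Trials share a
common noise component per trial (`simulate_trials()`) so the generative
noise correlates across trials at mean 0.1, sd 0.07 — the shared-component
construction is this package's own; only the target statistics are given by
the study design. Corruption operators add white observation noise at a
given linear SNR (`add_observation_noise()`; a decibel flag is provided
since the two conventions are easy to conflate) and instantaneous Gaussian
spatial mixing on a 150 × 150 mm grid (`apply_spatial_mixing()`).

Stability: a regime is accepted when its companion matrix has spectral
radius below one. Random draws from the full magnitude grid are almost
always stable at 10 nodes but essentially never at 20 or more (the radius
grows with network size); after 50 failed redraws the interaction block of
a fresh draw is therefore shrunk geometrically (factor 0.95 per step,
preserving delays, signs and relative magnitudes) until stable. At the
default 10 nodes plain rejection virtually always succeeds, so the printed
magnitude grid holds exactly there; large networks trade coefficient
magnitude for stability, which is the physically meaningful direction
(denser coupling must be weaker to remain stationary).

The simulator does not emulate: 1/f background spectra, non-Gaussian or
heavy-tailed noise, volume conduction beyond the Gaussian kernel, latency
jitter across trials, or nonlinear coupling. Passing the benchmark suite
therefore demonstrates correct tracking under the stated linear-Gaussian
conditions, not performance on any particular real recording.

`bivariate_demo()` reproduces the canonical two-node illustration: AR(1)
self-coefficients of 0.9, a directed coupling of 0.5 switched on for a
200-sample window mid-recording (samples 401–600 of 1000 at 200 Hz by
default, 200 trials).

## Validation harness

`roc_auc()` scores an estimated PDC tensor against the ground truth by
detection theory: ground truth binarized at `> 0` (or against its own
median), the estimate thresholded at 20 equally spaced quantile criteria
(1st–99th percentile) of its pooled off-diagonal distribution, sensitivity
and specificity per criterion, and the trapezoid area under the resulting
curve with anchors at (0,0) and (1,1). Cells are pooled over directed pair,
frequency and time within one network; per-network AUCs are then averaged
across realizations. Diagonal (self) cells are excluded — self-influence is
always present and would inflate sensitivity. `strongest_connections()`
restricts scoring to true links above a magnitude quantile while keeping
all absent cells as negatives (tied magnitudes are retained, so a single
repeated link does not empty the subset).

`summed_flow()`, `baseline_zscore()`, `global_connectivity()` and
`bootstrap_difference_test()` (subject-level resampling, two-sided p-values
floored at `1/n_boot`) implement the descriptive statistics used for real
event-related recordings: band-limited per-node outflow/inflow time
courses, baseline-standardized connectivity, and network-wide
time-frequency summaries.

`run_experiment()` chains simulate → corrupt → filter → PDC → ROC over
seeded realizations and returns a tidy AUC table plus a manifest (seed,
configuration, versions) sufficient to reproduce every number.

## Problem sizes and numerical expectations

The shipped test-suite and the acceptance script use: the two-node demo at
its printed size (1000 samples, 200 trials); default 10-node networks with
200 trials for the ordering and noise-trend properties (10 and 4 seeded
realizations); and the network-size sweep at 20/30/40 nodes with 5 seeded
realizations per size. On these conditions the two filters' mean AUC stays
above the fair-performance floor of 0.75, STOK exceeds the KF at its
benchmark `c = 0.02` on default noiseless networks, and STOK recovers the
demo coefficients to within ±0.05 while `c_t` stays inside [0.05, 0.95]
and the retained SVD variance never drops below 99%. The demo recovery
averages exclude `2p` samples at the window edges (transition transients)
and the first 50 samples (filter adaptation).

## Known limitations

* Multi-trial epochs only: no single-trial or real-time variant, and no
  continuous-recording windowing; trials are assumed to be temporally
  aligned realizations of the same process.
* No backward smoother and no Kalman variants with estimated noise
  covariances; these are deliberate non-goals of the design.
* The ROC harness pools cells over frequency and time; a per-frequency or
  per-time variant would weight sparse dynamics differently.
* PDC is a relative (row-normalized) measure within the Granger framework:
  it quantifies linear temporal predictability, not anatomical connection
  strength.
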