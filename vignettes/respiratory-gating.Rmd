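---
title: "Adaptive Kalman filtering and anticipatory gating of respiratory motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Kalman filtering and anticipatory gating of respiratory motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respgate)
```

## The problem

Image-guided thoracoabdominal interventions track a surface displacement
signal (optical markers, a belt, an IMU) as a surrogate for internal target
motion. Two things corrupt what the operator sees. First, measurement noise.
Second, and more importantly, latency: the tracker, the compute pipeline and
the display each add delay, so the displayed target position trails the true
one by 100–300 ms. At typical breathing velocities of ~10 mm/s this alone
produces millimetre-scale dynamic error, and an "end-of-inhale" alert raised
when the peak is *detected* arrives after the window has already opened.

`respgate` addresses both with a single state estimator: filter the noisy
delayed stream, predict it a configurable number of steps ahead to cancel
the latency, and raise the end-inspiration prompt from the *predicted*
velocity zero-crossing so the prompt leads the true peak.

## State-space model

The measured displacement is

$$z_k = X_{r,k} + C_k + v_k, \qquad v_k \sim N(0, R_k),$$

with a three-dimensional state $x = (X_r, V_r, C)$: the respiratory
displacement [mm], its velocity [mm/s], and a slowly varying baseline offset
[mm] capturing posture shifts and platform drift. The observation row is
fixed at $H = [1, 0, 1]$ by the measurement physics: displacement and
baseline add, velocity is not directly observed.

The transition is an Euler-discretised harmonic oscillator at the current
angular breathing frequency $\omega_r = 2\pi f_r$:

$$A_k = \begin{pmatrix} 1 & \Delta t & 0 \\ -\omega_r^2 \Delta t & 1 & 0 \\ 0 & 0 & 1 \end{pmatrix}.$$

This encodes the oscillatory character of breathing without committing to a
fixed waveform; cycle-shape detail beyond the fundamental is absorbed by the
process noise. The $2 \times 2$ oscillator block equals
$s\, D R(\theta) D^{-1}$ with $s = \sqrt{1 + (\omega\Delta t)^2}$,
$\theta = \arctan(\omega\Delta t)$ and $D = \mathrm{diag}(1, \omega)$, i.e. a
rotation with a per-step amplitude inflation of
$(\omega\Delta t)^2/2 \approx 8\cdot10^{-5}$ at 100 Hz — negligible over the
prediction horizons used, and corrected continuously by the measurement
updates. `run_filter()` uses this closed form for the per-step multi-step
predictions; `kf_predict_ahead()` is the reference repeated-multiplication
route, and a test asserts the two agree to $10^{-9}$.

### Adaptive components

Three quantities are re-estimated on-line, strictly causally:

* **Breathing frequency** $f_r$: reciprocal of the mean peak-to-peak
  interval over a 20 s buffer of the filtered signal, then smoothed by a
  one-pole IIR low-pass ($y \mathrel{+}= a(x - y)$,
  $a = 1 - e^{-2\pi f_c \Delta t}$, $f_c = 0.05$ Hz) and clamped to
  $[0.05, 1]$ Hz — generous around the 10–20 breaths/min resting range.
  Peaks are prominence-filtered (20% of the buffer's peak-to-peak range,
  minimum separation $1/f_{max}$); the prominence-relative rule is
  amplitude-scale-free. The buffer is decimated to ~25 Hz before peak
  detection: interval quantisation is then still below 0.5% of a breathing
  period while the scan cost drops by an order of magnitude. The raw
  estimate is refreshed every `freq_update_every = 25` samples (0.25 s); the
  IIR runs every sample, and with a ~3.2 s smoothing time constant the
  coarser refresh is numerically indistinguishable from a per-sample one.
* **Measurement noise** $R = \sigma_{noise}^2$:
  $\sigma_{noise} = \mathrm{sd}(\Delta z)/\sqrt{2}$ over the last 5 s of the
  raw stream, floored at $10^{-6}$ mm. At 100 Hz the first difference of
  smooth respiration (~0.1 mm per sample at 10 mm amplitude) is small
  relative to i.i.d. sensor noise, so differencing isolates the noise.
* **Process noise** $Q = \mathrm{diag}(q_0,\ \omega_r^2,\ \alpha\,\sigma^2_{resp})$
  with $\alpha = 0.01$ and $\sigma^2_{resp}$ the variance of the filtered
  $X_r$ over a 60 s buffer. The first diagonal is exposed as `q0`
  (default 1 mm²) rather than hard-coded, since its scale is a modelling
  choice.

The update is the standard Kalman gain with the covariance in
Joseph-stabilised form, which keeps $P$ symmetric positive semidefinite over
arbitrarily long runs (property-tested: minimum eigenvalue $> -10^{-9}$ at
every step).

### Initialisation and burn-in

$x_0 = (z_0 - m, 0, m)$ with $m$ the median of the first 2 s, and
$P_0 = 25 I$. The median split assigns the slow offset to $C$; it is exact
when the window straddles a whole cycle and biased otherwise. This bias is
not an implementation artifact: from a cold start, $X_r$ and $C$ are not
separately observable from $z = X_r + C$ until roughly one full cycle has
been seen, for any estimator — separation comes only from the oscillator
dynamics. The gating layer therefore withholds prompts for a burn-in of
`warmup_s = 10` s (two nominal cycles, also the time the template learner
needs two completed cycles), and the evaluation harness scores post-burn-in
cycles. This mirrors continuous clinical operation, where the filter is
long settled before any prompt matters.

## Anticipatory gating

The filter tracks the *delayed* measurement, so its state lags the true
respiratory phase by the latency $L$. Prompting ahead of the **true** peak
therefore requires the prediction window to cover both the latency and the
desired anticipation: `run_gating()` searches for the predicted velocity
zero-crossing within $\mathrm{round}(L/\Delta t) + \texttt{horizon\_steps}$
steps (default horizon 14 steps = 140 ms at 100 Hz). In the harmonic closed
form the crossing is analytic: with $X_r = \rho\sin\psi$,
$V_r = \rho\,\omega\cos\psi$, the peak lies $h^* = (\pi/2 - \psi)/\theta$
steps ahead; a candidate fires at the first step where $h^*$ enters the
window. Guards require the filtered displacement to be non-decreasing over
the last 10 steps (tolerance 1% of the causal running range) and within 10%
of its running cycle maximum, and at most one candidate per 2 s refractory
period (roughly the shortest plausible half-cycle at 20 breaths/min).

Every candidate then passes a dual validation against a personal breathing
template learned on-line from the last 5 completed valley-to-valley cycles
(each resampled to 100 points and normalized to $[0,1]$, then averaged):

1. normalized cross-correlation of the current cycle prefix with the
   template prefix $\ge 0.8$;
2. cycle amplitude within $\pm 50\%$ of the template mean;
3. elapsed time since the cycle-start valley within $\pm 30\%$ of the
   template's mean valley-to-peak time. (The comparison is against the
   valley-to-*peak* time, not the full period: a candidate fires near the
   peak, about half a period after the valley, so a full-period band would
   reject every valid event.)

Rejected candidates are suppressed and logged with their reason. With fewer
than two learned cycles the primary rule decides alone and the event is
flagged `template_ready = FALSE`.

Cycle segmentation accepts a velocity $-\!\to\!+$ crossing as a cycle-start
valley only while the displacement sits below its causal running mean minus
15% of the causal running range, with crossings within 1 s of an accepted
valley dropped. This rejects the velocity wiggles that occur around the flat
end-inspiration plateau, which would otherwise fragment cycles.

**Mode A** (the uncompensated baseline) detects end-inspiration
instantaneously on the delayed measurement: causal 5-sample moving average,
velocity by backward difference over a 10-sample baseline, the same trend
and refractory guards. The causal window adds a fixed ~70 ms detector lag on
top of the latency, so Mode A prompts trail the true peak by roughly
$L + 70$ ms — the behaviour the compensated mode is measured against. A
central difference would remove the lag but is non-causal and, on noisy
input, fires on noise.

## The simulator

`sim_sine()` produces the benchmark waveform: 10 mm amplitude, 5 s period —
adult resting respiration. `sim_breathing()` builds waveforms cycle by
cycle: each breath is a raised-cosine bump $A_j (1 - \cos 2\pi\tau/T_j)/2$
(a realistic flat end-inspiration plateau; within a cycle it is a pure
harmonic, which the state model represents well), with $A_j$ and $T_j$ drawn
as $\text{nominal}\times(1 + \text{jitter}\cdot N(0,1))$ and clipped away
from zero. Defaults: 10 mm / 5 s nominal, 5% cycle-to-cycle jitter for
regular breathing; 4 mm (of the physiologic 3–5 mm band) for shallow;
irregular adds Poisson pulse artifacts (4/min, 5 mm, ~0.3 s raised-cosine
bumps) and a slow linear amplitude trend ($\pm 30\%$ over the signal) for
non-stationarity. Corruption stages are explicit and composable:
`add_noise()` (i.i.d. Gaussian, default 0.3 mm — a plausible figure for an
optical tracking chain, configurable), `add_baseline_drift()` (default
1 mm / 120 s scale when used; it warns if the drift period is under five
breathing periods), and `apply_latency()` (sample-shift with leading-edge
hold; fractional latencies round to the nearest sample and the realized
value is recorded in the signal meta, from which `run_gating()` and
`compare_modes()` read it).

What the simulator does **not** emulate: 3-D chest-surface motion fields
(motion is the 1-D principal axis, mapped onto a configurable unit axis for
the 3-D error metric), airflow physics, cough/hiccup transients beyond the
pulse model, sensor dropouts, or correlated (non-white) measurement noise.
Passing the simulated benchmarks therefore demonstrates correct behaviour of
the estimation and gating logic under the stated noise model, not clinical
performance.

## Classification indices

For a signal $S$ with detected peaks $\{P_k\}$ and valleys $\{V_l\}$
(prominence $\ge 20\%$ of the global peak-to-peak range, separation
$\ge 1$ s, the same detector the gating and gold annotation use):

* mean amplitude $M_a = \frac{1}{N}\sum_i |S(t_i)|$ — computed literally on
  the raw samples; a DC offset inflates it, so an optional `detrend` flag
  subtracts the mean first (off by default, matching the index definition);
* amplitude irregularity $I_a = (\sigma(\{P_k\}) + \sigma(\{V_l\}))/2$;
* phase irregularity $I_p = (\sigma(\{T_{p,k}\}) + \sigma(\{T_{v,l}\}))/2$
  over peak-to-peak and valley-to-valley interval durations.

$\sigma$ is the population standard deviation (a flag switches to the
sample convention). Thresholds over a signal collection: the medians of
$I_a$ and $I_p$, and the 25th percentile of $M_a$ with linear interpolation
between order statistics (`quantile(type = 7)`; quartile conventions differ,
so this is pinned). Rule order: either irregularity index strictly above its
median ⇒ *irregular*; otherwise $M_a \le q_{25}$ ⇒ *shallow* (inclusive
boundary); else *regular*. Threshold derivation needs at least 3 signals.

## Rigid registration

`umeyama_rigid()` is the closed-form SVD least-squares solution for the
rotation and translation aligning matched point sets, with the reflection
corrected via the determinant sign so the result is always a proper
rotation. Scale is fixed to 1 by default (both frames are metric); the
similarity variant sits behind `allow_scale`. Degeneracy checks: pairwise
distances $> 10^{-9}$ mm and smallest-to-largest singular value ratio of the
centred source $> 10^{-6}$. Correspondence is by label when point sets carry
labels, by row order otherwise. No anatomical axis convention is assumed;
any frame flip appears in the rotation.

## Evaluation protocol

`compare_modes()` corrupts one ground-truth signal with seeded noise and
latency, feeds the *same* measurement stream to both modes, and scores both
against the same gold annotation: Mode A displays the raw delayed
measurement; Mode B displays the filter's latency-compensated prediction
($h = \mathrm{round}(L/\Delta t)$ steps). The target-point error is
$\mathrm{TPE}(t) = \lVert P_{true}(t) - P_{displayed}(t)\rVert_2$ after
mapping the 1-D displacement onto a unit motion axis (default
superior–inferior), summarised as mean, population sd and RMSE (so
$\mathrm{RMSE}^2 = \mathrm{mean}^2 + \mathrm{sd}^2$ exactly).

Gold end-inspiration times come from the clean signal via the shared
extremum detector with parabolic sub-sample refinement. Prompt matching is
one-to-one, closest pairs first, with a maximum matching radius of half the
median gold interval so a prompt is never attributed to a different cycle;
unprompted cycles count as misses for accuracy and contribute no
$\Delta T = T_{prompt} - T_{gold}$. Accuracy is the percentage of gold peaks
with a matched prompt inside a $\pm 300$ ms tolerance window — the window is
not stated by typical gating protocols and is exposed as a parameter; 300 ms
comfortably contains an uncompensated detector at 200 ms latency, so the
contrast between modes shows in $\Delta T$, not in a degenerate 0% baseline.

Problem sizes: the bundled checks use a 310 s sine (60 scored cycles after
burn-in), five 520 s jittered-breathing waveforms (~100 scored cycles each),
ten 60 s paired mode comparisons, and 100 random-transform registration
trials — large enough for stable statistics while keeping a full run in the
tens of seconds.

## Known limitations

* A single harmonic plus baseline cannot track cough-like transients;
  irregular waveforms degrade prediction accuracy, and the template
  validation is the guard that suppresses (not fixes) those prompts.
* The frequency estimator needs at least two prominent peaks in its buffer;
  until then the initial guess (`f0`, default 0.2 Hz) holds.
* Within ~one breathing cycle of a cold start the displacement/baseline
  split is unidentifiable; prompts are withheld during the burn-in.
* The noise estimator assumes the high-frequency content of the stream is
  sensor noise; strongly non-smooth true motion inflates $R$ and slows the
  filter's response.
* `apply_latency()` models a constant integer-sample delay; latency jitter
  is not modelled.
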