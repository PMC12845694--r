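# respgate

Respiratory motion makes image-guided thoracoabdominal interventions hard:
the target drifts by up to 2 cm over a breathing cycle, and every display
chain (optical tracker → compute → headset/screen) adds a latency of the
order of 100–300 ms, so what the operator sees is always where the target
*was*. `respgate` is an R toolkit for the signal-processing core of
latency-compensated respiratory navigation:

- **Adaptive Kalman filtering** of a 1-D respiratory displacement stream with
  a harmonic state-space model, on-line frequency estimation and adaptive
  noise covariances, plus multi-step-ahead prediction that cancels the
  display latency.
- **Anticipatory end-inspiration gating**: predictive detection of the flat
  end-inspiration plateau (the preferred puncture window), validated against
  an on-line-learned personal breathing template, emitting prompts *before*
  the true peak.
- **Breathing-pattern classification** (regular / shallow / irregular) from
  amplitude and rhythm irregularity indices.
- **Rigid point-set registration** (Umeyama) of fiducial correspondences
  between an imaging frame and a world/tracker frame.
- A **seeded waveform simulator** (sine, regular, shallow, irregular
  breathing; noise, baseline drift, latency) and an **evaluation harness**
  for target-point error and prompt-timing statistics.

Everything is tibble-first: signals, traces, events and reports are tibbles,
so the pieces compose with the pipe and `dplyr`; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## The model

The displacement measurement is modeled as `z_k = Xr_k + C_k + v_k` with
state `x = (Xr, Vr, C)`: respiratory displacement [mm], velocity [mm/s] and
a slowly varying baseline offset [mm], `v_k ~ N(0, R)`. The transition is a
locally harmonic oscillator at the current breathing frequency `f_r`,

```
A = | 1        dt  0 |
    | -w^2 dt  1   0 |        w = 2 pi f_r,
    | 0        0   1 |
```

with `f_r` re-estimated on-line from peak intervals of the filtered signal
(20 s buffer, 0.05 Hz one-pole IIR smoothing), measurement noise
`R = sigma_noise^2` from first differences of the raw stream, and process
noise `Q = diag(q0, w^2, alpha * sigma2_resp)` with `alpha = 0.01`.
Predictions `Xr_hat(k + h | k) = [1 0 0] A^h x_k` propagate the state `h`
steps ahead; with `h = latency / dt` the displayed position is
latency-compensated, and a further 140 ms horizon drives the anticipatory
end-inspiration prompt.

## Worked example

Simulate the benchmark waveform (10 mm amplitude, 5 s period), corrupt it
with 0.3 mm measurement noise and 200 ms latency, and compare uncompensated
display + instantaneous detection (Mode A) against Kalman-compensated
display + predictive gating (Mode B):

```r
library(respgate)

truth <- sim_sine(amplitude_mm = 10, period_s = 5, duration_s = 120)
ev <- compare_modes(truth, noise_sd_mm = 0.3, latency_s = 0.2, seed = 7)
ev
#> <resp_eval> noise 0.3 mm, latency 0.2 s, tolerance +/-0.3 s
#> # A tibble: 2 x 13
#>   mode  tpe_mean tpe_sd tpe_rmse tpe_max tpe_n accuracy_pct dt_mean_ms dt_sd_ms
#> 1 A        1.60   0.805    1.80     3.45 12000         81.8       165.     69.5
#> 2 B        0.327  0.305    0.447    2.62 12000        100        -139.     14.6
```

Reading the numbers: with no compensation the displayed target trails the
true one, giving a mean target-point error (TPE) of 1.60 mm and prompts that
arrive on average 165 ms *after* the true end-inspiration. With the filter,
mean TPE drops to 0.33 mm and every evaluated cycle gets a prompt on average
139 ms *before* the true peak (negative Delta_T) — preparation time for the
operator. `autoplot(ev)` plots the two TPE traces.

Registration of a five-marker calibration plate between the CT frame and
the tracker/world frame:

```r
ct <- point_set(paste0("qr", 1:5),
                matrix(c(0, 0, 0,  60, 0, 5,  60, 60, 0,
                         0, 60, 8,  30, 30, 25), ncol = 3, byrow = TRUE))
world <- apply_transform(list(R = Rz20deg, t = c(120, -40, 15), scale = 1), ct)
umeyama_rigid(ct, world)
#> <rigid_transform> n = 5 points, scale = 1, fiducial RMSE = 1.441e-14 mm
#> R:
#>          [,1]      [,2] [,3]
#> [1,] 0.939693 -0.342020    0
#> [2,] 0.342020  0.939693    0
#> [3,] 0.000000  0.000000    1
#> t:  120, -40, 15  mm
```

A thin command-line front end is installed with the package
(`inst/cli/respgate.R`) with subcommands
`simulate | filter | gate | classify | register | evaluate | demo`.

## Documentation

The methods vignette (`vignettes/respiratory-gating.Rmd`) describes the
state-space model and its assumptions, the adaptive estimators, the gating
and validation rules, the simulator, every tunable parameter with units and
defaults, and the known limitations.
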