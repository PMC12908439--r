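# pronypv

Prony analysis of left-ventricular pressure and volume signals.

Conductance-catheter recordings of left-ventricular (LV) pressure (mmHg) and
volume (µL) are cyclic, uniformly sampled signals. `pronypv` decomposes such
a record into a sum of exponentially damped cosines

```
y(t_k) = Σ_{i=0}^{N−1} A_i e^{σ_i t_k} cos(2π f_i t_k + φ_i)
       = Re Σ_i C_i μ_i^{τ_k},     μ_i = e^{σ_i + 2πj f_i},  C_i = A_i e^{jφ_i}
```

and analyzes the complex poles μ_i and coefficients C_i that result. Unlike
a Fourier series, the decomposition yields a *damping spectrum* σ[f] in
addition to amplitude A[f] and phase φ[f], supports stability analysis
(poles on/inside the unit circle are stable, outside unstable), and gives
every fitted signal an analytic Laplace transform — so two fits (pressure
and volume) combine into an analytic pressure→volume transfer function
Z(s) with Bode curves.

The pipeline is the classical linear-prediction route:

1. **Linear prediction** — solve the Hankel system `[d] = [D][a]` for the
   prediction coefficients (least squares over all available rows).
2. **Poles** — eigenvalues of the companion matrix of the characteristic
   polynomial `x^N − a_0 x^{N−1} − … − a_{N−1}`.
3. **Coefficients** — Moore–Penrose pseudoinverse solve of the Vandermonde
   system `Y = V^T C` with entries `μ_i^{k/d}`, where the time-scaling
   factor `d` counters the notorious ill-conditioning of Vandermonde bases
   at high sampling rates. `d` is optimized by maximizing R² over a
   logarithmic grid with golden-section refinement; the number of terms `N`
   is a hyperparameter searched up to the cap `floor(M/2)`.

Target users are cardiovascular physiologists and biomedical-signal
engineers working with multi-beat PV-loop data (typical records: 1 s at
1000 Hz from rodents at ~420 bpm), but nothing in the method is specific to
hearts — any uniformly sampled real signal works. A seeded generator of
pulsatile pressure/volume waveforms with exact harmonic ground truth is
included, so every stage can be validated without animal data.

## Worked example

```r
library(pronypv)

pv  <- make_pv_waveforms(pv_sim_config(noise_sd = 0.8, seed = 1))
fit <- prony_fit(pv$pressure)           # auto N, auto d
fit
#> <prony_model 'pressure': N = 450, d = 1, SR = 1000 Hz, M = 1000, R^2 = 0.999162>

dominant_frequency(fourier_power_spectrum(pv$pressure))
#> [1] 7

pole_metrics(fit, subset = "stable")
#> <pole_metrics (stable, 326 poles): mean angle 29.22 deg, dispersion 0.1954,
#>  top-5 distance 0.2901, 2 off circle (>= 0.2), 326 stable / 124 unstable>

mvol <- prony_fit(pv$volume)
tf <- build_transfer_function(fit, mvol)
bc <- bode(tf)                          # 1..100 Hz, 1 Hz steps
bc[bc$frequency_hz == 7, ]
#>   frequency_hz magnitude_db magnitude_linear phase_deg masked
#> 7            7    -17.84349        0.1281815  202.5824  FALSE
```

Reading the output: the auto search settled on `N = 450` of the admissible
500 terms and scale `d = 1`, reconstructing the noisy pressure waveform
with R² = 0.9992. The Fourier power spectrum peaks at 7 Hz — the 420 bpm
heart-rate fundamental. Of the 450 poles, 326 are stable; two stable poles
sit at least 0.2 radial units off the unit circle (strong damping), and the
importance-weighted mean pole angle is ~29°. At the heart-rate fundamental
the pressure→volume transfer function has magnitude −17.8 dB (0.128 in
linear units: µL-scale volume oscillations are larger than mmHg-scale
pressure ones at 7 Hz).

A stable-poles-only refit (`stable_refit(pv$pressure, fit)`) drops the 124
unstable poles and re-solves the coefficients; on heavily overfitted noisy
models the R² loss from discarding unstable poles can be large, which is
itself a finding about how much signal content those poles carry.

A thin command-line driver ships in `inst/scripts/pronypv`
(`simulate`, `fit`, `spectra`, `poles`, `transfer`, `bode`, `run`).

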