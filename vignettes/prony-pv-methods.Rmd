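---
title: "Prony analysis of pressure–volume signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prony analysis of pressure-volume signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pronypv)
```

## The model

A uniformly sampled real signal $y(t_k)$, $t_k = k/\mathrm{SR}$, is fitted
to a sum of exponentially damped cosines

$$y(t_k) \;=\; \sum_{i=0}^{N-1} A_i \, e^{\sigma_i t_k}
  \cos(2\pi f_i t_k + \phi_i),$$

which, by Euler's formula and the assumption that the signal is real,
collapses to the pole form

$$y(t_k) \;=\; \mathrm{Re}\sum_i C_i\,\mu_i^{\tau_k}, \qquad
  \mu_i = e^{\sigma_i + 2\pi j f_i},\quad C_i = A_i e^{j\phi_i}.$$

The decomposition is linear in two stages once the poles are known, which
is what makes the classical linear-prediction route fast:

1. **Linear prediction.** Each sample is expressed as a linear combination
   of the $N$ samples preceding it; stacking all available prediction rows
   ($l = N,\dots,M-1$) gives a Hankel system $[d] = [D][a]$ solved by least
   squares (`solve_linear_prediction`). Using every row rather than only
   the square $2N$-sample block makes the estimate an honest least-squares
   fit when $M > 2N$ and is identical when $M = 2N$.
2. **Poles.** The prediction coefficients define the monic characteristic
   polynomial $x^N - a_0 x^{N-1} - \dots - a_{N-1}$, whose roots — the
   poles — are computed as the eigenvalues of its companion matrix
   (`poles_from_lp`).
3. **Coefficients.** With poles fixed, $Y = V^{T}C$ is a (complex)
   Vandermonde least-squares problem solved by a truncated Moore–Penrose
   pseudoinverse (`fit_coefficients`).

The admissible model order is capped at $N \le \lfloor M/2 \rfloor$: the
linear-prediction stage consumes two samples per pole (one equation, one
lag), the Prony analogue of the Nyquist constraint. Requests above the cap
are refused rather than truncated.

### The time-scaling factor $d$

Vandermonde matrices built from $\mu_i^{k}$ at high sampling rates are
ill-conditioned: hundreds of poles packed near $1 + 0j$ raise powers up to
$k = M-1$ with enormous dynamic range. The implementation therefore fits
the basis $\mu_i^{k/d}$ and chooses $d$ by maximizing the coefficient of
determination $R^2$ of the full fit. At $d = 1$ the basis is the exact
index-time model; $d > 1$ compresses all dampings and frequencies jointly,
trading representational exactness for conditioning. For signals that are
exactly representable the optimizer is expected to return $d \approx 1$
(the suite asserts the maximization contract, not a particular value).

"Gradient ascent" over a quantity as cheap and as potentially non-smooth
as $R^2(d)$ is fragile; the search here is deterministic and
derivative-free: a 25-point logarithmic grid on $[1, \mathrm{SR}]$
followed by golden-section refinement of $\log d$ to a relative tolerance
of $10^{-3}$ (i.e. $d$ resolved to ~0.1%, far below any observable change
in $R^2$ for these signals). Crucially, the search scores each candidate
$d$ with the *same* truncated-pseudoinverse solver used for the final
coefficients. During development a faster QR-based scorer was tried and
rejected: at ill-conditioned $(N, d)$ combinations the QR fit and the
truncated-pseudoinverse fit diverge wildly, and the optimizer then selects
a $d$ at which the returned model is poor. Scoring what you return removes
that failure mode by construction.

### Model-order search

With `n_poles = "auto"` the order is treated as a hyperparameter and the
$R^2$-maximizing candidate is kept. The default candidate grid is the
multiples of $\lfloor M/20 \rfloor$ up to $\lfloor M/2 \rfloor$ (ten
candidates at any $M$), which for the study-scale $M = 1000$ spans
$N = 50, 100, \dots, 500$. The grid is configurable (`candidates =`); no
search rule finer than this is claimed.

## Key tunables

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_poles` | `"auto"` | – | model order; capped at $\lfloor M/2\rfloor$ |
| `scale_d` | `"auto"` | – | Vandermonde conditioning knob, $\ge 1$ |
| `sv_cutoff` | $10^{-13}$ | relative | singular values below `sv_cutoff`·$\sigma_{\max}$ are truncated in the pseudoinverse; rank-deficient bases are expected, not errors |
| `threshold` (pole metrics) | 0.2 | radial units | a pole at least this far from the unit circle (either direction) counts as significantly damped |
| Bode grid | 1–100 Hz, step 1 | Hz | physiologically relevant band for rodents |
| stability `tol` | 0 | radial units | $|\mu| \le 1 + tol$ counts stable; the default applies the definition exactly, a small positive value absorbs round-off for poles numerically on the circle |

## Pole analysis

Stability is purely geometric: $|\mu| \le 1 \Leftrightarrow \sigma \le 0$.
`stable_refit` keeps the stable poles and re-solves only the coefficients
against the original signal — the pole set is never re-estimated, so the
operation is idempotent and never increases $N$.

`pole_metrics` summarizes a pole diagram with importance weights
$\alpha_i = |C_i| / \max_i |C_i|$:

* **Mean angle** — the importance-weighted mean of the principal pole
  angles, $\sum \alpha_i \theta_i / \sum \alpha_i$, in degrees. The
  alternative normalization by $\sum \theta_i$ (available as
  `as_printed = TRUE`) fails the single-pole sanity check — the "mean
  angle" of one pole would equal its importance rather than its angle —
  and flips sign with the angle sum, so the importance-normalized form is
  the default. Angles are principal values in $(-180°, 180°]$, treated
  linearly; no circular averaging is applied.
* **Dispersion** — $1/s$ with $s$ the $n-1$ standard deviation of the raw
  $|C_i|$. It is therefore *not* invariant to rescaling the signal
  (dispersion scales inversely with a common coefficient factor); the
  importance vector and all ratio comparisons are invariant. When all
  $|C_i|$ are equal $s = 0$ and dispersion is reported as $+\infty$ with a
  flag rather than an error.
* **Unit-circle deviation** — distances $\big||\mu_i| - 1\big|$, counted
  inward and outward; reported as the count of poles at least `threshold`
  away and the mean of the five largest distances. With fewer than five
  poles all of them are averaged and the result flagged. "Top five" ranks
  by distance only, not by importance.

## Spectra

Real signals produce conjugate pole pairs; spectra fold each pair onto its
$f \ge 0$ representative with the pair's coefficient magnitudes summed, so
a unit-amplitude cosine appears as a single point of amplitude 1. Damping
and frequency are converted to physical units by the factor
$\mathrm{SR}/d$ before plotting/export.

The Fourier power spectral density uses $|{\rm DFT}|^2/M^2$ with one-sided
doubling of every bin except DC and (for even $M$) Nyquist; with this
normalization total one-sided power equals the mean squared signal, and
the test suite checks that Parseval identity to $10^{-8}$. The DC bin is
kept — dropping it would break Parseval — but `dominant_frequency()`
excludes it by default when locating the spectral peak, because for a
baseline-offset physiological signal the zero-frequency bin reflects the
mean level (e.g. mean LV pressure), not pulsatile content; with it
excluded the synthetic pressure waveform peaks at the heart-rate
fundamental.

The Fourier-series comparator fits a truncated series on the record-length
fundamental by least squares rather than coefficient integration, so it
remains well defined when the record holds a non-integer number of cardiac
cycles — exactly the regime in which series truncation shows edge effects.
With poles placed evenly on the unit circle at the Fourier frequencies,
the Prony machinery spans the same space as the truncated Fourier basis
and reproduces its fit; the suite asserts this equivalence to $10^{-6}$.

## Transfer function and Bode curves

Each folded real component has the closed-form Laplace transform

$$\mathcal{L}\{A e^{\sigma t}\cos(2\pi f t + \phi)\}(s)
  = A\,\frac{\cos\phi\,(s-\sigma) - 2\pi f \sin\phi}
            {(s-\sigma)^2 + 4\pi^2 f^2},$$

verified in the suite against direct numerical quadrature of
$\int_0^\infty f(t) e^{-st}\,dt$ (truncated where the integrand envelope
falls below $10^{-10}$) to $10^{-4}$ relative error. The $\sin\phi$ form
of the numerator is used throughout; the quadrature cross-check is what
pins that choice down.

The pressure→volume transfer function $Z(s)$ is the ratio of the two
component-sum transforms. Its poles are the pressure-model poles and its
zeros the volume-model poles, so the two fitted pole diagrams double as
"pseudo-pole" diagrams of $Z$ and are analyzed with the same
`pole_metrics` machinery. The rational form is deliberately *not*
simplified to a minimal pole–zero representation.

Bode curves sample $Z(2\pi f j)$ on the 1–100 Hz grid. Magnitude is
reported in dB ($20\log_{10}|Z|$) with the linear magnitude exported
alongside, phase in degrees, unwrapped along the grid. Singular grid
points — a vanishing denominator, or a closed-form component pole landing
exactly on a grid frequency, which happens whenever an undamped component
sits at an integer frequency — are masked (`NA`) and flagged rather than
aborting the curve; point evaluation (`evaluate_tf`) by contrast refuses
singular points with an error, since there is no curve context in which to
mask. Composite curves average magnitude (dB) and phase (degrees)
pointwise across animals/time points, excluding masked points per
frequency; complex-domain averaging is deliberately not used, matching
how plotted curves are averaged.

## The synthetic generator

`make_pv_waveforms` emulates what the method needs from a catheterization
record — strong cyclicity at a known fundamental, a realistic harmonic
roll-off, configurable physiological ranges, seeded measurement noise —
without attempting hemodynamic realism (no elastance model, no Windkessel
afterload, no beat-to-beat variability). Defaults: 420 bpm (7 Hz
fundamental), 1000 Hz, 1 s, pressure 80–120 mmHg, volume 150–350 µL
(typical anesthetized-rat LV values), 8 harmonics with $1/k$ amplitude
decay and fixed phases $-k\pi/3$, volume harmonics counter-phased against
pressure (filling while pressure falls). The harmonic construction is
intentional: the noiseless waveforms are *exact* finite Prony models
(DC + 8 undamped cosine pairs, 17 poles), so recovery tests have
closed-form ground truth. The affine rescaling to the configured ranges
preserves that structure.

What passing tests on this generator do **not** show: robustness to
baseline drift, arrhythmic beats, catheter artifacts, non-white noise, or
model misspecification — real records are not finite sums of damped
cosines. The generator's role is to validate the algebra and the
numerics, not to certify field performance.

All randomness flows through the single `seed` in the configuration; the
generator saves and restores the session RNG state so simulation does not
perturb user code.

## Numerical choices and degenerate inputs

* Pseudoinverse truncation at $10^{-13}\sigma_{\max}$ (configurable);
  a fully truncated basis returns zero coefficients rather than failing.
* Hankel rank detection at tolerance $10^{-12}$: Prony systems are
  routinely ill-conditioned without being singular, and the scale factor
  $d$ is the designed remedy; only genuine singularity (e.g. an all-zero
  signal) triggers the warning + minimum-norm fallback.
* Pole ordering: descending magnitude with magnitudes equal to 10
  significant digits treated as ties, broken by ascending phase — makes
  root ordering stable across LAPACK versions. Model components are
  ordered by descending $|C|$ (importance), ties by ascending phase, so
  "top-$k$" selections are deterministic.
* Zero poles ($|\mu| = 0$) yield damping $-\infty$; the component is
  flagged and retained.
* $R^2$ is undefined for constant observed signals and errors explicitly;
  it may be negative for fits worse than the mean.
* Overflowing pole powers (large $|\mu|$, small $d$) are treated as
  $R^2 = -\infty$ during the scale search and as an explicit error in a
  direct `fit_coefficients` call.
* Phases are wrapped to $(-\pi, \pi]$ everywhere (principal values).

## Problem sizes

Acceptance-level checks run at the full study scale (1 s at 1000 Hz,
auto-$N$ up to 500 terms); unit tests exercise the same code paths at
100–500 samples and 100–250 Hz, where noiseless recovery is
well conditioned enough to assert $10^{-6}$-level parameter equality and
$R^2 \ge 1 - 10^{-10}$.

## Known limitations

* The linear-prediction route shares the classical Prony sensitivity to
  noise in the pole-estimation stage; the scale search mitigates the
  coefficient stage only. Total-least-squares and matrix-pencil variants
  are out of scope by design.
* Long, highly sampled records (beyond ~10 s at 1000 Hz) push the Hankel
  and Vandermonde systems beyond what this pipeline conditions well.
* Prony frequency spectra of overfitted models do not represent physical
  frequencies; interpret amplitude/damping spectra of large-$N$ fits with
  care (the package reports them as computed).
* Stable-only refits of heavily overfitted noisy models can lose
  substantial $R^2$: unstable poles of such fits carry real signal
  content. This is a property of the decomposition, not a bug in the
  refit.
* On noisy signals the auto-$N$ search tends toward the upper end of its
  candidate grid (more terms always fit noise better); if parsimony
  matters, supply a candidate grid or a fixed $N$.
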