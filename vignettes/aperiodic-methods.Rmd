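---
title: "Measuring aperiodic neural activity: models, measures, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring aperiodic neural activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neuro-electrophysiological time series contain a prominent non-rhythmic
component whose power spectrum decays approximately as 1/f^χ. The exponent
χ is dynamic and physiologically meaningful, but it is quantified across
the literature by a patchwork of measures developed in different
traditions: correlation-based (autocorrelation decay time), fluctuation
scaling (DFA, rescaled range), fractal geometry (Higuchi, Katz, Petrosian
dimensions), signal-descriptive (Hjorth parameters), algorithmic
complexity (Lempel-Ziv), information theory (approximate, sample,
permutation, spectral entropy), and direct frequency-domain fits of the
spectral exponent. `aperiodica` implements this battery together with
ground-truth simulators and a comparison harness, so the relationships
between the measures can be established on signals whose generating
parameters are known.

## Signal models

**Power-law ("colored") noise.** `sim_powerlaw()` draws Gaussian white
noise and rotates its amplitude spectrum about a 1 Hz anchor by
(f / 1 Hz)^(−χ/2), zeroing the DC bin, then returns to the time domain and
z-scores. The anchor frequency only scales amplitudes (which z-scoring
removes); 1 Hz is chosen to match the lower bound of the standard spectral
fitting range. The result has a full-band f^(−χ) spectrum down to the
lowest resolvable frequency — it is *not* high-pass filtered, so for
χ ≥ 1.5 slow drifts are a real (and realistic for unfiltered recordings)
part of the signal.

**Knee signals.** `sim_synaptic_knee()` uses a physiologically inspired
model: a Poisson event train (1000 sources × 2 events/s, collapsed into
one rate-scaled train) convolved with a causal single-exponential kernel
exp(−t/τ) with instantaneous rise. A white (Poisson) drive through this
kernel has a Lorentzian spectrum — flat below, χ ≈ 2 above a knee at
f ≈ 1/(2πτ). The τ grid used in evaluations
(0.005, 0.015, 0.030, 0.050, 0.075 s) moves the knee from ~32 Hz down to
~2 Hz.

**Oscillations.** `sim_oscillation()` produces sinusoidal cycles at a
center frequency; with `burst_prob < 1` each whole cycle is independently
present or silent (the bursting unit is the cycle; the underlying phase
keeps advancing through silent cycles by default, with a
`phase_continuous = FALSE` alternative that restarts each present cycle at
phase zero — the published protocols do not pin this down, so both are
exposed). Nonzero `bandwidth` turns the pure tone into a narrowband
process by frequency-modulating with a smoothed random walk whose spread
is bandwidth/2 (the bandwidth convention throughout is 2 Gaussian standard
deviations).

**Combination.** `combine_signals()` z-scores each component and returns
`z(aperiodic) + sqrt(rel_power) · z(periodic)`, so `rel_power` is the
variance of the periodic component relative to the aperiodic one, and the
combined variance is 1 + rel_power for uncorrelated components. This
variance-ratio semantic is a deliberate decision: "relative power" is
otherwise ambiguous, and a variance ratio makes the ground-truth column of
every sweep directly interpretable.

**Simulated spectra.** `sim_power_spectrum()` builds
log10 P(f) = offset − log10(k + f^χ) + Σ Gaussian peaks + N(0, noise_sd),
with peaks parameterized by center frequency (Hz), height (log10 power
units) and bandwidth (Hz = 2 SD). Peak heights default to the grid
{0.15, 0.25, 0.5, 1.0, 1.5}, bandwidths to {1.0, 1.5, 2.0, 2.5} Hz, and
center frequencies to draws from 3–34 Hz. The empirical peak-frequency
occurrence table from large MEG datasets is not redistributable here, so
`sample_peak_cf()` accepts any user table and defaults to uniform — a
caveat for anyone comparing against peak-frequency-sensitive results.
`noise_sd` defaults to 0.005 log10 units, enough to make fits non-trivial
without dominating small peaks.

## Measure settings (defaults)

| measure | settings | notes |
|---|---|---|
| autocorrelation | max_lag 250 samples, step 1 | biased (1/n) estimator |
| AC decay time | max_lag 1500, step 2, level 0.5 | censored at max_lag if never reached |
| Hurst (R/S) | 10 log-spaced scales, 0.1–2.0 s | non-overlapping windows, per-window mean removed |
| DFA | 10 scales, 0.1–2.0 s, degree 1 | profile = cumsum of centered signal, OLS slope |
| Higuchi | kmax 10 | slope of log L(k) vs log 1/k |
| Katz, Petrosian | — | closed-form |
| Lempel-Ziv | normalize FALSE | median binarization, LZ76 parsing |
| ApEn / SampEn | order 2, r = 0.2 sd | Chebyshev distance; SampEn excludes self-matches |
| permutation entropy | order 3, delay 1 | ties broken by temporal order |
| spectral fits | 1–50 Hz (fixed), 1–100 Hz (knee) | Welch: 2 s Hann segments, 50 % overlap |
| specparam | 8 peaks, widths 1–8 Hz, threshold 2 SD, min height 0.05 (fixed); 12 peaks, min height 0.1 (knee) | |
| IRASA | h = 1.1–1.95 step 0.05 | geometric mean per h pair, median across h |

Several conventions are decisions rather than givens, recorded here
because they shift values: the ApEn/SampEn tolerance (unstated in most
reports) uses the field-standard 0.2·sd; Lempel-Ziv binarizes at the
median (robust to skew); ordinal-pattern ties are broken by temporal order
(a stable argsort — tie handling visibly shifts permutation entropy on
quantized data); the autocorrelation uses the biased estimator;
degenerate inputs (constant signals) raise a typed error rather than
silently returning NaN, and the batch harness converts that error into a
flagged, censored row.

## Spectral parameterization

`specparam()` follows the iterative fit-and-remove scheme: (1) a robust
aperiodic fit — an initial least-squares fit, after which only bins whose
flattened (data − fit, clipped at 0) value lies at or below a low
percentile are kept for a refit, which anchors the aperiodic component
under the peaks; (2) iterative peak extraction from the flattened
spectrum — the largest residual maximum is taken while it exceeds
max(threshold · SD, min height), its width guessed from the half-height
span and clamped to the width limits; (3) a joint bounded multi-Gaussian
refit (centers within ±1.5 guessed SD, heights ≥ 0, widths within
limits); (4) a final aperiodic fit on the peak-removed spectrum; (5) R²
and mean absolute error in log10 space. The knee form
offset − log10(k + f^χ) is fit by bounded L-BFGS-B (k ≥ 0); the fixed form
reduces to linear least squares. Optimizer failure returns a flagged
unsuccessful model, not an exception, so batch sweeps always complete.

Of the direct line fits, `ols`/`rlm`/`ransac` fit log10 P against
log10 f; `exp` fits the exponential 1/f form offset − log10(k + f^χ) in
semi-log space by Levenberg-Marquardt. RANSAC uses 2-point minimal
samples, 100 iterations, a MAD-scaled inlier threshold from an initial
OLS fit, and an internal fixed seed so results are deterministic. The
optional exclusion band for all line fits defaults to 7–14 Hz (the alpha
band), matching the common "fit around alpha" practice.

`irasa()` resamples the signal by h and 1/h for each factor h (rational
polyphase resampling; the default h grid in 0.05 steps is exact at
denominator 20), evaluates both Welch spectra on the original frequency
grid, takes their geometric mean, and reduces across the h set by the
median (robust to individual factors landing a displaced peak on top of a
harmonic). Scale-free spectra are invariant under this construction;
spectral peaks are displaced and attenuated. The residual
(original − aperiodic) estimates the periodic component. IRASA assumes a
single scale-free regime: on knee spectra the resampling mixes the two
regimes and the recovered exponent is biased — the package's tests verify
this known failure mode and that the knee-mode parameterization does not
share it.

## Analytic expectations

For colored noise the fluctuation and fractal measures have known
closed-form relations to χ: DFA α = (χ + 1)/2, FD = 3 − α, and
D = (5 − χ)/2 in the fractional-Brownian regime (χ ∈ [1, 3]). A sign
variant of the α relation, α = (−χ + 1)/2, also circulates — it is
written for the spectral *slope* b = −χ; read with χ positive it yields
impossible values (α = −0.5 for brown noise) and contradicts simulation
for every χ > 0, while agreeing at χ = 0. `expected_measure()` exposes
both (`convention = "standard"` vs `"printed"`) rather than silently
correcting, and the package's tests pin the standard form to simulation.
No analytic expectations exist for the complexity/entropy measures on
colored noise; those are evaluated purely by simulation.

## The comparison protocol

`sim_comparison_set()` generates the mixed evaluation set: 30 s signals,
30 % aperiodic-only (χ uniform on {0, 0.1, …, 2.5}) and 70 % combined
(same χ, plus a continuous sinusoid with CF uniform on 5–35 Hz and
relative power uniform on {0.1, …, 1.0}). `run_sweep()` applies a measure
battery; `spearman_matrix()`, `error_stats()`, `bootstrap_corr()`,
`bootstrap_corr_diff()` and `semipartial_corr()` supply the comparison
statistics (5000 resamples and 95 % percentile intervals by default;
bootstrap resampling is by paired cases; censored rows are excluded
pairwise with counts retained).

The default sampling rate of the comparison protocol is 250 Hz. This is a
consequential choice, because several measure settings are denominated in
samples, not seconds: at 250 Hz, Higuchi's k = 1…10 probes 4–40 ms
structure (25–250 Hz) and the decay-time lag step is 8 ms, so 5–35 Hz
oscillations fall inside the probed scales of several time-domain
measures; at higher rates the same sample-denominated settings probe
proportionally finer scales and become less sensitive to the oscillation
band. Cross-measure concordance on combined signals therefore depends on
the rate in a way that concordance on aperiodic-only signals does not —
worth keeping in mind when comparing time-domain results across studies
that sampled at different rates.

Two further properties of this protocol deserve honesty. First, the decay
time is a threshold-crossing statistic on a discrete lag grid: every
sufficiently shallow signal (roughly χ below ~0.9 at 250 Hz) crosses the
0.5 level at the first measured lag, so a large fraction of a uniform
χ draw lands in a single tie group, which bounds how close rank
correlations involving the decay time can get to 1 regardless of sample
size. Second, DFA, Hurst and the decay time carry genuine
oscillation-power sensitivity under the variance-ratio combination
semantics, so their correlation with ground-truth oscillation power
across combined signals is not negligible. Both behaviors are properties
of the definitions at these settings, not estimator defects; the
acceptance checks report whatever the protocol yields.

## Problem sizes

The packaged checks run the comparison protocol at 250 signals per class
(aperiodic-only / combined), spectral-fit comparisons on 100 simulated
spectra, knee comparisons on 20 knee and 20 aperiodic signals, analytic
DFA checks on 20 realizations per exponent, and bootstrap coverage on 200
repetitions of n = 200 with 500 resamples. These sizes give sampling
error comfortably below the tolerances being asserted while keeping a
full run in minutes on a single core.

## What the simulations do and do not establish

The generators emulate stationary signals with a single aperiodic regime
(or one knee), at most one oscillation, Gaussian innovations, and
time-invariant parameters. Real recordings violate most of these at
least mildly: multiple simultaneous rhythms, nonstationary exponents and
oscillation bursts, line noise, artifacts, and filtering applied during
acquisition. Passing tests therefore establish correctness of the
measures and the internal consistency of the comparison framework on
in-model signals; they do not certify that the measured relationships
transfer quantitatively to any particular empirical dataset. In
particular, preprocessing high-pass filters act like an implicit change
of the lowest probed scale and can shift fluctuation measures
substantially.

## Known limitations

* State-space measures (correlation dimension, Lyapunov exponents) and
  multiscale variants (multiscale DFA/entropy) are out of scope.
* Single-channel only; no cross-spectral or topographic machinery.
* The peak-frequency probability table defaults to uniform (see above).
* Sample entropy is O(n²); it dominates battery runtime at 30 s × 250 Hz
  and grows fourfold at 500 Hz.
* The RANSAC inlier threshold is data-scaled; on spectra with almost no
  outliers it behaves like OLS rather than improving on it.
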