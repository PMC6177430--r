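---
title: "Methods: envelope detection by MET-channel rectification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope detection by MET-channel rectification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochlenv)
```

## The scientific problem

Speech recognition relies on the slowly varying envelope of sound, yet no
component at the envelope frequency is present in the vibration of the
basilar membrane at the cochlear base. `cochlenv` implements the
computational machinery needed to study the proposed resolution: the
sigmoidal activation of mechanoelectrical transduction (MET) channels in
hair-cell stereocilia rectifies the stimulus, and this electrical distortion
— not a mechanical signal — carries the envelope to the auditory nerve.

The experimental workhorse is a three-tone complex

$$x(t) = A\sin(2\pi f_1 t) + A\sin(2\pi f_2 t + \varphi) + A\sin(2\pi f_3 t),
\qquad f_2 = f_1 + f_e,\; f_3 = f_1 + 2 f_e,$$

whose envelope shape is controlled by the centre-tone phase $\varphi$ while
its magnitude spectrum is fixed. At $\varphi = 0$ the envelope has large
peaks recurring at $f_e$; at $\varphi = 90^\circ$ those peaks vanish and the
envelope fluctuates at $2 f_e$. Writing the three components as phasors
gives the closed-form envelope

$$|z(t)| = A\sqrt{3 + 4\cos\varphi\,\cos(2\pi f_e t) + 2\cos(4\pi f_e t)},$$

so the *squared* envelope has an $f_e$ component exactly proportional to
$2\cos\varphi$ and a phase-independent $2 f_e$ component — the same
coefficients a quadratic Taylor term of any memoryless nonlinearity
produces. This is the `quadratic_prediction()` used throughout.

An important numerical subtlety follows: the prediction $2|\cos\varphi|$ is
exact for the squared envelope only. The magnitude envelope itself (what
`hilbert_envelope()` returns, matching how envelope spectra are measured)
deviates from $|\cos\varphi|$ by up to about 7% of the sweep maximum at
intermediate phases ($\varphi \approx 60^\circ$); the package reports the
deviation rather than hiding it, and the test suite records the
magnitude-envelope behaviour as measured.

## The MET model

The receptor current is a first-order Boltzmann function of bundle
displacement $X$ (nm):

$$I(X) = \frac{I_{\max}}{1 + e^{-Z (X - X_0) / (k_B T)}}$$

* `I_max` — saturating current, nA (default 2.5),
* `Z` — single-channel gating force, pN (default 1.05),
* `X0` — operating-point offset, nm (default 5.5, resting open probability
  $\approx 0.206$; `X0 = 0` gives exactly 0.5),
* `temperature` — K (default 310.15), with $k_B$ fixed.

The model is deliberately memoryless (channels treated as infinitely fast):
`simulate_receptor_current()` maps displacement samples to current samples
one-for-one with no filtering or adaptation state. Channel kinetics, bundle
mechanics and organ-of-Corti feedback are out of scope; because of that, the
model's $f_e$ level re the first primary (about $-17$ dB at `X0 = 5.5` nm)
is smaller than levels measured in vivo, where additional nonlinearities
contribute.

With the default stimulus (14.5/15/15.5 kHz, 1 nm per component, 100 ms) the
simulated current shows a large $f_e = 500$ Hz component at $\varphi = 0$
that collapses to the numerical floor at $\varphi = 90^\circ$, while the
$2 f_e$ component moves by barely 0.1 dB — rectification encodes the
envelope, and only when the operating point sits off the symmetric midpoint.

### The operating-point sweep

`sweep_operating_point()` scans `X0` (default 0–20 nm in 0.05-nm steps,
ties broken toward smaller `X0`). At `X0 = 0` the sigmoid is symmetric about
rest and the even-order distortion — hence the $f_e$ component — vanishes.
As computed by this package, the $f_e$ amplitude peaks at `X0 = 5.5` nm
under the default 1-nm stimulus. That location is what small-signal theory
predicts: the quadratic distortion scales with the second derivative of the
logistic, whose magnitude is maximal at $X_0 = \ln(2+\sqrt{3})\,k_B T/Z
\approx 5.4$ nm for these parameters; the moderate 3-nm envelope peak moves
it only slightly. The curve is flat near its top (values at 5.5 and 7 nm
differ by only ~0.5 dB), so read-offs from coarse grids or larger assumed
stimulus amplitudes can land noticeably to the right without much change in
the current.

## Spectral conventions

All component extraction is exact-bin: analysis records are an integer
number of $1/f_e$ periods, rectangular-windowed, so primaries, envelope
components and every integer-combination distortion product fall exactly on
Fourier bins and leakage is zero by construction (the `exact_bins` flag
enforces this at stimulus definition). `amplitude_spectrum()` uses the
peak-amplitude convention (a sinusoid of amplitude $A$ on a bin reads $A$),
and `component_amplitude()` treats an off-bin query as an error rather than
interpolating. The default sample rate is $16 f_3$ (minimum 64 kHz), leaving
third-order products far below Nyquist. Components below $10^{-12}$ of
scale are treated as a numerical floor so dB arithmetic stays finite.

Envelope analysis discards the first and last 5% of samples before
truncating to whole $f_e$ periods; for strictly periodic records the FFT
analytic signal is already exact, but the trim keeps the statistics honest
for ramped or noisy inputs.

`distortion_frequencies()` carries the bookkeeping for the named products
($f_e$, $2f_e$, $3f_e$; `2f1-f2`, `3f1-2f2`, `2f3-f2`), and
`tip_to_tail()` summarizes a phase sweep as the dB difference between the
peaked-envelope response (mean of 0° and 180°, or 0° alone if 180° was not
measured) and the flat-envelope response at 90°.

### Electrode correction

A glass microelectrode acts as a first-order low-pass filter
$H(f) = 1/(1 + i f/f_c)$ with cutoffs typically between 1 and 5 kHz.
`correct_electrode_filter()` divides each complex bin by $H(f)$; the boost
is capped at its value at $10 f_c$ (about 20 dB) so that noise far above the
cutoff is not amplified without bound. Below the cap the correction inverts
`apply_electrode_filter()` to $10^{-6}$ relative.

## Synthetic recordings

The generators produce data with the statistical structure the analysis
assumes, not a mechanical model of the cochlea:

* `generate_bm_recording()` — basilar-membrane-like: primaries plus
  requested high-frequency distortion products, with *zero* deterministic
  energy at $f_e$/$2f_e$ (requesting one is an error), plus shaped noise.
* `generate_ooc_recording()` — organ-of-Corti-like: Boltzmann current,
  electrode low-pass, shaped noise.
* `generate_rw_recording()` — round-window-like: a population sum of MET
  currents with per-cell operating points $\mathcal N(\mu_{X_0},
  \sigma_{X_0})$ and log-normal gain jitter, plus a stereotyped
  envelope-locked "neural" waveform that the `ttx` flag removes, plus noise.

Noise is white Gaussian shaped in the frequency domain: flat amplitude
density above a corner frequency, rising at a configurable dB/octave below
it — mimicking the low-frequency noise rise of interferometric recordings.
Defaults (0.01 units/√Hz floor, 1 kHz corner, 6 dB/octave) were chosen as
plausible for the emulated instruments; presets are not fitted to any
dataset.

The neural surrogate is a half-wave-rectified, low-pass-filtered copy of the
stimulus envelope, scaled by `neural_gain` *relative to the $f_e$ component
of the hair-cell sum* — the quantity a sodium-channel block actually removes
from the envelope-tracking response. It exists solely so that TTX emulation
has a component to remove; it makes no claim about auditory-nerve
physiology. With the default `neural_gain = 0.05` the tip-to-tail ratio
changes by well under 1 dB when `ttx` is toggled, emulating the experimental
observation that blocking the nerve leaves envelope tracking intact.

`average_with_artifact_rejection()` mirrors the acquisition protocol
(100-ms stimuli presented 60 or 120 times): a sweep is rejected when its
0–50 Hz r.m.s. exceeds 3× the median across sweeps (breathing-artifact
scale; the protocol's threshold is not published, so the factor is a
package default), and survivors are averaged in the time domain.

What passing tests on these generators shows: the analysis chain recovers
exactly the structure it assumes (components at stated levels, noise
behaving as $\sqrt{N}$ under averaging, TTX-invariant ratios). What it does
not show: anything about cochlear micromechanics, travelling-wave
compression, or real electrode behaviour beyond first order.

## Statistics

`permutation_test_vs_noise()` tests response amplitudes against noise-floor
amplitudes with the difference of group means, one-sided (signal exceeds
noise), add-one p-value $p = (1 + \#\{s^* \ge s\})/(B+1)$; the pool is
canonicalized (sorted within group) so $p$ depends only on the two sets of
values. Under the null with $B = 199$ the rejection rate at
$\alpha = 0.05$ is exactly nominal, which the suite verifies by
Monte-Carlo.

`fit_phase_effect()` fits $\log(\text{level}) = \beta_0^{(prep)} + \beta_1
|\cos\varphi|$ with per-preparation fixed intercepts and a one-sided
permutation p-value obtained by shuffling phase labels within preparation.
This deliberately replaces a restricted-maximum-likelihood mixed model with
a fixed-effects approximation plus permutation inference: the design
(log response, $|\cos\varphi|$ predictor, within-preparation structure) is
preserved while the inference stays exact and dependency-free; its slope is
invariant under per-preparation gain changes, which the suite checks.

## Problem sizes and determinism

The packaged experiments use a 100-ms record at $16 f_3$ (24 800 samples
for the 14.5/15/15.5-kHz stimulus) and a 401-point `X0` grid; the full
receptor-current experiment runs in seconds. Monte-Carlo checks use 2000
null replicates for the permutation-test size, 20 replicates for the
$\sqrt{N}$ averaging property, and 150–400 replicates for the slope-null
calibration — sizes at which the binomial standard error sits comfortably
inside the asserted bounds. Every stochastic generator takes an explicit
seed, recorded in the output metadata; derived child seeds keep the TTX
toggle from perturbing unrelated draws, and the model experiments are
bit-reproducible.

## Known limitations

* The MET model is memoryless; adaptation, channel kinetics and bundle
  mechanics are excluded by design, so absolute envelope-component levels
  are lower than measured in vivo.
* The magnitude-envelope phase curve follows $|\cos\varphi|$ only
  approximately (exact for the squared envelope); consumers who need the
  exact quadratic law should analyse the squared envelope.
* Synthetic recordings emulate spectra and noise structure, not physiology;
  the round-window neural surrogate in particular is a placeholder for
  "something envelope-locked that TTX removes".
* Exact-bin analysis requires commensurate record lengths; arbitrary-length
  records with windowing/averaging (Welch, multitaper) are out of scope.
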