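---
title: "The phase-delay metabolic index: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The phase-delay metabolic index: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemophase)
```

## The signal model

`hemophase` estimates a blood-glucose-correlated index from ordinary
two-wavelength photoplethysmography (PPG), the sensing modality of every
pulse oximeter and most smartwatches. The chain rests on the modified
Beer-Lambert law (MBLL): the change in absorbance at wavelength
$\lambda$ relative to a reference instant is

$$\Delta A(\lambda, t) = \varepsilon_{\mathrm{HbO_2}}(\lambda)\,
N_{\mathrm{HbO_2}}(t) + \varepsilon_{\mathrm{Hb}}(\lambda)\, N_{\mathrm{Hb}}(t),$$

where $N_x(t) = \Delta[c_x(t) L(t)]$ is the change in molar concentration
times optical path length for each hemoglobin species (mM cm). With two
wavelengths the $2 \times 2$ system inverts to the oxy/deoxy signals.

Within a short analysis window the cardiac (AC) components are modelled as
sinusoids of common angular frequency $\omega$ with slowly varying
amplitudes, the deoxy signal carrying a small, slowly varying phase delay
$\Delta\theta(t)$:

$$N_{\mathrm{HbO_2,AC}}(t) = A_{\mathrm{HbO_2}}(t) \sin \omega t, \qquad
N_{\mathrm{Hb,AC}}(t) = A_{\mathrm{Hb}}(t) \sin[\omega t - \Delta\theta(t)].$$

Three constraints close the model: total hemoglobin concentration is
constant over a session ($c_0$); the concentration pulsations of the two
species cancel ($c_{\mathrm{HbO_2,AC}} + c_{\mathrm{Hb,AC}} = 0$); and the
path-length pulsation is small against its baseline
($L_{\mathrm{LF}} \gg |L_{\mathrm{AC}}|$). Together they force
$L_{\mathrm{AC}}(t) = [N_{\mathrm{HbO_2,AC}}(t) + N_{\mathrm{Hb,AC}}(t)]/c_0$
— a conservation law the simulator satisfies to $10^{-10}$ and the test
suite verifies.

Under these assumptions the amplitude of the deoxyhemoglobin concentration
pulsation — the per-beat oxygen consumption — is proportional to the
**metabolic index**

$$\mathrm{MI}(t) = S_aO_2(t)\,[1 - S_aO_2(t)]\,|\Delta\theta(t)|, \qquad
S_aO_2(t) = \frac{A_{\mathrm{HbO_2}}(t)}{A_{\mathrm{HbO_2}}(t) + A_{\mathrm{Hb}}(t)},$$

up to the subject's total hemoglobin and a perfusion factor. MI is built
entirely from AC quantities, so multiplicative source drift cancels; the
suite checks that a ±5 %/min drift moves the session-mean MI by well under
2 %. An observed consequence of the saturation factor: with $S_aO_2$
between 88 % and 92 %, $S(1-S)$ spans 0.0736–0.1056 (a max/min ratio of
about 1.4), so MI trends are dominated by $\Delta\theta$.

The small-angle step ($2\sin(\Delta\theta/2) \approx \Delta\theta$) is
accurate to better than 0.4 % for $|\Delta\theta| \le 0.3$ rad;
`chb_ac_amplitude()` exposes both the exact and small-angle forms so the
approximation is testable rather than assumed.

## The processing pipeline

`process_ppg()` implements the inverse chain:

1. **Absorbance and inversion.** $\Delta A = -\log_{10}(I/I_{\mathrm{ref}})$
   per channel, inverted through the extinction matrix. The embedded
   matrix holds literature-compiled molar extinction coefficients at
   650/930 nm; any other pair (e.g. camera red/blue "pseudo-visible"
   channels) must supply explicit values, since no published matrix exists
   for that mode. The reference intensity is the per-record channel mean:
   any positive reference only shifts $\Delta A$ by a constant, and the
   pipeline consumes AC content exclusively (a tested invariance). Using
   one record-wide reference lets the band-pass run once, continuously,
   with no per-window filter transients.
2. **Band-pass.** A zero-phase (forward-backward) Butterworth band-pass
   designed from the specification *passband 0.8–10 Hz, max loss 3 dB,
   stopband attenuation 10 dB* with stopband edges defaulting to 0.4 and
   15 Hz. Order selection from this specification yields a prototype order
   of 3 at 100 Hz (the selected order is logged in the run manifest).
   Zero-phase application matters because $\Delta\theta$ is the measurand;
   a causal filter's phase at the cardiac frequency would be common to both
   species and cancel anyway, but the forward-backward pass removes even
   that concern and is standard for offline PPG.
3. **Pulse trimming.** Waveform troughs are detected on the oxyhemoglobin
   channel (local minima below zero, separated by at least the minimum
   cardiac period) and applied to both species, so the inter-channel phase
   relationship is untouched. Windows of four beats (configurable) are cut
   trough-to-trough and mean-subtracted, making the cycle-average-zero
   assumption hold numerically and placing the cardiac fundamental almost
   exactly on a DFT bin.
4. **Spectral estimates.** Each window is linearly resampled to the next
   power of two over the same time span, multiplied by a *periodic*
   Hamming window, and Fourier transformed. The periodic (DFT-even) window
   convention makes on-bin amplitude and phase extraction exact: an on-bin
   tone leaks only into adjacent bins, so the negative-frequency image
   cannot bias the phase. Amplitudes are calibrated as $2|X_k|/\sum w$;
   $\Delta\theta$ is the wrapped phase difference at the peak bin
   (positive = deoxy lags), taken from the single fundamental bin with no
   sub-bin interpolation.
5. **Quality gating.** Spectral SNR is the peak magnitude over the median
   off-peak *in-band* magnitude (out-of-band bins are suppressed by the
   filter and would flatter the ratio). The default threshold of 10 was
   calibrated on the simulator: pure-noise windows stay below ~7, while
   signal windows at three times the default noise stay above ~20. An
   amplitude-sum floor additionally rejects poor-perfusion windows, which
   would otherwise inflate the corrected index (the false-hyperglycemia
   hazard: the correction exponent $1 - 1/n$ is nonpositive). Flagged
   windows are kept and labelled, never silently dropped.

## The perfusion ($\alpha$) correction

MI is deliberately invariant to common amplitude rescaling, but the
underlying oxygen-consumption quantity scales with the relative
path-length pulsation. Assuming
$L_{\mathrm{AC,amplitude}} \propto L_{\mathrm{LF}}^n$ with $0 < n \le 1$,
the correction

$$\alpha(t) = \left[\frac{A_{\mathrm{HbO_2}}(t) + A_{\mathrm{Hb}}(t)}
{A_{\mathrm{HbO_2,0}} + A_{\mathrm{Hb,0}}}\right]^{1 - 1/n}, \qquad
\mathrm{MI}'(t) = \alpha(t)\,\mathrm{MI}(t)$$

compensates perfusion variation. $n = 1$ gives $\alpha \equiv 1$ (no
correction). The default $n = 0.5$ is tentative — the exponent has no
established physiological basis — so `sweep_alpha_exponent()` traces
$r(n)$ against a reference; on simulated sessions generated with a true
exponent of 0.5 the curve is flat-topped around $n \approx 0.4$–0.7 with
its maximum at 0.5, matching the reported behaviour of the method. The
baseline $A_{\mathrm{HbO_2,0}} + A_{\mathrm{Hb,0}}$ defaults to the median
amplitude sum over the first 10 minutes of the session (a resting/fasting
interval), overridable in config.

## Trend post-processing and evaluation

Per-window MI values are averaged in one-minute chunks after removing
outliers by the 1.5×IQR rule (the rule is scale-free and robust for the
10–60 values a chunk holds; no rule is prescribed by the source method, so
the fences are configurable). A chunk losing more than 40 % of its values
is marked missing rather than averaged from a minority. Interior gaps up
to 3 minutes are bridged linearly; longer gaps propagate as missing, so
trends are never fabricated across dropouts. The chunk series is smoothed
by a Savitzky-Golay filter of order 1 and window 29 (29 one-minute
points); at the series edges the polynomial is fitted on the truncated
window rather than on padded data — padding would invent samples exactly
where smoothing artifacts already concentrate. Edge estimates consequently
carry roughly 2–3× the interior standard deviation; the flat-session
simulations below quantify this.

Evaluation interpolates the smoothed trend onto the reference timestamps
(linear, exact at knots, never extrapolated), compensates the reference
sensor's constant delay (e.g. the ~15-minute lag of interstitial-fluid
glucose sensors), fits glucose on MI by ordinary least squares, and
reports Pearson r, MARD, RMSE and Parkes (consensus) error-grid zones for
type 1 diabetes. The zone geometry is embedded as a vertex table from the
consensus publication; the published grid ends at 550 mg/dL and is
extended to the 600 mg/dL working domain by continuing each boundary's
final segment slope. Points exactly on a boundary are assigned the
lower-risk zone — a convention fixed so tests are bit-exact. The zones
partition $[0,600]^2$ totally; the suite rasterizes the square at
1 mg/dL to verify no gaps or overlaps.

## The simulator: what it emulates and what it does not

`simulate_window()` / `simulate_session()` generate the forward model:
sinusoidal AC NIRS signals with the stated phase delay, the
conservation-law path-length pulsation, forward MBLL mapping to
intensities, multiplicative source drift, additive white noise and ADC
quantization. Defaults describe a resting fingertip measurement and were
fixed once, before any acceptance measurement:

* 75 bpm heart rate with ±5 % slow sinusoidal variation (exercising the
  "negligible heart-rate variation" assumption);
* $S_aO_2 = 0.90$, the value observed at capillary-rich sites where
  arterial and tissue saturation converge;
* total fundamental amplitude 0.01 mM cm against $c_0 = 2.3$ mM
  (≈15 g/dL hemoglobin) and a 1 cm baseline path — a perfusion-index-scale
  pulsation of ~0.4 %;
* fasting phase delay 0.10 rad, glucose coupling 0.1 rad per 40 mg/dL
  (the reported magnitude scale: about 1.5 % of a cardiac cycle per
  40 mg/dL);
* a second cardiac harmonic at 0.3 relative amplitude, so main-peak
  selection is nontrivial;
* additive noise at 10 % of each channel's pulsatile intensity amplitude
  (the `noise_sd` convention is noise-to-AC-signal ratio), 16-bit
  quantization.

Oral-challenge sessions follow a double-sigmoid glucose profile (fasting
baseline 95 mg/dL, +65 mg/dL excursion after a challenge at 30 min,
slower decay), sampled by a reference sensor every 5 minutes with an
optional constant delay. Perfusion modulation couples the amplitude sum to
$L_{\mathrm{LF}}^{n}$ so the $\alpha$-sweep experiment has a recoverable
ground truth.

The simulator does **not** model real pulse morphology (dicrotic notch),
motion artifacts, 1/f noise, scattering changes, camera spectral response,
or any physiological glucose-to-phase mechanism — the linear coupling is a
stand-in of the observed magnitude, nothing more. A green end-to-end test
therefore establishes that the *inverse pipeline recovers what the forward
model encodes*, not that the method measures glucose in vivo.

## Numerical choices and degenerate inputs

* Logarithm convention: base-10 absorbance with extinction in
  1/(mM cm); the convention is tagged on the matrix so natural-log tables
  can be used consistently. Only consistency matters for MI.
* The differential path-length factor is not modelled (set to 1): the
  derivation treats $L(t)$ explicitly rather than through a DPF.
* Phase wrapping maps to $(-\pi, \pi]$; e.g. phases $+3.1$ and $-3.1$ rad
  differ by $-0.083$ rad, not $+6.2$.
* Zero or negative intensities, singular extinction matrices (including a
  duplicated wavelength pair), empty heart-rate bands, and windows with
  fewer than three beats raise typed errors rather than propagating NaN.
* Window phases are treated independently across windows (no unwrapping);
  $S_aO_2$ enters MI per window, unsmoothed.
* Savitzky-Golay windows longer than the series shrink to the largest
  valid odd length, with a message.

## Known limitations

* The flat-session (control) simulations show a quantified smoothing
  artifact: with the default noise level the smoothed trend's interior
  varies by 2–4 % around its mean, but the truncated-window edge fits
  raise the full-series range to 4–9 % depending on seed. Real sessions
  show the same effect — apparent MI drifts near recording boundaries
  under fasting conditions are a property of the smoother, not of the
  signal.
* Calibration (slope/intercept of MI to mg/dL) is per-subject and
  per-session; no transfer across subjects is attempted.
* Evaluation against a delayed interstitial-fluid reference mixes the
  method's error with the reference sensor's; reported MARD/RMSE are
  combined errors.
* The index is bounded below by zero, so sensitivity below roughly
  70 mg/dL is structurally limited; this package reports trends and makes
  no hypoglycemia claims.
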