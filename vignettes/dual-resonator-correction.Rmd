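---
title: "Dual-resonator wavelet correction of QCM-D signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-resonator wavelet correction of QCM-D signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcmdwt)
```

## The measurement model

A miniaturised QCM-D array exposes pairs of acoustic resonators, millimetres
apart on the same quartz substrate, to a flowing liquid. One resonator of a
pair (the *sensor*) receives the sample; its partner (the *reference*) is
isolated from it. Both see the same environment. We model the two sampled
channels (either resonance-frequency shift in Hz or dissipation shift in
units of $10^{-6}$) as

$$x(n) = s(n) + d(n) + \varepsilon_x(n), \qquad
  y(n) = g\, d(n) + \varepsilon_y(n),$$

where $s$ is the sample response (present only on the sensor), $d$ is the
combined environmental and setup disturbance (temperature, pressure, flow,
cell stress), $g$ is an unknown, slowly varying gain expressing that the two
resonators respond *similarly but not identically* to shared disturbances,
and $\varepsilon$ are independent electronic-noise terms.

Plain subtraction $x - y$ (Mecea compensation) removes $d$ only when
$g = 1$: any mismatch leaves a residual $(1 - g)\,d$. The correction
implemented here instead estimates the relationship between the channels
*locally, per frequency sub-band, on derivatives*, and removes the
reference's contribution by linear projection wherever the two channels are
demonstrably correlated.

## The algorithm

`correct_pair()` applies, per paired record:

1. **Decomposition.** Both traces pass through a multi-level Mallat
   filter-bank DWT (`dwt_decompose()`), default Daubechies db3 with 4
   levels, giving an approximation series A and detail series D1…D4 per
   channel. Each series isolates one frequency sub-band, so slow
   temperature-like drift (in A) and fast flow spikes (in D1–D2) are handled
   with statistics appropriate to their own scale.
2. **Shrinkage.** Detail coefficients are hard-thresholded
   (`hard_threshold()`): coefficients below a per-level threshold are zeroed
   exactly, survivors are untouched. The approximation is never thresholded.
3. **Differentiation.** Every coefficient series is differenced
   (`derivative()`). Derivatives remove each band's local level, so the
   subsequent correlation measures *co-movement*, not shared offsets.
4. **Windowed significance.** For each coefficient index, the Pearson
   correlation between the sensor and reference derivatives is computed over
   a `window`-sample window centred on the index
   (`windowed_correlation()`), with a two-sided p-value from
   $t = R\sqrt{(w-2)/(1-R^2)}$ on $w - 2$ degrees of freedom.
5. **Conditional cancellation** (`project_and_cancel()`). Where
   $P(n) < \alpha$, the corrected derivative is the projection residual
   $Z'(n) = \hat X'(n) - a - b\,\hat Y'(n)$ with $(a, b)$ the least-squares
   fit in the window: $b$ absorbs the gain mismatch and $a$ any rate offset.
   Where the correlation is not significant — including windows where either
   derivative has zero variance — the derivative of the reference is
   subtracted directly.
6. **Re-integration.** Corrected derivatives are cumulatively summed
   (`integrate_series()`), each series anchored at the sensor's thresholded
   coefficient at index 1, keeping the output on the sensor's scale.
7. **Reconstruction.** The inverse DWT returns the corrected time-domain
   trace with the input's length, sample rate and channel kind.

The algorithm is channel-agnostic: dissipation traces follow the identical
path in their own units.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `wavelet` | db3 | — | three vanishing moments annihilate locally quadratic baselines in the detail bands; db1–db6 available |
| `levels` | 4 | — | deepest band then spans $2^4$ samples (≈ 5 s at 3 S/s); deeper levels resolve slower disturbances but shorten the coarse series |
| `window` | 32 | coefficient samples | the correlation/fit window. It lives in *coefficient index* space because each decimated series has its own time scale: 32 samples of D1 span ≈ 21 s, of A ≈ 171 s at 3 S/s. Smaller windows adapt faster but lose test power (the t-test has `window` − 2 df); larger windows are more selective but smear transients. Values of 16–64 behave similarly on the synthetic suite |
| `alpha` | 0.05 | — | significance level; the projection branch requires $P(n) < \alpha$ strictly. Larger values project more aggressively (risking absorption of sample signal), smaller values fall back to direct subtraction more often |
| `threshold_rule` | universal | — | per-level $\lambda = \hat\sigma\sqrt{2\ln N}$ with the MAD scale $\hat\sigma = \mathrm{median}(|d|)/0.6745$; the alternative `energy` rule zeroes the smallest coefficients holding at most `energy_fraction` (default 1%) of a level's energy |
| `extension_mode` | symmetric | — | half-point reflection at the edges avoids wrap-around artifacts on drifting baselines; `periodic` gives the orthonormal (energy-preserving) transform |
| `lambda` | NULL | signal units | optional frozen threshold(s); see *Streaming* |

The defaults for the sensor constants are the standard AT-cut values
($\rho_q = 2648$ kg/m³, $\eta_q = 2.947\times10^{10}$ Pa), overridable in
`sensor_spec()`.

## What the synthetic generator emulates — and what it does not

`simulate_pair()` builds the statistical structure the method assumes:

* a **saturating binding transient** $A(1 - e^{-t/\tau_b})$ on the sensor
  only (defaults: two sequential steps of −3681 Hz and −1400 Hz with
  $\tau_b = 300$ s, the first at the scale of a dense protein monolayer on a
  50 MHz resonator);
* a **common disturbance** felt by both channels with a reference gain
  `gain_mismatch` (default 1.2): a piecewise-linear temperature excursion
  23 → 34 → 23 °C mapped through a frequency–temperature coefficient
  (default −50 Hz/°C, i.e. an effective 1 ppm/K at 50 MHz — the magnitude
  consistent with a few-hundred-Hz distortion from a ~10 °C swing on a
  liquid-loaded AT-cut resonator), and/or a constant ramp in Hz/h, and
  optionally a common random walk;
* a **sawtooth interference** emulating periodic flow-rate modulation
  (default 30 Hz amplitude, 60 s period, applied 6000–6300 s — the amplitude
  is a package choice since only the flow-rate range, not its frequency
  imprint, is typically reported);
* independent **white Gaussian noise** per channel (default 2 Hz).

Ground-truth components are returned and sum *exactly* to the emitted
traces, which is what the parameter-recovery tests rely on.

The generator deliberately omits several features of real recordings:
quadratic/cubic AT-cut temperature curves, viscoelastic (Kanazawa) liquid
loading, compressional-wave and flow-cell stress physics,
1/f-like electronic noise, and any coupling between temperature and the
adsorption kinetics. Consequently, passing the synthetic suite shows that
the algorithm removes *linearly gain-mismatched, additive* common-mode
structure under white noise; it does not certify performance against
nonlinearly transduced disturbances.

## Numerical choices and degenerate inputs

* **Derivative scheme.** Forward first difference, because it is *exactly*
  inverted by the cumulative sum that re-integration uses; a centred stencil
  would not telescope.
* **Integration constant.** Each corrected series starts at the sensor's
  thresholded coefficient value at index 1, so quiescent output stays on the
  sensor's scale. One documented consequence: if a *detail* series is
  corrected to a constant (e.g. a pair with identical smooth inputs whose
  first detail coefficient survives thresholding), that constant leaks a
  small oscillatory component into the reconstruction. With realistic noisy
  inputs the universal threshold zeroes those coefficients and the effect
  vanishes.
* **Window placement.** Windows are centred and *truncated* at the series
  edges, never padded with fabricated data; truncated windows shorter than
  `min_window` (default 8) fall back to direct subtraction, as do windows
  with zero variance in either derivative (flat post-threshold runs). The
  zero-variance test uses a relative tolerance of $10^{-12}$ against the
  window's mean square to survive catastrophic cancellation.
* **Correlations** are clamped to $[-1, 1]$; $|R| = 1$ maps to $p = 0$.
  Undefined windows carry `NA` with a `defined = FALSE` flag rather than a
  silent numeric value.
* **Per-sample fit.** The projection $(a, b)$ is re-fit for every index from
  its own centred window (a per-block variant would be cheaper but steps at
  block edges); all rolling first and second moments are computed from
  cumulative sums, so the whole correction is vectorised.
* **Allan deviation** uses the non-overlapping two-sample estimator matching
  the adjacent-average definition (`overlapping = TRUE` is available for
  smoother curves). Fractional frequency is mean-centred before the
  cumulative sums — mathematically a no-op for the deviation, numerically it
  makes a constant trace yield exactly zero.
* **Baseline noise** detrends each of the `n_intervals` segments with its
  own least-squares line before taking the residual standard deviation
  (denominator $k - 2$), so `sigma` measures the fluctuation floor, not
  drift. Detection limits computed from it inherit this convention — a
  deliberately documented choice, since IDL values depend on it.
* **Sampling-rate validation** on CSV ingestion enforces strict monotone,
  uniform time to a $10^{-6}$ relative tolerance and refuses missing values
  rather than imputing.

## Streaming

`correct_stream()` processes blocks with an overlap-discard scheme: each
block is corrected independently and only its central region is emitted;
consecutive emissions are stitched by anchoring each block's first emitted
increment to the previously emitted sample, keeping the integrated baseline
continuous. The default margin (`overlap = 4 * window * 2^levels` samples)
keeps a full correlation window of the coarsest series inside the discarded
edge.

Two distinct error sources separate stream from batch output. Block-edge
effects are controlled by `overlap` and are tiny in practice. Threshold
re-estimation is not: a detail coefficient close to the universal threshold
can survive in one segmentation and be zeroed in another, producing a local
discrepancy of order $\lambda$ relative to the signal scale. Freezing the
threshold (`correction_params(lambda = ...)`, e.g. from a calibration
segment — the natural mode for a real-time instrument, which cannot
re-estimate its noise floor per block without output jumps) removes this
source entirely, and the streaming output then agrees with batch processing
to near machine precision in the interior.

## Design decisions that were genuinely open

* **Threshold selection.** The shrinkage step is specified only as removing
  detail coefficients that contribute insignificantly to the signal energy.
  We adopt the per-level universal/MAD threshold as the standard
  wavelet-shrinkage default and expose a cumulative-energy-fraction rule as
  the alternative reading.
* **Correlation window length.** No canonical value exists; 32 coefficient
  samples is the default as the smallest window whose t-test comfortably
  resolves moderate correlations (30 df) while still spanning only ~3
  minutes on the level-4 series at 3 S/s.
* **Boundary handling** of the filter bank (symmetric vs periodic) and
  strict inequality at the significance boundary ($P < \alpha$, not
  $\le$) are fixed as documented above.
* **Pairing** of sensors and references in an array is by explicit user
  mapping only.

## Known limitations

* **Perfectly linear common drift is the method's blind spot.** The first
  difference of an exact ramp is constant, contributes zero windowed
  covariance, and therefore never triggers the projection branch; the
  correction degenerates to direct subtraction and a gain-mismatched ramp
  leaves a residual $(1-g) \times$ rate (40 Hz/h for the 200 Hz/h,
  $g = 1.2$ benchmark). Real instrument drift wanders, and it is exactly the
  correlated wander that the projection branch removes — the intercept $a$
  then also absorbs the rate offset. The quiescent white-noise-plus-ramp
  benchmark is thus the *worst case* for drift suppression, and the package
  reports it as such rather than emulating more favourable drift.
* **Sample-signal absorption at high gain.** During a binding transient,
  windows in which the disturbance correlates strongly let the intercept
  absorb part of the binding derivative's window mean. The effect grows with
  the reference gain and with the disturbance-to-noise ratio of the
  derivatives; on the synthetic suite the plateau bias stays within a few
  percent across gains 0.5–2.
* **Under purely white noise** the corrected output's noise floor is close
  to that of 16-sample filtered subtraction (both are ~16-sample smoothers
  of a doubled-variance difference); the wavelet arm's measured advantage on
  the synthetic suite is real but modest. The large gaps reported on real
  instruments come from correlated, non-white noise that the white-noise
  generator does not contain — another reason the synthetic benchmark is
  conservative.
* At the integration time equal to the coarsest wavelet scale
  ($2^{levels}$ samples), the Allan deviations of corrected and raw traces
  nearly coincide under white noise; ordering there is assessed on the
  median curve over the benchmark suite.

## Problem sizes used in the validation suite

The bundled tests simulate one-hour quiescent runs (10,800 samples at
3 S/s, 100 seeds) for the drift and detection-limit benchmarks, two-hour
harsh-environment runs (21,600 samples) for parameter recovery, and shorter
traces for the property checks; these sizes give the Monte-Carlo assertions
comfortable margins while keeping the default test run fast.
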