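---
title: "Coherence-adaptive clutter filtering: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-adaptive clutter filtering: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented by `cacf`, the reasoning
behind the tunable parameters and numerical choices, and what the
synthetic-data generator does and does not emulate.

## Signal model

Every pipeline stage operates on focused complex baseband (IQ) receive
channel ensembles $u_i[\vec r, k]$: pixel $\vec r$ on a rectangular
axial–lateral grid (mm), receive element $i = 1..M$, slow-time sample
$k = 1..K$ at the pulse repetition frequency (PRF), over one or more
frames. The working decomposition is

$$u_i[k] = s_i[k] + c_i[k] + n_i[k],$$

with $s$ the coherent on-axis signal (blood or stationary tissue), $c$
acoustic clutter, and $n$ thermal noise. The premise of the adaptive
method is that these terms differ in *receive-aperture spatial
coherence*: diffuse on-axis scattering through a rectangular aperture has
the van Cittert–Zernike triangle coherence $\rho[m] = 1 - m/M$ at element
separation (lag) $m$; reverberation and off-axis clutter decorrelate
faster across the aperture; thermal noise is channel-independent.

## Conventional processing

The fixed-filter baseline beamsums the channels, high-pass filters the
beamsum along slow time, and estimates the mean phase shift by 2-D
autocorrelation, converted to axial velocity by
$\hat v = -\,c\,\mathrm{PRF}\,\hat\varphi / (4\pi f_0)$ (cm/s). Two
implementation notes:

* The phase is taken as the four-quadrant angle of the complex lag-one
  accumulator rather than a literal arctangent of the ratio, which would
  fold quadrants for $|\varphi| > \pi/2$.
* The slow-time sum runs over the $K-1$ adjacent pairs of the ensemble
  (the only well-defined reading of a lag-one product over $K$ samples).

Priority encoding follows: a pixel is rejected (set to 0 cm/s *and*
flagged in a separate mask, so downstream statistics can distinguish
"measured zero" from "rejected") when the population variance of the
kernel velocities exceeds $\sigma^2$ — the threshold parameter is the
velocity spread in mm/s, squared internally — or when the kernel-mean
ensemble power falls below $P$ dB relative to the image-maximum *pixel*
ensemble power. The maximum is taken per frame; normalizing across a
whole cine acquisition instead would couple frames through a single
bright pixel, which we judged less predictable. Kernels are truncated at
image borders with the divisor reduced to the pixels actually present.

## Clutter filters and projection initialization

Bank members are Butterworth high-pass filters in the slow-time domain,
order 2 by default. The family and order are free parameters of the
design; order 2 keeps the impulse response short relative to ensembles of
10–16 samples while providing a monotonic stopband and two transmission
zeros at DC. Cutoffs are expressed as fractions of the PRF; the default
bank is the identity ("no filter") member plus eight members evenly
spaced over 0.03–0.24 PRF, i.e. velocity cutoffs of 2.0–15.8 cm/s under
the default 3.5 MHz / 3 kHz acquisition.

On a 14-sample ensemble an IIR start-up transient can leak more clutter
than the stopband does, so filters are *projection-initialized*: the
internal states are set so that the component of the ensemble lying in a
low-degree polynomial subspace produces zero output at every slow-time
index. Concretely, with $F$ the zero-state response matrix, $G$ the
matrix of zero-input responses to unit initial states, and $P_p$ the
projector onto polynomials of degree $\le p$, the initial state is the
least-squares solution $z_0 = -G^{+} F P_p\, x$. An order-$n$ Butterworth
high-pass carries $n$ zeros at $z = 1$, so the polynomial component is
annihilated *exactly* for $p \le n-1$; the default $p = 0$ (the DC
subspace) makes any constant complex input map to an output that is zero
to machine precision, which is the testable core of the technique. The
polynomial order is exposed (`init_order`) because the literature's usage
spans several orders; we default to 0 and validate $p \le n-1$.

Filtering is a single complex recursion per channel (direct-form II
transposed), all $K$ output samples are retained (the estimators sum over
the full ensemble), and the per-channel application commutes with the
beamsum because both maps are linear — `conventional_image()` exploits
this so that a one-member bank reproduces the adaptive pipeline
bit-exactly.

## Coherence feedback

The normalized channel correlation (per lag, averaged over slow time and
element pairs) uses per-sample normalization, so every term has unit
modulus and $|\hat R[m]| \le 1$ without a separate power estimate. Two
consequences drive design choices:

* $\hat R[m]$ is complex; the short-lag sum (SLSC, $Q = 10$ by default)
  takes the **real parts**. For aligned data the imaginary parts average
  to zero, and the real part is also used for the lag-one coherence (LOC)
  ROI statistic.
* Samples that are exactly zero after aggressive filtering would produce
  0/0 terms; they are dropped with the divisor reduced accordingly, and a
  lag with no valid terms yields 0. This avoids NaNs without biasing the
  remaining terms.

Selection is the per-pixel argmax of (optionally weighted) SLSC across
the bank, with ties broken toward the lowest cutoff — the conservative
direction, preserving slow flow. Weighting is an opt-in mitigation for
the correlated-clutter failure mode discussed below; the default uniform
weights reduce to the plain argmax. SLSC is computed pixel-wise from the
same ensemble used for velocity (no temporal compounding); an optional
spatial kernel exists for the velocity estimate but no smoothing is
applied to SLSC itself.

Coherence thresholding rejects pixels whose maximum SLSC falls below a
fraction (2–6% in practice) of the theoretical speckle maximum
$\sum_{m=1}^{Q}(1 - m/M) = Q - Q(Q+1)/(2M)$. Whether sub-threshold pixels
should be rejected from display or assigned the identity filter is
genuinely open; we implement rejection as the default and expose
`threshold_mode = "identity"` as the alternative.

## The synthetic-data generator

The generator imposes spatial coherence *statistically* rather than by
physical wave simulation: a component with profile $\rho[m]$ draws
zero-mean circular complex Gaussian channel vectors with Toeplitz
covariance $T_{ij} = \rho[|i-j|]$, factorized by eigendecomposition with
negative eigenvalues clipped to zero (and numerically-zero modes dropped,
so degenerate profiles such as $\rho \equiv 1$ are exact). This directly
controls the quantity the coherence estimator measures, at desk scale.

Slow-time behavior per component kind:

* **speckle** — frozen across the ensemble and across frames (stationary
  tissue);
* **blood** — a frozen channel draw times a pure phase ramp at the local
  Doppler frequency, redrawn per frame (frames are hundreds of pulse
  intervals apart); slow-time decorrelation of flow is off by default but
  available through a first-order autoregressive coefficient;
* **clutter** — like blood, plus an optional 2 Hz cyclic modulation of
  its Doppler frequency sampled at the frame times (bulk tissue motion),
  and a default AR coefficient of 0.9, which broadens its spectrum the
  way physically jostled tissue does — this broadening is what makes
  low-cutoff filters leak clutter;
* **noise** — redrawn every sample and channel.

The sign convention ties the generator to the estimator: the velocity
conversion carries a leading minus, so the generator uses a phase-ramp
sign such that positive axial velocity (toward the transducer) is
recovered as positive by the estimator. The vessel is modeled as an axial
band with a plug or parabolic profile; the Doppler angle enters only
through the $\cos\theta$ scaling of the sensed velocity (the display
geometry of an inclined vessel adds nothing to per-pixel statistics).
Pixels are generated independently — there is no lateral speckle
correlation — which is acceptable because every estimator here operates
per pixel or on kernels of statistically identical pixels.

### Preset calibration

The per-sample-normalized correlation estimator is *biased downward*
relative to the true channel correlation: for a jointly circular Gaussian
pair with correlation $\rho$ its expectation is
$g(\rho) = \tfrac{\pi}{4}\rho\;{}_2F_1(\tfrac12,\tfrac12;2;\rho^2)$
(e.g. $g(0.75) \approx 0.64$). The scene presets therefore calibrate
*measured* LOC, not $\rho$: given the speckle and clutter amplitudes and
profiles, the effective lag-one correlation is the power-weighted mixture
$\rho_{\mathrm{eff}} = (P_s \rho_s[1] + P_c \rho_c[1]) / (P_s + P_c +
P_n)$, and the noise power $P_n$ is solved from
$g(\rho_{\mathrm{eff}}) = \mathrm{LOC}_{\mathrm{target}}$ by root
finding. The three calibrated presets target background LOC values of
0.75 (`water_path`, no clutter), 0.45 (`tissue1`, +10 dB weakly coherent
clutter), and 0.36 (`tissue2`, +16 dB clutter; the solved noise is
correspondingly large). The clutter coherence *shapes* beyond the LOC
calibration — a triangle damped by $e^{-m/m_0}$ with $m_0 = 2$ — are
implementation choices: the tissue layers are characterized only by LOC
and contrast, not by full coherence profiles. A fourth preset,
`correlated_clutter`, gives the clutter the *full* triangle coherence at
+20 dB with high noise; under these conditions unfiltered clutter is the
most coherent hypothesis and the selector prefers no filtering inside the
vessel, collapsing flow velocities toward zero — the method's documented
failure mode, reproduced deliberately.

What the generator does **not** emulate: attenuation, aberration,
reverberation path structure, curvilinear geometry, the elevation
dimension, lateral speckle correlation, and deterministic transit-time
decorrelation of flow. Tests passing on these scenes therefore validate
the estimators and the selection logic under controlled coherence and
spectra; they do not certify performance on physically acquired channel
data.

## Numerical and validation choices

* The tests pin the estimators to independent brute-force transcriptions
  (triple-loop correlation, literal arctangent, a steady-state filter
  reached by long constant burn-in) at tolerances of $10^{-10}$–$10^{-12}$.
* Tone transmission through a filter equals $|H(f)|^2$ only up to the
  start-up transient; on 14-sample ensembles the deviation near the
  cutoff is tens of percent, so the frequency-selectivity property is
  asserted on 128-sample ensembles, and the Nyquist-tone check uses RMS
  amplitude over the ensemble.
* Coherence-recovery tests compare measured profiles against the analytic
  expectation $g(\rho[m])$, not against $\rho[m]$, for the reason above.
* Behavioral analyses use the default 64 × 40-pixel scene grid
  (0.4 mm pitch), $M = 64$, $K = 14$, single frames, and a 2 × 2 mm
  velocity-estimation kernel (the same extent used for priority
  encoding); vessel ROIs are shrunk by 1.6 mm so the kernel never
  straddles the vessel wall. These sizes give roughly 1600 background
  pixels for LOC measurements and stable ROI means.
* Conversions reported at one decimal follow the formula; the formula
  value 1.98 cm/s for a 0.03 PRF cutoff prints as 2.0, and no printed
  value is special-cased.

## Limitations

The adaptive method inherits the failure modes it is known for: in
regions where SLSC is low across the whole bank (deep noise, focusing
error) selections are high-variance — coherence thresholding mitigates
this; under strong *correlated* clutter the selector preserves clutter
instead of flow — per-filter weights are the sketched mitigation, and
both behaviors are reproducible with the shipped presets. Computationally
the adaptive pipeline costs roughly $F K M^2 + F K^2 M + F K M$
operations against $K M + K^2$ conventionally — about 520× for
$M = 64$, $K = 14$, $F = 8$ — which this implementation does not try to
parallelize.
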