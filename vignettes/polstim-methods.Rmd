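---
title: "Models and methods behind polstim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polstim)
```

polstim reimplements, at the desk, the computational core of a dual-projector
polarised-light stimulation method for insect vision: two digital light
processing (DLP) projectors superimpose their images on a
polarisation-preserving screen, one behind a linear polariser (DLP1) and one
behind a neutral-density filter (DLP2). Sharing each pixel's luminance
between the two projectors sets the degree of linear polarisation (DoLP)
independently of intensity, and parsing 24-bit video frames as 4-bit
subframes raises the pattern rate well above insect flicker-fusion
frequencies. This vignette documents the models, the tunable parameters,
the numerical choices, and what the built-in simulators do and do not
establish.

## Frame encoding and packing

A pixel command is a pair (intensity, DoLP), both in [0, 1]. With a 4-bit
depth the greyscale budget is `max_grey = 15`; the encoder computes

* `total = round(intensity * 15)` — the summed greyscale, which fixes
  luminance;
* `g_pol = round(dolp * total)`, `g_nonpol = total - g_pol`.

Rounding is half-away-from-zero (so a DoLP request of 0.5 at full intensity
splits 8/7 in favour of the polarised channel), and the non-polarised
channel takes the remainder, so `g_pol + g_nonpol = total` holds exactly —
at full intensity the two channels always sum to 15, with maximal DoLP at
(15, 0) and minimal at (0, 15). The achieved DoLP, `g_pol/total`, is
quantised to `total + 1` levels; it is non-decreasing in the request.

The projector firmware reads 24-bit RGB words in B,R,G byte order as six
4-bit subframes. The exact bit-plane order inside the word is not public;
polstim fixes a dialect — subframe *i* occupies bits [4i, 4i+4), least
significant bit first, so subframes 1–2 fill the blue byte, 3–4 red, 5–6
green — and guarantees it only through the exact
`unpack_video_frames(pack_video_frames(x)) = x` round trip, which is the
testable contract for any downstream consumer. The pattern rate is
`video_rate * bits_per_video_frame / bit_depth` (360 Hz for 60 Hz, 24-bit,
4-bit).

Contrast between an object and its background is reported as the difference
of normalised intensities, spanning −1 (dark object, bright background)
through 0 (matched) to +1 (bright object, dark background). The protocols
this mirrors label that scale "Weber contrast"; the classical Weber ratio
cannot produce +1 on a dark background, and the difference form is the only
definition consistent with all three endpoint conditions, so polstim uses
it and keeps the conventional label only informally.

Two stimulus protocols are generated natively. The receptive-field grid
presents one 0.5° square per cell of a 20×20 grid for 100 ms with a 50 ms
gap, scanned row-major from the top left (the original protocol does not
fix a scan order); entry *k* starts at `k × 150 ms`, so the full
schedule spans 60 s. Because the first presentation starts at t = 0, its
baseline gap lies before zero: traces are expected (and simulated) to start
at `t0 = −gap`. The circular-dot protocol revolves a 7.6° dot along a
10.4°-diameter path at 2 cycles/s for 10 cycles, clockwise and
counter-clockwise. The position angle ψ starts at the rightmost point of
the path (ψ0 = 0°, counter-clockwise positive — the same convention as the
angle-of-polarisation maps), and the motion direction is the tangent,
ψ ± 90°. `render_frames()` rasterises either protocol, with a corner sync
patch alternating black/white every pattern frame.

## LED calibration

Intrinsic projector polarisation makes each LED's luminance vary
sinusoidally with the polariser angle θ, with a 180° period:
`L(θ) = c (offset + amplitude cos 2(θ − phase))`, linear in drive current
c. `fit_polariser_sinusoid()` is linear least squares on
(1, cos 2θ, sin 2θ); amplitude is non-negative by construction and phase is
reported in [0, 180). Rank is checked by SVD (three distinct angles mod
180° are required). The calibration target is the lowest uncalibrated
luminance over all LEDs and angles (`offset − amplitude` per LED), so every
LED can be driven *down* to it. `equalise_led()` solves the monotone
current→luminance map by bracketing (doubling) plus bisection with a secant
step — a damped descent; the original device used a fixed-step gradient
descent, but only the family, not the step rule, is material, and the
convergence criterion (relative luminance error, default 0.5%, budget 100
evaluations) is a repository choice since none is published.
`build_lut()` tabulates currents on a 15°-spaced angle grid.

## Imaging polarimetry

From four analyser-angle images (0/45/90/135°, camera-linear counts) the
Stokes estimators are

$$S_0 = \tfrac{1}{2}(I_0 + I_{45} + I_{90} + I_{135}),\qquad
S_1 = I_0 - I_{90},\qquad S_2 = I_{45} - I_{135},$$

$$\mathrm{AoP} = \tfrac{1}{2}\,\mathrm{atan2}(S_2, S_1),\qquad
\mathrm{DoLP} = \sqrt{S_1^2 + S_2^2}\,/\,S_0.$$

The S0 normalisation (sum/2, not the mean) makes S0 the total intensity
(`I0 + I90`) and gives fully polarised light DoLP exactly 1; it is verified
by the synthesis inverse `synthesize_stack()`, which applies Malus's law
for partially polarised light, `I(φ) = (S0 + S1 cos 2φ + S2 sin 2φ)/2`, and
round-trips through the analysis chain to 1e−9. Numerical conventions: AoP
lives in (−90°, 90°] with 0° at the analyser's 0° axis and is undefined
(NA) where S1 = S2 = 0; DoLP is masked below an S0 floor (default 1e−6 of
the image maximum) to avoid NaN storms in dark regions; DoLP values above 1
(possible under noise) are counted and reported, never clipped, and the
physical bound S1² + S2² ≤ S0² is flagged per pixel. Inputs are assumed
linear (un-brightened, un-gamma-corrected); linearity is asserted in
documentation, not checked. Raw Bayer mosaics are handled by strided 2×2
subsampling per RGGB channel — never demosaiced — and the
`dolp_weighted_aop_image()` display encodes AoP as hue (180°-periodic) and
DoLP as brightness.

Because no R TIFF reader is available in the supported environment (and the
package ships text-only), images cross the CLI boundary as headerless CSV
matrices; the in-memory API takes plain matrices, so any image reader can
feed it.

## Photoreceptor receptive fields

A presentation's response is the mean membrane voltage in its 100 ms window
minus the mean over the 50 ms gap immediately preceding it (the protocol
does not define "baseline"; the preceding gap is the natural choice and
makes each response locally detrended). Window edges are snapped to sample
instants when within 1e−6 samples, so schedule times that are exact
multiples of the sampling step never gain or lose an edge sample to
floating-point error. Maps are normalised per cell by the single maximum
across all of that cell's trials and conditions, preserving
between-condition amplitude ratios.

Display smoothing/upsampling applies a separable Gaussian (the kernel
width is quoted upstream without units; polstim fixes it at sd = 1 cell of
the pre-interpolation grid) followed by separable cubic-spline upsampling
(default 10×); the kernel is renormalised at edges so constants are
preserved. The smoothing order (smooth, then interpolate) differs
immaterially from interpolate-then-smooth in the near-linear regime and
keeps the kernel's units well defined. None of this affects analysis:
centroids and tuning curves are computed on the raw grid.

The receptive-field centroid is the **unweighted** centre of mass of the
binary mask thresholded at 30% of the maximum — the mask itself, not the
response amplitudes, carries the mass; a response-weighted variant exists
(`weighted = TRUE`) but is off by default. Maps are aligned by translating
each cell's maps by its non-polarised centroid (rounded to whole cells)
before cross-cell averaging. The polarisation tuning curve is the maximum
of each condition's map versus AoP; the polarisation-sensitivity (PS) ratio
is its max/min.

## Local motion analysis (fast protocol)

For each spike, the dot's instantaneous motion direction θ(t) is evaluated
in closed form at the spike time. The single-rotation local preferred
direction (LPD) is the circular mean of these spike-triggered directions;
response latency Δ rotates it by ±ωΔ (ω = 720°/s at 2 cycles/s), in
opposite senses for the two rotation directions, so the latency-corrected
LPD is the resultant of the CW and CCW unit vectors — exact when the two
biases are symmetric, undefined (flagged) if the estimates are antipodal.

Local motion sensitivity (LMS) compares the spike rate within ±45° of the
LPD (a) with the rate within ±45° of the anti-LPD (b), averaged over
rotation directions:

$$\mathrm{LMS} = \tfrac{1}{2}\big[(a_{CW} - b_{CW}) + (a_{CCW} - b_{CCW})\big].$$

Sectors are defined in motion-direction space (position space rotated 90°
gives the same LMS), centred on the corrected LPD, and rates are
dwell-time-normalised (spikes divided by the time the dot's motion
direction spends in the sector — 1.25 s per rotation for a 90° sector over
10 cycles), which is robust to partial coverage. Note one deliberate,
faithful artefact: because the sectors are centred on an LPD estimated from
the *same* spikes, an untuned (homogeneous Poisson) response yields a small
positive LMS by selection — a few spikes/s at typical counts — matching the
small positive minima such protocols report; tests therefore assess
"LMS ≈ 0" as the mean lying within 2 sd of zero, not exactly zero.

Tuning curves average LMS over trials within each animal before averaging
across animals (mean ± 1 sd). Vector-field receptive fields
(azimuth −120°…+30°, elevation −75°…+75°, dorsal- and right-positive) are
interpolated to 15° steps by decomposing each node into Cartesian
components `lms·(cos lpd, sin lpd)` and applying a separable cubic spline
per component (`stats::spline`, FMM end conditions) — nodes are reproduced
exactly and planar fields exactly; magnitudes are normalised to the maximum
of the non-polarised condition. The two polariser rotations of the AoP
protocol are pooled (the alternative, per-rotation analysis, is a trivial
split upstream).

## Simulators: the stated world

The simulators exist so every analysis can be validated against known
ground truth without hardware or animals; their defaults are fixed once and
deliberately *not* adjusted to test outcomes.

**Photoreceptor.** Photon capture for partially polarised light mixes the
dichroic profile with its e-vector average:
`C = I[(1−d)(1+1/PS)/2 + d(cos²(a−φmax) + sin²(a−φmax)/PS)]`, so
non-polarised light sits strictly between the polarised extremes for
PS > 1. Voltage is Naka–Rushton, `V = v_max·C/(C + C50)`, with
`v_max = 40` mV and `C50 = 19` capture units: real photoreceptor transfer
saturates, but the published depolarisation-based protocol implies
operation far from saturation, and with C ≤ 1 this keeps responses
near-linear (≤ 2 mV, the right order for 0.5° objects) so measured tuning
ratios track the true PS to within a few percent. During a presentation
the capture at the cell is `C_bg + (C_obj − C_bg)·G`, with G the Gaussian
envelope (sd 1.5°, a typical acceptance angle) — a mixture, rather than
scaling the saturated voltage by G, because it makes a luminance-matched
polarised object on a non-polarised background with PS = 1 produce exactly
zero drive, as the masked control condition requires. Additive Gaussian
noise (sd 0.1 mV ≈ 5% of the response range) models recording noise.

**H1-like neuron.** An inhomogeneous Poisson process with rate
`max(0, baseline + gain·contrast²·cos(θ(t−Δ) − θ_pref))` times a Gaussian
spatial envelope; defaults baseline 20 spikes/s, gain 80 (peak ≈ 100
spikes/s, chosen once for test power; no quantitative rates are published),
latency 20 ms implemented as a pure time shift of the direction signal (the
phase-lag account). The contrast exponent is fixed at 2 (the correlator
signature) and the model is polarisation-blind by construction; an optional
polarisation-sensitive front end (capture-scaled gain) is off by default
and exists to show what a positive AoP tuning would look like. Spikes are
drawn by thinning against the rate ceiling; exact RNG ties (which appear at
~1e5 draws) are dropped as unphysical simultaneous spikes. Thinning output
is Poisson (Fano factor within [0.9, 1.1] in tests) and matches the target
rate integral to 2%.

**Device.** Four LEDs (blue/green × polarised/non-polarised paths) with
sinusoidal angle dependence and linear current gain; the polarised paths
get non-zero modulation amplitudes and distinct phases so the calibration
inverse is non-trivial.

What a green test does *not* establish: the simulators are phenomenological
(no photon shot noise or adaptation in the photoreceptor, no spike
refractoriness, no correlated noise, idealised optics with no projector
misalignment or screen depolarisation artefacts), so passing recovery tests
validates the *analysis chain*, not biological realism, and says nothing
about the physical device's headline numbers (screen DoLP maxima, measured
PS ratios), which require hardware and animals.

## Known limitations and numerical notes

* Recovery tests run at reduced scale (10×10 grids, 1 kHz sampling instead
  of 20×20 at 30 kHz) to fit the test-time budget; the code paths are
  identical and the full-scale protocol constants are the defaults.
* One documented acceptance property is left failing by design: under
  dwell-time-normalised sector rates, Poisson theory caps the slope of
  LMS variance against LMS mean at `1/(2·dwell) = 0.4` (measured ≈ 0.3,
  with the *linearity* itself clearly present, R² > 0.8); the expected
  slope band [0.7, 1.3] would require an effective ~0.5 s integration
  window that nothing in the protocol provides. The generator was not
  re-tuned to force a pass.
* `equalise_led()` reports non-convergence (with its evaluation trace)
  instead of erroring, so per-angle failures surface in calibration
  reports.
* Angles are degrees everywhere in the API; axial quantities (AoP, LED
  phase) are 180°-periodic, directional ones (LPD, motion direction)
  360°-periodic.
* All stochastic functions accept an integer seed and restore the caller's
  RNG state; CSV/JSON writers embed no timestamps, so a config plus seed
  reproduces outputs byte-for-byte.
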