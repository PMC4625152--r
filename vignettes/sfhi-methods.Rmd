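---
title: "Grid-based x-ray scatter imaging: model, reconstruction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based x-ray scatter imaging: model, reconstruction and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfhi)
```

## The imaging problem

Conventional radiography images the x-rays a sample absorbs and rejects the
x-rays it scatters. Spatial-frequency heterodyne (dark-field) imaging turns
the scattered photons into the signal: an absorption mesh placed between
the x-ray source and the sample imprints a sharp periodic shadow — a
spatial-frequency carrier — on the beam. Small-angle scattering inside the
sample blurs that shadow locally, damping the carrier harmonics in the
image spectrum, while plain attenuation scales the whole local spectrum.
Demodulating the harmonics of a *single* exposure therefore yields three
co-registered images: a conventional absorption image and two directional
scatter images (horizontal and vertical). Dense nanoparticle labels — gold,
in the application this package models — scatter strongly at small angles,
so tissue that has taken up the contrast agent lights up in the scatter
channels long before it becomes visible in absorption.

## Forward model (the synthetic-data generator)

The generator produces the two rasters the reconstruction consumes: a
grid-only *reference* exposure and a *sample* exposure.

**Grid.** An ideal binary crossed mesh: period `pitch_px` pixels per axis,
wire duty `d` per axis, transmissions `t_open` in open cells and `t_wire`
under any wire. For an axis-aligned mesh each pixel's wire coverage is
computed by exact area overlap, so the spatial mean equals the duty-weighted
mix `t_open (1-d)^2 + t_wire (1-(1-d)^2)` to machine precision. The default
(`pitch_px = 8`, `d = 0.05`, `t_open = 0.98`, `t_wire = 0.10`) has mean
transmission 0.894, inside the 85--90% range typical of the nickel meshes
used on such benches. The pitch must be at least 4 px so the first harmonic
stays below Nyquist. At the default duty the wires are narrower than one
pixel; the sampled profile is then a near-ideal comb whose harmonic
multiples carry near-equal power, which is why the carrier estimator picks
the *lowest* near-maximal spectral peak rather than the global maximum.

**Sample exposure.** With per-pixel optical depth $A(x,y)$ and scatter blur
width $\sigma(x,y)$,

$$E[I](x,y) \;=\; F\, e^{-A(x,y)}\,\bigl[T_{grid} * G_{\sigma(x,y)}\bigr](x,y),$$

with $F$ the open-beam fluence (photons/pixel) and $G_\sigma$ a unit-mass
isotropic Gaussian. The order — blur the grid shadow, then attenuate, then
count — matches a bench with the grid on the source side of the sample.
Choices worth stating:

* **Gaussian blur** is applied as the exact frequency-domain transfer
  function $\exp(-2\pi^2\sigma^2|f|^2)$ with periodic boundary. Its DC gain
  is exactly 1 (photon-conserving), and the first-harmonic damping
  $\exp(-2\pi^2\sigma^2 f_0^2)$ holds to numerical precision, which the
  closed-form tests exploit.
* **Spatially varying blur** uses a bank of uniformly blurred grids at
  $\sigma$ levels quantized to 0.1 px, blended linearly per pixel —
  per-pixel kernels would cost $O(N^2 w^2)$ for no benefit at these scales.
* **Scatter--concentration coupling.** The application evidence is a direct
  correlation between tissue gold concentration and scatter signal, with no
  stated functional form. We take $\sigma^2(x,y) = k\, c(x,y)$ with
  configurable coupling $k$ (default 0.05 px² per µg/cm³): harmonic damping
  is then log-linear in concentration, the simplest model consistent with
  that correlation. No bench-anchored value of $k$ exists; it is a phantom
  parameter, not a physical calibration.
* **Noise** is Poisson only, drawn from the expectation with a fixed seed
  (bit-reproducible); detector read noise and PSF are not modelled.
  Exposure-time-to-fluence conversion for a 15--20 W tube is unknown, so
  fluence is specified directly (defaults around $10^4$--$10^5$
  photons/pixel in the tests).
* **Geometry** enters only through the projected pitch in detector pixels
  (`detector_pitch_px()` for a 1.6 m source--detector bench at
  magnification 2 or 4); no cone-beam divergence is simulated.

**Phantoms** are sums of elliptical regions (body, organs, tumors), each
adding optical depth and optionally a gold concentration; overlapping
optical depths add, gold concentrations take the maximum. Tumor
concentrations in the packaged demo (26 and 18 µg/cm³) match the
concentrations measured in the targeted-labeling study the package's
ratio tables reproduce.

## Reconstruction

Let $M_{mn}(\cdot)$ be the envelope magnitude of harmonic $(m,n)$,
obtained by cropping the half-open square window of half-width
$1/(2\,\mathrm{pitch})$ around the harmonic, re-centring it at DC (nearest
integer bin) and inverse-transforming at full resolution. Then

$$\mathrm{absorption} = -\ln\frac{M_{00}(S)}{M_{00}(R)},\qquad
  \mathrm{scatter}_h = -\ln\frac{M_{01}(S)/M_{00}(S)}{M_{01}(R)/M_{00}(R)},$$

and analogously for $\mathrm{scatter}_v$ with the $(1,0)$ harmonic. Design
choices, each logged in the result object:

* **Log ratio-of-ratios metric.** It linearises Gaussian damping — uniform
  blur gives exactly $S = 2\pi^2\sigma^2 f_0^2$ — and makes $S$ additive
  along the beam. `scatter_to_sigma()` inverts this closed form, clipping
  negative noise values to zero with a counter.
* **Harmonic set** $(1,0)$ and $(0,1)$ only; the diagonal $(1,1)$ harmonic
  is ignored because exactly two scatter directions are reported.
* **Hard rectangular windows, no apodization**, half-open bounds so the
  zero-order and first-order bands partition frequencies without overlap.
* **Magnitude-only envelopes**: the carrier phase (refraction contrast) is
  discarded.
* **Flat-fielding** uses a single reference exposure; no drift correction.
* **Edge margin.** The FFT wraps image edges, so one grid period is
  excluded from every quantitative statistic (`interior()`, and the
  `margin` field of the reconstruction).
* **Failure modes**: a non-positive zero-order reference envelope raises a
  flat-field error; a first-harmonic reference amplitude near zero (e.g. a
  wire-free, duty-0 grid) raises "no grid detected".

## Quantification

ROI statistics are arithmetic mean/SD over rasterized ellipse or mask
pixels. Signal enhancement is $100(\bar x_t - \bar x_c)/\bar x_c$ percent —
scale-invariant, undefined (an error) when the control mean is ~0.
Integrated optical density is the background-subtracted sum
$\sum (I - \tau)_+$, the standard densitometric definition capturing both
stained area and brightness. Enhancement factors divide a target IOD by the
*mean* of its controls — the aggregation that reproduces both printed
factors (11 for 10 nm conjugates, 12 for 50 nm) from the packaged tables.
Ratio tables divide by a reference row, propagate SDs in quadrature, and
display at 2 decimals while retaining full precision; biodistribution
summaries report reference-organ-to-organ mean ratios raw and rounded, with
`Inf` as the marker for a zero-uptake organ. The packaged tables also show
the limits of printed-precision arithmetic: 26/18 prints as 1.45 in the
source yet is 1.44 at two decimals, so only the self-consistent 1.33 ratio
is asserted in tests.

## What the simulations do and do not establish

The generator emulates the *statistical structure* the reconstruction
assumes — a periodic carrier, Gaussian small-angle blur tied linearly (in
variance) to label concentration, Beer--Lambert attenuation, Poisson
counting noise. The test suite shows that under those assumptions the
pipeline is exact-to-tolerance: null residuals at machine precision, the
closed-form scatter metric to well under 2%, blur-width recovery within 5%
under Poisson noise at $10^5$ photons/pixel, absorption fidelity within 2%
RMS, and 90° rotation equivariance of the two scatter channels within 1%
RMS for smooth scatter fields.

It does **not** establish performance on real in-vivo data: real scatter is
not Gaussian or isotropic, gold distributes heterogeneously, detectors add
read noise and a PSF, and the beam is polychromatic. The published in-vivo
numbers (liver scatter six times the unlabeled liver, scatter enhancements
eight times absorption enhancements, tumor enhancements of 0.5% vs 12.9%)
depend on those data and are *not* reproduced here; the simulations
reproduce the qualitative ordering (scatter-channel enhancement of a
gold-labeled tumor far exceeds its absorption-channel enhancement) and the
printed-table arithmetic only.

Known numerical limitations, visible in the demo run:

* **Edge ringing.** Hard steps in the $\sigma$ map ring directionally after
  band-limited demodulation (the method's intrinsic resolution loss).
  Quantitative ROI statistics should stay off such steps; this is why the
  rotation-equivariance property is stated for smooth scatter fields, and
  why the demo inverts the tumor-ROI *mean* (recovering $\sigma$ = 1.08 px
  of a true 1.14 px) rather than the ringing-inflated maximum.
* **Periodic boundaries.** Simulation and reconstruction share the
  periodic-FFT convention; the excluded one-period margin covers the
  wrap-around, and phantoms should keep structures away from edges.
* **Enhancement controls.** A control ROI with near-zero scatter makes
  percent enhancement unstable; phantoms for enhancement studies include a
  small background gold level, mirroring real tissue's nonzero baseline
  scatter.

## Problem sizes and reproducibility

The validation suite runs on 128²--512² rasters at pitch 8 px: 512² for the
closed-form sweep, 256² for noise-recovery and absorption fidelity, 160²
for the rotated-blob and tumor-enhancement studies — sizes at which every
quantity above is stable to far better than its tolerance and the whole
suite runs in seconds. All randomness flows from explicit integer seeds
(`acquisition_settings()`, the pipeline config, the acceptance script's
`--seed`), and `run_pipeline()` writes an MD5 manifest so a rerun of the
same configuration reproduces every artifact byte.
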