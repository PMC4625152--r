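# sfhi — grid-based x-ray scatter (dark-field) imaging of nanoparticle contrast agents

`sfhi` is an R package plus analysis workflow for single-shot x-ray
scatter imaging with an absorption grid. A mesh between source and sample
imprints a spatial-frequency carrier on the beam; small-angle scattering in
the sample — dominated, in the application this package models, by gold
nanoparticle contrast agents accumulating in liver tissue and
hepatocellular-carcinoma xenografts — blurs the grid shadow and damps the
carrier harmonics. Fourier demodulation of one exposure then yields three
co-registered images: a conventional absorption image and horizontal and
vertical scatter images.

The package is aimed at people developing or teaching dark-field x-ray
methods who need a fully simulated, seed-reproducible test bench: a forward
simulator (digital mouse phantoms, Beer–Lambert attenuation, gold-driven
Gaussian scatter blur, Poisson noise), the harmonic reconstruction, ROI
uptake statistics, and the ratio/factor arithmetic used to summarise
nanoparticle biodistribution studies.

## The model and reconstruction

Forward model for one exposure at fluence $F$:

$$E[I](x,y) = F\, e^{-A(x,y)} \left[T_{grid} * G_{\sigma(x,y)}\right](x,y),
\qquad \sigma^2(x,y) = k\,c(x,y),$$

where $A$ is the attenuation optical depth, $c$ the gold concentration map
and $G_\sigma$ a unit-mass Gaussian. With $M_{mn}$ the envelope magnitude
of spectral harmonic $(m,n)$ of a sample $S$ or grid-only reference $R$:

$$\mathrm{absorption} = -\ln\frac{M_{00}(S)}{M_{00}(R)}, \qquad
\mathrm{scatter}_h = -\ln\frac{M_{01}(S)/M_{00}(S)}{M_{01}(R)/M_{00}(R)},$$

and analogously for the vertical channel. For uniform Gaussian blur the
scatter metric has the closed form $S = 2\pi^2\sigma^2 f_0^2$ at carrier
frequency $f_0 = 1/\mathrm{pitch}$, which `scatter_to_sigma()` inverts.

## Worked example

```r
library(sfhi)

cfg <- read_config(system.file("extdata", "demo_config.yaml", package = "sfhi"))
ref <- simulate_reference(cfg$grid, cfg$shape,
                          acquisition_settings(2e4, 8L), cfg$geometry)
img <- simulate_acquisition(cfg$phantom, cfg$grid, cfg$acquisition)

rec <- reconstruct(img, ref, pitch_px = 8)
enh_s <- signal_enhancement(rec$scatter_h,  cfg$rois[[1]], cfg$rois[[2]])
enh_a <- signal_enhancement(rec$absorption, cfg$rois[[1]], cfg$rois[[2]])
round(c(scatter = enh_s$enhancement_pct, absorption = enh_a$enhancement_pct), 1)
#>    scatter absorption
#>     3058.8       18.1
```

The demo phantom's tumor carries 26 µg/cm³ of gold on a 2 µg/cm³ tissue
background, with the same optical depth contrast a small soft-tissue lesion
would give. The tumor is barely visible in the absorption channel (+18%
over the control region) but enhances the scatter channel two orders of
magnitude more (+3059%) — the ordering that makes scatter imaging attractive for
millimetre-scale lesions. Inverting the tumor-ROI mean scatter recovers the
blur width:

```r
scatter_to_sigma(roi_stats(rec$scatter_h, cfg$rois[[1]])$mean, 1/8)
#> [1] 1.08   # true phantom value: sqrt(0.05 * 26) = 1.14 px
```

The `analysis/` directory holds the same pipeline as numbered narrative
scripts (`01_simulate.R` … `05_overlay.R`), writing images, calibration
tables and the dual-modality overlay under `results/`.

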