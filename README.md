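# wlrs: white light reflectance spectroscopy modeling and assay analysis

White light reflectance spectroscopy (WLRS) is a label-free optical
biosensing technique: broadband visible light hits an engineered Si chip
(typically 1000 nm of thermal SiO₂ on Si) at normal incidence, the partial
reflections from each interface interfere, and the recorded spectrum shows
fringes whose positions encode the optical thickness of the layers. When
biomolecules bind to the functionalized surface they form an adlayer a few
nanometers thick; the interference pattern shifts, and fitting the spectrum
with the multilayer reflectance model tracks that thickness in real time
with sub-Angstrom resolution.

This package is an instrument-less workbench for that measurement chain,
aimed at sensor developers and assay modelers:

* **Forward optics** — complex Fresnel coefficients at normal incidence,
  the Abeles backward recursion for a stack's effective reflection
  coefficient

  r_eff ← (r_top + r_eff·e^{−2iδ}) / (1 + r_top·r_eff·e^{−2iδ}),
  δ = 2π n d / λ,

  an algebraically independent explicit closed form E = A/B for the
  two-layer chip, and spectrum synthesis over a wavelength grid
  (450–800 nm by default).
* **Spectrum operations** — absolute-reflectance normalization
  R(λ) = (S − D)/(REF − D) against reference and dark acquisitions,
  interference-extremum location with sub-grid quadratic interpolation,
  fringe counting, drift-following peak tracking, and the simplified
  conversion Δd₁ = 2.06·(Δλ/λ)·d₂ from peak shift to adlayer growth.
* **Fitting** — Levenberg–Marquardt full-spectrum inversion of layer
  thicknesses (via minpack.lm), warm-started time-series fitting into
  sensorgrams, and Monte-Carlo detection-resolution estimation (3 × SD of
  replicate fits).
* **Assay layer** — Langmuir 1:1 binding and first-order polymer-swelling
  sensorgram generators, endpoint and initial-rate readouts,
  four-parameter-logistic calibration with blank + 3 SD limits of
  detection (direct, two-site and competitive formats), chip-regeneration
  statistics, and Gaussian-probe multi-band scan simulation.
* **I/O and CLI** — plain-text spectrum/sensorgram/calibrator formats, a
  validated key-value run configuration, and a command line
  (`inst/cli/wlrs`, or `wlrs_main()` in R) with subcommands
  `simulate | fit | monitor | calibrate | scan | resolve`.

## Worked example

Simulate the canonical chip, then run a streptavidin-style binding
experiment end to end — generate a Langmuir sensorgram, render it as noisy
spectra, and recover it by spectral fitting:

```r
library(wlrs)

chip <- layer_stack(list(
  optical_layer("adlayer", 1.46, 0),   # protein layer, grows during binding
  optical_layer("SiO2",    1.46, 1000) # thermal oxide transducer
))

sp <- simulate_spectrum(chip, wavelength_grid())
locate_extrema(sp)
#>   wavelength_nm      value type
#> 1      486.6670 0.35999986  max
#> 2      530.9099 0.09285212  min
#> 3      584.0005 0.35999995  max
#> 4      648.8893 0.09285212  min
#> 5      730.0006 0.35999999  max
```

The two minima sit at the destructive-interference condition
2 n d = (m + ½) λ — analytically 530.91 and 648.89 nm for 1000 nm of oxide.

```r
p  <- binding_params(k_on = 1e5, k_off = 1e-3, conc = 1e-8, d_max = 5)
sg <- simulate_binding(p, seq(0, 600, by = 30))
series <- sensorgram_to_spectra(sg, chip, "adlayer",
                                wavelength_grid(points = 256),
                                noise_sd = 0.002, seed = 1)
pr  <- fit_problem(chip, free = "adlayer", grid = wavelength_grid(points = 256))
rec <- fit_time_series(series, pr)
head(cbind(time_s = rec$time_s, true_nm = sg$thickness_nm,
           fitted_nm = rec$thickness_nm))
#>      time_s true_nm fitted_nm
#> [1,]      0  0.0000    0.0000
#> [2,]     30  0.1456    0.1563
#> [3,]     60  0.2827    0.2770
#> [4,]     90  0.4118    0.4019
#> [5,]    120  0.5334    0.5182
#> [6,]    150  0.6480    0.6440

endpoint_signal(rec, 600)   # nm bound after 10 min of reaction
#> [1] 1.7371
initial_rate(rec, 120)      # nm/s over the first two minutes
#> [1] 0.004274

detection_resolution(pr, noise_sd = 0.002, n_replicates = 50, seed = 1)
#> <detection resolution> 3 x SD = 0.1682 Angstrom (SD 0.05607 A, bias 0.0406 A; 50 fits, 0 failed; noise 0.002)
```

At 0.2 % photometric noise the fitted adlayer scatters by ~0.06 Å, i.e. the
minimum detectable thickness change (3 × SD) is well below one Angstrom.

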