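---
title: "Modeling white light reflectance spectroscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling white light reflectance spectroscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlrs)
```

## The measurement this package models

A WLRS sensor chip is a stack of transparent films on an opaque silicon
substrate — canonically 1000 nm of thermal SiO₂, carrying the biomolecular
adlayer that grows during an assay. Broadband visible light arrives at
normal incidence through the ambient medium (air or buffer); every
interface reflects a partial wave, and the superposition recorded by the
spectrometer is an interference spectrum with alternating maxima and
minima. Binding increases the optical path through the top of the stack,
shifting the pattern to longer wavelengths. Two quantification routes
exist, and the package implements both:

1. **Full-spectrum inversion**: fit the normalized reflectance with the
   multilayer model and read off the adlayer thickness.
2. **Single-peak tracking**: follow the wavelength of one interference
   extremum (λ_max) and convert its shift with a linear calibration.

## Forward model

At normal incidence a boundary between media with real indices $n_i$ and
$n_j$ has Fresnel amplitude $r_{ij} = (n_i - n_j)/(n_i + n_j)$, and one
traversal of a film accumulates the phase $\delta = 2\pi n d / \lambda$.
The stack's effective reflection coefficient is built by the Abeles
backward recursion, starting from the bare coefficient at the deepest
interface and folding in one film at a time through its round-trip factor
$e^{-2i\delta}$:

$$r_\mathrm{eff} \leftarrow
\frac{r_\mathrm{top} + r_\mathrm{eff}\,e^{-2i\delta}}
     {1 + r_\mathrm{top}\, r_\mathrm{eff}\,e^{-2i\delta}},
\qquad R(\lambda) = |r_\mathrm{eff}|^2 .$$

For the two-film chip the same quantity has an explicit closed form
$E = A/B$, the trigonometric expansion of the squared modulus of the
two-layer Airy coefficient (see `?reflectance_two_layer` for the full
expressions). The two code paths share nothing beyond the Fresnel helper —
one is complex-arithmetic recursion, the other a real cosine expansion —
and the test suite holds them together, plus an independent
characteristic-matrix implementation living only in the tests, to below
$10^{-10}$ over randomized stacks. This three-route agreement is the main
correctness argument for the optics core.

Assumptions, all standard for this transducer and deliberately kept:

* **Normal incidence only.** The reflection probe delivers and collects
  light vertically; oblique angles and polarization are out of scope.
* **Real, dispersionless indices by default** (SiO₂ 1.46, protein adlayer
  1.46 in air / 1.40 as composite with photoresist, Si 4.00), so canonical
  spectra reproduce exactly. Real Si is dispersive and absorbing in the
  visible; a wavelength→index function can be attached per layer
  (`optical_layer(..., dispersion = )`) when that matters, but no complex
  indices — absorbing films would break the $R \le 1$ energy-bound tests
  as written.
* **Semi-infinite substrate**: opaque Si contributes no backside
  reflection.

## Normalization and peak tracking

Raw spectra are referenced as $R(\lambda) = (S - D)/(REF - D)$ with $REF$
from a plain Si chip and $D$ recorded with the source off; this cancels the
source envelope and detector offset. The implementation refuses any
wavelength where $REF - D \le 0$ and names it, since a silently negative
denominator would corrupt every later step.

Extrema are located on the grid and refined by the vertex of the quadratic
through the extremal sample and its two neighbours. On a 512-point
450–800 nm grid this localizes a fringe minimum to better than
$10^{-3}$ nm, comfortably below the 0.01 nm the peak-tracking contract
promises. A three-point parabola was chosen over wider stencils: the
refinement is already far below the noise floor of any realistic spectrum,
and the narrow stencil is robust to fringe asymmetry.

A *fringe* is operationalized as one reflectance **minimum** in the range —
the feature the real-time analysis tracks, and the one that reaches near
zero for Si₃N₄-type stacks. The prominence filter (default 2 % of the
in-range peak-to-peak amplitude) rejects noise wiggles; exact analytic
fringe counting in the tests uses prominence 0, because a genuine minimum
squeezed against the range edge has little rise on one side and the 2 %
rule may legitimately drop it.

Tracking re-centers its window (default half-width 40 nm) on the previous
frame's λ_max, so the extremum can drift across the full spectrum without
escaping; exactly one prominent extremum of the tracked type must lie in
the window, and anything else raises a tracking failure carrying the
timestamp rather than returning a silently wrong series.

The simplified conversion $\Delta d_1 = 2.06\,(\Delta\lambda/\lambda)\,d_2$
turns a tracked shift into adlayer growth. The constant 2.06 is a
calibration of the protein / SiO₂–photoresist / Si system; it is stored as
an overridable parameter of `shift_conversion_params()` and not re-derived,
since its derivation requires phase details the index triple alone does not
fix.

## Spectral fitting

`fit_spectrum()` minimizes the sum of squared differences between the
observed and modeled reflectance with the Levenberg–Marquardt algorithm
(minpack.lm), the standard choice for this deterministic, smooth,
small-parameter problem. Residuals are defined on plain reflectance values
— the direct output of the normalization step — rather than a log or
derivative transform. Convergence: relative cost tolerance $10^{-10}$, cap
200 iterations; a capped fit is returned flagged, never as a bare
estimate.

Default bounds encode the two roles a free layer plays: adlayers (nominal
$\le 50$ nm) in $[0, 50]$ nm, transducer layers within ±20 % of nominal.
Starting values default to the nominal fabrication thicknesses.

One numerical property drives a design choice: the cost as a function of a
film thickness is quasi-periodic, with local minima repeating every
$\lambda/2n \approx 200$ nm, so a start near the basin ridge can descend
into the wrong basin. The fitter therefore runs a deterministic coarse
presearch — 15 equally spaced candidates of the leading free parameter
across its bounds, others held at their starts — and begins the descent
from the best candidate. This keeps self-inversion exact from any starting
point the bounds allow while remaining fully deterministic; `presearch = 0`
restores pure LM from the given start. Time-series fitting warm-starts
every frame from the previous estimate and re-starts from the last
converged estimate after a flagged frame.

Both fitting ranges seen in practice are supported: full-grid fits (the
default, maximal information) and a restricted window around λ_max
(`fit_problem(window = )`), which is preferable when the source envelope
drifts between reference and measurement; sensorgram workflows may use
either, and the window mode mirrors what peak tracking does.

`detection_resolution()` answers "what is the smallest thickness change
distinguishable from noise": fit `n_replicates` noisy copies of the truth
spectrum and report $3\times$SD of the recovered thickness in Angstrom.
The noise model is per-wavelength independent multiplicative Gaussian —
published resolution claims for this class of instrument rarely state a
noise model, so here the level is always an explicit parameter of any
statement this package makes. At 0.2 % noise on
a 512-point grid the canonical chip resolves ≈ 0.2 Å; resolution grows
essentially linearly with noise over 0.1–1 % and shrinks with grid density.

## Synthetic experiments

The generator exists so every analysis stage is testable without an
instrument; its defaults are the canonical study conditions.

* **Binding** is 1:1 Langmuir kinetics with adlayer thickness proportional
  to fractional occupancy: rate constant $k_\mathrm{obs} = k_\mathrm{on}C +
  k_\mathrm{off}$, plateau $d_\mathrm{max}\,C/(C + K_D)$. Defaults used
  throughout tests — $k_\mathrm{on} = 10^5\,\mathrm{M^{-1}s^{-1}}$,
  $k_\mathrm{off} = 10^{-3}\,\mathrm{s^{-1}}$ ($K_D = 10$ nM),
  $d_\mathrm{max} = 5$ nm — are typical antibody–antigen values and a
  protein-monolayer saturation thickness. Real sensorgrams add
  mass-transport limitation, surface heterogeneity and drift, none of
  which the generator emulates; passing round-trip tests therefore
  demonstrates the *analysis chain*, not the realism of any binding model.
* **Swelling** of a polymer film under volatile organic compounds is a
  first-order relaxation to $\mathrm{baseline}\times(1 +
  \mathrm{equilibrium\ swelling})$ with time constant $\tau$, symmetric on
  desorption. This is a stand-in chosen for testability: sorption kinetics
  of real films are frequently non-exponential.
* **Two-site / enhancement steps** (secondary antibody, streptavidin) are a
  multiplicative gain on the response (`enhance_response()`, default 4,
  matching the typical secondary-antibody signal increase).
* **Scanning** renders top-hat bands convolved with a Gaussian probe spot —
  computed analytically as differences of normal CDFs, so no discretization
  error — sampled at the scan step. The spot FWHM is not quantified by the
  hardware description; 0.4 mm is the default and any scan claim carries
  it. Scan noise is additive Gaussian scaled to the largest band response
  (multiplicative noise would vanish in the zero-background gaps).
  The reference layout (seven 0.5 mm bands, 1.0 mm pitch, 0.25 mm step)
  reads out with between-band CV ≈ 1.5 % at 1 % noise, safely inside the
  5 % discrimination criterion.

`sensorgram_to_spectra()` bridges generator and fitter; with a fixed seed
the series is bit-reproducible, and every function that consumes
randomness takes the seed explicitly.

## Calibration and detection limits

Calibration curves use the four-parameter logistic
$f(x) = d + (a - d)/(1 + (x/c)^b)$ for all three formats — increasing for
direct and two-site, decreasing for competitive, with the direction checked
against the fitted asymptotes and flagged on violation. The 4PL is the
field's default dose-response family and contains the Langmuir equilibrium
hyperbola exactly ($b = 1$, $a = 0$), which is what makes the
generator→fit→calibration round trip recover $K_D$ as the fitted midpoint.

The LOD rule is blank + 3 SD (configurable to 2 SD via `sd_mult`): the LOD
is the concentration where the fitted curve departs from the blank mean by
that many blank standard deviations, inverted analytically from the 4PL. A
zero blank SD makes the rule degenerate and is flagged rather than
reported as a genuine limit; a critical response outside the fitted
dynamic range reports the range bound, flagged `outside_range`.

Regeneration quality is summarized as the CV across cycles plus each
cycle's percent deviation from the fresh-surface (first-cycle) response,
with the conventional ±5 % stability band.

## Problem sizes and numerical choices

Test and acceptance workloads are sized for a desk run: 512-point grids
for resolution studies (200 replicates, ≈ 2 s), 128–256-point grids for
time-series round trips, 15–40 Monte-Carlo replicates in property tests.
Tolerances follow the quantity: $10^{-10}$ for cross-route optics
equivalence, $10^{-12}$ for collapse identities, $10^{-4}$ nm for
noiseless self-inversion, $10^{-9}$ for the Langmuir equilibrium identity.
Ties and degenerate inputs are decided explicitly: collinear three-point
stencils return the middle sample; plateau extrema are skipped rather than
split; zero-thickness and index-matched layers are exact no-ops of the
recursion.

## Known limitations

* No absorbing (complex-index) media, roughness or effective-medium
  models, oblique incidence, or polarization.
* Binding is ideal Langmuir: no mass transport, no heterogeneity, no
  cross-reactivity.
* The 2.06 peak-shift constant is accepted as supplied calibration, valid
  for the specific stack it was derived on.
* The fitter is local (with a coarse presearch): simultaneous multi-spectrum
  fitting and global optimizers are out of scope, as is fitting dispersion
  models beyond a single free index.
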