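---
title: "Methods: simulating and fingerprinting liquids with a cross-reactive plasmonic array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and fingerprinting liquids with a cross-reactive plasmonic array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A liquid in contact with the chip is measured as follows. Each of the
24 gold-nanostructure elements supports a localized surface plasmon
resonance, rendered in transmission as a dip

$$T(\lambda) = T_0\left[1 - \frac{d}{1 + \left(\frac{\lambda -
\lambda_0}{\Gamma/2}\right)^2}\right]$$

on the lamp spectrum. The dip centre $\lambda_0$ responds to the
refractive index of the element's few-nanometre sensing volume through
two physically distinct channels:

1. **Bulk refractive index.** All elements shift together by
   $S_{bulk}(n_{sample} - n_{water})$. Ethanol dominates $n$ for
   beverages; dissolved solids add linear increments per g/L at
   standard $dn/dc$ magnitudes. The ethanol–water curve is a monotone
   cubic interpolation of an embedded 25 °C table (non-monotone above
   ~90 % v/v, as the real mixture is).
2. **Chemistry-specific adsorption.** Element $i$ gains
   $\sum_j A_{ij}\, c_j/(K_j + c_j)$: Langmuir saturation per analyte
   feature, with the affinity matrix $A$ expressing cross-reactivity.

Adsorption develops in time as a saturating exponential, the
"on-curve" $a(1 - e^{-kt})$. The simulator applies the bulk term
*instantaneously* (the liquid exchanges within one 30 s reading
interval) and develops each adsorption feature on its own exponential.
This composition was a deliberate choice: applying one exponential to
the entire equilibrium shift would delay the bulk ethanol signal of
slow-binding samples, making an early beer reading resemble mineral
water — contrary to how such instruments behave, where the bulk jump
is immediate and only the slow macromolecule interaction elongates the
response over ~8 minutes. The exported primitive `kinetic_shift()`
retains the plain single-exponential contract; the composition lives in
`shift_at_time()`.

Single-element fits by `fit_on_curve()` remain single-exponential: for
real data the multi-rate structure is unknown, and a single effective
rate is the standard, deliberately simple summary (no offset term,
because shifts are already baseline-referenced; an offset variant
exists behind a flag for drifting data).

# Simulator defaults and why

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| dip shape | Lorentzian, $\Gamma$ = 80, $d$ = 0.5 | nm, – | typical LSPR lineshape/width; instrument values unpublished |
| wavelength range | 550–900, 0.1 grid | nm | covers the 709 nm resonance with margin; 0.1 nm is the stated resolution |
| `bulk_sensitivity` | 250 | nm/RIU | typical LSPR order of magnitude |
| water resonance | 709 + N(0, 4/√2) per element | nm | honours the stated 709 ± 4 nm spread across elements |
| `intensity_noise_sd` | 0.005 (0.5 %) | relative | realistic shot/readout noise for a cooled monochrome camera |
| `lambda_noise_sd` | 0.04 | nm | measured once: sd of extracted minima through the full optical pipeline at 0.5 % intensity noise was 0.037 nm |
| lamp | Gaussian, centre 725, sd 150 | nm | smooth tungsten-halogen stand-in; cancels in normalisation |
| macromolecule rate | 1/180 | s⁻¹ | macromolecule-dominated responses stabilise after ~8 min |
| small-molecule rate | 0.08 | s⁻¹ | near-equilibrated by the first 30 s reading |
| drift, carryover | 0 (opt-in) | nm/h, – | QC features, not part of the default stated world |
| reversion tolerance | 0.2 | nm | twice the instrument resolution |

The **chemistry catalogue** (`default_chemistries()`) is synthetic, not
measured: 24 labelled monolayers with a hand-set affinity matrix chosen
so the qualitative behaviour of a cross-reactive array holds —
carboxylates and the cation receptor respond strongly to divalent
cations, cyclodextrin cavitands to aroma compounds and sugars, alkyl
and ester surfaces to macromolecules and hydrophobes, and an
antifouling PEG element responds to almost nothing.

The **sample catalogue** draws class-conditional lognormal
compositions at realistic beverage magnitudes (beer ~5 % ABV with
~25 g/L residual sugars and ~3 g/L macromolecules; wine ~12 % with wide
sugar spread; spirits ~40 % with class-specific congeners; mineral
waters differing in dissolved cations — including deliberately low-TDS
examples). One construction note: whiskey and gin are distinguished the
way they are in reality — whiskey by cask-derived organic acids and
sugars with moderate congeners, gin by botanical (terpene) aroma — and
the aroma half-saturation is 0.3 g/L so that flavoured spirits do not
all saturate to the same occupancy. An earlier draft with a 0.1 g/L
half-saturation collapsed the two classes, an artifact of the
constructed world rather than a property of such arrays. These
parameters were frozen before the acceptance values were produced and
are not revisited.

# Numerical choices

* **Spline extraction.** Cubic smoothing spline with the smoothing
  parameter chosen by generalized cross-validation, capped at 50
  equivalent degrees of freedom (GCV can chase noise on 3500-point
  grids). The minimum is the argmin on a grid 10× finer than the data
  (0.01 nm); ties break to the lowest wavelength; a minimum on the
  window edge is flagged `boundary`, never silently returned, since it
  usually means a drifted resonance or a wrong window.
* **Readout.** Each sensor is normalised against the adjacent
  reference aperture *following* it in layout order (the last sensor,
  which has none, uses the preceding one). With strict alternation any
  adjacent-neighbour rule is equivalent up to this edge case; the rule
  is isolated in `pair_references()` for substitution. References below
  1 % of their maximum raise an error rather than produce huge ratios.
  Resampling to the exact 0.1 nm grid uses cubic (natural spline)
  interpolation.
* **Baselines.** The rolling baseline is the mean of the most recent
  ten DI-water readings; with fewer than ten available all are used
  with a warning — refusing would block a cold start.
* **Kinetic fits.** `nls` with the `port` algorithm, bounded
  ($|a| \le 50$ nm, $k \in [10^{-5}, 1]$ s⁻¹) to stop runaway fits;
  initialisation $a_0$ = last observation, $k_0 = 1/\mathrm{median}(t)$.
  Series with range below 3× the per-point noise estimate are declared
  flat (amplitude 0) without fitting.
* **LDA.** Implemented as Gaussian classes with pooled within-class
  covariance; when the smallest class has fewer than 3× 24 rows the
  covariance is shrunk 10 % toward a scaled identity, keeping it
  invertible for 24-dimensional fingerprints with few replicates.
  On well-conditioned data it agrees with `MASS::lda`, which the test
  suite uses as the independent oracle. Priors default to training
  proportions.
* **PCA.** Covariance (not correlation) of column-centred data — the
  24 columns share units of nm; correlation scaling is available via
  `scale.`. Signs are fixed deterministically (largest-magnitude
  loading positive).
* **HCA.** Euclidean distance, Ward (`ward.D2`) linkage for both rows
  and columns — the standard choice behind clustered heat-map figures —
  with dendrograms reordered against data means for deterministic leaf
  order.

# What the synthetic world establishes — and what it does not

The generator emulates: the 55-aperture geometry; per-element spectra
with a plasmonic dip near 709 nm in water; bulk-RI shifts from ethanol
and dissolved solids; chemistry-specific Langmuir adsorption with
saturable, cross-reactive affinities; slow beer-like kinetics; the
acquisition protocol (10 readings per sample at 30 s, 20 for beer,
3 randomized replicates, rolling 10-reading DI baselines); and
instrument noise at both the intensity and wavelength level.

It does **not** emulate: electromagnetic structure of the
nanostructures (no FDTD/Mie), real monolayer chemistry or rinse
chemistry, inter-day drift of a real instrument, spectral structure of
real lamps or detectors, or the composition of any actual commercial
beverage. A green classification test therefore establishes that the
*pipeline* — extraction, baselining, standardisation, and classifiers —
is correct and behaves as the workflow intends on data with the stated
structure; it does not re-demonstrate the empirical performance of the
physical chip. Class-level LDA reaching 100 % here says the synthetic
classes are separable and the machinery finds them; the individual
-sample accuracy (~94–97 % with intraclass confusions) emerges from the
constructed world rather than being calibrated to any published figure.

# Detection threshold: an honest discrepancy

`detection_threshold()` reports the smallest injected shift recovered
with correct sign and < 50 % relative error in ≥ 95 % of trials, with
each reading averaging 16 exposures (consistent with sub-2 s frames on
a 30 s cadence). Under the default world — a broad Lorentzian
($\Gamma$ = 80 nm, depth 0.5) at 0.5 % intensity noise — the spline
extractor has a ≈ 0.03 nm noise floor and this criterion yields
**0.2 nm**, not the 0.1 nm one might expect from the instrument's
stated resolution. The 0.1 nm figure is a statement about response
magnitudes being measurable, not a 95 %-confidence detection claim; a
narrower or deeper dip, or more exposure averaging, would lower the
threshold. The tests assert the honestly measured values (0.01 nm at
zero noise, 0.2 nm at default noise, monotone in noise) rather than the
optimistic bound. Note the related pipeline-accuracy criterion — median
absolute extraction error over noisy spectra — passes at ≈ 0.05 nm,
comfortably within 0.1 nm.

# Known limitations

* The affinity matrix and composition distributions are plausible but
  invented; absolute Δλ magnitudes should not be compared with
  published instrument data.
* The wavelength calibration is affine; nonlinear dispersion is out of
  scope.
* One resonance per element is assumed in-window; no multi-dip
  deconvolution.
* Session simulation at signal level injects Gaussian λ-noise
  calibrated to the optical route at default settings only; at very
  different noise levels, re-measure `lambda_noise_sd` or use
  `source = "optical"`.
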