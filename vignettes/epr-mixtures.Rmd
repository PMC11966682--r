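---
title: "Resolving coexisting [4Fe4S]+ species in field-swept EPR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving coexisting [4Fe4S]+ species in field-swept EPR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprmix)
```

## Scope and model

`eprmix` treats a frozen-solution sample of a reduced [4Fe4S]$^{1+}$
cluster as a mixture of a small number of $S = 1/2$ species, each fully
described by three principal g-values, per-axis Gaussian g-strain widths
and a residual linewidth. The spin Hamiltonian is first order in the
electron Zeeman interaction only:

$$ g_\mathrm{eff}(\theta,\varphi) =
   \sqrt{g_1^2\sin^2\theta\cos^2\varphi + g_2^2\sin^2\theta\sin^2\varphi
         + g_3^2\cos^2\theta},
   \qquad B_\mathrm{res} = \frac{h\nu}{g_\mathrm{eff}\,\mu_B}. $$

No hyperfine structure, zero-field splitting, field-dependent state
mixing or exchange coupling is modelled, and no $S > 1/2$ manifolds are
supported: for protein [4Fe4S]$^{1+}$ spectra of this kind only g-values
and linewidths are experimentally resolved, so a richer Hamiltonian would
add parameters the data cannot constrain. Relaxation is likewise outside
the model; temperature is carried as a per-spectrum condition label with
freely fitted weights, because echo-detected amplitudes confound
population and relaxation effects and must not be read as spin counts.

The electronic-structure side is deliberately minimal: a reduced cubane
partitions its four Fe sites into a delocalised mixed-valence
Fe$^{2.5+}$ pair and a ferrous Fe$^{2+}$ pair, giving the
$\binom{4}{2} = 6$ valence isomers that `enumerate_valence_isomers()`
lists. `classify_valence()` consumes externally computed broken-symmetry
site spin populations (the package never computes them) and assigns the
two most positive sites to the mixed-valence pair, which for any valid
2-positive/2-negative record coincides with the partition minimising the
within-pair population variance over all six candidates — the exhaustive
search is kept as an oracle in the test suite, not in the implementation.
Records without the 2/2 sign pattern are rejected rather than guessed at.
The package never maps valence isomers onto the axial/rhombic EPR
species: that link is not experimentally established, and conformer
labels enter only through a user-supplied pair-to-plane map.

## Tunable parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `g_strain` | dimensionless (σ per axis) | 0.004 | typical protein FeS heterogeneity; gives ~2–3 mT Q-band widths |
| `linewidth` | mT FWHM | 1.2 | residual (frequency-independent) broadening |
| `modulation_amplitude` | mT | 1.4 (X-band), 4 (Q-band) | the two-band acquisition settings the presets emulate |
| `snr` | peak-to-peak / noise σ | 20 | the level at which weight-recovery accuracy is characterised |
| `n_orient` | knots | 2048 | grid-refinement error < 0.1 % (see below) |
| axiality `tol` | dimensionless | 0.005 | half the smallest g-difference separating published parameter sets |
| `baseline_order` | — | 1 (max 3) | drifts are gentle; higher orders absorb broad spectral features |
| `n_e`, `n_H` | — | 1 | one-electron couple / single protonation; fixed by default and reported as fixed, never silently estimated |

Fields are mT and frequencies GHz everywhere; the only unit conversion in
the package is the exact Gauss→mT factor 0.1 applied at file ingest and
recorded in the spectrum metadata.

## Numerical design

**Orientation averaging.** Powder integration uses a deterministic
equal-area grid: uniform midpoints in $(\cos\theta, \varphi)$ over one
octant (sufficient by g-tensor symmetry), chosen over Monte-Carlo
sampling for exact reproducibility. Each knot represents a finite cell
across which the resonance field sweeps approximately linearly, so its
contribution is integrated as a uniform box of matching variance
convolved analytically with the Gaussian broadening (a pair of error
functions), rather than as a bare stick. This keeps the discrete sum
smooth near powder-pattern turning points. At the default 2048 knots the
maximum relative difference against a 4× finer grid is below $10^{-3}$;
at ~1000 knots it is ~$1.5\times10^{-3}$, which is why the default is
2048. The absorption integral is area-normalised per species and stable
to 0.1 % under both grid and field-axis refinement.

**Strain propagation.** The effective strain width along an orientation
interpolates the per-axis widths with the same squared-direction-cosine
weights that define $g_\mathrm{eff}$, and maps to field as
$\sigma_B = B\,\sigma_{g,\mathrm{eff}}/g_\mathrm{eff}$ — the standard
frequency-scaling model. It combines with the residual width in
quadrature (Gaussian) or through a pseudo-Voigt approximation
(Lorentzian/Voigt residual). Increasing any per-axis strain strictly
increases the spectral second moment (a tested invariant).

**Pseudo-modulation.** The first-harmonic transform multiplies the
zero-padded FFT of the absorption spectrum by $2i\,J_1(2\pi a u)$, with
$u$ the conjugate variable of field. `a` is the *half*-amplitude of the
sinusoidal field excursion, fixed by the small-amplitude limit
`pseudo_modulate(s, a)/a → ds/dB` that the package guarantees (checked at
$a = $ linewidth/100, tolerance 0.5 %). Records shorter than 64 points
fall back to a central-difference derivative scaled by `a`.

**Decomposition.** The linear step is non-negative least squares
(Lawson–Hanson via `pracma::lsqnonneg`); baseline columns are allowed to
be negative by splitting each into a $(+,-)$ pair of non-negative
columns. Weights are reported both raw and normalised. Nearly collinear
species designs are flagged with a warning and the smallest-norm
solution, never silently regularised. g-value refinement is variable
projection: an L-BFGS-B box-constrained search over g-values (and
optionally linewidths) whose objective is the residual *sum of squares*
after re-solving the weights — the sum of squares, not its square root,
because the root's gradient has constant magnitude near a perfect fit and
breaks the line search. An objective at the numerical floor (relative
RSS $< 10^{-12}$) is treated as converged even if the line search aborts
there. Five deterministically jittered starts (an internal
Lehmer-stream RNG, independent of the user's RNG state) guard against
local minima on broad rhombic features; solutions on a box boundary are
flagged. Multi-frequency datasets are fitted jointly by summing
per-spectrum residuals, each spectrum simulated on its own field axis —
the model is never resampled onto a foreign axis.

**Condition fits.** Midpoint and pKa estimation use Levenberg–Marquardt
(`minpack.lm::nls.lm`) on the sigmoid residuals directly, with the
starting transition point taken from the sample nearest the observed
half-transition (interpolation through noisy, non-monotone series is
unreliable). Plateau fractions are co-estimated within $[0,1]$ so that
incomplete conversion — a mixture rather than a pure species at the
acidic plateau — is representable. Series lying entirely on one plateau,
or with fewer points than parameters, return flagged non-identifiable
results instead of numbers. Parameter uncertainties come from the
curvature at the optimum; a singular curvature yields `NA` standard
errors, not an error.

**Model-count tables.** `model_selection()` reports residual norms and
AIC/BIC against nested candidate pools and never auto-selects: residual
improvements alone cannot establish a true species count for spectra of
this kind, so the choice is left to the analyst.

## What the synthetic data emulate — and what they do not

`generate_spectrum()` reproduces the statistical structure of
echo-detected, pseudo-modulated field sweeps: a weighted sum of powder
patterns, white Gaussian noise at a stated peak-to-peak SNR (the usual
convention for derivative-like EPR traces), an optional low-order
polynomial baseline, and an optional narrow isotropic radical line near
g = 2.004 of the kind that contaminates reduced-protein spectra.
`generate_condition_series()` drives two-species weights through a
Nernst or pH model across a condition grid, optionally at both microwave
frequencies with shared truth. Everything is bit-reproducible from the
noise model's mandatory seed.

Not emulated: temperature-dependent relaxation editing of amplitudes
(weights per temperature are free inputs, not physics), correlated or
1/f noise, cavity background and phase errors, field offsets between
bands, microheterogeneity beyond discrete species (g-strain stands in
for a continuum), and exchange-coupled radical features. Passing the
recovery suite therefore demonstrates that the *estimators* are unbiased
and well-calibrated under the stated noise model — not that real spectra
with uncorrected instrumental artefacts will decompose equally well.

## Problem sizes and tolerances used in the checks

Round-trip accuracy checks run on 512–1024-point field axes with
576-knot orientation grids and two refinement starts; those sizes hold
the tested tolerances (g-recovery to $10^{-3}$, weights to 0.01 on
noiseless targets) with comfortable margin, and the tolerances, not the
sizes, are the contract. Monte-Carlo recovery uses 50–100 noise seeds for
weights and condition-model parameters at SNR 20 (weight bias < 0.05,
midpoint within ±5 mV, pKa within ±0.1) and 12 seeds for full g-value
refinements. The classification oracle is exercised on 10 000 random
records. The whole suite runs in a few minutes on one CPU.

## Known limitations

- First-order resonance fields only: strongly anisotropic systems at low
  field, where second-order Zeeman corrections matter, are outside scope.
- The pseudo-Voigt approximation for Lorentzian-plus-strain profiles is
  accurate to ~1 % of peak height, which is below the noise floor of the
  intended applications but not exact.
- Weight fractions are effective amplitudes, not spin quantitation:
  relaxation editing in echo-detected spectra makes absolute spin counts
  per species meaningless without a calibration standard.
- The tie branch in `classify_valence()` (two candidate partitions
  reported) is defensive: a valid 2-positive/2-negative record cannot
  actually tie at the group boundary, since the smallest positive and
  largest negative populations are always separated.
- BES3T support is read-only and covers 1D field sweeps (the keys
  `XPTS/XMIN/XWID/IRFMT/BSEQ/XUNI/MWFQ`); 2D datasets and the legacy
  ESP format are not supported.
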