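---
title: "Microdosimetry of radioiodine in thyroid follicle models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdosimetry of radioiodine in thyroid follicle models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radioiodine taken up by the thyroid concentrates in the colloid of the
follicle lumen and in the follicular cells, not uniformly across the gland.
Whether that heterogeneity matters for dose depends on the electron ranges
involved: the ~2 mm β particles of ¹³¹I average over many follicles, while
the Auger and Coster–Kronig electrons (AE) of ¹²⁵I and ¹²³I deposit their
energy within nanometres to a few tens of micrometres of the decay site.
`thyrodose` quantifies this by computing **cellular S values** — the mean
absorbed dose to a follicle-cell nucleus per decay in a source region,
in Gy/(Bq·s) — for ¹²³I, ¹²⁵I and ¹³¹I in nested-sphere follicle models of
mouse, rat and man, and by comparing the resulting mean absorbed doses with
the MIRD-formalism mean dose computed from the same cumulated activity.

## Geometry

A single follicle is a sphere of colloid (the lumen) surrounded by one layer
of follicular cells; six spherical cell nuclei — the dose targets — sit on
the Cartesian axes at the mid-depth of the cell layer, which is the unique
symmetric reading of a "centrally located" nucleus. Species presets (lumen
diameter, cell thickness, nucleus diameter, µm): mouse 50/6/4, rat 70/8/6,
man 150/10/8. Everything is unit-density water; radial intervals are
half-open with boundary points assigned inward.

The multiple-follicle model surrounds the central follicle with concentric
layers, each consisting of an inner cell shell, a lumen shell of the species
lumen diameter and an outer cell shell (for man: boundaries at 0, 75, 85,
95, 245, 255, 265, 415, … µm). The default number of surrounding layers is
the number beyond which further layers contribute negligibly: 2/1/8 for
¹²³I/¹²⁵I/¹³¹I in man, 5/1/10 in mouse, 4/1/16 in rat.

One geometric convention deserves emphasis: **the cell compartments include
the nucleus volumes as source**. A decay in a follicle cell can occur inside
its nucleus, and the rare in-nucleus decays dominate the per-decay average
for the AE emitters. `region_volumes()` keeps the strict geometric partition
(nuclei listed separately); `source_compartments()` gives the activity view
with the nuclei merged into the central cell layer.

## Decay data

Only non-radiative emissions are carried: grouped AE lines, internal
conversion electron (CE) lines and β branches. The spectra shipped in
`inst/extdata/` are curated groupings assembled from the standard decay
schemes (electron-capture fractions, fluorescence yields, conversion
coefficients, β branch intensities), constrained to reproduce the published
per-decay summaries: total AE counts of 14/23/0.7 per decay, sub-1-keV AE
energies of 1.25 keV / 2.11 keV / 78.3 eV, and total mean electron energies
of ≈28/19/191 keV for ¹²³I/¹²⁵I/¹³¹I. AE below 1 keV (the transport cutoff)
are not transported; their summed energy is deposited at the decay site.
Daughter-state contributions with long delays (¹³¹ᵐXe; ¹²³Te/¹²³ᵐTe) are
excluded, as are photons and bremsstrahlung.

Two curation choices matter downstream. First, the conventional
(uncorrelated) AE spectrum is used: per-decay emission counts are
independent Poisson draws per line, which is the construction the grouped
yields assume. Second, the ¹²⁵I electron energy balance built bottom-up from
the decay scheme totals ≈19 keV per decay; the older summary value of
16.5 keV is *retained on the MIRD-formalism side* (`mird_mean_energy()`),
mirroring the dual data sourcing of the comparison itself. The two sides of
the comparison intentionally do not share decay data.

β branches use the allowed spectral shape with the relativistic
point-Coulomb Fermi function (evaluated via a complex log-gamma); the two
first-forbidden ¹³¹I branches are approximated with the same shape. The
branch means this produces (e.g. ≈191.5 keV for the 606.3 keV branch) agree
with evaluated values to a fraction of a percent, which a non-relativistic
Fermi factor does not achieve (~3% high).

## Electron transport

Transport is a **straight-track continuous-slowing-down (CSDA) point-kernel
model**, the classical basis of analytic cellular dosimetry, with two
calibrated ingredients:

1. **Range–energy relation.** Below 40 keV, Cole's empirical relation
   `R(E) = 0.0431 (E + 0.367)^1.77 − 0.007` µm (E in keV), which puts the
   1 keV range at ≈68 nm and the 30 keV range at ≈19 µm. Above 40 keV the
   relation continues along a log-log piecewise-linear table of standard
   CSDA water ranges; the 40–100 keV knots are raised by a factor tapering
   from ~1.027 to 1 so the two pieces meet smoothly. Cole's fit alone
   overshoots measured CSDA ranges badly at β energies (+36% at 400 keV,
   +60% at 600 keV), which would corrupt every ¹³¹I cross-fire quantity.
   The model is closed-form invertible, so residual energies along a track
   are exact and per-track energy is conserved to machine precision.

2. **Detour correction.** Multiple scattering makes an electron's radial
   displacement shorter than its path length. The radial depth after a path
   `s` is taken as `z(s) = s (1 − 0.15 s/R₀)`, so the maximum radial
   penetration is 85% of the CSDA range. The factor is fixed by the ratio of
   the observed onset distance of AE/CE dose in these models (≈20 µm for the
   hardest ¹²⁵I conversion electrons) to their CSDA range (23.7 µm), and is
   consistent with tabulated extrapolated-range/CSDA ratios for water.
   Energy is still lost per unit path length, so energy conservation, the
   range identities and radiation equilibrium are untouched. Without this
   term a straight-track model underestimates near-field dose by ~10% and
   overestimates deep penetration roughly twofold at the end of range.

What is *not* modelled: energy-loss straggling, δ-ray transport,
bremsstrahlung, and the full angular diffusion of condensed-history codes.
The residual signature is a few-percent underestimate of β cross-fire dose
at distances well inside the range, and β energy leaking slightly too far
out of a finite model (see Limitations).

## The S-value estimators

`compute_s_value()` samples decay positions and per-decay emissions, then
scores energy imparted to the six nuclei. Two estimators share all sampling
code:

* **expected** (default): each emission's contribution is the exact average
  over emission directions of the straight-track chord deposit, computed per
  target as an integral of stopping power against the fraction of the
  source-centred shell inside the target, evaluated by Gauss–Legendre
  quadrature in residual-energy space (which resolves the end-of-track rise
  exactly). This removes all directional variance — every history
  contributes a smooth expectation — and is what makes 10⁶-history runs of
  the 8-layer ¹³¹I model take seconds.
* **analog**: isotropic directions are sampled and chord deposits scored,
  with sub-cutoff energy deposited at the point where the electron falls
  below 1 keV. Analog runs cross-validate the kernel in the test suite.

Normalisation follows the conventions of the published tables: for shared
source compartments (lumen, cells, surfaces) the S value is the dose
averaged over the six targets per decay in the compartment; for the
nucleus-to-nucleus rows the source region is each single nucleus paired with
itself (per decay in one nucleus; inter-nucleus cross-fire included).

The standard error is estimated from 20 batches. `layer_contributions()`
runs one estimate per source compartment, stratifying the central cell layer
into its cell-volume and nucleus-volume parts (removing the rare-event
variance of in-nucleus decays) and oversampling the central-follicle
compartments 25-fold relative to their mass; both devices change only the
variance, not the estimate.

A deterministic oracle, `brute_force_s_value()`, computes line-spectrum S
values with no randomness: by the sixfold symmetry, the direction-averaged
chord deposit into one nucleus depends only on the source distance, and the
compartment-volume density in that distance has closed form, leaving a
doubly one-dimensional Gauss–Legendre quadrature. It is restricted to
configurations in which an emission can reach at most one nucleus.

## MIRD formalism and the comparison

The MIRD mean dose is `D = (Ã/M) · ΣEᵢYᵢ · φ` with absorbed fraction φ = 1
for electrons in a thyroid-scale target. `required_csa()` inverts it: the
cumulative specific activity giving 1 Gy is 234 / 378 / 32.6 TBq·s/kg at the
MIRD mean energies 26.7 / 16.5 / 191.2 keV. `run_mird_comparison()` places
that same total cumulated activity in the multiple-follicle model —
homogeneously, in the lumens only, in the cells only, or at intermediate
fractions — and reports the model dose to the central nuclei, which is
linear in the placement fractions by superposition.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| transport cutoff | 1 | keV | below it, energy is deposited locally (range ≈ 68 nm) |
| detour coefficient | 0.15 | — | penetration = 85% of CSDA range (see above) |
| `n_histories` | 10⁵–10⁶ | decays | 10⁶ gives sub-percent SE for every published quantity |
| `batches` | 20 | — | batch SE of the mean |
| surrounding layers | 2/1/8 (man) | — | convergence of the layer contribution per nuclide |
| `seed` | mandatory | — | all randomness flows from R's seeded stream |

## What the tests do and do not show

The synthetic-data path (`make_toy_nuclide()`) produces monoenergetic and
few-line spectra for which absorbed fractions, self-dose S values,
reciprocity, radiation equilibrium and the deterministic quadrature give
closed-form or convergent reference values; the test suite checks the
engine against these with no reference to the published tables. The
acceptance layer then reproduces the published quantities at reduced
histories. Neither exercises real thyroid biology: follicle size
distributions, interstitial tissue (deliberately absent from the model),
biokinetics, charge effects of the tellurium recoil atom and stable-iodine
mass loading are all out of scope, so agreement here says nothing about
those effects in real glands.

## Numerical choices

Gauss–Legendre with 24 nodes in residual-energy space for the direction
kernel (relative error far below the Monte Carlo SE); half-open radial
intervals with boundary points assigned inward; decays exactly on a
compartment boundary belong to the inner compartment; mixture sampling uses
a multinomial split of histories across compartments; β sampling inverts a
2048-point cached CDF. Reported problem sizes: unit tests run at 10³–10⁵
histories, the acceptance layer at 10⁵–2×10⁶, which keeps every published
quantity's Monte Carlo SE well inside its comparison tolerance.

## Known limitations

* Straight tracks with a global detour factor approximate, but do not
  reproduce, condensed-history angular diffusion. The clearest residual: in
  the 8-layer ¹³¹I model our homogeneous-placement dose sits ~1% below the
  MIRD dose (β leakage from the finite model), where the published
  comparison reports +4%; the corresponding acceptance band is met only at
  its edge.
* Line-level fidelity of the curated spectra is not claimed — only the
  published per-decay summaries and the resulting S values.
* First-forbidden β shapes are approximated as allowed; the dose-weighted
  error is far below the comparison tolerances.
* The quadrature oracle cannot handle β spectra or long-range lines; those
  are validated by estimator cross-checks and equilibrium identities
  instead.
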