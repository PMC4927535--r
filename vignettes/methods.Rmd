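---
title: "Modeling amino-acid protonation, solubility and weak complexation in salt media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling amino-acid protonation, solubility and weak complexation in salt media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aathermo)
```

## The problem

The acid–base behaviour of an α-amino acid in a real matrix — seawater,
a fermentation broth, a physiological fluid — is governed by its two
stepwise protonation constants, and both depend strongly on the
composition and concentration of the background electrolyte and on
temperature. `aathermo` provides a closed-form model of that dependence
for six amino acids (glycine, alanine, valine, leucine, serine,
phenylalanine) in NaCl and tetramethylammonium chloride media, a
weighted least-squares fitter to re-derive the model parameters from
measurement compilations, solubility and salting-out analysis, and a
method to quantify the weak ion pairs that large organic cations form
with the deprotonated amino group.

The ligand is treated as a diprotic system with a neutral zwitterion:

* step 1 (amino group): H⁺ + L⁻ = HL⁰, log K₁ ≈ 9–10
* step 2 (carboxylate): H⁺ + HL⁰ = H₂L⁺, log K₂ ≈ 2.1–2.4

## Ionic-strength dependence (SIT)

On the molal scale the model for each step is

log K(I) = log K⁰ − z\* · A·√I / (1 + B·√I) + Δε(I) · I

with A = 0.51, B = 1.5 and z\* the difference of summed squared charges
across the reaction: z\* = 2 for the amino-group step, z\* = 0 for the
carboxylate step (whose ionic-strength dependence is therefore purely
linear in the SIT term). The reaction-level interaction coefficient
relaxes hyperbolically between its dilute and concentrated limits,

Δε(I) = Δε∞ + (Δε⁰ − Δε∞)/(I + 1),

which is the same functional form used for single ion-pair coefficients
ε(M⁺, X⁻). `decompose_delta_eps()` converts between the reaction-level
Δε and single-pair coefficients; because no conventional value of
ε(H⁺, Cl⁻) is assumed anywhere, that coefficient is a required input of
the decomposition.

## Temperature dependence (Clarke–Glew)

Around the reference temperature θ = 298.15 K,

log K(I, T) = log K(I, θ) + (ΔH⁰ + ΔC_p·(T − θ)/1000 + Δε′·I) · 52.23 · (1/θ − 1/T)

with ΔH⁰ in kJ mol⁻¹, ΔC_p in J K⁻¹ mol⁻¹ (converted internally) and
Δε′ the ionic-strength coefficient of the enthalpy. The protonation
enthalpy itself is modelled as

ΔH(I, T) = ΔH⁰ − z\*·1.5·√I/(1 + 1.5·√I) + ΔC_p·(T − θ)/1000 + Δε′·I.

The Debye–Hückel-shaped enthalpy coefficient (1.5 kJ mol⁻¹ per unit
z\*) is a package design choice: it is the simple limiting-law constant
that reproduces the packaged reference enthalpies at 298.15 K to within
their rounding for the amino-group step, and it is configurable through
`model_constants(dh_enthalpy_coeff = )`. Likewise the Debye–Hückel
slope A = 0.51 is held temperature independent by default; tabulated
amino-group constants at 310.15 K are consequently reproduced only to
about 0.01 log units (the carboxylate step, with z\* = 0, is
insensitive). A temperature-dependent slope was deliberately not
enabled by default because the packaged parameters were evaluated under
the fixed slope.

```{r}
gly <- aat_model("gly", "nacl")
logk_at(gly, step = 1, I = c(0, 0.1, 1, 5))
enthalpy_at(gly, step = 1, I = 1)
```

## Concentration scales

SIT works on the molal scale (mol per kg of water); speciation and the
weak-complex analysis work on the molar scale (mol per dm³ of
solution). `molar_to_molal()`, `molal_to_molar()` and
`convert_logk_scale()` convert using a polynomial density model of the
salt solution. The shipped density polynomials for NaCl and
tetramethylammonium chloride at 298.15 K are smooth package-supplied
approximations, editable as data; no quantitative result packaged here
depends on them, because every packaged comparison is same-scale.
Temperature dependence of density is out of scope: conversions at other
temperatures warn and use the 298.15 K coefficients.

## Solubility and salting-out

The total solubility of the amino acid adds the charged species to the
fixed solubility S⁰ of the neutral zwitterion,
Sᵀ = S⁰·(1 + 1/(K₁[H⁺]) + K₂[H⁺]), so Sᵀ ≥ S⁰ with a flat minimum
between the two pK values. Against salt molality the neutral species
follows the Setschenow law log S⁰(m) = log S₀⁰ − k_m·m (positive k_m =
salting-out); the total solubility supports the more general hyperbolic
law with parameters a₀, a∞ that collapses to the linear law when
a₀ = a∞. The packaged leucine and phenylalanine models use the
constant-k_m reduction, since only single salting coefficients were
evaluated; the two-parameter form is available in `fit_solubility()`
for user data. Salting parameters are stored so that positive k_m
always means salting-out (the sign convention a = −k_m is resolved at
the data layer).

Chaining the Setschenow law with the protonation law yields solubility
products, log K_S0 = log S⁰(I) − log K₁(I), both factors evaluated at
the same molality and scale (mixed-scale requests are an error):

```{r}
solubility_product_chain("leu", "nacl", I = c(0, 0.5, 3, 5))
```

The analogous phenylalanine chain reproduces the packaged reference
solubility products only to about 0.06; the tabulated phenylalanine
values are therefore shipped as reference data, not used as a
consistency check.

## Weak complexes by the Δpk method

In a medium whose cation associates weakly with the deprotonated amino
group, the apparent protonation constant is depressed:
log K\* = log K − log₁₀(1 + 10^{log K^M}·c_M). For a monoprotic system
this inverts in closed form (`invert_apparent_logk()`). In general the
association constants are estimated by minimising

U = Σ (p̄ − p̄\*)²

over a pH grid, where p̄\* is the mean number of bound protons computed
from the apparent constants alone and p̄ from the effective constants
plus the candidate complexes — the two are algebraically identical when
the complex model is correct. Implementation choices, each of which is
exercised by a test:

* the pH grid defaults to 2.0–11.5 in steps of 0.1 with equal weights;
  the estimate moves by less than 0.001 on noise-free data when the
  grid is refined to 0.02;
* the species set defaults to the single ML ion pair (j = 1, i = 0),
  extensible through `weak_complex_model()`;
* one parameter is minimised exactly (golden-section with a polishing
  pass); multi-parameter species sets use Nelder–Mead with five seeded
  starts;
* a flat objective surface (e.g. no depression in the data) is an
  error, not a silent boundary estimate;
* everything runs on the molar scale, because the cation concentration
  enters the mass balance directly.

The baseline medium is taken as NaCl on the grounds that the
Na⁺–carboxylate interaction is negligible at this level of precision;
an optional two-medium mode that would fit Na⁺ and the organic cation
simultaneously against a hypothetical fully non-interacting baseline is
deliberately not provided as a default workflow.

```{r}
obs <- generate_paired_media_dataset(aat_model("gly"), -0.38, sigma = 0)
fit <- fit_weak_complexes(obs)
fit$species
```

## Refitting measurement data

`fit_protonation_model()` refits the full law to a record table. The
law is linear in every fitted parameter, so the weighted least-squares
problem is solved exactly by `stats::lm` — no initial values, no
convergence tolerance, and machine-precision recovery on noise-free
synthetic data. Records carry IUPAC-style quality flags; only
`recommended` and `tentative` records enter the fit, and the exclusion
count is reported. Uncertainty floors are applied per source
(0.01 experimental, 0.02 literature-recommended, 0.05
literature-tentative log units, 0.1 kJ mol⁻¹ for enthalpy records) —
the reliability weighting of heterogeneous compilations is only
qualitative, so the floors are explicit configuration rather than an
estimated quantity. `logK0`, `ΔH⁰` and `ΔC_p` are shared across media
(they are infinite-dilution thermodynamic quantities); the SIT columns
are per-medium. Degenerate designs degrade explicitly: an isothermal
dataset reports the thermal block as not estimable and still fits the
SIT parameters, and a rank-deficient design is an error naming the
unidentifiable parameters.

`recommend_table()` evaluates a fitted model on an (I, T) grid with
exact (linear-model) CI propagation and assigns quality flags: `R`
requires a propagated CI ≤ 0.015 log units and at least 3 supporting
records within 0.5 mol kg⁻¹; `T` requires CI ≤ 0.035; everything else,
including any point outside the data support, is `P`. The thresholds
are configurable; the defaults express the qualitative rule that flags
should tighten with data support and interval width.

## Synthetic data

The generator reproduces the statistical structure the analysis
assumes: Gaussian noise in log K (the scale on which uncertainties are
reported), a default ionic-strength grid of
{0.1, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0, 3.0, 4.0, 5.0} mol kg⁻¹ — denser
below 1.5 to mimic the literature's concentration of scattered data at
low ionic strength — temperatures {278.15, 288.15, 298.15, 310.15,
318.15} K, optional heteroscedasticity growing with I, and a single
seed that makes every dataset byte-reproducible. Salt grids for
solubility designs stop at 3.5 mol kg⁻¹ in the tetramethylammonium
medium (its practical range) and 5 mol kg⁻¹ in NaCl.

What the generator does *not* emulate: raw titration curves and
electrode calibration error, inter-laboratory systematic offsets,
correlated errors along a titration, or self-association of the ligand
at high concentration. Tests that pass on synthetic data therefore
demonstrate the correctness and calibration of the estimators under
the stated error model, not robustness to structured experimental bias.

## Problem sizes and numerical choices

The shipped test suite fits 200 replicate synthetic datasets of 100
records each for the coverage check, uses 200 replicates for the
salting-fit bias check and 30 for the noisy Δpk check; these sizes make
the whole suite run in well under a minute while keeping Monte-Carlo
error on coverage near 1.5 percentage points. Speciation works in log
space, so distributions are exact at extreme pH; the scale conversion
inverts the density polynomial by bracketed root finding to 1e−13;
tie-breaks and degenerate inputs (zero ionic strength, zero noise,
zero cation concentration) all reduce to the exact limiting formulas
rather than being special-cased numerically.

## Known limitations

* Ligands outside the packaged six are supported only through user
  parameter files; no prediction is attempted for them.
* A Pitzer-equation formulation is out of scope.
* The reference enthalpies at 298.15 K carry an internal inconsistency
  of up to ~0.13 kJ mol⁻¹ between the parameter table and the
  tabulated values (visible directly at I = 0 for the leucine
  carboxylate step, where no ionic-strength term exists); the package
  reproduces the parameter-table side exactly and documents the gap in
  its regression tests.
* Serine's positive Δε′ values are retained as evaluated; the fitter
  never special-cases a ligand.
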