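---
title: "Methods: whole-body PBPK-PD modelling of GalNAc-siRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK-PD modelling of GalNAc-siRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galnacpbpk)
```

This vignette documents the model implemented by `galnacpbpk`: its
structure and assumptions, the provenance and meaning of its parameters,
the numerical and design choices that were genuinely open, and what the
synthetic-data-based evaluation does and does not demonstrate.

## Model structure

The state vector has 65 named states: a subcutaneous depot, central venous
and arterial plasma, a lymph pool, three subcompartments (vascular,
interstitial, endothelial-endosomal) for each of fifteen tissues, the liver
ASGPR/TMDD block (free surface receptor, surface complex, internalized
complex, internalized free receptor, endosomal drug, cytosolic antisense
strand, free and loaded RISC), the two pharmacodynamic states (mRNA and
protein as fractions of baseline), and six cumulative elimination ledgers.
Non-liver tissues have no intracellular drug state because intracellular
uptake is zero by assumption — drug in a tissue resides in the vascular,
interstitial and endosomal spaces.

All amounts are tracked in µmol and time in hours; doses in mg/kg are
converted at the dosing boundary using the compound's molar mass and the
body weight. The right-hand side is affine-linear (all transport and
first-order steps are precomputed into a constant matrix) plus three
nonlinear couplings: ASGPR binding (`k_on·C_int·R`), RISC loading
(`k_onRISC·C_cyto·RISC_free`) and the PD turnover. This structure gives an
exact, cheap analytic Jacobian, which the stiff solver (`deSolve::lsoda`)
uses by default; `jacobian = "internal"` switches to the solver's
finite-difference Jacobian, and the two agree to solver tolerance (tested).
The analytic Jacobian was adopted because the estimation studies run
hundreds of simulations; it is exact rather than approximate, so nothing is
traded for the speed.

### Circulation and extravasation

Venous plasma perfuses the lung; arterial plasma perfuses the remaining
fourteen tissues; spleen, gut, pancreas and stomach drain through the
portal vein into the liver. Lymph drains every interstitial space into a
lymph pool returning to venous plasma. Capillary exchange uses the two-pore
formalism with one small-pore (4.5 nm) and one large-pore (25 nm)
population, 5% of hydraulic conductance through the large pores, and an
isogravimetric circular flux of half the lymph flow. Organ hydraulic
conductance is sized from the organ's transcapillary fluid turnover at an
effective net filtration pressure of 1 mmHg; that fluid turnover is the
lymph flow (0.2% of plasma flow, the standard large-molecule PBPK
convention; 0.02% for brain) for all organs except the kidney, whose
fenestrated glomerular and peritubular walls cycle the reabsorbed filtrate
— its conductance is sized from the GFR. This choice matters: it gives the
kidney a diffusive backflux comparable to its very fast endosomal uptake
(25 min⁻¹), which is what makes that uptake constant identifiable from
kidney tissue data at all. Pore hindrance uses the classical steric
partition `(1−λ)²`, the Renkin diffusive hindrance polynomial and the
convective sieving `1−σ = Φ(2−Φ)(1−λ²/3)`; solute diffusivity comes from
Stokes–Einstein at 37 °C. All pore constants are exposed in
`default_pore_config()` and overridable.

The liver additionally exchanges drug by passive bidirectional permeation
`P_liver·S_cap·(C_v−C_i)`. The bundled capillary surface densities
(250 cm²/mL liver, lower elsewhere) are documented stand-ins: only the
product `P_liver·S_cap` is identifiable, and `P_liver` values were
estimated in the source analyses against a different (closed) surface-area
database, so absolute per-species permeabilities should be interpreted
through that product.

### Liver TMDD, endosomal processing and escape

ASGPR binding acts on the liver interstitial concentration, with the
receptor pool referenced to the liver interstitial volume (the same space
the mass-action term is written in); receptor homeostasis is enforced by
`k_syn = R_tot·k_deg`. The internalized complex is cleaved at `k_cle`,
releasing the receptor to an internal pool (surface return at `k_rec`,
degradation at `k_deg.R`) and the siRNA to the endosomal pool. A fraction
`f_escape` of the *cleaved flux* enters the cytosol (default); the
alternative reading — first-order escape from the endosomal pool — is
available as `options = list(escape_mode = "pool")` but changes the liver
half-life, which the data model attributes to `k_endosome` alone, so the
flux interpretation is the default. `k_endosome` degrades both liver
endosomal drug pools (ASGPR-derived and unspecific), while RNase-mediated
degradation operates everywhere *except* the liver: in central plasma
(venous + arterial only by default) and in the endosomal compartment of
kidney (abundance 1.17 µmol/L) and remaining tissues (0.0275 µmol/L). The
RNase reaction is second order (`k_RNase × abundance × C`), which uses both
printed quantities consistently; the plasma abundance is not separately
reported and defaults to the remaining-tissue value.

RISC degradation (`k_DR`) destroys the guide strand only and returns free
RISC to the pool, keeping total RISC at its fixed literature value; loaded
RISC in nmol/L (converted from the µmol-scale states; the 1000× factor is
unit-tested) drives the indirect-response mRNA model and protein follows as
`mRNA^γ`.

### Structural switches

The exact compartment wiring of the reference model family is not fully
published, so the builder exposes the open choices as options with
documented defaults: `asgpr_site` (binding at the interstitial face,
default, or at the sinusoidal plasma face), `uptake_from_vascular` (whether
endothelial endosomes also take up from the vascular side),
`recycle_to_vascular` (destination split of endosomal recycling; default
fully interstitial) and `plasma_rnase_central_only`. The defaults follow
the simplest reading of the model description; sensitivity of conclusions
to these switches can be probed directly.

## Parameters and species translation

`assemble_parameterization()` merges three layers: global/species-specific
values, compound-specific values (bioavailability, tissue endosomal
recycling, RISC-complex turnover — `k_DR` is the only compound × species
cell, and combinations with no PD estimate error out unless
`require_pd = FALSE`), and user overrides. Two derived rules run at
assembly: `k_syn = R_tot·k_deg`, and allometric translation of the liver
endosomal degradation rate from the mouse standard individual
(`k_std·(BW/0.025)^{-0.25}`), giving 1.51 × 10⁻³ h⁻¹ for a 3 kg monkey and
6.8 × 10⁻⁴ h⁻¹ for a 73 kg human. Every resolved value carries a provenance
tag. Where the narrative text and the parameter summary tables disagree
(monkey/human ka, `P_liver`, liver recycling), the tables are canonical and
the text values ship as a selectable `variant = "text"` set. Molar mass
(16 kDa) and hydrodynamic radius (3 nm) are not reported for the compounds
and are documented assumptions — the radius especially is user-visible
because the sensitivity analysis shows it matters.

Bioavailability is shared across species for each compound (47% for
siRNA-1, 22% for siRNA-2/-3), the reading implied by the table layout.

### Physiology

The bundled physiology tables (one TSV per species plus a species-level
table) are a documented reference individual per species compiled from
standard open compendia: organ volumes as fractions of body weight,
regional plasma flows as fractions of cardiac plasma output (closed exactly
by assigning the carcass the remainder), subcompartment volume fractions,
lymph at 0.2% of plasma flow, and GFR/hematocrit/central plasma volumes.
They stand in for the closed platform database the model family is built
on; everything is overridable by pointing the loader at alternative tables,
and body-weight rescaling is proportional (flow ratios and volume fractions
invariant). Default body weights: mouse 0.025 kg, monkey 3 kg, human 73 kg.

## Numerics

Default solver tolerances are rtol 1e-8 / atol 1e-12 on the µmol scale
(estimation uses 1e-6/1e-10); halving tolerances changes plasma AUC by
< 0.1% (tested). Dosing is handled by depot events with solver restarts.
Transient negative states beyond 10⁻⁵ of the dose scale abort the
simulation; smaller ones are clipped for reporting only. Every simulation
reconciles `depot + in-system + eliminated` against `F × dose` and fails
hard above 0.1% residual. The Peclet number in the Patlak flux is guarded
against overflow (convective limit beyond |Pe| > 700, diffusive limit below
10⁻¹²), and full steric exclusion (solute ≥ pore radius) yields exactly
zero flux.

## Estimation and evaluation

The loss is the sum of squared residuals, equally weighted per observation,
in log10 space for concentrations (appropriate for data spanning several
orders of magnitude and invariant to common unit rescaling) and in linear
percent space for baseline-normalized PD. The optimizer is a seeded
multistart (log-uniform draws within bounds) with local refinement (bounded
Brent in one dimension, Nelder–Mead otherwise), stopping early when the
best loss improves by less than 0.1% across a block of starts — the only
published contract of the reference optimization procedure. AFE/AAFE are
geometric-mean (absolute) fold errors with the conventional 0.5–2 and ≤ 2
adequacy bands, pooled per curve then geometrically averaged. Local
sensitivity uses a forward +10% perturbation of one parameter and the
relative change of AUC₀₋₈₀₀₀ₕ at 1 mg/kg (backward perturbation when the
parameter sits at a constraint boundary, e.g. fu = 1), classified high
(≥ 0.5), medium (≥ 0.2), low (≥ 0.1), negligible.

## The synthetic-data generator

`study_design()`/`generate_study()` emulate the reference study structure:
the dose groups and biospecimen menus of the original mouse, monkey and
human studies; destructive sampling with n = 3 independent animals per time
point; multiplicative lognormal residual error on concentrations with 20%
CV, unbiased in log space; additive Gaussian error of 5 percentage points
on baseline-normalized PD, truncated to [0, 120]% to mimic assay
normalization. The noise magnitudes are not reported in the source material
and are documented, configurable assumptions. Sampling-time grids are
likewise unpublished ("warranted time points"); the defaults (dense to
24 h, sparse to 672 h for mouse; to 1344/2016 h for monkey and human)
resolve the three plasma phases.

The generator produces data from the *same* model that is then refit, so
recovery studies demonstrate estimator correctness and practical
identifiability under the stated designs — not model correctness against
real animals. Features of real data the generator does not emulate:
below-quantification censoring, inter-animal parameter variability,
assay-specific bias, and model misspecification of any kind.

## Problem sizes used in the shipped analyses

The recovery studies refit one parameter at a time, with all others fixed
at their generating values, across 20 seeds: bioavailability against
plasma + liver data (three dose groups), liver endosomal degradation
against liver data (100 mg/kg), the kidney endosomal uptake constant in log
space against kidney data (3 and 100 mg/kg), and the RISC/PD parameters
(`k_DR`, `S_max`, `SC_50`) against liver mRNA data. Two random starts per
fit suffice for these one-dimensional problems (Brent refinement is
deterministic within bounds). These sizes were chosen as the smallest
studies that exercise every estimator path while keeping each fit to a few
seconds.

## Known limitations

* **Kidney disposition.** Sizing the kidney's pore conductance from GFR
  makes the kidney a strong distribution site; kidney tissue levels are of
  the same order as liver levels at early times, at the upper end of what
  is plausible for GalNAc conjugates. The alternative (lymph-sized
  conductance) makes kidney uptake unidentifiable and kidney exposure
  likely too low. Filtration routes directly to urine; tubular reabsorption
  of filtered drug is not separately modelled.
* **Liver redistribution magnitude.** With the tabulated ASGPR kinetics
  (association 0.53 L/nmol/h at 5.23 µmol/L receptor density, receptor
  turnover 1.52 h⁻¹), receptor-mediated capture outcompetes the 0.29 min⁻¹
  unspecific liver endosomal uptake under every wiring variant this package
  exposes, capping the liver unspecific pool near 1% of the absorbed dose.
  Zeroing that pathway therefore lowers post-10 h plasma by only a factor
  ~2–3 here, weaker than the dominant role the source analysis attributes
  to it; the corresponding structural test records this honestly. The
  mechanism is present and directionally correct, but the late plasma phase
  in this reconstruction is co-supplied by kidney and off-target endosomal
  recycling.
* **PD magnitude in higher species.** With the flux interpretation of
  endosomal escape, predicted human knockdown at 1 mg/kg is small; deep
  knockdown requires the higher mouse dose groups. The pool interpretation
  (`escape_mode = "pool"`) produces much deeper knockdown but shortens the
  liver half-life, contradicting the attribution of that half-life to
  `k_endosome`; the flux reading is therefore the default.
* The appendix-level wiring of the reference model is unpublished; this
  implementation is a documented interpretation with its open choices
  exposed as options, and absolute tissue predictions inherit the
  uncertainty of the stand-in physiology.
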