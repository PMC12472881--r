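# galnacpbpk

Whole-body physiologically based pharmacokinetic–pharmacodynamic
(WB-PBPK-PD) modelling of GalNAc-conjugated siRNAs in mouse, cynomolgus
monkey and human.

GalNAc-siRNAs are cleared from plasma within hours by the hepatocyte
asialoglycoprotein receptor (ASGPR), accumulate in a long-lived liver
endosomal depot, and silence their target gene for weeks through the
RNA-induced silencing complex (RISC). At the same time a measurable fraction
of a subcutaneous dose distributes to off-target organs (kidney, gonads,
heart, lung, spleen) and slowly redistributes back into plasma. This package
implements a mechanistic whole-body model of those processes for use by
PK/PD modellers working on siRNA therapeutics: simulation, species
translation, sensitivity analysis, model-performance metrics, parameter
estimation, and a synthetic study generator that emulates the preclinical
and clinical study designs the model family is developed on.

## The model

Fifteen tissues (liver, kidney, lung, heart, spleen, gonads, brain, muscle,
skin, adipose, bone, gut, pancreas, stomach, carcass), each split into
vascular, interstitial and endothelial-endosomal subcompartments, are
connected by plasma flows (with portal drainage into the liver) and lymph.

* **Extravasation** follows the two-pore formalism: for each pore population
  the Patlak flux `J_v(1-σ)(C_v − C_i e^{−Pe})/(1 − e^{−Pe})` with
  `Pe = J_v(1−σ)/PS`, where the reflection coefficient σ and
  permeability–surface product PS derive from steric hindrance at
  λ = r_solute/r_pore. The liver adds bidirectional passive permeation
  `P_liver · S_cap · (C_v − C_i)`.
* **Liver uptake** is an extended target-mediated drug disposition (TMDD)
  scheme: association with free surface ASGPR (`k_on`, `k_off`), receptor
  turnover (`k_syn = R_tot · k_deg`), internalization (`k_int`), cleavage of
  the internalized complex (`k_cle`) with receptor recycling (`k_rec`), an
  endosomal drug pool degrading at `k_endosome`, and an escape fraction
  (`f_escape`, ~1%) reaching the cytosol as antisense strand.
* **RISC kinetics**: second-order loading (`k_onRISC`), slow dissociation,
  first-order complex turnover (`k_DR`) with conservation of total RISC.
* **Pharmacodynamics**: an indirect-response model in which loaded RISC
  stimulates mRNA degradation,
  `d(mRNA)/dt = k_deg.mRNA (1 − (1 + S_max·C/(SC_50+C)) · mRNA)`,
  and protein follows `d(Protein)/dt = k_deg.protein (mRNA^γ − Protein)`.
* **Eliminations**: glomerular filtration of unbound drug, RNase-mediated
  degradation in plasma and non-liver tissue endosomes (disabled in liver),
  and liver endosomal decay; every elimination is routed into a ledger
  state so each simulation carries a mass-balance audit.
* **Species translation**: the mouse is the standard individual;
  `k_endosome` scales allometrically as `(BW_i/BW_std)^{-0.25}`, and the
  remaining species-specific parameters (ka, P_liver, liver recycling, RISC
  parameters, receptor density) use the tabulated per-species values.

## Worked example

```r
library(galnacpbpk)

p <- assemble_parameterization("siRNA-1", "mouse")
sim <- simulate_pbpk(p, dose_regimen(3), t_end = 1500)   # 3 mg/kg SC

round(observable_at(sim, "plasma", c(1, 8, 24, 336)), 5)
#> [1] 0.16476 0.00068 0.00020 0.00007
round(observable_at(sim, "liver", c(8, 24, 336)), 1)
#> [1] 17.3 16.1  4.1
round(min(sim$observables$value[sim$observables$observable == "mrna"]), 1)
#> [1] 87.4
round(sim$audit$eliminated["elim_liver_endosome"] / sim$total_dose_umol, 2)
#> elim_liver_endosome
#>                0.79
```

The plasma curve (µg/mL) shows the three characteristic phases: an
absorption peak around 1 h, a rapid receptor-driven decline to ~10 h, and a
shallow redistribution phase thereafter. The liver holds most of the
absorbed dose and decays with the ~139 h endosomal half-life
(`ln 2 / k_endosome`); at 3 mg/kg about 79% of the absorbed dose is
eventually degraded in the liver endosome, and target liver mRNA dips to
~87% of baseline (deep knockdown needs the higher dose groups).

Sensitivity analysis and estimation follow the same pattern:

```r
sensitivity_coefficient(p, "F", "plasma")        # S = 1, "high"
d   <- study_design("siRNA-1", "mouse", biospecimens = c("plasma", "liver"))
obs <- generate_study(d, p, seed = 1)            # noisy synthetic study
fs  <- fit_spec(p, free = "F", lower = 0.05, upper = 0.95,
                data = obs$observations)
monte_carlo_fit(fs, seed = 1)$par                # 0.4717 (truth 0.47)
```

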