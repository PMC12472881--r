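# Elementary transport and elimination processes of the whole-body model.
# All component functions work in model units (amounts umol, time h,
# volumes L, concentrations umol/L) and are the same expressions the
# assembled right-hand side uses, so they can be tested in isolation.

#' Non-specific endosomal trafficking fluxes
#'
#' First-order uptake from the interstitial space into the
#' endothelial-endosomal compartment and first-order recycling back.
#' Intracellular uptake is zero for all non-liver tissues; hepatocellular
#' entry is exclusively via the ASGPR pathway.
#'
#' @param A_interstitial,A_endosomal compartment amounts (umol).
#' @param k_uptake,k_recycle rate constants (1/min, as tabulated).
#' @return list with `uptake` and `recycle` fluxes (umol/h) and the net
#'   derivative contributions `dA_interstitial`, `dA_endosomal` (umol/h).
#' @export
endosomal_trafficking_rhs <- function(A_interstitial, A_endosomal,
                                      k_uptake, k_recycle) {
  if (k_uptake < 0 || k_recycle < 0)
    stop("trafficking rate constants must be non-negative")
  up <- 60 * k_uptake * A_interstitial
  re <- 60 * k_recycle * A_endosomal
  list(uptake = up, recycle = re,
       dA_interstitial = re - up, dA_endosomal = up - re)
}

#' RNase-mediated degradation rate
#'
#' Metabolic elimination in plasma and in the endosomal compartment of the
#' kidney and remaining tissues: second order in the local RNase abundance
#' and the drug concentration. The reaction is disabled in the liver, where
#' endosomal degradation is governed separately by `k_endosome`.
#'
#' @param C drug concentration (umol/L).
#' @param RNase_conc local ribonuclease abundance (umol/L).
#' @param k_RNase rate constant (1/(umol/L)/h).
#' @param organ organ name; `"liver"` returns 0.
#' @param V compartment volume (L; default 1 gives the rate per litre).
#' @return elimination rate (umol/h).
#' @export
rnase_degradation_rate <- function(C, RNase_conc, k_RNase, organ, V = 1) {
  if (any(c(C, RNase_conc, k_RNase, V) < 0))
    stop("inputs must be non-negative")
  if (identical(organ, "liver")) return(0)
  k_RNase * RNase_conc * C * V
}

#' Glomerular filtration of unbound drug
#'
#' @param C_plasma plasma concentration in the kidney vascular space
#'   (umol/L).
#' @param fu unbound fraction in plasma.
#' @param GFR glomerular filtration rate (L/h).
#' @return elimination flux into urine (umol/h).
#' @export
renal_filtration_rate <- function(C_plasma, fu, GFR) {
  if (any(c(C_plasma, fu, GFR) < 0) || fu > 1)
    stop("need C_plasma >= 0, GFR >= 0 and fu in [0, 1]")
  GFR * fu * C_plasma
}

#' First-order subcutaneous absorption
#'
#' The depot is initialized to `F x dose` at each dosing time and drains
#' into venous plasma; there is no depot loss pathway, so the totally
#' absorbed amount equals `F x dose`.
#'
#' @param depot depot amount (umol).
#' @param ka absorption rate constant (1/h).
#' @return absorption flux into venous plasma (umol/h).
#' @export
sc_absorption_rate <- function(depot, ka) {
  if (ka < 0) stop("ka must be non-negative")
  ka * depot
}

#' Passive bidirectional permeation across the liver endothelium
#'
#' Additional (non-pore) translocation pathway across the fenestrated liver
#' capillary wall, added to the liver two-pore flux.
#'
#' @param C_vascular,C_interstitial concentrations (umol/L).
#' @param P_liver permeability (cm/min).
#' @param S_cap capillary exchange surface (cm^2).
#' @return flux vascular to interstitial (umol/h); negative when the
#'   gradient is reversed.
#' @export
liver_passive_permeation <- function(C_vascular, C_interstitial, P_liver,
                                     S_cap) {
  if (any(c(C_vascular, C_interstitial, P_liver, S_cap) < 0))
    stop("inputs must be non-negative")
  PS <- P_liver * S_cap * 60 / 1000   # cm^3/min -> L/h
  PS * (C_vascular - C_interstitial)
}
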