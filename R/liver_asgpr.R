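# Extended TMDD model of ASGPR-mediated hepatic uptake and RISC kinetics.
# Component functions operate in concentration space (umol/L, 1/h) for
# direct comparison with reduced-system oracles; the whole-body assembly
# applies the same rate expressions to compartment amounts.

#' ASGPR surface binding dynamics
#'
#' Second-order association of the GalNAc conjugate with free surface
#' receptor, first-order dissociation and internalization, receptor turnover
#' (synthesis/degradation) and receptor return from the internalized pool.
#'
#' @param C_liver_interstitial free drug concentration at the hepatocyte
#'   surface (umol/L).
#' @param R free surface receptor (umol/L).
#' @param DR_s surface drug-receptor complex (umol/L).
#' @param params list with `k_on` (L/nmol/h), `k_off`, `k_int`, `k_syn`
#'   (umol/L/h), `k_deg`, `k_rec` (1/h); optional `R_i` (internalized free
#'   receptor, umol/L, default 0).
#' @return list of derivative contributions (umol/L/h): `dR`, `dDR_s`,
#'   `dC_drug` (change of free drug), and the elementary fluxes `binding`,
#'   `dissociation`, `internalization`.
#' @export
asgpr_binding_rhs <- function(C_liver_interstitial, R, DR_s, params) {
  if (any(c(C_liver_interstitial, R, DR_s) < 0))
    stop("states must be non-negative")
  p <- params
  R_i <- if (is.null(p$R_i)) 0 else p$R_i
  bind <- 1000 * p$k_on * C_liver_interstitial * R   # L/nmol/h -> 1/(umol/L)/h
  diss <- p$k_off * DR_s
  int <- p$k_int * DR_s
  list(dR = p$k_syn - p$k_deg * R - bind + diss + p$k_rec * R_i,
       dDR_s = bind - diss - int,
       dC_drug = diss - bind,
       binding = bind, dissociation = diss, internalization = int)
}

#' Liver endosomal processing of internalized complex
#'
#' The internalized complex is cleaved at `k_cle`, freeing the receptor into
#' an internal pool (recycled to the surface at `k_rec`, degraded at
#' `k_deg_R`) and the siRNA into the endosomal pool. A fraction `f_escape`
#' of the cleaved flux escapes directly to the cytoplasm as antisense strand
#' (set `escape_mode = "pool"` for first-order escape from the endosomal
#' pool instead); endosomal drug degrades at `k_endosome`.
#'
#' @param DR_i internalized complex (umol/L).
#' @param A_endo free drug in the liver (ASGPR-derived) endosome (umol/L).
#' @param R_i internalized free receptor (umol/L).
#' @param params list with `k_cle`, `k_endosome`, `f_escape`, `k_rec`,
#'   `k_deg_R`; optional `escape_mode` (`"flux"` default, or `"pool"`).
#' @return list of derivative contributions (umol/L/h): `dDR_i`, `dA_endo`,
#'   `dR_i`, plus fluxes `escape`, `degradation` and the receptor return
#'   flux `recycle_R`.
#' @export
endosomal_processing_rhs <- function(DR_i, A_endo, R_i, params) {
  if (any(c(DR_i, A_endo, R_i) < 0)) stop("states must be non-negative")
  p <- params
  mode <- if (is.null(p$escape_mode)) "flux" else p$escape_mode
  cle <- p$k_cle * DR_i
  if (mode == "flux") {
    escape <- p$f_escape * cle
    to_endo <- cle - escape
    esc_pool <- 0
  } else {
    escape <- p$f_escape * A_endo          # 1st-order escape from the pool
    to_endo <- cle
    esc_pool <- escape
  }
  deg <- p$k_endosome * A_endo
  list(dDR_i = -cle,
       dA_endo = to_endo - deg - esc_pool,
       dR_i = cle - (p$k_rec + p$k_deg_R) * R_i,
       escape = escape, degradation = deg,
       recycle_R = p$k_rec * R_i)
}

#' RISC loading and turnover kinetics
#'
#' Second-order association of cytoplasmic antisense strand with free RISC,
#' slow dissociation, and first-order degradation of the loaded complex.
#' Degradation destroys the guide strand only and returns free RISC to the
#' pool, so total RISC is conserved.
#'
#' @param A cytoplasmic antisense strand (umol/L).
#' @param RISC_free free RISC (umol/L).
#' @param CRISC siRNA-loaded RISC (umol/L).
#' @param params list with `k_onRISC` (L/nmol/h), `k_offRISC`, `k_DR`,
#'   `k_deg_C` (1/h).
#' @return list of derivative contributions (umol/L/h): `dA`, `dRISC_free`,
#'   `dCRISC`.
#' @export
risc_kinetics_rhs <- function(A, RISC_free, CRISC, params) {
  if (any(c(A, RISC_free, CRISC) < 0)) stop("states must be non-negative")
  p <- params
  load <- 1000 * p$k_onRISC * A * RISC_free
  rel <- (p$k_offRISC + p$k_DR) * CRISC
  list(dA = -load - p$k_deg_C * A + p$k_offRISC * CRISC,
       dRISC_free = -load + rel,
       dCRISC = load - rel)
}
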