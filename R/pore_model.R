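# Two-pore capillary extravasation.
#
# The capillary wall carries two parallel pore populations (small and large).
# For each population the solute flux follows the Patlak expression
#   J_s = J_v (1 - sigma) (C_v - C_i exp(-Pe)) / (1 - exp(-Pe)),
#   Pe  = J_v (1 - sigma) / PS,
# where the reflection coefficient sigma and the permeability-surface product
# PS derive from steric pore hindrance at the ratio lambda = r_solute/r_pore.
# Fluid flow: net trans-capillary filtration equals organ lymph flow, split
# between the populations by their hydraulic conductance fractions, with an
# isogravimetric circular flux recirculating through large (out) and small
# (in) pores.

#' Default two-pore configuration
#'
#' Standard two-pore literature constants: small/large pore radii, fraction
#' of hydraulic conductance through large pores, isogravimetric circular flux
#' as a multiple of organ lymph flow, effective net filtration pressure used
#' to convert lymph flow into hydraulic conductance, plasma viscosity and
#' temperature for the Stokes-Einstein diffusivity.
#'
#' @param r_small,r_large pore radii (nm).
#' @param alpha_large fraction of hydraulic conductance via large pores.
#' @param J_iso_frac isogravimetric circular flux / lymph flow.
#' @param dP_eff effective net filtration pressure (mmHg).
#' @param eta plasma viscosity (Pa s), `temperature` (K).
#' @param temperature absolute temperature (K).
#' @return a list of class `pore_config`.
#' @export
default_pore_config <- function(r_small = 4.5, r_large = 25,
                                alpha_large = 0.05, J_iso_frac = 0.5,
                                dP_eff = 1.0, eta = 6.91e-4,
                                temperature = 310.15) {
  stopifnot(r_small > 0, r_large > r_small, alpha_large > 0,
            alpha_large < 1, dP_eff > 0, eta > 0, temperature > 0,
            J_iso_frac >= 0)
  structure(list(r_small = r_small, r_large = r_large,
                 alpha_large = alpha_large, J_iso_frac = J_iso_frac,
                 dP_eff = dP_eff, eta = eta, temperature = temperature),
            class = "pore_config")
}

# steric hindrance for a sphere in a cylindrical pore, lambda = r_s/r_pore:
# partitioning (1-lambda)^2, Renkin diffusive hindrance, and the convective
# sieving coefficient 1 - sigma = Phi (2 - Phi) (1 - lambda^2/3)
pore_hindrance <- function(lambda) {
  if (lambda >= 1) return(list(phi = 0, F_diff = 0, sigma = 1))
  phi <- (1 - lambda)^2
  F_diff <- phi * (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5)
  F_diff <- max(F_diff, 0)
  sigma <- 1 - phi * (2 - phi) * (1 - lambda^2 / 3)
  list(phi = phi, F_diff = F_diff, sigma = sigma)
}

# free diffusivity from Stokes-Einstein, m^2/h; r in nm
stokes_einstein_D <- function(r_nm, eta, temperature) {
  kB <- 1.380649e-23
  kB * temperature / (6 * pi * eta * (r_nm * 1e-9)) * 3600
}

#' Linearized two-pore exchange coefficients for one organ
#'
#' Computes, for both pore populations, the fluid fluxes, reflection
#' coefficients and permeability-surface products for a solute of given
#' hydrodynamic radius, and folds the Patlak expression into linear exchange
#' coefficients so that the vascular-to-interstitial solute flux is
#' `a * C_v - b * C_i` (umol/h with concentrations in umol/L).
#'
#' @param L_lymph organ lymph flow (L/h), which equals net trans-capillary
#'   fluid filtration at steady state.
#' @param solute_radius hydrodynamic radius of the solute (nm).
#' @param pore_config see [default_pore_config()].
#' @param conductance_flux fluid flux (L/h) used to size the hydraulic
#'   conductance (and hence the pore areas); defaults to `L_lymph`. The
#'   kidney uses its glomerular filtration rate here: its fenestrated
#'   capillary walls cycle the reabsorbed filtrate, a fluid turnover two
#'   orders of magnitude above its lymph drainage.
#' @return list with `a`, `b` (L/h) and per-pore details (`J`, `sigma`, `PS`,
#'   `Pe`).
#' @export
two_pore_coefficients <- function(L_lymph, solute_radius,
                                  pore_config = default_pore_config(),
                                  conductance_flux = NULL) {
  pc <- pore_config
  if (!is.numeric(solute_radius) || solute_radius <= 0)
    stop("solute_radius must be positive")
  if (L_lymph < 0) stop("lymph flow must be non-negative")
  # hydraulic conductance sized from the organ's transcapillary fluid
  # turnover (lymph flow by default; organs with reabsorptive fluid cycling
  # such as the kidney pass far more fluid than their lymph drains)
  if (is.null(conductance_flux)) conductance_flux <- L_lymph
  LpS <- (conductance_flux * 1e-3) / (pc$dP_eff * 133.322)   # m^3/(h Pa)
  eta_h <- pc$eta / 3600                               # Pa h
  D <- stokes_einstein_D(solute_radius, pc$eta, pc$temperature)
  J_iso <- pc$J_iso_frac * L_lymph
  out <- list(a = 0, b = 0, pores = list())
  for (pore in c("small", "large")) {
    r_p <- if (pore == "small") pc$r_small else pc$r_large
    alpha <- if (pore == "small") 1 - pc$alpha_large else pc$alpha_large
    J <- if (pore == "small") alpha * L_lymph - J_iso
    else alpha * L_lymph + J_iso                        # L/h
    h <- pore_hindrance(solute_radius / r_p)
    A0_dx <- 8 * eta_h * (alpha * LpS) / (r_p * 1e-9)^2    # m
    PS <- D * h$F_diff * A0_dx * 1e3                    # L/h
    Jeff <- J * (1 - h$sigma)
    if (PS <= 0) {
      a <- max(Jeff, 0); b <- max(-Jeff, 0)             # pure convection
      Pe <- Inf
    } else {
      Pe <- Jeff / PS
      if (abs(Pe) < 1e-12) {            # diffusive limit
        a <- PS; b <- PS
      } else if (Pe > 700) {            # convective limit guard
        a <- Jeff; b <- 0
      } else if (Pe < -700) {
        a <- 0; b <- -Jeff
      } else {
        a <- Jeff / (-expm1(-Pe))
        b <- a * exp(-Pe)
      }
    }
    out$a <- out$a + a
    out$b <- out$b + b
    out$pores[[pore]] <- list(J = J, sigma = h$sigma, PS = PS, Pe = Pe)
  }
  out
}

#' Two-pore solute flux between vascular and interstitial space
#'
#' Patlak convection-diffusion flux summed over the small- and large-pore
#' populations. Positive values are vascular-to-interstitial transport.
#'
#' @param C_vascular,C_interstitial solute concentrations (umol/L).
#' @param organ one-row organ data frame (as in
#'   `load_species_physiology()$organs`) providing `L_lymph`.
#' @param solute_radius hydrodynamic radius (nm).
#' @param pore_config see [default_pore_config()].
#' @return solute flux (umol/h).
#' @examples
#' phys <- load_species_physiology("mouse")
#' two_pore_flux(1, 0, phys$organs[phys$organs$organ == "muscle", ], 3)
#' @export
two_pore_flux <- function(C_vascular, C_interstitial, organ, solute_radius,
                          pore_config = default_pore_config()) {
  if (C_vascular < 0 || C_interstitial < 0)
    stop("concentrations must be non-negative")
  cf <- two_pore_coefficients(organ$L_lymph, solute_radius, pore_config)
  cf$a * C_vascular - cf$b * C_interstitial
}
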