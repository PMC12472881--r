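# Indirect-response pharmacodynamics: loaded RISC stimulates mRNA
# degradation; protein production follows mRNA through a power law.
# mRNA and Protein are fractions of baseline (baseline 1 = 100%).

#' Turnover of target mRNA under RISC-mediated silencing
#'
#' `d(mRNA)/dt = k_deg_mRNA * (1 - (1 + S_max * C/(SC_50 + C)) * mRNA)`
#' with `C` the loaded-RISC concentration; at `C = 0` the baseline
#' `mRNA = 1` is a steady state.
#'
#' @param mRNA mRNA as fraction of baseline.
#' @param CRISC loaded RISC concentration (nmol/L).
#' @param S_max maximum stimulation of mRNA degradation (dimensionless).
#' @param SC_50 loaded RISC at half-maximal stimulation (nmol/L).
#' @param k_deg_mRNA mRNA turnover rate (1/h).
#' @return d(mRNA)/dt (1/h).
#' @export
mrna_rhs <- function(mRNA, CRISC, S_max, SC_50, k_deg_mRNA) {
  if (mRNA < 0 || CRISC < 0) stop("states must be non-negative")
  stim <- S_max * CRISC / (SC_50 + CRISC)
  k_deg_mRNA * (1 - (1 + stim) * mRNA)
}

#' Turnover of target protein driven by mRNA level
#'
#' `d(Protein)/dt = k_deg_protein * ((mRNA)^gamma - Protein)`; gamma is an
#' empirical power shaping the steepness of the protein response.
#'
#' @param Protein protein as fraction of baseline.
#' @param mRNA mRNA as fraction of baseline.
#' @param k_deg_protein protein turnover rate (1/h).
#' @param gamma power coefficient (> 0).
#' @return d(Protein)/dt (1/h).
#' @export
protein_rhs <- function(Protein, mRNA, k_deg_protein, gamma) {
  if (Protein < 0 || mRNA < 0) stop("states must be non-negative")
  k_deg_protein * (mRNA^gamma - Protein)
}

#' Closed-form steady-state knockdown at constant loaded RISC
#'
#' `mRNA_ss = 1 / (1 + S_max * C/(SC_50 + C))`, `Protein_ss = mRNA_ss^gamma`.
#' ODE trajectories with constant `CRISC` converge to these values.
#'
#' @inheritParams mrna_rhs
#' @inheritParams protein_rhs
#' @return list with `mRNA` and `Protein` steady-state fractions of
#'   baseline.
#' @examples
#' steady_state_knockdown(3.52, 58.84, 3.52, 1.5)
#' @export
steady_state_knockdown <- function(CRISC, S_max, SC_50, gamma) {
  if (CRISC < 0) stop("CRISC must be non-negative")
  m <- 1 / (1 + S_max * CRISC / (SC_50 + CRISC))
  list(mRNA = m, Protein = m^gamma)
}
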