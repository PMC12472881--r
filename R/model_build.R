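# Whole-body model assembly.
#
# The full right-hand side is affine-linear (transport, trafficking,
# eliminations) plus a small nonlinear block (ASGPR binding, RISC loading,
# indirect-response PD). Assembly therefore precomputes a constant matrix M
# and constant vector c0 so that
#     dy/dt = c0 + M y + n(y),
# where n(y) carries the two bilinear couplings and the PD turnover. This
# makes the RHS cheap and gives an exact analytic Jacobian M + dn/dy.

state_layout <- function(organs) {
  nm <- c("depot", "ven", "art", "lymph",
          as.vector(t(outer(organs, c("vas", "int", "endo"), paste,
                            sep = "_"))),
          "asgpr_R", "asgpr_DRs", "asgpr_DRi", "asgpr_Ri",
          "liver_endo_asgpr", "liver_cyto", "risc_free", "risc_loaded",
          "mrna", "protein",
          "urine", "elim_plasma_rnase", "elim_tissue_rnase",
          "elim_liver_endosome", "elim_cyto", "elim_risc")
  setNames(seq_along(nm), nm)
}

# drug-bearing states (for mass balance); complexes carry one drug molecule
drug_states <- function(idx) {
  nm <- names(idx)
  nm[grepl("_(vas|int|endo)$", nm) |
       nm %in% c("depot", "ven", "art", "lymph", "asgpr_DRs", "asgpr_DRi",
                 "liver_endo_asgpr", "liver_cyto", "risc_loaded")]
}

elim_states <- function(idx) {
  c("urine", "elim_plasma_rnase", "elim_tissue_rnase",
    "elim_liver_endosome", "elim_cyto", "elim_risc")
}

#' Build the assembled whole-body ODE system
#'
#' Constructs the constant part of the right-hand side (blood and lymph
#' transport with portal drainage, two-pore extravasation, liver passive
#' permeation, endosomal trafficking, RNase and liver-endosomal degradation,
#' glomerular filtration, subcutaneous absorption, and all first-order parts
#' of the ASGPR/RISC cascade) plus closures for the nonlinear couplings and
#' the exact Jacobian. Elimination fluxes are routed into cumulative
#' accumulator states, which provides the mass-balance ledger.
#'
#' @param parameterization a [assemble_parameterization()] result.
#' @param pore_config two-pore constants, see [default_pore_config()].
#' @param options list of structural switches: `recycle_to_vascular`
#'   (fraction of endosomal recycling returned to the vascular rather than
#'   the interstitial side, default 0), `uptake_from_vascular` (`TRUE` also
#'   takes up into endothelial endosomes from the vascular side, default
#'   `FALSE`), `asgpr_site` (`"interstitial"` default, or `"vascular"` to
#'   bind ASGPR at the sinusoidal plasma face), `escape_mode` (`"flux"`
#'   default or `"pool"`), `plasma_rnase_central_only` (default `TRUE`;
#'   `FALSE` also applies the plasma reaction in every organ vascular
#'   space).
#' @return an object of class `pbpk_model` with elements `rhs(t, y, parms)`,
#'   `jac(t, y, parms)`, `idx` (state index), `y0`, `M`, `c0`, volumes and
#'   bookkeeping used by [simulate_pbpk()].
#' @export
build_whole_body_rhs <- function(parameterization,
                                 pore_config = default_pore_config(),
                                 options = list()) {
  p <- parameterization
  if (!inherits(p, "parameterization"))
    stop("parameterization must come from assemble_parameterization()")
  v <- p$values
  phys <- p$physiology
  org <- phys$organs
  organs <- org$organ
  idx <- state_layout(organs)
  n <- length(idx)
  opt <- list(recycle_to_vascular = 0, uptake_from_vascular = FALSE,
              asgpr_site = "interstitial", escape_mode = "flux",
              plasma_rnase_central_only = TRUE)
  opt[names(options)] <- options

  M <- matrix(0, n, n, dimnames = list(names(idx), names(idx)))
  c0 <- numeric(n)

  i_dep <- idx["depot"]; i_ven <- idx["ven"]; i_art <- idx["art"]
  i_lym <- idx["lymph"]
  iv <- idx[paste0(organs, "_vas")]
  ii <- idx[paste0(organs, "_int")]
  ie <- idx[paste0(organs, "_endo")]
  names(iv) <- names(ii) <- names(ie) <- organs

  V_vas <- setNames(org$V_vascular, organs)
  V_int <- setNames(org$V_interstitial, organs)
  V_cell <- setNames(org$V_intracellular, organs)
  V_endo <- setNames(org$V_endosomal, organs)
  Q <- setNames(org$Q_plasma, organs)
  L <- setNames(org$L_lymph, organs)
  S_cap <- setNames(org$S_cap, organs)
  V_liver_tot <- V_vas["liver"] + V_int["liver"] + V_cell["liver"] +
    V_endo["liver"]

  add <- function(i, j, val) M[i, j] <<- M[i, j] + val

  # --- subcutaneous absorption
  add(i_dep, i_dep, -v$ka)
  add(i_ven, i_dep, v$ka)

  # --- circulation: ven -> lung -> art -> organs -> ven (portal via liver)
  Q_lung <- Q["lung"]
  add(i_ven, i_ven, -Q_lung / phys$V_venous)
  add(iv["lung"], i_ven, Q_lung / phys$V_venous)
  k_lung_out <- (Q_lung - L["lung"]) / V_vas["lung"]
  add(iv["lung"], iv["lung"], -k_lung_out)
  add(i_art, iv["lung"], k_lung_out)
  nonlung <- setdiff(organs, "lung")
  for (o in nonlung) {
    add(i_art, i_art, -Q[o] / phys$V_arterial)
    add(iv[o], i_art, Q[o] / phys$V_arterial)
  }
  # venous drainage; portal organs drain into the liver vascular space
  Q_liver_in <- Q["liver"] + sum(Q[PORTAL_ORGANS] - L[PORTAL_ORGANS])
  for (o in setdiff(nonlung, "liver")) {
    kout <- (Q[o] - L[o]) / V_vas[o]
    dest <- if (o %in% PORTAL_ORGANS) iv["liver"] else i_ven
    add(iv[o], iv[o], -kout)
    add(dest, iv[o], kout)
  }
  k_liv_out <- (Q_liver_in - L["liver"]) / V_vas["liver"]
  add(iv["liver"], iv["liver"], -k_liv_out)
  add(i_ven, iv["liver"], k_liv_out)

  # --- two-pore extravasation and liver passive permeation
  for (o in organs) {
    cf <- two_pore_coefficients(L[o], v$r_hyd, pore_config,
                                conductance_flux =
                                  if (o == "kidney") phys$GFR else NULL)
    a <- cf$a; b <- cf$b
    if (o == "liver") {
      PS <- v$P_liver * S_cap["liver"] * 60 / 1000
      a <- a + PS; b <- b + PS
    }
    add(ii[o], iv[o], a / V_vas[o]); add(iv[o], iv[o], -a / V_vas[o])
    add(iv[o], ii[o], b / V_int[o]); add(ii[o], ii[o], -b / V_int[o])
    # lymph drainage of the interstitial space
    add(i_lym, ii[o], L[o] / V_int[o]); add(ii[o], ii[o], -L[o] / V_int[o])
  }
  add(i_ven, i_lym, sum(L) / phys$V_lymph)
  add(i_lym, i_lym, -sum(L) / phys$V_lymph)

  # --- non-specific endosomal trafficking (rates tabulated per minute)
  k_up <- setNames(rep(v$k_uptake_generic, length(organs)), organs)
  k_up[c("liver", "kidney", "gonads", "lung", "heart", "spleen")] <-
    c(v$k_uptake_liver, v$k_uptake_kidney, v$k_uptake_gonads,
      v$k_uptake_lung, v$k_uptake_heart, v$k_uptake_spleen)
  k_re <- setNames(rep(v$k_recycle_tissue, length(organs)), organs)
  k_re[c("liver", "kidney")] <- c(v$k_recycle_liver, v$k_recycle_kidney)
  fr_v <- opt$recycle_to_vascular
  for (o in organs) {
    up <- 60 * k_up[o]; re <- 60 * k_re[o]
    add(ie[o], ii[o], up); add(ii[o], ii[o], -up)
    if (isTRUE(opt$uptake_from_vascular)) {
      add(ie[o], iv[o], up); add(iv[o], iv[o], -up)
    }
    add(ii[o], ie[o], re * (1 - fr_v))
    add(iv[o], ie[o], re * fr_v)
    add(ie[o], ie[o], -re)
  }

  # --- RNase degradation (disabled in liver) and liver endosomal decay
  i_etr <- idx["elim_tissue_rnase"]
  for (o in setdiff(organs, "liver")) {
    ab <- if (o == "kidney") v$RNase_kidney else v$RNase_remaining
    k <- v$k_RNase * ab
    add(i_etr, ie[o], k); add(ie[o], ie[o], -k)
  }
  k_pl <- v$k_RNase * v$RNase_plasma
  i_epl <- idx["elim_plasma_rnase"]
  for (i in c(i_ven, i_art)) {
    add(i_epl, i, k_pl); add(i, i, -k_pl)
  }
  if (!opt$plasma_rnase_central_only) {
    for (o in organs) {
      add(i_epl, iv[o], k_pl); add(iv[o], iv[o], -k_pl)
    }
  }
  i_ele <- idx["elim_liver_endosome"]
  add(i_ele, ie["liver"], v$k_endosome)
  add(ie["liver"], ie["liver"], -v$k_endosome)

  # --- glomerular filtration from the kidney vascular space
  k_fil <- phys$GFR * v$fu / V_vas["kidney"]
  add(idx["urine"], iv["kidney"], k_fil)
  add(iv["kidney"], iv["kidney"], -k_fil)

  # --- ASGPR cascade, linear part (amount space)
  iR <- idx["asgpr_R"]; iDRs <- idx["asgpr_DRs"]; iDRi <- idx["asgpr_DRi"]
  iRi <- idx["asgpr_Ri"]; iEA <- idx["liver_endo_asgpr"]
  iCy <- idx["liver_cyto"]; iRF <- idx["risc_free"]; iRL <- idx["risc_loaded"]
  iLi <- if (opt$asgpr_site == "vascular") iv["liver"] else ii["liver"]
  c0[iR] <- v$k_syn * unname(V_int["liver"])
  add(iR, iR, -v$k_deg)
  add(iR, iDRs, v$k_off); add(iLi, iDRs, v$k_off)
  add(iR, iRi, v$k_rec)
  add(iDRs, iDRs, -(v$k_off + v$k_int))
  add(iDRi, iDRs, v$k_int)
  add(iDRi, iDRi, -v$k_cle)
  add(iRi, iDRi, v$k_cle)
  add(iRi, iRi, -(v$k_rec + v$k_deg_R))
  if (opt$escape_mode == "flux") {
    add(iEA, iDRi, (1 - v$f_escape) * v$k_cle)
    add(iCy, iDRi, v$f_escape * v$k_cle)
    add(iEA, iEA, -v$k_endosome)
    add(i_ele, iEA, v$k_endosome)
  } else {
    add(iEA, iDRi, v$k_cle)
    add(iCy, iEA, v$f_escape)
    add(iEA, iEA, -(v$k_endosome + v$f_escape))
    add(i_ele, iEA, v$k_endosome)
  }
  add(iCy, iCy, -v$k_deg_C)
  add(idx["elim_cyto"], iCy, v$k_deg_C)
  add(iCy, iRL, v$k_offRISC)
  add(iRF, iRL, v$k_offRISC + v$k_DR)
  add(iRL, iRL, -(v$k_offRISC + v$k_DR))
  add(idx["elim_risc"], iRL, v$k_DR)

  # --- nonlinear couplings
  kon <- 1000 * v$k_on          # 1/(umol/L)/h
  konR <- 1000 * v$k_onRISC
  ViL <- if (opt$asgpr_site == "vascular") unname(V_vas["liver"]) else
    unname(V_int["liver"])
  VcL <- unname(V_cell["liver"])
  im <- idx["mrna"]; ipr <- idx["protein"]
  S_max <- v$S_max; SC50 <- v$SC_50; gam <- v$gamma
  kdm <- v$k_deg_mRNA; kdp <- v$k_deg_protein

  rhs <- function(t, y, parms) {
    dy <- c0 + M %*% y
    bind <- kon * (y[iLi] / ViL) * y[iR]
    dy[iLi] <- dy[iLi] - bind
    dy[iR] <- dy[iR] - bind
    dy[iDRs] <- dy[iDRs] + bind
    load <- konR * (y[iCy] / VcL) * y[iRF]
    dy[iCy] <- dy[iCy] - load
    dy[iRF] <- dy[iRF] - load
    dy[iRL] <- dy[iRL] + load
    Cn <- 1000 * y[iRL] / VcL              # nmol/L
    stim <- S_max * Cn / (SC50 + Cn)
    dy[im] <- kdm * (1 - (1 + stim) * y[im])
    dy[ipr] <- kdp * (max(y[im], 0)^gam - y[ipr])
    list(dy)
  }

  jac <- function(t, y, parms) {
    J <- M
    bC <- kon * y[iR] / ViL       # d bind / d liver_int
    bR <- kon * y[iLi] / ViL      # d bind / d R
    J[iLi, iLi] <- J[iLi, iLi] - bC; J[iLi, iR] <- J[iLi, iR] - bR
    J[iR, iLi] <- J[iR, iLi] - bC;   J[iR, iR] <- J[iR, iR] - bR
    J[iDRs, iLi] <- J[iDRs, iLi] + bC; J[iDRs, iR] <- J[iDRs, iR] + bR
    lC <- konR * y[iRF] / VcL
    lF <- konR * y[iCy] / VcL
    J[iCy, iCy] <- J[iCy, iCy] - lC; J[iCy, iRF] <- J[iCy, iRF] - lF
    J[iRF, iCy] <- J[iRF, iCy] - lC; J[iRF, iRF] <- J[iRF, iRF] - lF
    J[iRL, iCy] <- J[iRL, iCy] + lC; J[iRL, iRF] <- J[iRL, iRF] + lF
    Cn <- 1000 * y[iRL] / VcL
    stim <- S_max * Cn / (SC50 + Cn)
    dstim <- S_max * SC50 / (SC50 + Cn)^2 * (1000 / VcL)
    J[im, im] <- -kdm * (1 + stim)
    J[im, iRL] <- -kdm * y[im] * dstim
    J[ipr, im] <- kdp * gam * max(y[im], 1e-300)^(gam - 1)
    J[ipr, ipr] <- -kdp
    J
  }

  y0 <- numeric(n)
  y0[iR] <- v$R_tot * unname(V_int["liver"])
  y0[iRF] <- v$RISC_tot * VcL
  y0[im] <- 1
  y0[ipr] <- 1

  structure(list(rhs = rhs, jac = jac, idx = idx, y0 = y0, M = M, c0 = c0,
                 organs = organs, iv = iv, ii = ii, ie = ie,
                 V_vas = V_vas, V_int = V_int, V_cell = V_cell,
                 V_endo = V_endo, V_liver_tot = V_liver_tot,
                 parameterization = p, options = opt),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s x %s: %d states (%d tissues)\n",
              x$parameterization$compound_id, x$parameterization$species,
              length(x$idx), length(x$organs)))
  invisible(x)
}
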