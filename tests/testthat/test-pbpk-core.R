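test_that("endosomal trafficking fluxes and limiting behaviour", {
  tr <- endosomal_trafficking_rhs(2, 3, k_uptake = 0.5, k_recycle = 0.1)
  expect_equal(tr$uptake, 60 * 0.5 * 2)
  expect_equal(tr$recycle, 60 * 0.1 * 3)
  expect_equal(tr$dA_interstitial, -tr$dA_endosomal)
  expect_equal(endosomal_trafficking_rhs(2, 3, 0, 0.1)$uptake, 0)
  expect_error(endosomal_trafficking_rhs(1, 1, -1, 0), "non-negative")
})

test_that("kidney endosome/interstitial ratio reaches k_uptake/k_recycle at
           quasi-steady state (2-state oracle)", {
  k_up <- 24.98; k_re <- 3.90e-4      # 1/min
  rhs <- function(t, y, p) {
    tr <- endosomal_trafficking_rhs(y[1], y[2], k_up, k_re)
    list(c(tr$dA_interstitial + 1e-3 * (1 - y[1]),  # slow constant supply
           tr$dA_endosomal))
  }
  out <- deSolve::lsoda(c(1, 0), c(0, 1e5), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-14)
  ratio <- out[2, 3] / out[2, 2]
  expect_equal(unname(ratio), k_up / k_re, tolerance = 1e-3)
})

test_that("RNase degradation is second order, disabled in liver", {
  expect_equal(rnase_degradation_rate(2, 1.17, 1.21e-4, "kidney", V = 3),
               1.21e-4 * 1.17 * 2 * 3)
  expect_equal(rnase_degradation_rate(5, 10, 1, "liver"), 0)
  expect_equal(rnase_degradation_rate(0, 1.17, 1.21e-4, "kidney"), 0)
  # kidney-to-remaining abundance ratio sets the rate ratio at equal C
  r_kid <- rnase_degradation_rate(1, 1.17, 1.21e-4, "kidney")
  r_rem <- rnase_degradation_rate(1, 2.75e-2, 1.21e-4, "muscle")
  expect_equal(r_kid / r_rem, 1.17 / 2.75e-2)
  expect_equal(round(r_kid / r_rem, 1), 42.5)
})

test_that("renal filtration is linear in GFR and unbound concentration", {
  expect_equal(renal_filtration_rate(2, 0, 5), 0)
  expect_equal(renal_filtration_rate(2, 1, 5), 10)
  expect_equal(renal_filtration_rate(2, 1, 10), 20)
  expect_equal(renal_filtration_rate(3, 0.5, 4), 6)
  expect_error(renal_filtration_rate(1, 1.5, 1), "fu")
})

test_that("subcutaneous absorption: first order, conserves F x dose", {
  expect_equal(sc_absorption_rate(0, 0.84), 0)
  expect_equal(sc_absorption_rate(2, 0.84), 1.68)
  expect_equal(log(2) / 0.84, 0.825, tolerance = 1e-3)   # absorption t1/2
  # closed depot: fraction absorbed after t -> infinity equals F x dose
  sim <- sim_mouse_3()
  absorbed <- sim$total_dose_umol - sim$states[nrow(sim$states), "depot"]
  expect_equal(unname(absorbed / sim$total_dose_umol), 1, tolerance = 1e-9)
})

test_that("liver passive permeation is symmetric and species-ordered", {
  expect_equal(liver_passive_permeation(1, 1, 0.02, 100), 0)
  f1 <- liver_passive_permeation(2, 1, 0.02, 100)
  f2 <- liver_passive_permeation(1, 2, 0.02, 100)
  expect_equal(f1, -f2)
  # mouse vs human permeability ratio at equal gradient and area
  r <- liver_passive_permeation(1, 0, 0.02, 1) /
    liver_passive_permeation(1, 0, 1.21e-4, 1)
  expect_equal(r, 0.02 / 1.21e-4)
  expect_equal(round(r), 165)
})

test_that("zero initial state and zero dose give an identically zero drug RHS", {
  m <- build_whole_body_rhs(p_mouse())
  dy <- m$rhs(0, m$y0, NULL)[[1]]
  drug <- setdiff(names(m$idx), c("asgpr_R", "risc_free", "mrna", "protein"))
  expect_true(all(abs(dy[m$idx[drug]]) < 1e-12))
  # receptor and PD states are at homeostasis too
  expect_lt(abs(dy[m$idx["asgpr_R"]]), 1e-10)
  expect_equal(dy[m$idx["mrna"]], 0)
})

test_that("total drug is conserved when all eliminations are disabled", {
  pc <- p_mouse()
  for (nm in c("k_RNase", "k_endosome", "k_cle", "k_DR", "k_deg_C"))
    pc <- set_parameter(pc, nm, 0)
  pc <- set_parameter(pc, "GFR", 0)
  sim <- simulate_pbpk(pc, dose_regimen(10), t_end = 1000)
  expect_lt(sim$audit$max_residual, 1e-3)
})

test_that("analytic Jacobian matches a numerical differentiation of the RHS", {
  m <- build_whole_body_rhs(p_mouse())
  y <- m$y0
  # put drug everywhere to engage the bilinear terms
  y[] <- y + 1e-4
  J <- m$jac(0, y, NULL)
  f0 <- m$rhs(0, y, NULL)[[1]]
  set.seed(11)
  for (j in sample(seq_along(y), 12)) {
    h <- max(1e-8, abs(y[j]) * 1e-6)
    yh <- y; yh[j] <- yh[j] + h
    fd <- (m$rhs(0, yh, NULL)[[1]] - f0) / h
    expect_equal(unname(J[, j]), unname(as.vector(fd)), tolerance = 1e-4)
  }
})

test_that("simulated plasma shows absorption, rapid decline and a shallow
           redistribution phase after ~10 h", {
  sim <- sim_mouse_3()
  pl <- function(t) observable_at(sim, "plasma", t)
  expect_gt(pl(0.5), pl(4))                 # past the absorption peak by 4 h
  # rapid distribution/elimination phase: >100x drop between 2 and 10 h
  expect_gt(pl(2) / pl(10), 100)
  # shallow terminal phase: much slower decline after the transition
  slope_fast <- log(pl(2) / pl(8)) / 6
  slope_late <- log(pl(48) / pl(336)) / 288
  expect_gt(slope_fast / slope_late, 50)
  expect_gt(pl(336), 0)
})
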