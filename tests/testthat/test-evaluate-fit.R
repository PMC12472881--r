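test_that("trapezoidal AUC on canonical shapes", {
  expect_equal(auc_trapezoid(c(0, 10), c(3, 3)), 30)        # constant
  expect_equal(auc_trapezoid(c(0, 1), c(0, 2)), 1)
  # dense exponential decay vs closed form C0/k
  k <- 0.3; tt <- seq(0, 60, by = 0.05)
  a <- auc_trapezoid(tt, exp(-k * tt))
  expect_lt(abs(a - (1 - exp(-k * 60)) / k) / ((1 - exp(-k * 60)) / k),
            0.005)
  # window clipping, no extrapolation
  expect_equal(auc_trapezoid(c(0, 1, 2), c(1, 1, 1), -5, 10), 2)
  expect_error(auc_trapezoid(1, 1), "insufficient")
  expect_error(auc_trapezoid(c(2, 1), c(1, 1)), "sorted")
})

test_that("AFE and AAFE behave as geometric fold-error metrics", {
  expect_equal(afe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(aafe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(afe(c(2, 0.5), c(1, 1)), 1)
  expect_equal(aafe(c(2, 0.5), c(1, 1)), 2)
  expect_error(afe(c(1, -1), c(1, 1)), "positive")
  # acceptance bands: boundary values
  expect_false(fold_error_adequate(0.49, 1))
  expect_true(fold_error_adequate(0.5, 1))
  expect_true(fold_error_adequate(2, 2))
  expect_false(fold_error_adequate(1, 2.01))
})

test_that("AFE <= AAFE and AAFE >= 1 for random exposure pairs", {
  set.seed(42)
  for (i in 1:20) {
    sim <- exp(rnorm(8)); obs <- exp(rnorm(8))
    expect_gte(aafe(sim, obs), 1)
    expect_lte(afe(sim, obs), aafe(sim, obs))
  }
})

test_that("sensitivity classification uses the WHO-style bands", {
  expect_equal(classify_sensitivity(0.5), "high")
  expect_equal(classify_sensitivity(-0.3), "medium")
  expect_equal(classify_sensitivity(0.15), "low")
  expect_equal(classify_sensitivity(0.05), "negligible")
  expect_equal(classify_sensitivity(-2), "high")
  expect_error(classify_sensitivity(NaN), "finite")
})

test_that("sensitivity coefficient agrees with a central-difference
           derivative on a one-compartment closed form", {
  # AUC of a one-compartment SC model is F*Dose/(CL); S(AUC, F) = 1 and
  # S(AUC, CL) = -1 analytically. Check the finite-difference machinery on
  # the whole-body model in its linear regime against the F proportionality.
  s <- sensitivity_coefficient(p_mouse(), "F", "plasma",
                               dose_mg_per_kg = 0.01, t_end = 500,
                               rtol = 1e-7, atol = 1e-12)
  expect_equal(s$S, 1, tolerance = 0.01)
  expect_equal(s$class, "high")
})

test_that("parameters with no pathway to an output have zero sensitivity", {
  s <- sensitivity_coefficient(p_mouse(), "SC_50", "plasma",
                               dose_mg_per_kg = 1, t_end = 300,
                               rtol = 1e-6, atol = 1e-10)
  expect_lt(abs(s$S), 1e-4)
})

test_that("objective is zero at truth on noiseless data, increases under
           perturbation, and is invariant to unit rescaling", {
  p <- p_mouse()
  d <- study_design("siRNA-1", "mouse", doses = 3,
                    biospecimens = c("plasma", "liver"), cv = 0, n = 1)
  obs <- generate_study(d, p, seed = 1)
  fs <- fit_spec(p, free = "F", lower = 0.05, upper = 0.95,
                 data = obs$observations)
  l0 <- objective_function(fs, 0.47)
  expect_lt(l0, 1e-6)
  expect_gt(objective_function(fs, 0.6), l0)
  expect_gt(objective_function(fs, 0.3), l0)
  # log-space residuals make the loss invariant to a common unit rescaling
  # of predictions and observations
  r <- log10(c(2, 5) * 1000) - log10(c(1, 4) * 1000)
  expect_equal(sum(r^2), sum((log10(c(2, 5)) - log10(c(1, 4)))^2))
})

test_that("monte_carlo_fit is deterministic for a fixed seed and recovers a
           single parameter from noiseless data", {
  p <- p_mouse()
  d <- study_design("siRNA-1", "mouse", doses = 100,
                    biospecimens = "liver", cv = 0, n = 1)
  obs <- generate_study(d, p, seed = 3)
  fs <- fit_spec(p, free = "k_endosome", lower = 1e-4, upper = 1e-1,
                 data = obs$observations)
  f1 <- monte_carlo_fit(fs, seed = 5, n_starts = 2, block = 1)
  f2 <- monte_carlo_fit(fs, seed = 5, n_starts = 2, block = 1)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$value, f2$value)
  expect_lt(abs(f1$par - 5e-3) / 5e-3, 0.05)
  expect_true(f1$converged_by %in% c("break_condition", "budget"))
})

test_that("parameter recovery error shrinks as the noise CV decreases", {
  p <- p_mouse()
  seeds <- 1:5
  rmse_at <- function(cv) {
    err <- vapply(seeds, function(s) {
      d <- study_design("siRNA-1", "mouse", doses = 3,
                        biospecimens = "plasma", cv = cv)
      obs <- generate_study(d, p, seed = s)
      fs <- fit_spec(p, free = "F", lower = 0.05, upper = 0.95,
                     data = obs$observations)
      monte_carlo_fit(fs, seed = s, n_starts = 2, block = 1)$par - 0.47
    }, numeric(1))
    sqrt(mean(err^2))
  }
  r40 <- rmse_at(0.40); r20 <- rmse_at(0.20); r05 <- rmse_at(0.05)
  expect_gt(r40, r20)
  expect_gt(r20, r05)
})

test_that("a joint two-parameter fit recovers bioavailability and liver
           endosomal degradation together", {
  p <- p_mouse()
  d <- study_design("siRNA-1", "mouse", doses = c(3, 100),
                    biospecimens = c("plasma", "liver"), cv = 0.1)
  obs <- generate_study(d, p, seed = 21)
  fs <- fit_spec(p, free = c("F", "k_endosome"),
                 lower = c(0.1, 1e-3), upper = c(0.9, 2e-2),
                 data = obs$observations)
  fit <- monte_carlo_fit(fs, seed = 21, n_starts = 4, block = 2,
                         maxit = 150)
  expect_lt(abs(fit$par["F"] - 0.47) / 0.47, 0.25)
  expect_lt(abs(fit$par["k_endosome"] - 5e-3) / 5e-3, 0.25)
})
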