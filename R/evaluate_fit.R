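# Model-performance metrics, local sensitivity analysis, and seeded
# multistart least-squares estimation.

#' Linear trapezoidal AUC on an observation window
#'
#' No extrapolation is performed: the window is clipped to the observed time
#' range, with linear interpolation at the window edges.
#'
#' @param times sorted observation times (h).
#' @param values concentrations (or any response) at `times`.
#' @param t_start,t_end window limits (h); default full range.
#' @return area under the linear interpolant.
#' @examples
#' auc_trapezoid(c(0, 1), c(0, 2))   # 1
#' @export
auc_trapezoid <- function(times, values, t_start = NULL, t_end = NULL) {
  if (length(times) < 2L) stop("insufficient data: need at least 2 points")
  if (is.unsorted(times)) stop("times must be sorted")
  if (is.null(t_start)) t_start <- times[1L]
  if (is.null(t_end)) t_end <- times[length(times)]
  t_start <- max(t_start, times[1L])
  t_end <- min(t_end, times[length(times)])
  if (t_end <= t_start) stop("empty AUC window")
  keep <- times > t_start & times < t_end
  tt <- c(t_start, times[keep], t_end)
  vv <- approx(times, values, xout = tt, ties = "ordered")$y
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
}

#' Average fold error and absolute average fold error
#'
#' `AFE = 10^mean(log10(sim/obs))` measures bias; `AAFE =
#' 10^mean(|log10(sim/obs)|)` measures spread. Adequate model performance is
#' conventionally `0.5 <= AFE <= 2` and `AAFE <= 2`.
#'
#' @param sim,obs paired positive exposure metrics (e.g. AUCs), simulated
#'   and observed.
#' @return the metric (scalar).
#' @examples
#' afe(c(2, 0.5), c(1, 1))    # 1
#' aafe(c(2, 0.5), c(1, 1))   # 2
#' @export
afe <- function(sim, obs) {
  check_auc_pairs(sim, obs)
  10^mean(log10(sim / obs))
}

#' @rdname afe
#' @export
aafe <- function(sim, obs) {
  check_auc_pairs(sim, obs)
  10^mean(abs(log10(sim / obs)))
}

check_auc_pairs <- function(sim, obs) {
  if (length(sim) != length(obs) || !length(sim))
    stop("sim and obs must be non-empty and of equal length")
  if (any(sim <= 0) || any(obs <= 0))
    stop("fold-error metrics require strictly positive exposure values")
}

#' Whether AFE/AAFE meet the adequacy bands
#'
#' @param afe,aafe metric values.
#' @return logical: `0.5 <= AFE <= 2` and `AAFE <= 2`.
#' @export
fold_error_adequate <- function(afe, aafe) {
  afe >= 0.5 && afe <= 2 && aafe <= 2
}

#' Local sensitivity coefficient of an exposure metric
#'
#' Computes `S_ij = (dPK/PK) / (dp/p)` by a forward relative perturbation
#' (default +10%) of one parameter, with the PK metric taken as the AUC of
#' the named observable from 0 to `t_end` (default 8000 h) at the stated
#' dose.
#'
#' @param parameterization base parameterization.
#' @param parameter parameter name (a resolved model parameter, or `"GFR"`,
#'   `"BW"`).
#' @param output observable name (e.g. `"plasma"`, `"liver"`, `"kidney"`,
#'   `"crisc"`, `"mrna"`, `"protein"`).
#' @param dose_mg_per_kg single SC dose (default 1 mg/kg).
#' @param perturbation relative perturbation (default 0.1).
#' @param t_end AUC horizon (h).
#' @param ... passed to [simulate_pbpk()] (tolerances, options).
#' @return object of class `sensitivity_result`: list with `parameter`,
#'   `output`, `S`, `class` (see [classify_sensitivity()]).
#' @export
sensitivity_coefficient <- function(parameterization, parameter, output,
                                    dose_mg_per_kg = 1, perturbation = 0.1,
                                    t_end = 8000, ...) {
  if (!is.numeric(perturbation) || perturbation <= 0)
    stop("perturbation must be small and positive")
  base_val <- get_parameter(parameterization, parameter)
  auc_of <- function(p) {
    sim <- simulate_pbpk(p, dose_regimen(dose_mg_per_kg), t_end = t_end, ...)
    ob <- sim$observables
    ob <- ob[ob$observable == output, ]
    if (!nrow(ob)) stop("output not simulable: ", output)
    auc_trapezoid(ob$time_h, ob$value, 0, t_end)
  }
  pk0 <- auc_of(parameterization)
  if (pk0 == 0) stop("baseline AUC of ", output, " is zero")
  # forward perturbation; parameters at a constraint boundary (e.g. fu = 1)
  # fall back to a backward perturbation
  up <- try(set_parameter(parameterization, parameter,
                          base_val * (1 + perturbation)), silent = TRUE)
  if (inherits(up, "try-error")) {
    pk1 <- auc_of(set_parameter(parameterization, parameter,
                                base_val * (1 - perturbation)))
    S <- ((pk1 - pk0) / pk0) / (-perturbation)
  } else {
    pk1 <- auc_of(up)
    S <- ((pk1 - pk0) / pk0) / perturbation
  }
  structure(list(parameter = parameter, output = output, S = S,
                 class = classify_sensitivity(S),
                 dose_mg_per_kg = dose_mg_per_kg, t_end = t_end),
            class = "sensitivity_result")
}

#' Classify a sensitivity coefficient
#'
#' WHO-style bands on the absolute coefficient: high `>= 0.5`; medium
#' `>= 0.2` and `< 0.5`; low `>= 0.1` and `< 0.2`; otherwise negligible.
#'
#' @param S sensitivity coefficient (finite).
#' @return `"high"`, `"medium"`, `"low"` or `"negligible"`.
#' @examples
#' classify_sensitivity(0.5)    # "high"
#' classify_sensitivity(-0.3)   # "medium"
#' @export
classify_sensitivity <- function(S) {
  if (!is.finite(S)) stop("S must be finite")
  a <- abs(S)
  if (a >= 0.5) "high"
  else if (a >= 0.2) "medium"
  else if (a >= 0.1) "low"
  else "negligible"
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("S(%s -> AUC[%s]) = %.3g  [%s]\n", x$parameter, x$output,
              x$S, x$class))
  invisible(x)
}

#' Specify an estimation problem
#'
#' Bundles the base (truth or initial) parameterization, the free parameters
#' with bounds and scales, the observed data, and solver/optimizer settings
#' into a fit specification consumed by [objective_function()] and
#' [monte_carlo_fit()].
#'
#' Observed data use the long study format produced by [generate_study()]:
#' columns `compound`, `species`, `dose_mg_per_kg`, `biospecimen`, `time_h`,
#' `value`, `unit` (and optionally `replicate`). Concentration residuals are
#' taken in log10 space; PD residuals (`mrna`, `protein`) in linear percent
#' space.
#'
#' @param parameterization base parameterization; free parameters are
#'   overridden during estimation, all others stay fixed at these values.
#' @param free character vector of free parameter names.
#' @param lower,upper named (or positionally matched) bounds for the free
#'   parameters.
#' @param data observed data frame (see above).
#' @param scale `"log"` (default; estimation on log10 scale) or `"linear"`.
#' @param t_end simulation horizon for predictions; default slightly beyond
#'   the last observation.
#' @param rtol,atol solver tolerances used during estimation.
#' @param options structural options passed to the model builder.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(parameterization, free, lower, upper, data,
                     scale = c("log", "linear"), t_end = NULL,
                     rtol = 1e-6, atol = 1e-10, options = list()) {
  scale <- match.arg(scale)
  if (!length(free)) stop("no free parameters")
  if (length(lower) != length(free) || length(upper) != length(free))
    stop("bounds must match free parameters")
  if (any(lower <= 0) && scale == "log")
    stop("log-scale estimation requires positive lower bounds")
  if (any(upper <= lower)) stop("upper bounds must exceed lower bounds")
  need <- c("biospecimen", "time_h", "value", "dose_mg_per_kg")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(data$value < 0)) stop("observed values must be non-negative")
  if (is.null(t_end)) t_end <- max(data$time_h) * 1.001
  structure(list(parameterization = parameterization, free = free,
                 lower = setNames(as.numeric(lower), free),
                 upper = setNames(as.numeric(upper), free),
                 data = data, scale = scale, t_end = t_end,
                 rtol = rtol, atol = atol, options = options),
            class = "fit_spec")
}

pd_specimens <- c("mrna", "protein")

apply_free <- function(fs, theta) {
  p <- fs$parameterization
  for (k in seq_along(fs$free))
    p <- set_parameter(p, fs$free[k], theta[k])
  p
}

predict_for_data <- function(fs, p) {
  d <- fs$data
  pred <- numeric(nrow(d))
  for (dose in unique(d$dose_mg_per_kg)) {
    sel <- d$dose_mg_per_kg == dose
    sim <- simulate_pbpk(p, dose_regimen(dose), t_end = fs$t_end,
                         times = sort(unique(d$time_h[sel])),
                         rtol = fs$rtol, atol = fs$atol,
                         options = fs$options, check_balance = FALSE)
    for (bs in unique(d$biospecimen[sel])) {
      s2 <- sel & d$biospecimen == bs
      pred[s2] <- observable_at(sim, bs, d$time_h[s2])
    }
  }
  pred
}

#' Least-squares objective for a fit specification
#'
#' Sum of squared residuals, equally weighted per observation: residuals in
#' log10 concentration space for concentration biospecimens (which makes the
#' loss invariant to unit rescaling) and in linear percent space for
#' baseline-normalized PD (`mrna`, `protein`). Simulation failures yield a
#' large finite penalty.
#'
#' @param fitspec a [fit_spec()].
#' @param theta free parameter vector (natural scale, within bounds).
#' @return scalar loss.
#' @export
objective_function <- function(fitspec, theta) {
  fs <- fitspec
  if (any(theta < fs$lower - 1e-12) || any(theta > fs$upper + 1e-12))
    stop("theta outside bounds")
  p <- try(apply_free(fs, theta), silent = TRUE)
  if (inherits(p, "try-error")) return(1e10)
  pred <- try(predict_for_data(fs, p), silent = TRUE)
  if (inherits(pred, "try-error")) return(1e10)
  d <- fs$data
  is_pd <- d$biospecimen %in% pd_specimens
  floor_c <- 1e-12
  r_conc <- log10(pmax(pred[!is_pd], floor_c)) -
    log10(pmax(d$value[!is_pd], floor_c))
  r_pd <- pred[is_pd] - d$value[is_pd]
  sum(r_conc^2) + sum(r_pd^2)
}

to_opt_scale <- function(x, fs) if (fs$scale == "log") log10(x) else x
from_opt_scale <- function(x, fs) if (fs$scale == "log") 10^x else x

#' Seeded multistart least-squares estimation
#'
#' Randomized multistart (log-uniform within bounds on the log scale)
#' followed by local refinement (bounded Brent for one free parameter,
#' Nelder-Mead on the transformed scale otherwise). Starts are processed in
#' blocks; the search stops early once the relative improvement of the best
#' loss across a block falls below `break_tol` (default 0.001), or when the
#' start budget is exhausted. Fully reproducible for a given seed.
#'
#' @param fitspec a [fit_spec()].
#' @param seed integer seed.
#' @param n_starts total random starts (default 6).
#' @param block starts per convergence block (default 2).
#' @param break_tol relative-improvement break condition (default 0.001).
#' @param maxit local-refinement iteration cap per start.
#' @return object of class `mc_fit`: list with `par` (best estimates,
#'   natural scale), `value` (loss), `history` (per-start data frame),
#'   `seed`, `converged_by` (`"break_condition"` or `"budget"`).
#' @export
monte_carlo_fit <- function(fitspec, seed, n_starts = 6, block = 2,
                            break_tol = 1e-3, maxit = 200) {
  fs <- fitspec
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  k <- length(fs$free)
  lo <- to_opt_scale(fs$lower, fs); hi <- to_opt_scale(fs$upper, fs)
  obj_t <- function(x) objective_function(fs, pmin(pmax(from_opt_scale(x, fs),
                                                        fs$lower), fs$upper))
  best <- NULL
  hist <- list()
  prev_best <- Inf
  stopped <- "budget"
  n_done <- 0
  while (n_done < n_starts) {
    nb <- min(block, n_starts - n_done)
    for (b in seq_len(nb)) {
      start <- lo + runif(k) * (hi - lo)
      fitb <- if (k == 1L)
        optim(start, obj_t, method = "Brent", lower = lo, upper = hi,
              control = list(maxit = maxit, reltol = 1e-8))
      else
        optim(start, obj_t, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-8))
      hist[[length(hist) + 1L]] <- data.frame(
        start = I(list(from_opt_scale(start, fs))),
        value = fitb$value)
      if (is.null(best) || fitb$value < best$value) best <- fitb
      n_done <- n_done + 1
    }
    impr <- (prev_best - best$value) / max(abs(prev_best), 1e-300)
    if (is.finite(prev_best) && impr < break_tol) {
      stopped <- "break_condition"
      break
    }
    prev_best <- best$value
  }
  par <- setNames(pmin(pmax(from_opt_scale(best$par, fs), fs$lower),
                       fs$upper), fs$free)
  structure(list(par = par, value = best$value,
                 history = do.call(rbind, hist), seed = seed,
                 n_starts = n_done, converged_by = stopped),
            class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<mc_fit> loss %.5g after %d starts (%s), seed %d\n",
              x$value, x$n_starts, x$converged_by, x$seed))
  print(signif(x$par, 4))
  invisible(x)
}
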