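# Synthetic study-data generation emulating the reference study designs:
# subcutaneous dosing, destructive sampling with n animals per time point,
# multiplicative lognormal residual error on concentrations and additive
# Gaussian error on baseline-normalized PD.

# biospecimen menus of the reference study designs, per compound x species
STUDY_MENU <- list(
  "siRNA-1" = list(
    mouse = list(doses = c(3, 10, 100),
                 biospecimens = c("plasma", "liver", "kidney", "gonads",
                                  "lung", "spleen", "mrna")),
    monkey = list(doses = c(1.5, 3), biospecimens = c("plasma", "liver",
                                                      "mrna")),
    human = list(doses = c(1, 3.5, 6.5, 13), biospecimens = "plasma")),
  "siRNA-2" = list(
    mouse = list(doses = c(3, 100, 300),
                 biospecimens = c("plasma", "liver", "kidney", "gonads",
                                  "lung", "spleen")),
    monkey = list(doses = 1, biospecimens = c("plasma", "liver", "mrna")),
    human = list(doses = c(0.1, 1, 3, 6, 12),
                 biospecimens = c("plasma", "protein"))),
  "siRNA-3" = list(
    mouse = list(doses = c(3, 100), biospecimens = c("plasma", "liver",
                                                     "kidney")),
    monkey = list(doses = 3, biospecimens = c("plasma", "liver", "mrna")),
    human = list(doses = c(1.5, 3, 6),
                 biospecimens = c("plasma", "protein"))))

default_sampling_times <- function(species, biospecimen) {
  pk_mouse <- c(0.5, 1, 2, 4, 8, 24, 48, 96, 168, 336, 672)
  pk_large <- c(1, 2, 4, 8, 24, 48, 96, 168, 336, 672, 1344)
  pd_mouse <- c(24, 72, 168, 336, 672)
  pd_large <- c(168, 336, 672, 1008, 1344, 2016)
  if (biospecimen %in% pd_specimens) {
    if (species == "mouse") pd_mouse else pd_large
  } else {
    if (species == "mouse") pk_mouse else pk_large
  }
}

#' Define a synthetic study design
#'
#' Defaults reproduce the reference study structure for the given compound
#' and species: the dose groups and biospecimen menu of the original
#' studies, destructive sampling with n = 3 animals per time point, a 20%
#' lognormal coefficient of variation on concentration measurements and a 5
#' percentage-point additive error on baseline-normalized PD readouts
#' (truncated to [0, 120]%).
#'
#' @param compound,species compound id and species.
#' @param doses dose groups (mg/kg); default the reference design.
#' @param biospecimens observables sampled; default the reference menu
#'   (tissue names, `"plasma"`, `"mrna"`, `"protein"`).
#' @param times sampling times (h), either a numeric vector shared by all
#'   biospecimens or a named list per biospecimen; defaults resolve the
#'   three plasma phases (dense to 24 h, sparse to the horizon).
#' @param n animals per time point (destructive sampling).
#' @param cv lognormal CV for concentration observations.
#' @param pd_sd additive SD (percentage points) for PD observations.
#' @param pd_truncate range to which PD observations are clipped; `NULL`
#'   disables truncation.
#' @return object of class `study_design`.
#' @export
study_design <- function(compound, species, doses = NULL,
                         biospecimens = NULL, times = NULL, n = 3,
                         cv = 0.2, pd_sd = 5, pd_truncate = c(0, 120)) {
  menu <- STUDY_MENU[[compound]][[species]]
  if (is.null(doses)) doses <- menu$doses
  if (is.null(biospecimens)) biospecimens <- menu$biospecimens
  if (is.null(doses) || is.null(biospecimens))
    stop("no default design for ", compound, " x ", species,
         "; supply doses and biospecimens")
  if (n < 1) stop("n must be >= 1")
  if (cv < 0 || pd_sd < 0) stop("noise magnitudes must be non-negative")
  if (!is.list(times)) {
    tt <- times
    times <- lapply(setNames(biospecimens, biospecimens), function(b)
      if (is.null(tt)) default_sampling_times(species, b) else tt)
  }
  structure(list(compound = compound, species = species, doses = doses,
                 biospecimens = biospecimens, times = times, n = n,
                 cv = cv, pd_sd = pd_sd, pd_truncate = pd_truncate),
            class = "study_design")
}

#' Generate a synthetic observed dataset from a study design
#'
#' Simulates the true model once per dose group, samples the design's
#' biospecimens at the design times, and emits `n` independent replicate
#' observations per point (destructive sampling): concentrations receive
#' multiplicative lognormal noise that is unbiased in log space
#' (`sdlog = sqrt(log(1 + cv^2))`), PD readouts receive additive Gaussian
#' noise in percentage points, truncated to the design range. The
#' generating truth (parameter values and noiseless curves) is returned for
#' recovery testing.
#'
#' @param design a [study_design()].
#' @param parameterization generating parameterization (must match the
#'   design's species).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param rtol,atol solver tolerances for the truth simulation.
#' @param options structural model options.
#' @return list with `observations` (data frame: `compound`, `species`,
#'   `dose_mg_per_kg`, `biospecimen`, `time_h`, `value`, `unit`,
#'   `replicate`) and `truth` (list: `parameters`, `curves`).
#' @examples
#' \donttest{
#' p <- assemble_parameterization("siRNA-1", "mouse")
#' d <- study_design("siRNA-1", "mouse", biospecimens = "plasma")
#' obs <- generate_study(d, p, seed = 1)
#' head(obs$observations)
#' }
#' @export
generate_study <- function(design, parameterization, seed,
                           rtol = 1e-6, atol = 1e-10, options = list()) {
  if (!inherits(design, "study_design")) stop("invalid design")
  p <- parameterization
  if (p$species != design$species)
    stop("parameterization species does not match design")
  if (missing(seed)) stop("a seed is required for reproducibility")
  t_max <- max(unlist(design$times))
  set.seed(seed)
  obs <- list(); curves <- list()
  unit_of <- function(b) if (b %in% pd_specimens) "%" else "ug/mL"
  for (dose in design$doses) {
    sim <- simulate_pbpk(p, dose_regimen(dose), t_end = t_max * 1.001,
                         times = sort(unique(unlist(design$times))),
                         rtol = rtol, atol = atol, options = options)
    for (b in design$biospecimens) {
      tt <- design$times[[b]]
      truth <- observable_at(sim, b, tt)
      curves[[length(curves) + 1L]] <- data.frame(
        dose_mg_per_kg = dose, biospecimen = b, time_h = tt, value = truth)
      for (r in seq_len(design$n)) {
        if (b %in% pd_specimens) {
          val <- truth + rnorm(length(tt), 0, design$pd_sd)
          if (!is.null(design$pd_truncate))
            val <- pmin(pmax(val, design$pd_truncate[1]),
                        design$pd_truncate[2])
        } else {
          sdlog <- sqrt(log(1 + design$cv^2))
          val <- truth * exp(rnorm(length(tt), 0, sdlog))
        }
        obs[[length(obs) + 1L]] <- data.frame(
          compound = design$compound, species = design$species,
          dose_mg_per_kg = dose, biospecimen = b, time_h = tt,
          value = val, unit = unit_of(b), replicate = r)
      }
    }
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  list(observations = observations,
       truth = list(parameters = p$values,
                    curves = do.call(rbind, curves)))
}
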