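#' @keywords internal
PBPK_ORGANS <- c("liver", "kidney", "lung", "heart", "spleen", "gonads",
                 "brain", "muscle", "skin", "adipose", "bone", "gut",
                 "pancreas", "stomach", "carcass")

# organs whose venous outflow drains into the liver (portal circulation)
PORTAL_ORGANS <- c("spleen", "gut", "pancreas", "stomach")

extdata_file <- function(name, path = NULL) {
  f <- if (is.null(path)) system.file("extdata", name, package = "galnacpbpk")
  else file.path(path, name)
  if (!nzchar(f) || !file.exists(f))
    stop("bundled data file not found: ", name)
  f
}

read_ref_table <- function(name, path = NULL) {
  read.delim(extdata_file(name, path), comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Load the reference physiology for a species
#'
#' Returns organ volumes (vascular, interstitial, intracellular and
#' endothelial-endosomal), organ plasma and lymph flows, capillary surface
#' areas, glomerular filtration rate and central plasma pool volumes for one
#' of the three supported species. The bundled tables describe a documented
#' reference individual; when `body_weight` is supplied all volumes and flows
#' (including GFR) are rescaled proportionally, so flow ratios and volume
#' fractions are preserved.
#'
#' @param species one of `"mouse"`, `"monkey"`, `"human"`.
#' @param body_weight optional body weight (kg); defaults to the reference
#'   individual (mouse 0.025, monkey 3, human 73 kg).
#' @param path optional directory holding alternative physiology tables with
#'   the bundled file layout (advanced use; all values are overridable).
#' @return an object of class `species_physiology`: a list with elements
#'   `species`, `body_weight`, `hematocrit`, `Q_cardiac` (total cardiac
#'   plasma flow, L/h), `GFR` (L/h), `V_venous`, `V_arterial`, `V_lymph` (L)
#'   and `organs`, a data frame with one row per tissue (volumes L, flows
#'   L/h, surface areas cm^2). The liver row's `Q_plasma` is the
#'   hepatic-arterial inflow; portal drainage is part of the circulation
#'   topology.
#' @examples
#' phys <- load_species_physiology("mouse")
#' sum(phys$organs$Q_plasma[phys$organs$organ != "lung"]) / phys$Q_cardiac
#' @export
load_species_physiology <- function(species, body_weight = NULL, path = NULL) {
  species <- match.arg(species, c("mouse", "monkey", "human"))
  sp <- read_ref_table("physiology_species.tsv", path)
  row <- sp[sp$species == species, , drop = FALSE]
  if (nrow(row) != 1L) stop("unsupported species: ", species)
  organs <- read_ref_table(paste0("physiology_", species, ".tsv"), path)
  scale <- 1
  if (!is.null(body_weight)) {
    if (!is.numeric(body_weight) || length(body_weight) != 1L ||
        !is.finite(body_weight) || body_weight <= 0)
      stop("body_weight must be a single positive number")
    scale <- body_weight / row$body_weight
  } else {
    body_weight <- row$body_weight
  }
  num <- c("V_vascular", "V_interstitial", "V_intracellular", "V_endosomal",
           "Q_plasma", "L_lymph", "S_cap")
  organs[num] <- organs[num] * scale
  phys <- structure(list(
    species = species,
    body_weight = body_weight,
    hematocrit = row$hematocrit,
    Q_cardiac = row$Q_cardiac * scale,
    GFR = row$GFR * scale,
    V_venous = row$V_venous * scale,
    V_arterial = row$V_arterial * scale,
    V_lymph = row$V_lymph * scale,
    organs = organs), class = "species_physiology")
  validate_physiology(phys)
  phys
}

#' Validate a species physiology object
#'
#' Checks the structural invariants of the circulation: all volumes and flows
#' strictly positive, lymph flow below plasma flow in every organ, exactly
#' the fifteen expected tissues present, and organ plasma flows closing
#' against total cardiac plasma output to within 1e-6 relative.
#'
#' @param phys a `species_physiology` object.
#' @return `phys`, invisibly; errors describe the violated invariant.
#' @export
validate_physiology <- function(phys) {
  org <- phys$organs
  if (!setequal(org$organ, PBPK_ORGANS) || nrow(org) != length(PBPK_ORGANS))
    stop("physiology must contain exactly the 15 reference tissues")
  num <- c("V_vascular", "V_interstitial", "V_intracellular", "V_endosomal",
           "Q_plasma", "L_lymph", "S_cap")
  if (any(!is.finite(as.matrix(org[num]))) || any(as.matrix(org[num]) <= 0))
    stop("all organ volumes, flows and surfaces must be strictly positive")
  if (any(org$L_lymph >= org$Q_plasma))
    stop("lymph flow must be below plasma flow for every organ")
  if (any(c(phys$GFR, phys$V_venous, phys$V_arterial, phys$V_lymph,
            phys$Q_cardiac, phys$body_weight) <= 0))
    stop("species-level volumes and flows must be strictly positive")
  qsum <- sum(org$Q_plasma[org$organ != "lung"])
  if (abs(qsum - phys$Q_cardiac) > 1e-6 * phys$Q_cardiac)
    stop("organ plasma flows do not close against cardiac plasma output")
  invisible(phys)
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s, BW %.4g kg, %d tissues\n",
              x$species, x$body_weight, nrow(x$organs)))
  cat(sprintf("  cardiac plasma flow %.4g L/h, GFR %.4g L/h\n",
              x$Q_cardiac, x$GFR))
  invisible(x)
}

organ_row <- function(phys, name) {
  i <- match(name, phys$organs$organ)
  if (is.na(i)) stop("unknown organ: ", name)
  phys$organs[i, , drop = FALSE]
}
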