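# DES recipes -> mole fractions -> mixture descriptors.
# The mixing rule is linear: S_mix^i = sum_j X_j * S_j^i over all NC
# constituents (HBA, HBD(s) and water alike).

#' Molar masses of the stock DES constituents
#'
#' Standard molar masses (g/mol) for the constituents of the screening
#' library: betaine, choline chloride (treated as a single ion pair),
#' ethylene glycol, propylene glycol, glycerol, urea, and water. Anything
#' else requires an explicit molar mass: silent defaults for arbitrary
#' chemicals invite wrong compositions.
#'
#' @return Named numeric vector of molar masses.
#' @export
default_molar_masses <- function() {
  c("betaine" = 117.15,
    "choline chloride" = 139.62,
    "ethylene glycol" = 62.07,
    "propylene glycol" = 76.09,
    "glycerol" = 92.09,
    "urea" = 60.06,
    "water" = 18.015)
}

#' Construct a DES constituent
#'
#' @param name Identifier. If `molar_mass` is missing it is looked up in
#'   [default_molar_masses()]; an unknown name without an explicit mass is
#'   an error.
#' @param role One of `"HBA"`, `"HBD"`, `"water"`.
#' @param molar_mass g/mol, > 0.
#' @param descriptors Optional [descriptor_vector()] for the constituent.
#' @return Object of class `constituent`.
#' @export
constituent <- function(name, role = c("HBA", "HBD", "water"),
                        molar_mass = NULL, descriptors = NULL) {
  role <- match.arg(role)
  if (is.null(molar_mass)) {
    mm <- default_molar_masses()
    if (!name %in% names(mm))
      stop("no molar mass on record for '", name,
           "'; supply molar_mass explicitly")
    molar_mass <- mm[[name]]
  }
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0)
    stop("molar_mass must be a single positive number")
  if (!is.null(descriptors) && !inherits(descriptors, "descriptor_vector"))
    stop("descriptors must be a descriptor_vector")
  structure(list(name = name, role = role, molar_mass = molar_mass,
                 descriptors = descriptors),
            class = "constituent")
}

#' Construct a DES recipe
#'
#' A recipe is an ordered set of non-water constituents with their molar
#' parts (e.g. ChCl:Gly 1:2) plus a water content in weight percent of the
#' final mixture, as the library tabulates them.
#'
#' @param label Identifier, e.g. `"DES 3.2"`.
#' @param constituents List of [constituent()] objects (excluding water).
#' @param molar_parts Positive numeric vector, one entry per constituent.
#' @param water_wt_percent Water mass fraction times 100, in \[0, 100).
#' @param liquid_at_rt Is the formulation liquid at room temperature?
#' @return Object of class `des_recipe`.
#' @export
des_recipe <- function(label, constituents, molar_parts, water_wt_percent,
                       liquid_at_rt = TRUE) {
  if (!is.list(constituents) || !length(constituents) ||
      !all(vapply(constituents, inherits, TRUE, "constituent")))
    stop("constituents must be a non-empty list of constituent objects")
  if (length(molar_parts) != length(constituents))
    stop("molar_parts must match constituents in length")
  if (any(!is.finite(molar_parts)) || any(molar_parts <= 0))
    stop("molar_parts must be positive")
  if (!is.numeric(water_wt_percent) || water_wt_percent < 0 ||
      water_wt_percent >= 100)
    stop("water_wt_percent must be in [0, 100)")
  structure(list(label = label, constituents = constituents,
                 molar_parts = as.numeric(molar_parts),
                 water_wt_percent = as.numeric(water_wt_percent),
                 liquid_at_rt = isTRUE(liquid_at_rt)),
            class = "des_recipe")
}

#' Mole fractions from a DES recipe
#'
#' On a basis of the stated molar parts, the non-water mass is
#' `sum(parts_j * M_j)`; with water mass fraction w the water moles are
#' `(w / (1 - w)) * mass_des / M_water`, and every mole fraction is the
#' corresponding mole count over the grand total. The water entry is always
#' present (zero for anhydrous recipes).
#'
#' @param recipe A [des_recipe()].
#' @param water_molar_mass g/mol; fixed default 18.015.
#' @return Object of class `mixture_composition`: `X`, a named mole-fraction
#'   vector summing to 1 within 1e-12 (constituent names then `"water"`),
#'   and `NC`, the number of constituents including water.
#' @export
mole_fractions_from_recipe <- function(recipe, water_molar_mass = 18.015) {
  stopifnot(inherits(recipe, "des_recipe"))
  w <- recipe$water_wt_percent / 100
  if (w >= 1) stop("water mass fraction must be < 1")
  M <- vapply(recipe$constituents, function(x) x$molar_mass, numeric(1))
  parts <- recipe$molar_parts
  mass_des <- sum(parts * M)
  moles_water <- if (w > 0) (w / (1 - w)) * mass_des / water_molar_mass else 0
  tot <- sum(parts) + moles_water
  X <- c(parts, moles_water) / tot
  names(X) <- c(vapply(recipe$constituents, function(x) x$name, character(1)),
                "water")
  if (abs(sum(X) - 1) > 1e-12) stop("mole fractions failed to normalize")
  structure(list(X = X, NC = length(X), label = recipe$label),
            class = "mixture_composition")
}

#' Mixture descriptors by linear mole-fraction mixing
#'
#' `S_mix^i = sum_j X_j * S_j^i` for i = 1..10, the weighted sum running over
#' every constituent of the mixture including water. Truncated masses mix by
#' the same rule.
#'
#' @param composition A [mixture_composition][mole_fractions_from_recipe()].
#' @param constituents List of [constituent()] objects carrying descriptor
#'   vectors, aligned (by position) with `composition$X`; the water
#'   constituent included.
#' @return A [descriptor_vector()] named after the composition label.
#' @export
mix_descriptors <- function(composition, constituents) {
  stopifnot(inherits(composition, "mixture_composition"))
  if (length(constituents) != composition$NC)
    stop("constituent list (", length(constituents),
         ") does not match composition (NC = ", composition$NC, ")")
  S <- numeric(10L)
  trunc <- 0
  for (j in seq_along(constituents)) {
    d <- constituents[[j]]$descriptors
    if (is.null(d))
      stop("constituent '", constituents[[j]]$name, "' has no descriptors")
    S <- S + composition$X[j] * d$S
    trunc <- trunc + composition$X[j] * d$truncated_mass
  }
  descriptor_vector(S, truncated_mass = trunc,
                    name = if (!is.null(composition$label)) composition$label else "mixture")
}

#' A DES system template for library enumeration
#'
#' @param index System number (drives labels `"DES <index>.<level>"`).
#' @param constituents List of [constituent()] objects (no water).
#' @param molar_parts Molar parts aligned with `constituents`.
#' @param solid_at Water levels (wt%) at which the formulation is solid and
#'   must be excluded from the library.
#' @return Object of class `des_system`.
#' @export
des_system <- function(index, constituents, molar_parts, solid_at = numeric(0)) {
  structure(list(index = index, constituents = constituents,
                 molar_parts = molar_parts, solid_at = as.numeric(solid_at)),
            class = "des_system")
}

#' Enumerate a DES screening library
#'
#' Crosses each system template with the water levels and drops entries
#' flagged solid, labelling survivors `"DES s.i"` where `s` is the system
#' index and `i` the 1-based position of the water level in `water_levels`.
#'
#' @param systems List of [des_system()] templates.
#' @param water_levels Water contents in wt%, e.g. `c(10, 30, 50)`.
#' @return List of [des_recipe()] objects.
#' @export
enumerate_library <- function(systems, water_levels = c(10, 30, 50)) {
  stopifnot(is.list(systems), length(systems) > 0,
            all(vapply(systems, inherits, TRUE, "des_system")))
  recipes <- list()
  for (sys in systems) {
    for (i in seq_along(water_levels)) {
      wl <- water_levels[i]
      if (wl %in% sys$solid_at) next
      recipes[[length(recipes) + 1L]] <- des_recipe(
        label = sprintf("DES %s.%d", sys$index, i),
        constituents = sys$constituents,
        molar_parts = sys$molar_parts,
        water_wt_percent = wl)
    }
  }
  labels <- vapply(recipes, function(r) r$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate recipe labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  recipes
}

#' The screening library of ten DES systems
#'
#' The betaine- and choline-chloride-based systems used for dehydrogenase
#' stability screening: B:EG 1:2, B:PG 1:3, B:Gly 1:2, B:U 1:3, ChCl:U 1:2,
#' ChCl:U:EG 1:2:2, ChCl:U:Gly 1:2:2, ChCl:EG 1:2, ChCl:Gly 1:2 and
#' ChCl:PG 2:3, each at 10/30/50 wt% water. B:U 1:3 is solid at 10 and
#' 30 wt% water, so the full library has 28 liquid formulations.
#'
#' @param descriptors Optional named list of [descriptor_vector()] objects
#'   keyed by constituent name, attached to the constituents when given.
#' @return List with `systems` (templates) and `recipes` (the 28 entries).
#' @export
des_library_screening <- function(descriptors = NULL) {
  mk <- function(name, role) {
    d <- if (!is.null(descriptors) && name %in% names(descriptors))
      descriptors[[name]] else NULL
    constituent(name, role = role, descriptors = d)
  }
  B <- mk("betaine", "HBA"); ChCl <- mk("choline chloride", "HBA")
  EG <- mk("ethylene glycol", "HBD"); PG <- mk("propylene glycol", "HBD")
  Gly <- mk("glycerol", "HBD"); U <- mk("urea", "HBD")
  systems <- list(
    des_system(1, list(B, EG), c(1, 2)),
    des_system(2, list(B, PG), c(1, 3)),
    des_system(3, list(B, Gly), c(1, 2)),
    des_system(4, list(B, U), c(1, 3), solid_at = c(10, 30)),
    des_system(5, list(ChCl, U), c(1, 2)),
    des_system(6, list(ChCl, U, EG), c(1, 2, 2)),
    des_system(7, list(ChCl, U, Gly), c(1, 2, 2)),
    des_system(8, list(ChCl, EG), c(1, 2)),
    des_system(9, list(ChCl, Gly), c(1, 2)),
    des_system(10, list(ChCl, PG), c(2, 3))
  )
  list(systems = systems, recipes = enumerate_library(systems))
}

#' Mixture descriptor table for a set of recipes
#'
#' Convenience wrapper running [mole_fractions_from_recipe()] and
#' [mix_descriptors()] over a recipe list.
#'
#' @param recipes List of [des_recipe()] objects whose constituents carry
#'   descriptors.
#' @param water_constituent A [constituent()] for water with descriptors.
#' @return Data frame: label, water_wt_percent, S1..S10, truncated_mass.
#' @export
mixture_descriptor_table <- function(recipes, water_constituent) {
  stopifnot(inherits(water_constituent, "constituent"))
  rows <- lapply(recipes, function(r) {
    comp <- mole_fractions_from_recipe(r)
    d <- mix_descriptors(comp, c(r$constituents, list(water_constituent)))
    cbind(data.frame(label = r$label, water_wt_percent = r$water_wt_percent,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(d$S)),
          data.frame(truncated_mass = d$truncated_mass))
  })
  do.call(rbind, rows)
}
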