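#' @import methods
NULL

.PHASES <- c("aqueous", "solid", "gas", "liquid-water")

#' Chemical species in a redox reaction
#'
#' A `Species` holds the elemental composition, charge and phase of one
#' chemical species. The phase determines the activity convention used when
#' evaluating reaction quotients: solids and liquid water are assigned unit
#' activity, aqueous (and gas) species take their concentration (molar) as
#' activity.
#'
#' @slot name Species name, e.g. `"CH4"`.
#' @slot phase One of `"aqueous"`, `"solid"`, `"gas"`, `"liquid-water"`.
#' @slot elementCounts Named integer-valued numeric vector of atoms per
#'   molecule, e.g. `c(C = 1, H = 4)`.
#' @slot charge Integer formal charge.
#'
#' @seealso [species()], [ReactionSpec-class]
#' @export
setClass("Species",
  representation(
    name          = "character",
    phase         = "character",
    elementCounts = "numeric",
    charge        = "numeric"
  )
)

setValidity("Species", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@phase) != 1L || !object@phase %in% .PHASES)
    msg <- c(msg, sprintf("'phase' must be one of: %s",
                          paste(.PHASES, collapse = ", ")))
  if (length(object@elementCounts) &&
      (is.null(names(object@elementCounts)) ||
       any(!nzchar(names(object@elementCounts)))))
    msg <- c(msg, "'elementCounts' must be a named vector")
  if (any(object@elementCounts < 0) ||
      any(object@elementCounts != round(object@elementCounts)))
    msg <- c(msg, "'elementCounts' must be nonnegative integers")
  if (length(object@charge) != 1L || object@charge != round(object@charge))
    msg <- c(msg, "'charge' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a chemical species
#'
#' @param name Species name.
#' @param phase Phase string; see [Species-class].
#' @param elements Named vector of element counts, e.g. `c(C = 1, H = 4)`.
#' @param charge Formal charge (default 0).
#' @return A [Species-class] object.
#' @examples
#' species("CH4", "aqueous", c(C = 1, H = 4))
#' species("Mn2+", "aqueous", c(Mn = 1), charge = 2)
#' @export
species <- function(name, phase, elements, charge = 0) {
  new("Species", name = name, phase = phase,
      elementCounts = elements, charge = as.numeric(charge))
}

#' A balanced redox reaction
#'
#' Reactants and products with positive stoichiometric coefficients. Element
#' and charge balance is an invariant of a *valid* reaction but is checked
#' explicitly by [validateReactionBalance()] (so that deliberately broken
#' reactions can be constructed in order to test the validator).
#'
#' @slot reactants List of [Species-class].
#' @slot products List of [Species-class].
#' @slot reactantCoeffs,productCoeffs Positive numeric coefficients, parallel
#'   to the species lists.
#'
#' @seealso [reactionSpec()], [mnAOMReaction()], [validateReactionBalance()]
#' @export
setClass("ReactionSpec",
  representation(
    reactants      = "list",
    products       = "list",
    reactantCoeffs = "numeric",
    productCoeffs  = "numeric"
  )
)

setValidity("ReactionSpec", function(object) {
  msg <- character()
  if (length(object@reactants) != length(object@reactantCoeffs))
    msg <- c(msg, "reactants and reactantCoeffs lengths differ")
  if (length(object@products) != length(object@productCoeffs))
    msg <- c(msg, "products and productCoeffs lengths differ")
  if (!all(vapply(c(object@reactants, object@products),
                  function(x) is(x, "Species"), logical(1))))
    msg <- c(msg, "all reaction members must be Species objects")
  if (any(c(object@reactantCoeffs, object@productCoeffs) <= 0))
    msg <- c(msg, "stoichiometric coefficients must be > 0")
  nm <- c(vapply(object@reactants, function(s) s@name, character(1)),
          vapply(object@products, function(s) s@name, character(1)))
  if (anyDuplicated(nm))
    msg <- c(msg, "species names must be unique within a reaction")
  if (length(msg)) msg else TRUE
})

#' Construct a reaction from species/coefficient pairs
#'
#' @param reactants,products Named lists mapping coefficient-bearing
#'   [Species-class] objects; supply as `list(list(species, coeff), ...)`.
#' @return A [ReactionSpec-class].
#' @seealso [mnAOMReaction()] for the Mn(IV)-AOM reaction preconfigured.
#' @export
reactionSpec <- function(reactants, products) {
  new("ReactionSpec",
      reactants      = lapply(reactants, `[[`, 1L),
      products       = lapply(products, `[[`, 1L),
      reactantCoeffs = vapply(reactants, function(x) as.numeric(x[[2L]]),
                              numeric(1)),
      productCoeffs  = vapply(products, function(x) as.numeric(x[[2L]]),
                              numeric(1)))
}

#' In-situ activities and temperature
#'
#' Activities are dimensionless: for aqueous/gas species the molar
#' concentration under the unit-activity-coefficient convention; solids and
#' liquid water are fixed at 1 during quotient evaluation regardless of any
#' entry here (unless solids are explicitly included; see
#' [reactionQuotient()]).
#'
#' @slot activities Named numeric vector, species name to activity (> 0).
#' @slot temperature Temperature in kelvin.
#' @seealso [conditionSet()], [mnAOMConditions()]
#' @export
setClass("ConditionSet",
  representation(activities = "numeric", temperature = "numeric")
)

setValidity("ConditionSet", function(object) {
  msg <- character()
  if (length(object@activities) &&
      (is.null(names(object@activities)) ||
       any(!nzchar(names(object@activities)))))
    msg <- c(msg, "'activities' must be named by species")
  if (any(object@activities <= 0))
    msg <- c(msg, "activities must be > 0")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "'temperature' must be a single positive kelvin value")
  if (length(msg)) msg else TRUE
})

#' @rdname ConditionSet-class
#' @param activities Named numeric vector of activities (mol/L for aqueous).
#' @param temperature Temperature in kelvin.
#' @return A [ConditionSet-class].
#' @export
conditionSet <- function(activities, temperature) {
  new("ConditionSet", activities = activities,
      temperature = as.numeric(temperature))
}

#' Standard Gibbs formation energies
#'
#' A lookup of standard-state formation energies (kJ/mol) with a provenance
#' label. The gas constant used throughout is
#' R = 8.314462618e-3 kJ/mol/K.
#'
#' @slot formationEnergies Named numeric, species name to delta-Gf (kJ/mol).
#' @slot sourceLabel Non-empty provenance string.
#' @seealso [thermoTable()], [defaultThermoTable()]
#' @export
setClass("ThermoTable",
  representation(formationEnergies = "numeric", sourceLabel = "character")
)

setValidity("ThermoTable", function(object) {
  msg <- character()
  if (length(object@formationEnergies) &&
      is.null(names(object@formationEnergies)))
    msg <- c(msg, "'formationEnergies' must be named by species")
  if (length(object@sourceLabel) != 1L || !nzchar(object@sourceLabel))
    msg <- c(msg, "'sourceLabel' must document the constants' provenance")
  if (length(msg)) msg else TRUE
})

#' @rdname ThermoTable-class
#' @param formationEnergies Named numeric vector (kJ/mol).
#' @param sourceLabel Provenance string (required, non-empty).
#' @return A [ThermoTable-class].
#' @export
thermoTable <- function(formationEnergies, sourceLabel) {
  new("ThermoTable", formationEnergies = formationEnergies,
      sourceLabel = sourceLabel)
}

#' Least-squares rate estimate from a concentration time series
#'
#' @slot rate Positive magnitude of the fitted slope, umol/L/day.
#' @slot intercept Fitted intercept, umol/L.
#' @slot residualSE Residual standard error of the fit.
#' @slot nPoints Number of points used (>= 2).
#' @slot direction `"consumption"` or `"production"` as requested.
#' @slot directionMismatch `TRUE` when the fitted slope sign contradicts the
#'   requested direction (flagged, not an error).
#' @seealso [estimateRate()]
#' @export
setClass("RateEstimate",
  representation(
    rate              = "numeric",
    intercept         = "numeric",
    residualSE        = "numeric",
    nPoints           = "integer",
    direction         = "character",
    directionMismatch = "logical"
  )
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "'nPoints' must be >= 2")
  if (!object@direction %in% c("consumption", "production"))
    msg <- c(msg, "'direction' must be consumption or production")
  if (object@rate < 0) msg <- c(msg, "'rate' is a magnitude, must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Reactor time series of methane and metal pools
#'
#' Wraps a measurement table (one row per sampling day) and an optional feed
#' event table. Required columns of `data`: `day`, `methane_umol_per_L`,
#' `mn2_dissolved`, `mn2_adsorbed`, `mn2_carbonate`; optional:
#' `fe2_dissolved`, `fe2_total`. Feed events: `day`, `birnessite_g`.
#'
#' @slot data data.frame of measurements; days strictly increasing, all
#'   concentrations (umol/L) nonnegative.
#' @slot feedEvents data.frame of birnessite additions (may be empty).
#' @seealso [reactorSeries()], [readReactorSeries()], [mnPoolSummary()]
#' @export
setClass("ReactorSeries",
  representation(data = "data.frame", feedEvents = "data.frame")
)

.REACTOR_COLS <- c("day", "methane_umol_per_L", "mn2_dissolved",
                   "mn2_adsorbed", "mn2_carbonate")

setValidity("ReactorSeries", function(object) {
  msg <- character()
  missing <- setdiff(.REACTOR_COLS, names(object@data))
  if (length(missing))
    msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
  else {
    if (is.unsorted(object@data$day, strictly = TRUE))
      msg <- c(msg, "'day' must be strictly increasing")
    conc <- setdiff(names(object@data), "day")
    vals <- unlist(object@data[conc], use.names = FALSE)
    if (any(vals < 0, na.rm = TRUE))
      msg <- c(msg, "concentrations must be >= 0")
  }
  if (nrow(object@feedEvents) &&
      !all(c("day", "birnessite_g") %in% names(object@feedEvents)))
    msg <- c(msg, "feedEvents needs columns 'day' and 'birnessite_g'")
  if (length(msg)) msg else TRUE
})

#' @rdname ReactorSeries-class
#' @param data Measurement data.frame (see class description).
#' @param feedEvents Optional data.frame of `day`, `birnessite_g`.
#' @return A [ReactorSeries-class].
#' @export
reactorSeries <- function(data, feedEvents = NULL) {
  if (is.null(feedEvents))
    feedEvents <- data.frame(day = numeric(), birnessite_g = numeric())
  new("ReactorSeries", data = as.data.frame(data),
      feedEvents = as.data.frame(feedEvents))
}

#' Genome-level multiheme cytochrome screen report
#'
#' @slot annotations Per-protein annotation data.frame with columns
#'   `gene_id`, `genome_id`, `heme_motif_count`, `motif_positions`
#'   (comma-separated 0-based offsets), `is_mhc`, `cytochrome_domain`,
#'   `is_extracellular_candidate`, `is_slayer_fusion`, `cluster_context`.
#' @slot summary Named list of summary counts: `n_proteins`, `n_mhc`,
#'   `n_extracellular`, `n_slayer_fusion`, `n_oxidoreductase_cluster`,
#'   `n_standalone`.
#' @slot genomeId Genome identifier.
#' @seealso [screenGenome()]
#' @export
setClass("MHCScreenReport",
  representation(annotations = "data.frame", summary = "list",
                 genomeId = "character")
)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Species", function(object) {
  comp <- paste(sprintf("%s%g", names(object@elementCounts),
                        object@elementCounts), collapse = " ")
  chg <- if (object@charge == 0) "" else sprintf(" charge %+d", object@charge)
  cat(sprintf("Species %s [%s] {%s}%s\n",
              object@name, object@phase, comp, chg))
})

setMethod("show", "ReactionSpec", function(object) {
  side <- function(sp, cf)
    paste(sprintf("%s%s", ifelse(cf == 1, "", paste0(cf, " ")),
                  vapply(sp, function(s) s@name, character(1))),
          collapse = " + ")
  cat("ReactionSpec:", side(object@reactants, object@reactantCoeffs),
      "->", side(object@products, object@productCoeffs), "\n")
})

setMethod("show", "ConditionSet", function(object) {
  cat(sprintf("ConditionSet at %.2f K (%d activities)\n",
              object@temperature, length(object@activities)))
  if (length(object@activities)) {
    a <- object@activities
    cat(paste(sprintf("  %-8s %g", names(a), a), collapse = "\n"), "\n")
  }
})

setMethod("show", "ThermoTable", function(object) {
  cat(sprintf("ThermoTable (%d species) source: %s\n",
              length(object@formationEnergies), object@sourceLabel))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate: %.3f umol/L/day (%s, n = %d, residual SE %.3f)%s\n",
    object@rate, object@direction, object@nPoints, object@residualSE,
    if (object@directionMismatch) " [direction mismatch]" else ""))
})

setMethod("show", "ReactorSeries", function(object) {
  cat(sprintf("ReactorSeries: %d timepoints (day %g-%g), %d feed events\n",
              nrow(object@data), min(object@data$day), max(object@data$day),
              nrow(object@feedEvents)))
})

setMethod("show", "MHCScreenReport", function(object) {
  s <- object@summary
  cat(sprintf(
    paste0("MHCScreenReport for genome '%s'\n",
           "  proteins screened: %d\n  putative MHCs: %d\n",
           "  extracellular candidates: %d\n  S-layer fusions: %d\n",
           "  oxidoreductase-cluster context: %d (standalone: %d)\n"),
    object@genomeId, s$n_proteins, s$n_mhc, s$n_extracellular,
    s$n_slayer_fusion, s$n_oxidoreductase_cluster, s$n_standalone))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for mnAOM S4 objects
#'
#' `rate()`, `residualSE()`, `nPoints()`, `directionMismatch()` read
#' [RateEstimate-class]; `seriesData()` and `feedEvents()` read
#' [ReactorSeries-class]; `annotations()`, `screenSummary()` read
#' [MHCScreenReport-class]; `activities()`, `temperatureK()` read
#' [ConditionSet-class]; `formationEnergies()` reads [ThermoTable-class].
#'
#' @param object The object to read from.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rate", function(object) standardGeneric("rate"))
#' @rdname accessors
#' @export
setMethod("rate", "RateEstimate", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("residualSE", function(object) standardGeneric("residualSE"))
#' @rdname accessors
#' @export
setMethod("residualSE", "RateEstimate", function(object) object@residualSE)

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setMethod("nPoints", "RateEstimate", function(object) object@nPoints)

#' @rdname accessors
#' @export
setGeneric("directionMismatch",
           function(object) standardGeneric("directionMismatch"))
#' @rdname accessors
#' @export
setMethod("directionMismatch", "RateEstimate",
          function(object) object@directionMismatch)

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setMethod("seriesData", "ReactorSeries", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("feedEvents", function(object) standardGeneric("feedEvents"))
#' @rdname accessors
#' @export
setMethod("feedEvents", "ReactorSeries", function(object) object@feedEvents)

#' @rdname accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "MHCScreenReport",
          function(object) object@annotations)

#' @rdname accessors
#' @export
setGeneric("screenSummary", function(object) standardGeneric("screenSummary"))
#' @rdname accessors
#' @export
setMethod("screenSummary", "MHCScreenReport", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("activities", function(object) standardGeneric("activities"))
#' @rdname accessors
#' @export
setMethod("activities", "ConditionSet", function(object) object@activities)

#' @rdname accessors
#' @export
setGeneric("temperatureK", function(object) standardGeneric("temperatureK"))
#' @rdname accessors
#' @export
setMethod("temperatureK", "ConditionSet", function(object) object@temperature)

#' @rdname accessors
#' @export
setGeneric("formationEnergies",
           function(object) standardGeneric("formationEnergies"))
#' @rdname accessors
#' @export
setMethod("formationEnergies", "ThermoTable",
          function(object) object@formationEnergies)
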