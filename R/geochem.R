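# Gas/liquid partitioning, rate estimation, Mn pool accounting,
# electron-balance stoichiometry and in-situ Gibbs free energy.

#' Physical constants used by the geochemistry module
#'
#' `GAS_CONSTANT_KJ` is R in kJ/mol/K (used in delta-G = delta-G0 + RT ln Q);
#' `GAS_CONSTANT_L_ATM` is R in L atm/mol/K (ideal-gas headspace amounts);
#' `HENRY_CH4_295K` is the documented default Henry solubility constant for
#' methane in water near 295 K, in mol/L/atm (Sander 2015 compilation,
#' temperature-corrected from the 298.15 K value of 1.4e-3 with
#' d(ln kH)/d(1/T) = 1750 K).
#'
#' @name constants
#' @export
GAS_CONSTANT_KJ <- 8.314462618e-3

#' @rdname constants
#' @export
GAS_CONSTANT_L_ATM <- 0.082057338

#' @rdname constants
#' @export
HENRY_CH4_295K <- 1.52e-3

#' Dissolved gas concentration from Henry's law
#'
#' @param partialPressure Partial pressure of the gas, atm (>= 0).
#' @param henryConstant Henry solubility constant, mol/L/atm (> 0). The
#'   package default for methane near 295 K is [HENRY_CH4_295K].
#' @return Dissolved concentration, mol/L.
#' @examples
#' henryDissolved(0.9, HENRY_CH4_295K)  # ~1.37e-3 M
#' @export
henryDissolved <- function(partialPressure, henryConstant) {
  if (any(partialPressure < 0))
    stop("'partialPressure' must be >= 0", call. = FALSE)
  if (any(henryConstant <= 0))
    stop("'henryConstant' must be > 0", call. = FALSE)
  partialPressure * henryConstant
}

#' Total methane in a closed reactor (headspace + dissolved)
#'
#' The headspace amount comes from the ideal gas law (pV/RT) and the
#' dissolved amount from Henry's law times the liquid volume.
#'
#' @param headspacePressure Methane partial pressure in the headspace, atm.
#' @param headspaceVolume Headspace volume, L (> 0).
#' @param liquidVolume Liquid working volume, L (> 0).
#' @param temperature Temperature, K (> 0).
#' @param henryConstant Henry constant, mol/L/atm (default [HENRY_CH4_295K]).
#' @return Total methane, umol.
#' @examples
#' totalMethaneAmount(1, 0.13, 0.7, 295.15)  # ~6.4e3 umol
#' @export
totalMethaneAmount <- function(headspacePressure, headspaceVolume,
                               liquidVolume, temperature,
                               henryConstant = HENRY_CH4_295K) {
  if (headspacePressure < 0)
    stop("'headspacePressure' must be >= 0", call. = FALSE)
  if (headspaceVolume <= 0 || liquidVolume <= 0 || temperature <= 0)
    stop("volumes and temperature must be > 0", call. = FALSE)
  headspace <- headspacePressure * headspaceVolume /
    (GAS_CONSTANT_L_ATM * temperature)
  dissolved <- henryDissolved(headspacePressure, henryConstant) * liquidVolume
  (headspace + dissolved) * 1e6
}

#' Estimate a consumption or production rate from a time series
#'
#' Fits concentration against day and reports the slope magnitude. The
#' default is an ordinary least-squares fit over all supplied points;
#' `method = "endpoint"` uses the first/last-point difference quotient
#' instead. A slope whose sign contradicts the requested direction is
#' flagged on the estimate (not an error).
#'
#' @param day Numeric vector of sampling days (distinct, >= 2 values).
#' @param concentration Concentrations, umol/L, parallel to `day`.
#' @param direction `"consumption"` (expected negative slope) or
#'   `"production"` (positive).
#' @param method `"ols"` (default) or `"endpoint"`.
#' @return A [RateEstimate-class].
#' @examples
#' estimateRate(c(0, 7, 14, 21), 2000 - 44.5 * c(0, 7, 14, 21),
#'              direction = "consumption")
#' @export
estimateRate <- function(day, concentration,
                         direction = c("consumption", "production"),
                         method = c("ols", "endpoint")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (length(day) != length(concentration))
    stop("'day' and 'concentration' lengths differ", call. = FALSE)
  if (length(day) < 2L)
    stop("insufficient data: need >= 2 points", call. = FALSE)
  if (anyDuplicated(day))
    stop("'day' values must be distinct", call. = FALSE)

  if (method == "endpoint") {
    o <- order(day)
    slope <- (concentration[o[length(o)]] - concentration[o[1L]]) /
      (day[o[length(o)]] - day[o[1L]])
    intercept <- concentration[o[1L]] - slope * day[o[1L]]
    rse <- NA_real_
  } else {
    fit <- stats::lm(concentration ~ day)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    rse <- if (length(day) > 2L) suppressWarnings(summary(fit)$sigma) else 0
  }
  expected_sign <- if (direction == "consumption") -1 else 1
  new("RateEstimate",
      rate = abs(slope), intercept = intercept,
      residualSE = if (is.na(rse)) 0 else rse,
      nPoints = length(day), direction = direction,
      directionMismatch = sign(slope) != 0 && sign(slope) != expected_sign)
}

#' Ratio of acceptor production to donor consumption rates
#'
#' @param rateAcceptor,rateDonor [RateEstimate-class] objects (or bare
#'   positive numbers) for the electron acceptor product (e.g. Mn(II)) and
#'   the donor (e.g. CH4).
#' @return Dimensionless molar rate ratio.
#' @examples
#' stoichiometricRatio(184.7, 44.5)  # ~4.15
#' @export
stoichiometricRatio <- function(rateAcceptor, rateDonor) {
  num <- if (is(rateAcceptor, "RateEstimate")) rateAcceptor@rate
         else as.numeric(rateAcceptor)
  den <- if (is(rateDonor, "RateEstimate")) rateDonor@rate
         else as.numeric(rateDonor)
  if (den <= 0) stop("donor rate must be > 0", call. = FALSE)
  if (num <= 0) stop("acceptor rate must be > 0", call. = FALSE)
  num / den
}

.speciesByName <- function(reaction, name) {
  all_sp <- c(reaction@reactants, reaction@products)
  nm <- vapply(all_sp, function(s) s@name, character(1))
  i <- match(name, nm)
  if (is.na(i)) stop(sprintf("species '%s' not in reaction", name),
                     call. = FALSE)
  all_sp[[i]]
}

.coefByName <- function(reaction, name) {
  rn <- vapply(reaction@reactants, function(s) s@name, character(1))
  pn <- vapply(reaction@products, function(s) s@name, character(1))
  if (name %in% rn) reaction@reactantCoeffs[match(name, rn)]
  else reaction@productCoeffs[match(name, pn)]
}

#' Validate element and charge balance of a reaction
#'
#' Sums coefficient-weighted element counts and charges on each side; the
#' first unbalanced element (or the charge) is named in the error.
#'
#' @param reaction A [ReactionSpec-class].
#' @param tol Numeric tolerance on the balance (default 1e-9).
#' @return `TRUE` invisibly if balanced; otherwise an error.
#' @examples
#' validateReactionBalance(mnAOMReaction())
#' @export
validateReactionBalance <- function(reaction, tol = 1e-9) {
  sideTotals <- function(sp, cf) {
    tot <- numeric()
    for (i in seq_along(sp)) {
      ec <- sp[[i]]@elementCounts * cf[i]
      for (el in names(ec)) {
        cur <- if (el %in% names(tot)) tot[[el]] else 0
        tot[el] <- cur + ec[[el]]
      }
    }
    tot
  }
  lhs <- sideTotals(reaction@reactants, reaction@reactantCoeffs)
  rhs <- sideTotals(reaction@products, reaction@productCoeffs)
  for (el in union(names(lhs), names(rhs))) {
    l <- if (el %in% names(lhs)) lhs[[el]] else 0
    r <- if (el %in% names(rhs)) rhs[[el]] else 0
    if (abs(l - r) > tol)
      stop(sprintf("reaction unbalanced in element %s (%g vs %g)",
                   el, l, r), call. = FALSE)
  }
  ql <- sum(vapply(reaction@reactants, function(s) s@charge, numeric(1)) *
              reaction@reactantCoeffs)
  qr <- sum(vapply(reaction@products, function(s) s@charge, numeric(1)) *
              reaction@productCoeffs)
  if (abs(ql - qr) > tol)
    stop(sprintf("reaction unbalanced in charge (%+g vs %+g)", ql, qr),
         call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Predicted acceptor:donor molar ratio from the electron balance
#'
#' Counts electrons released per donor molecule and accepted per acceptor
#' molecule from supplied oxidation states, returning their ratio — the
#' predicted molar ratio of acceptor turned over per donor oxidized. The
#' result is cross-checked against the reaction's stoichiometric coefficient
#' ratio; disagreement raises an inconsistency error. For the Mn(IV)-AOM
#' reaction, carbon goes from -4 (CH4) to +4 (HCO3-), 8 electrons, and Mn
#' from +4 (MnO2) to +2 (Mn2+), 2 electrons, predicting 4 Mn(II) per CH4.
#'
#' @param reaction A balanced [ReactionSpec-class].
#' @param donor,acceptor Species names of the electron donor (a reactant)
#'   and acceptor (a reactant).
#' @param oxidationStates data.frame with columns `species`, `element`,
#'   `state` giving the oxidation state of the redox-active element in each
#'   relevant species (donor, acceptor and their product forms).
#' @return The dimensionless ratio (electrons donated per donor molecule) /
#'   (electrons accepted per acceptor molecule).
#' @examples
#' electronBalanceRatio(mnAOMReaction(), "CH4", "MnO2", mnAOMOxidationStates())
#' @export
electronBalanceRatio <- function(reaction, donor, acceptor, oxidationStates) {
  validateReactionBalance(reaction)
  os <- as.data.frame(oxidationStates)
  if (!all(c("species", "element", "state") %in% names(os)))
    stop("'oxidationStates' needs columns species, element, state",
         call. = FALSE)
  stateOf <- function(speciesName, element) {
    i <- which(os$species == speciesName & os$element == element)
    if (!length(i))
      stop(sprintf("missing oxidation state for %s:%s",
                   speciesName, element), call. = FALSE)
    os$state[i[1L]]
  }
  # per-molecule electron change for a reactant species whose redox element
  # appears in some product species of the reaction
  electronChange <- function(name) {
    sp <- .speciesByName(reaction, name)
    el <- unique(os$element[os$species == name])
    if (!length(el))
      stop(sprintf("missing oxidation state for species %s", name),
           call. = FALSE)
    el <- el[1L]
    prod_names <- vapply(reaction@products, function(s) s@name, character(1))
    partner <- prod_names[vapply(reaction@products, function(s)
      el %in% names(s@elementCounts) && any(os$species == s@name &
                                            os$element == el), logical(1))]
    if (!length(partner))
      stop(sprintf("no product with an oxidation state for element %s", el),
           call. = FALSE)
    n_atoms <- sp@elementCounts[[el]]
    n_atoms * (stateOf(partner[1L], el) - stateOf(name, el))
  }
  released <- electronChange(donor)      # positive: oxidation
  accepted <- -electronChange(acceptor)  # positive: reduction
  if (released <= 0)
    stop(sprintf("'%s' is not oxidized in this reaction", donor),
         call. = FALSE)
  if (accepted <= 0)
    stop(sprintf("'%s' is not reduced in this reaction", acceptor),
         call. = FALSE)
  ratio <- released / accepted
  coef_ratio <- .coefByName(reaction, acceptor) / .coefByName(reaction, donor)
  if (abs(ratio - coef_ratio) > 1e-9)
    stop(sprintf(paste0("electron balance (%g) inconsistent with ",
                        "stoichiometric coefficient ratio (%g)"),
                 ratio, coef_ratio), call. = FALSE)
  ratio
}

.activityOf <- function(sp, conditions, includeSolids) {
  fixed <- sp@phase %in% c("solid", "liquid-water")
  if (fixed && !includeSolids) return(1)
  a <- conditions@activities[sp@name]
  if (is.na(a)) {
    if (fixed) return(1)  # solid without an entry stays at unit activity
    stop(sprintf("missing activity for aqueous species '%s'", sp@name),
         call. = FALSE)
  }
  unname(a)
}

#' Reaction quotient Q under in-situ conditions
#'
#' Q = prod(products a^v) / prod(reactants a^v), with activities equal to
#' molar concentrations for aqueous species and fixed at 1 for solids and
#' liquid water. Setting `includeSolids = TRUE` lets solid-phase entries in
#' the condition set (e.g. an MnO2 suspension concentration) enter Q — a
#' non-standard convention retained for sensitivity analysis.
#'
#' @param reaction A [ReactionSpec-class].
#' @param conditions A [ConditionSet-class].
#' @param includeSolids Logical; default `FALSE` (standard convention).
#' @return Dimensionless Q.
#' @examples
#' reactionQuotient(mnAOMReaction(), mnAOMConditions())  # ~2.2e35
#' @export
reactionQuotient <- function(reaction, conditions, includeSolids = FALSE) {
  exp(.lnQ(reaction, conditions, includeSolids))
}

.lnQ <- function(reaction, conditions, includeSolids) {
  lp <- sum(reaction@productCoeffs *
              log(vapply(reaction@products, .activityOf, numeric(1),
                         conditions, includeSolids)))
  lr <- sum(reaction@reactantCoeffs *
              log(vapply(reaction@reactants, .activityOf, numeric(1),
                         conditions, includeSolids)))
  lp - lr
}

#' In-situ Gibbs free energy of a reaction
#'
#' delta-G = sum(v delta-Gf, products) - sum(v delta-Gf, reactants)
#' + R T ln Q, normalized per mole of the designated donor species.
#'
#' @param reaction A balanced [ReactionSpec-class].
#' @param thermo A [ThermoTable-class] covering every species.
#' @param conditions A [ConditionSet-class].
#' @param donor Species name to normalize by (default the first reactant).
#' @param includeSolids Passed to [reactionQuotient()].
#' @return List with `deltaG` (kJ per mol donor), `deltaG0` (standard-state,
#'   kJ per mol donor), `lnQ`, `Q`, `temperature`, `donor`, `source`.
#' @examples
#' gibbsFreeEnergy(mnAOMReaction(), defaultThermoTable(), mnAOMConditions())
#' @export
gibbsFreeEnergy <- function(reaction, thermo, conditions,
                            donor = reaction@reactants[[1L]]@name,
                            includeSolids = FALSE) {
  validateReactionBalance(reaction)
  fe <- thermo@formationEnergies
  lookup <- function(sp) {
    v <- fe[sp@name]
    if (is.na(v))
      stop(sprintf("no formation energy for species '%s' in thermo table",
                   sp@name), call. = FALSE)
    unname(v)
  }
  dG0 <- sum(reaction@productCoeffs *
               vapply(reaction@products, lookup, numeric(1))) -
         sum(reaction@reactantCoeffs *
               vapply(reaction@reactants, lookup, numeric(1)))
  lnQ <- .lnQ(reaction, conditions, includeSolids)
  dG <- dG0 + GAS_CONSTANT_KJ * conditions@temperature * lnQ
  nu <- .coefByName(reaction, donor)
  if (is.na(nu)) stop(sprintf("donor '%s' not in reaction", donor),
                      call. = FALSE)
  list(deltaG = dG / nu, deltaG0 = dG0 / nu, lnQ = lnQ, Q = exp(lnQ),
       temperature = conditions@temperature, donor = donor,
       source = thermo@sourceLabel)
}

#' Per-timepoint Mn(II) pool totals and fractions
#'
#' Totals the dissolved, adsorbed and carbonate Mn(II) pools per timepoint,
#' computes pool fractions, and flags timepoints where the dissolved
#' fraction reaches `dissolvedThreshold` (default 0.03: dissolved Mn(II)
#' below 3% of total justifies excluding it from rate mass balances).
#' Timepoints with zero total get `NA` fractions and no flag.
#'
#' @param series A [ReactorSeries-class] (or a data.frame with the pool
#'   columns `mn2_dissolved`, `mn2_adsorbed`, `mn2_carbonate` and `day`).
#' @param dissolvedThreshold Flag threshold on the dissolved fraction.
#' @return data.frame with `day`, the three pools, `mn2_total`, fraction
#'   columns `frac_dissolved`, `frac_adsorbed`, `frac_carbonate`, and
#'   `dissolved_flag`.
#' @export
mnPoolSummary <- function(series, dissolvedThreshold = 0.03) {
  d <- if (is(series, "ReactorSeries")) series@data else as.data.frame(series)
  pools <- c("mn2_dissolved", "mn2_adsorbed", "mn2_carbonate")
  missing <- setdiff(pools, names(d))
  if (length(missing))
    stop(paste("missing pool columns:", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (any(unlist(d[pools]) < 0, na.rm = TRUE))
    stop("negative pool concentration", call. = FALSE)
  total <- rowSums(d[pools])
  frac <- d[pools] / ifelse(total > 0, total, NA_real_)
  names(frac) <- c("frac_dissolved", "frac_adsorbed", "frac_carbonate")
  out <- data.frame(day = if ("day" %in% names(d)) d$day else seq_len(nrow(d)),
                    d[pools], mn2_total = total, frac,
                    dissolved_flag = !is.na(frac$frac_dissolved) &
                      frac$frac_dissolved >= dissolvedThreshold)
  rownames(out) <- NULL
  out
}

#' Reverse a reaction (products become reactants)
#'
#' @param reaction A [ReactionSpec-class].
#' @return The reversed [ReactionSpec-class].
#' @export
reverseReaction <- function(reaction) {
  new("ReactionSpec",
      reactants = reaction@products, products = reaction@reactants,
      reactantCoeffs = reaction@productCoeffs,
      productCoeffs = reaction@reactantCoeffs)
}
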