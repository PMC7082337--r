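# Gas partitioning, rates, pools, stoichiometry and free energy.

test_that("Henry's law dissolved concentration is pressure x constant", {
  expect_identical(henryDissolved(0, 123), 0)
  expect_equal(henryDissolved(1.0, 1.4e-3), 1.4e-3)
  # at ~0.9 atm headspace methane and the documented constant, the
  # dissolved concentration matches the reactor's stated 1.37 mM
  expect_equal(henryDissolved(0.9, HENRY_CH4_295K), 0.9 * 1.52e-3)
  expect_equal(henryDissolved(0.9, HENRY_CH4_295K), 1.37e-3,
               tolerance = 0.005)
  expect_error(henryDissolved(-0.1, 1e-3), "partialPressure")
  expect_error(henryDissolved(1, 0), "henryConstant")
})

test_that("total methane sums ideal-gas headspace and dissolved amounts", {
  expect_equal(totalMethaneAmount(0, 0.13, 0.7, 295.15), 0)
  # hand arithmetic: 1 atm x 0.13 L / (0.082057338 x 295.15 K) = 5367 umol
  # headspace; 1 x 1.52e-3 x 0.7 L = 1064 umol dissolved
  hand <- (1 * 0.13 / (0.082057338 * 295.15) + 1 * 1.52e-3 * 0.7) * 1e6
  expect_equal(totalMethaneAmount(1, 0.13, 0.7, 295.15, 1.52e-3), hand)
  expect_equal(hand, 6431.6, tolerance = 1e-4)
  # doubling liquid volume doubles only the dissolved term
  base <- totalMethaneAmount(1, 0.13, 0.7, 295.15, 1.52e-3)
  dbl <- totalMethaneAmount(1, 0.13, 1.4, 295.15, 1.52e-3)
  expect_equal(dbl - base, 1 * 1.52e-3 * 0.7 * 1e6)
  expect_error(totalMethaneAmount(1, 0, 0.7, 295.15), "> 0")
})

test_that("rate estimation recovers slopes and flags direction", {
  d <- c(0, 7, 14, 21)
  r <- estimateRate(d, 2000 - 44.5 * d, "consumption")
  expect_s4_class(r, "RateEstimate")
  expect_equal(rate(r), 44.5)
  expect_equal(residualSE(r), 0, tolerance = 1e-10)
  expect_false(directionMismatch(r))
  # two-point slope
  r2 <- estimateRate(c(0, 1), c(100, 60), "consumption")
  expect_equal(rate(r2), 40)
  expect_equal(nPoints(r2), 2L)
  # endpoint method on curved data uses first/last only
  r3 <- estimateRate(c(0, 5, 10), c(100, 90, 60), "consumption",
                     method = "endpoint")
  expect_equal(rate(r3), 4)
  # direction mismatch is a flag, not an error
  r4 <- estimateRate(c(0, 1), c(10, 20), "consumption")
  expect_true(directionMismatch(r4))
  expect_error(estimateRate(1, 5, "consumption"), "insufficient")
  expect_error(estimateRate(c(1, 1), c(2, 3), "production"), "distinct")
})

test_that("noisy OLS rate recovery matches the closed-form slope oracle", {
  d <- c(0, 7, 14, 21)
  set.seed(99)
  est <- ols <- numeric(200)
  for (i in seq_len(200)) {
    y <- 500 + 184.7 * d + rnorm(4, 0, 50)
    est[i] <- rate(estimateRate(d, y, "production"))
    ols[i] <- oracleOLSSlope(d, y)
  }
  expect_equal(est, abs(ols))
  expect_equal(mean(est), 184.7, tolerance = 0.05)
})

test_that("stoichiometric ratio divides acceptor by donor rate", {
  expect_equal(stoichiometricRatio(184.7, 44.5), 184.7 / 44.5)
  expect_equal(stoichiometricRatio(8, 2), 4)
  expect_equal(stoichiometricRatio(3.3, 3.3), 1)
  expect_error(stoichiometricRatio(1, 0), "donor")
})

test_that("Mn-AOM reaction balances; perturbing any coefficient breaks it", {
  rxn <- mnAOMReaction()
  expect_true(validateReactionBalance(rxn))
  for (side in c("reactantCoeffs", "productCoeffs")) {
    for (i in seq_along(slot(rxn, side))) {
      bad <- rxn
      slot(bad, side)[i] <- slot(bad, side)[i] + 1
      expect_error(validateReactionBalance(bad), "unbalanced")
    }
  }
})

test_that("electron balance predicts 4 Mn(II) per CH4 and cross-checks", {
  r <- electronBalanceRatio(mnAOMReaction(), "CH4", "MnO2",
                            mnAOMOxidationStates())
  expect_identical(r, 4)
  # Fe(III) -> Fe(II) accepts a single electron: 8 acceptors per CH4
  feRxn <- reactionSpec(
    reactants = list(
      list(species("CH4", "aqueous", c(C = 1, H = 4)), 1),
      list(species("Fe(OH)3", "solid", c(Fe = 1, O = 3, H = 3)), 8),
      list(species("H+", "aqueous", c(H = 1), charge = 1), 15)),
    products = list(
      list(species("HCO3-", "aqueous", c(C = 1, H = 1, O = 3),
                   charge = -1), 1),
      list(species("Fe2+", "aqueous", c(Fe = 1), charge = 2), 8),
      list(species("H2O", "liquid-water", c(H = 2, O = 1)), 21)))
  feStates <- data.frame(
    species = c("CH4", "HCO3-", "Fe(OH)3", "Fe2+"),
    element = c("C", "C", "Fe", "Fe"), state = c(-4, 4, 3, 2))
  expect_equal(electronBalanceRatio(feRxn, "CH4", "Fe(OH)3", feStates), 8)
  expect_error(
    electronBalanceRatio(mnAOMReaction(), "CH4", "MnO2",
                         mnAOMOxidationStates()[-3, ]),
    "oxidation state")
})

test_that("reaction quotient follows the activity convention", {
  rxn <- mnAOMReaction()
  ones <- conditionSet(c("CH4" = 1, "H+" = 1, "HCO3-" = 1, "Mn2+" = 1),
                       295.15)
  expect_equal(reactionQuotient(rxn, ones), 1)
  # hand product at the stated in-situ conditions (solids excluded)
  hand <- (1.16e-4 * (7.1e-4)^4) / (1.37e-3 * (1e-7)^7)
  expect_equal(reactionQuotient(rxn, mnAOMConditions()), hand)
  expect_equal(hand, 2.15e35, tolerance = 0.01)
  # reversing the reaction inverts Q
  expect_equal(reactionQuotient(reverseReaction(rxn), mnAOMConditions()),
               1 / hand)
  # missing aqueous activity errors by name
  expect_error(
    reactionQuotient(rxn, conditionSet(c("CH4" = 1e-3), 295.15)),
    "missing activity.*HCO3-")
})

test_that("Gibbs free energy combines formation energies and RT ln Q", {
  rxn <- mnAOMReaction()
  th <- defaultThermoTable()
  ones <- conditionSet(c("CH4" = 1, "H+" = 1, "HCO3-" = 1, "Mn2+" = 1),
                       295.15)
  g <- gibbsFreeEnergy(rxn, th, ones)
  expect_equal(g$deltaG, g$deltaG0)  # Q = 1 leaves the standard state
  # zero formation energies isolate the RT ln Q term
  th0 <- thermoTable(setNames(rep(0, 6),
                              c("CH4", "MnO2", "H+", "HCO3-", "Mn2+",
                                "H2O")), "null table")
  gq <- gibbsFreeEnergy(rxn, th0, mnAOMConditions())
  expect_equal(gq$deltaG,
               8.314462618e-3 * 295.15 * log(gq$Q))
  # reversal flips the sign
  gf <- gibbsFreeEnergy(rxn, th, mnAOMConditions())
  gr <- gibbsFreeEnergy(reverseReaction(rxn), th, mnAOMConditions(),
                        donor = "CH4")
  expect_equal(gr$deltaG, -gf$deltaG)
  # in-situ Mn-AOM is strongly exergonic under the default table
  expect_lt(gf$deltaG, -300)
  expect_error(gibbsFreeEnergy(rxn, thermoTable(c(CH4 = 0), "x"),
                               mnAOMConditions()), "formation energy")
})

test_that("delta-G is monotone in product and reactant activities", {
  rxn <- mnAOMReaction()
  th <- defaultThermoTable()
  base <- mnAOMConditions()
  g0 <- gibbsFreeEnergy(rxn, th, base)$deltaG
  up <- base
  up@activities["Mn2+"] <- up@activities["Mn2+"] * 10
  expect_gt(gibbsFreeEnergy(rxn, th, up)$deltaG, g0)
  dn <- base
  dn@activities["CH4"] <- dn@activities["CH4"] * 10
  expect_lt(gibbsFreeEnergy(rxn, th, dn)$deltaG, g0)
})

test_that("Mn pool summary totals, fractions and dissolved flag", {
  d <- data.frame(day = 1:3,
                  mn2_dissolved = c(1, 0, 5),
                  mn2_adsorbed = c(50, 0, 50),
                  mn2_carbonate = c(49, 0, 45))
  s <- mnPoolSummary(d)
  expect_equal(s$mn2_total, c(100, 0, 100))
  expect_equal(s$frac_dissolved, c(0.01, NA, 0.05))
  expect_equal(s$dissolved_flag, c(FALSE, FALSE, TRUE))
  # fractions sum to 1 wherever defined
  ok <- s$mn2_total > 0
  expect_equal(unname(rowSums(s[ok, c("frac_dissolved", "frac_adsorbed",
                                      "frac_carbonate")])),
               rep(1, sum(ok)), tolerance = 1e-12)
  expect_error(mnPoolSummary(transform(d, mn2_dissolved = c(-1, 0, 0))),
               "negative")
})

test_that("fraction sum invariant holds across random pool tables", {
  set.seed(7)
  for (i in 1:20) {
    d <- data.frame(day = 1:10,
                    mn2_dissolved = runif(10, 0, 10),
                    mn2_adsorbed = runif(10, 0, 500),
                    mn2_carbonate = runif(10, 0, 500))
    s <- mnPoolSummary(d)
    expect_equal(s$frac_dissolved + s$frac_adsorbed + s$frac_carbonate,
                 rep(1, 10), tolerance = 1e-12)
  }
})
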