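test_that("expected counts sum stratified risks over informative members", {
  m <- data.frame(id = sprintf("i%d", 1:10), fatherId = NA, motherId = NA,
                  sex = "male", affected = "unaffected", stratum = "all")
  ped <- newPedigree("flat", m)
  rates <- populationRates(c(all = 0.01))
  expect_equal(expectedCount(ped, rates), 0.1)

  # person-year mode: rate x years at risk
  one <- newPedigree("one", data.frame(id = "a", fatherId = NA, motherId = NA,
                                       sex = "male", affected = "unaffected",
                                       stratum = "all"))
  py <- populationRates(c(all = 0.0002), mode = "person_year")
  expect_equal(expectedCount(one, py, yearsAtRisk = c(a = 50)), 0.01)
  expect_error(expectedCount(one, py), class = "famseg_config_error")

  # unknown affection drops members from the denominator
  m2 <- m
  m2$affected[1:4] <- "unknown"
  expect_equal(expectedCount(newPedigree("flat2", m2), rates), 0.06)

  # unresolvable stratum names the member
  m3 <- m
  m3$stratum[3] <- "missing_stratum"
  err <- tryCatch(expectedCount(newPedigree("flat3", m3), rates),
                  famseg_config_error = function(e) e)
  expect_match(conditionMessage(err), "i3")

  # all-unknown affection is degenerate
  m4 <- m
  m4$affected <- "unknown"
  expect_error(expectedCount(newPedigree("flat4", m4), rates),
               class = "famseg_degenerate_error")

  # generator bookkeeping: expected equals the analytic sum of planted rates
  cfg <- simConfig(nGenerations = 5, seed = TEST_SEED, familyId = "EXP1")
  ped5 <- assignAffection(generatePedigree(cfg), cfg)
  manual <- sum(unname(cfg$baseRates@rates[members(ped5)$stratum]))
  expect_equal(expectedCount(ped5, cfg$baseRates), manual, tolerance = 1e-12)
})

test_that("the exact Poisson SIR test matches a pmf-summation oracle", {
  grid <- expand.grid(observed = c(0L, 1L, 2L, 3L, 5L, 10L, 40L, 100L),
                      expected = c(1e-9, 0.01, 0.5, 1, 4.7, 20, 50))
  for (i in seq_len(nrow(grid))) {
    o <- grid$observed[i]; e <- grid$expected[i]
    st <- sirTest(o, e)
    expect_equal(st$pValue, poissonTailOracle(o, e), tolerance = 1e-12,
                 label = sprintf("p(obs=%d, exp=%g)", o, e))
    expect_equal(st$sir, o / e)
  }
  # the canonical worked example: three affected against half a case expected
  expect_equal(sirTest(3, 0.5)$pValue, poissonTailOracle(3, 0.5),
               tolerance = 1e-12)
  expect_equal(round(sirTest(3, 0.5)$pValue, 4), 0.0144)
  # near-zero expected: P(X >= 1) = 1 - exp(-lambda) ~ lambda
  st <- sirTest(1, 1e-9)
  expect_equal(st$pValue, 1e-9, tolerance = 1e-6)
  expect_equal(st$sir, 1e9)
  expect_equal(sirTest(0, 3.7)$pValue, 1)
  expect_error(sirTest(-1, 1), class = "famseg_domain_error")
  expect_error(sirTest(2, 0), class = "famseg_domain_error")
})

test_that("the Poisson tail is monotone in observed and expected", {
  for (e in c(0.2, 1, 5)) {
    p <- vapply(0:12, function(o) sirTest(o, e)$pValue, numeric(1))
    expect_true(all(diff(p) < 0)) # non-increasing in observed
  }
  for (o in c(1L, 3L, 8L)) {
    p <- vapply(c(0.1, 0.5, 1, 2, 5), function(e) sirTest(o, e)$pValue,
                numeric(1))
    expect_true(all(diff(p) > 0)) # non-decreasing in expected
  }
})

test_that("screenFamilies ranks, flags and isolates failures", {
  rates <- populationRates(c(all = 0.02))
  mk <- function(fid, nAff, nTot, stratum = "all") {
    newPedigree(fid, data.frame(
      id = sprintf("%s_i%d", fid, seq_len(nTot)), fatherId = NA, motherId = NA,
      sex = "male",
      affected = rep(c("affected", "unaffected"), c(nAff, nTot - nAff)),
      stratum = stratum))
  }
  cohort <- list(mk("hot", 5, 20), mk("cold", 0, 20), mk("warm", 1, 20),
                 mk("broken", 1, 5, stratum = "nope"))
  res <- screenFamilies(cohort, rates, alpha = 0.01)
  expect_equal(res$familyId, c("hot", "warm", "cold"))
  expect_true(res$highRisk[res$familyId == "hot"])
  expect_false(any(res$highRisk[res$familyId != "hot"]))
  expect_false(res$highRisk[res$familyId == "cold"]) # observed 0 never flags
  expect_named(attr(res, "failures"), "broken")
  expect_true(all(res$pValue == sort(res$pValue)))
  # Bonferroni flag is at least as strict
  expect_true(all(res$highRiskBonferroni <= res$highRisk))
})

test_that("null families are flagged at no more than the nominal rate", {
  # small in-suite calibration; the full-size run lives in the acceptance suite
  ex <- riskCohortExperiment(600, simConfig(nGenerations = 5),
                             alpha = 0.01, seed = TEST_SEED)
  frac <- mean(ex$highRisk)
  expect_lte(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(ex)))
})

test_that("planted risk families are recovered above chance", {
  ex <- riskCohortExperiment(150, simConfig(nGenerations = 5), alpha = 0.01,
                             plantedFraction = 0.2, plantedMultiplier = 10,
                             seed = TEST_SEED)
  planted <- ex$highRisk[ex$planted]
  null <- ex$highRisk[!ex$planted]
  expect_gt(mean(planted), 0.2)
  expect_gt(mean(planted), mean(null))
})
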