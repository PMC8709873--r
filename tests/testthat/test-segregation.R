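segFixtures <- function() {
  list(
    parent_child = list(ped = trioPedigree(), carriers = c("dad", "kid")),
    siblings = list(ped = sibPairPedigree(), carriers = c("sib1", "sib2")),
    cousins = list(ped = cousinPairPedigree(), carriers = c("leaf1", "leaf2")),
    avuncular = list(ped = branchPedigree(1, 2), carriers = c("leaf1", "leaf2")),
    grand_line = list(ped = directLinePedigree(3), carriers = c("anc", "desc")),
    three_carriers = {
      tc <- threeCarrierPedigree()
      list(ped = tc$ped, carriers = tc$carriers)
    })
}

test_that("marry-in introduction probability is Hardy-Weinberg", {
  expect_equal(introductionProbability(0), 0)
  expect_equal(introductionProbability(1), 1)
  expect_equal(introductionProbability(0.5), 0.75)
  expect_equal(introductionProbability(0.0032), 1 - 0.9968^2)
  expect_equal(introductionProbability(0.0032), 0.00638976)
  expect_error(introductionProbability(1.2), class = "famseg_domain_error")
  expect_error(introductionProbability(-0.1), class = "famseg_domain_error")
})

test_that("exact peeling matches brute-force enumeration on tiny pedigrees", {
  cases <- segFixtures()[c("parent_child", "siblings", "cousins")]
  for (nm in names(cases)) {
    fx <- cases[[nm]]
    for (q in c(0.001, 0.05, 0.3)) {
      ep <- exactPeeling(fx$ped, fx$carriers, q)
      oracle <- bruteForceSharing(fx$ped, q, function(g) {
        all(vapply(fx$carriers, function(id) g[[id]] >= 1, logical(1)))
      })
      expect_equal(ep@pAnySharing, oracle, tolerance = 1e-12,
                   label = sprintf("%s pAny q=%g", nm, q))
      idx <- sort(fx$carriers)[1]
      oracleIdx <- bruteForceSharing(fx$ped, q, function(g) g[[idx]] >= 1)
      expect_equal(ep@pIndexCarrier, oracleIdx, tolerance = 1e-12)
      oracleAny <- bruteForceSharing(fx$ped, q, function(g) {
        any(vapply(fx$carriers, function(id) g[[id]] >= 1, logical(1)))
      })
      expect_equal(ep@pAtLeastOne, oracleAny, tolerance = 1e-12)
    }
  }
})

test_that("closed form and exact peeling coincide on loop-free fixtures", {
  for (nm in names(segFixtures())) {
    fx <- segFixtures()[[nm]]
    for (q in c(1e-4, 1e-3, 1e-2, 0.1)) {
      cf <- closedFormSharing(fx$ped, fx$carriers, q)
      ep <- exactPeeling(fx$ped, fx$carriers, q)
      expect_equal(cf@pAnySharing, ep@pAnySharing, tolerance = 1e-9,
                   label = sprintf("%s q=%g", nm, q))
      expect_equal(cf@pConditional, ep@pConditional, tolerance = 1e-9)
      expect_equal(cf@pAtLeastOne, ep@pAtLeastOne, tolerance = 1e-9)
      expect_lte(cf@pSingleIntroduction, cf@pAnySharing)
      expect_gte(cf@pConditional, cf@pAnySharing)
    }
  }
})

test_that("the closed-form term table is a decomposition of pAnySharing", {
  cf <- closedFormSharing(cousinPairPedigree(), c("leaf1", "leaf2"), 0.01)
  expect_equal(sum(cf@terms$term), cf@pAnySharing, tolerance = 1e-12)
  expect_true(all(cf@terms$weight >= 0 & cf@terms$weight <= 1))
  # the configuration weights are a probability distribution over sources
  expect_equal(sum(cf@terms$weight), 1, tolerance = 1e-12)
  # the single-introduction formula is the leading term up to O(q^2)
  apexTerm <- cf@terms$term[cf@terms$configuration == "apex"]
  expect_equal(apexTerm, cf@pSingleIntroduction, tolerance = 0.01)
})

test_that("Hardy-Weinberg limits hold for single carriers", {
  ep <- exactPeeling(trioPedigree(), "kid", 0.01)
  expect_equal(ep@pAnySharing, 1 - 0.99^2) # 0.0199
  expect_equal(ep@pConditional, 1)
  cf <- closedFormSharing(trioPedigree(), "kid", 0.01)
  expect_equal(cf@pAnySharing, 1 - 0.99^2)
  expect_equal(cf@pConditional, 1)
})

test_that("rare-allele limits: sibling conditional tends to 1/2", {
  ep <- exactPeeling(sibPairPedigree(), c("sib1", "sib2"), 1e-6)
  expect_equal(ep@pConditional, 0.5, tolerance = 1e-4)
  cf <- closedFormSharing(sibPairPedigree(), c("sib1", "sib2"), 1e-6)
  expect_equal(cf@pConditional, 0.5, tolerance = 1e-4)
})

test_that("each added meiosis exactly halves the single-introduction term", {
  q <- 1e-6
  ps <- vapply(1:6, function(m) {
    closedFormSharing(directLinePedigree(m), c("anc", "desc"),
                      q)@pSingleIntroduction
  }, numeric(1))
  expect_equal(ps[-1] / ps[-6], rep(0.5, 5), tolerance = 1e-12)
  # and the exact probability follows at rare q
  pe <- vapply(1:6, function(m) {
    exactPeeling(directLinePedigree(m), c("anc", "desc"), q)@pAnySharing
  }, numeric(1))
  expect_equal(pe[-1] / pe[-6], rep(0.5, 5), tolerance = 1e-4)
})

test_that("sharing probability is monotone in q and in family depth", {
  qs <- c(1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.3)
  for (fx in segFixtures()[c("siblings", "cousins")]) {
    pAny <- vapply(qs, function(q)
      exactPeeling(fx$ped, fx$carriers, q)@pAnySharing, numeric(1))
    expect_true(all(diff(pAny) > 0))
  }
  # deeper relationships share less: cousins sit well below both one-meiosis
  # and two-meioses pairs. (Siblings in fact very slightly exceed
  # parent-child pairs — two parental genomes offer one more independent
  # introduction route, a difference of order q^2 — so no strict ordering
  # between those two is asserted.)
  for (q in c(1e-3, 1e-2, 0.1)) {
    pc <- exactPeeling(trioPedigree(), c("dad", "kid"), q)@pAnySharing
    sib <- exactPeeling(sibPairPedigree(), c("sib1", "sib2"), q)@pAnySharing
    cz <- exactPeeling(cousinPairPedigree(), c("leaf1", "leaf2"), q)@pAnySharing
    expect_gt(pc, cz)
    expect_gt(sib, cz)
  }
})

test_that("domain and size guards are enforced", {
  expect_error(exactPeeling(trioPedigree(), "kid", 0),
               class = "famseg_domain_error")
  expect_error(closedFormSharing(trioPedigree(), "kid", 1),
               class = "famseg_domain_error")
  expect_error(exactPeeling(trioPedigree(), character(0), 0.01),
               class = "famseg_domain_error")
  # ancestral closures beyond the exactness bound defer to gene dropping
  cfg <- simConfig(nGenerations = 7, seed = TEST_SEED, familyId = "BIG1",
                   riskMultiplier = 25)
  ped <- assignAffection(generatePedigree(cfg), cfg)
  aff <- members(ped)$id[members(ped)$affected == "affected"]
  err <- tryCatch(exactPeeling(ped, aff, 0.01),
                  famseg_use_genedrop = function(e) e)
  expect_s3_class(err, "famseg_use_genedrop")
  expect_match(conditionMessage(err), "genedrop")
})
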