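test_that("allele frequencies reproduce the printed display arithmetic", {
  expect_equal(alleleFrequency(28, 0, 4376), 28 / 8752)
  expect_equal(displayFrequency(alleleFrequency(28, 0, 4376)), 0.0032)
  expect_equal(displayFrequency(alleleFrequency(10, 0, 4376)), 0.0011)
  expect_equal(alleleFrequency(0, 5, 5), 1)
  expect_equal(alleleFrequency(0, 0, 100), 0)
  # monotone in both carrier counts
  expect_true(all(diff(alleleFrequency(0:10, 0, 100)) > 0))
  expect_true(all(diff(alleleFrequency(0, 0:10, 100)) > 0))
  expect_error(alleleFrequency(-1, 0, 10), class = "famseg_domain_error")
  expect_error(alleleFrequency(6, 5, 10), class = "famseg_domain_error")
  expect_error(alleleFrequency(1, 0, 0), class = "famseg_domain_error")
})

test_that("family-shared filter keeps planted records with attribution", {
  # 20 records, exactly 3 planted to satisfy every rule
  set.seed(TEST_SEED)
  recs <- do.call(rbind, lapply(1:20, function(i) {
    variantRow(sprintf("v%02d", i),
               impact = sample(c("LOW", "MODIFIER"), 1),
               famCarriers = sample(0:5, 1))
  }))
  recs$impact[1:3] <- c("HIGH", "MODERATE", "MEDIUM") # MEDIUM == MODERATE tier
  recs$famCarriers[1:3] <- 6
  rep <- familySharedFilter(recs, sharedIn = 6, controlMafMax = 0.01)
  expect_equal(rep@survivingCount, 3L)
  expect_setequal(surviving(rep)$id, c("v01", "v02", "v03"))
  expect_equal(rep@inputCount,
               rep@survivingCount + sum(eliminated(rep)))

  # impact failure is attributed to the impact rule when all else passes
  low <- variantRow("low_impact", impact = "LOW", famCarriers = 6)
  repLow <- familySharedFilter(low)
  expect_equal(unname(eliminated(repLow)["impact"]), 1L)
  expect_equal(repLow@survivingCount, 0L)

  # empty input gives an empty report
  rep0 <- familySharedFilter(recs[0, ])
  expect_equal(rep0@inputCount, 0L)
  expect_equal(sum(eliminated(rep0)), 0L)
})

test_that("cohort functional filter retains the two target variants", {
  rep <- cohortFunctionalFilter(cohortFixture())
  expect_setequal(surviving(rep)$id, c("P469S", "H885Y"))
  el <- eliminated(rep)
  expect_equal(unname(el["consequence"]), 1L)
  expect_equal(unname(el["annotations"]), 1L)
  expect_equal(unname(el["carriers"]), 1L)
  expect_equal(unname(el["control_frequency"]), 1L)
  expect_equal(unname(el["unannotated"]), 1L)
  # raising the control panel frequency evicts a surviving record
  recs <- cohortFixture()
  recs$controlAc_1kg[recs$id == "P469S"] <- round(0.02 * 8758)
  rep2 <- cohortFunctionalFilter(recs)
  expect_setequal(surviving(rep2)$id, "H885Y")
  expect_equal(unname(eliminated(rep2)["control_frequency"]), 2L)
})

test_that("filters are conjunctions: survival is order-independent", {
  recs <- cohortFixture()
  rep <- cohortFunctionalFilter(recs)
  manual <- with(recs, consequence == "missense" &
                 !is.na(sift) & sift == "deleterious" &
                 !is.na(polyphen) &
                 polyphen %in% c("probably_damaging", "possibly_damaging") &
                 caseHet + caseHom >= 5 &
                 alleleFrequency(caseHet, caseHom, caseN) >= 0.001 &
                 controlAc_1kg / controlAn_1kg < 0.01 &
                 controlAc_gnomad / controlAn_gnomad < 0.01)
  expect_setequal(surviving(rep)$id, recs$id[manual])
})

test_that("Fisher allele-count test matches the hypergeometric oracle", {
  cases <- list(c(5, 40, 2, 38), c(0, 20, 4, 30), c(10, 200, 10, 200),
                c(100, 200, 0, 200), c(1, 500, 3, 500), c(7, 13, 2, 19))
  for (cc in cases) {
    ct <- caseControlTest(cc[1], cc[2], cc[3], cc[4])
    expect_equal(ct$pValue,
                 fisherOracle(cc[1], cc[2] - cc[1], cc[3], cc[4] - cc[3]),
                 tolerance = 1e-10,
                 label = paste(cc, collapse = "/"))
  }
  # strong imbalance is decisively significant
  expect_lt(caseControlTest(100, 200, 0, 200)$pValue, 1e-6)
  # identical tables: no association
  eq <- caseControlTest(12, 300, 12, 300)
  expect_equal(eq$pValue, 1)
  expect_equal(eq$oddsRatio, 1)
  # Haldane-Anscombe correction keeps the odds ratio finite at zero cells
  z <- caseControlTest(3, 100, 0, 100)
  expect_true(is.finite(z$oddsRatio) && z$oddsRatio > 1)
  expect_error(caseControlTest(5, 3, 1, 10), class = "famseg_domain_error")
})

test_that("records without control panels fall under the unannotated rule", {
  recs <- cohortFixture()[1:2, !grepl("^control", names(cohortFixture()))]
  rep <- cohortFunctionalFilter(recs)
  expect_equal(rep@survivingCount, 0L)
  expect_equal(unname(eliminated(rep)["unannotated"]), 2L)
  repFam <- familySharedFilter(recs)
  expect_equal(repFam@inputCount, 2L)
})

test_that("variant tables round-trip through TSV", {
  recs <- cohortFixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(recs, f)
  back <- readVariantTable(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$caseHet, recs$caseHet)
  expect_equal(is.na(back$sift), is.na(recs$sift))
  rep <- cohortFunctionalFilter(back)
  expect_setequal(surviving(rep)$id, c("P469S", "H885Y"))
})
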