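test_that("deterministic two-generation config gives couple plus children", {
  cfg <- simConfig(nGenerations = 2, meanOffspring = 2,
                   deterministicOffspring = TRUE, seed = 1, familyId = "D2")
  ped <- generatePedigree(cfg)
  expect_equal(length(ped), 4L)
  expect_length(founders(ped), 2L)
  expect_equal(sum(!is.na(members(ped)$fatherId)), 2L)
  expect_equal(expectedPedigreeSize(cfg), 4)
  # zero-offspring config is degenerate
  expect_error(generatePedigree(simConfig(meanOffspring = 0)),
               class = "famseg_degenerate_error")
  expect_error(
    generatePedigree(simConfig(meanOffspring = 0.4,
                               deterministicOffspring = TRUE)),
    class = "famseg_degenerate_error")
})

test_that("the same seed regenerates identical families", {
  cfg <- simConfig(seed = TEST_SEED, familyId = "DET")
  a <- generatePedigree(cfg)
  b <- generatePedigree(cfg)
  expect_identical(members(a), members(b))
  aa <- assignAffection(a, cfg)
  bb <- assignAffection(b, cfg)
  expect_identical(members(aa), members(bb))
  cfgv <- cfg
  cfgv$plantedVariant <- list(penetrantTransmission = FALSE)
  expect_identical(plantVariant(aa, cfgv)$genotypes,
                   plantVariant(bb, cfgv)$genotypes)
  # different families draw from different streams
  cfg2 <- cfg
  cfg2$familyId <- "DET2"
  expect_false(identical(members(generatePedigree(cfg2))$sex,
                         members(a)$sex))
})

test_that("family size matches the branching-process expectation", {
  cfg <- simConfig(nGenerations = 5, meanOffspring = 2)
  sizes <- vapply(seq_len(300), function(i) {
    ci <- cfg
    ci$familyId <- sprintf("S%03d", i)
    ci$seed <- TEST_SEED
    length(generatePedigree(ci))
  }, numeric(1))
  expect_lt(abs(mean(sizes) - expectedPedigreeSize(cfg)),
            3 * sd(sizes) / sqrt(length(sizes)))
})

test_that("affection honours stratified rates and multipliers", {
  # multiplier 1: pooled affected fraction within 3 SE of the rate
  cfg <- simConfig(nGenerations = 6, meanOffspring = 2.2, seed = TEST_SEED,
                   baseRates = populationRates(c(male = 0.04, female = 0.04)))
  tot <- 0; aff <- 0
  for (i in 1:40) {
    ci <- cfg
    ci$familyId <- sprintf("A%03d", i)
    p <- assignAffection(generatePedigree(ci), ci)
    tot <- tot + length(p)
    aff <- aff + sum(members(p)$affected == "affected")
  }
  expect_lt(abs(aff / tot - 0.04), 3 * sqrt(0.04 * 0.96 / tot))

  # zero rates: nobody affected
  cfg0 <- simConfig(seed = 2, baseRates = populationRates(c(male = 0,
                                                            female = 0)))
  p0 <- assignAffection(generatePedigree(cfg0), cfg0)
  expect_equal(sum(members(p0)$affected == "affected"), 0L)

  # probabilities above one are rejected
  cfgBig <- simConfig(seed = 3, riskMultiplier = 200)
  expect_error(assignAffection(generatePedigree(cfgBig), cfgBig),
               class = "famseg_config_error")
})

test_that("planted variants force carriers along the recorded path", {
  cfg <- simConfig(nGenerations = 6, seed = TEST_SEED + 2, familyId = "PV1",
                   riskMultiplier = 20, q = 0.001,
                   plantedVariant = list(penetrantTransmission = TRUE))
  ped <- assignAffection(generatePedigree(cfg), cfg)
  v <- plantVariant(ped, cfg)
  intro <- v$truth$introducer
  expect_true(intro %in% founders(ped))
  expect_gte(v$genotypes[intro], 1L)
  lineage <- pedMetadata(ped)$truth$lineage
  affDesc <- setdiff(intersect(
    members(ped)$id[members(ped)$affected == "affected"], lineage),
    founders(ped)) # descendants only: the co-founder is not downstream
  expect_true(all(v$genotypes[affDesc] >= 1))
  expect_true(v$truth$penetrant)
  # a non-founder introducer is rejected
  cfgBad <- cfg
  cfgBad$plantedVariant <- list(introducer = affDesc[1])
  expect_error(plantVariant(ped, cfgBad), class = "famseg_domain_error")
})

test_that("null drops with q = 0 yield a monomorphic variant", {
  cfg <- simConfig(nGenerations = 4, seed = 5, q = 0, familyId = "MONO")
  ped <- assignAffection(generatePedigree(cfg), cfg)
  v <- plantVariant(ped, cfg)
  expect_true(all(v$genotypes == 0L))
  expect_length(v$carrierIds, 0)
})

test_that("emitted bundles validate, round-trip and stay Mendelian", {
  cfg <- simConfig(nGenerations = 5, seed = TEST_SEED + 3, familyId = "IO1",
                   riskMultiplier = 10, q = 0.01,
                   plantedVariant = list(penetrantTransmission = TRUE))
  ped <- assignAffection(generatePedigree(cfg), cfg)
  v <- plantVariant(ped, cfg)
  dir <- withr::local_tempdir()
  paths <- writeSimulatedFamily(ped, v, dir)
  expect_true(all(file.exists(paths)))

  ped2 <- readPed(paths[["ped"]], sidecar = paths[["sidecar"]])
  expect_identical(members(ped2)$id, members(ped)$id)
  expect_identical(members(ped2)$genotyped, members(ped)$genotyped)

  g2 <- readMinimalVcf(paths[["vcf"]])
  expect_identical(g2, v$genotypes)
  m <- members(ped2)
  nonf <- m$id[!is.na(m$fatherId)]
  fa <- m$fatherId[match(nonf, m$id)]
  mo <- m$motherId[match(nonf, m$id)]
  expect_true(all(g2[nonf] <= (g2[fa] > 0) + (g2[mo] > 0)))

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_true(truth$variant$penetrant)
  expect_setequal(truth$carrierIds, v$carrierIds)

  ann <- readVariantTable(paths[["annotation"]])
  expect_equal(ann$id, v$record$id)
  expect_equal(ann$impact, "MODERATE")
})

test_that("reference readers agree with the VCF writer", {
  skip_if_not_installed("vcfR")
  g <- c(a = 0L, b = 1L, c = 2L)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeMinimalVcf(g, f, chrom = "2", pos = 123L, ref = "G", alt = "A")
  vv <- vcfR::read.vcfR(f, verbose = FALSE)
  gt <- vcfR::extract.gt(vv)
  expect_equal(unname(gt[1, ]), c("0/0", "0/1", "1/1"))
  expect_equal(colnames(gt), names(g))
  expect_equal(vcfR::getPOS(vv), 123)
})
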