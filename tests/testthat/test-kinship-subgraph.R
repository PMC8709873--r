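test_that("kinship coefficients match closed forms", {
  ped <- trioPedigree()
  expect_equal(kinshipCoeff(ped, "dad", "kid"), 0.25)
  expect_equal(kinshipCoeff(ped, "dad", "mom"), 0)
  expect_equal(kinshipCoeff(ped, "dad", "dad"), 0.5)
  expect_equal(kinshipCoeff(sibPairPedigree(), "sib1", "sib2"), 0.25)
  expect_equal(kinshipCoeff(cousinPairPedigree(), "leaf1", "leaf2"), 0.0625)
  expect_equal(kinshipCoeff(branchPedigree(1, 2), "leaf1", "leaf2"), 0.125)
  km <- kinshipMatrix(sibPairPedigree())
  expect_true(isSymmetric(km))
  expect_error(kinshipCoeff(ped, "dad", "nobody"),
               class = "famseg_lookup_error")
})

test_that("meioses match canonical relationships", {
  expect_equal(meioses(connectingSubgraph(trioPedigree(), c("dad", "kid"))), 1L)
  expect_equal(meioses(connectingSubgraph(sibPairPedigree(),
                                          c("sib1", "sib2"))), 2L)
  expect_equal(meioses(connectingSubgraph(cousinPairPedigree(),
                                          c("leaf1", "leaf2"))), 4L)
  expect_equal(meioses(connectingSubgraph(branchPedigree(1, 2),
                                          c("leaf1", "leaf2"))), 3L)
  for (m in c(1, 3, 7, 11, 12)) {
    expect_equal(meioses(connectingSubgraph(directLinePedigree(m),
                                            c("anc", "desc"))), as.integer(m))
  }
  # single carrier: zero meioses, apex is the carrier itself
  s <- connectingSubgraph(trioPedigree(), "kid")
  expect_equal(meioses(s), 0L)
  expect_equal(s@apex, "kid")
})

test_that("apex couple and marry-in identification follow the model", {
  s <- connectingSubgraph(sibPairPedigree(), c("sib1", "sib2"))
  expect_setequal(s@apex, c("dad", "mom")) # founder couple = one introduction
  expect_length(s@marryIn, 0)
  expect_setequal(s@ties, c("dad", "mom"))

  cz <- connectingSubgraph(cousinPairPedigree(), c("leaf1", "leaf2"))
  expect_setequal(cz@apex, c("apexF", "apexM"))
  expect_setequal(cz@marryIn, c("b1_1sp", "b2_1sp"))

  # carrier apex stays single: the parent is the introduction point
  pc <- connectingSubgraph(trioPedigree(), c("dad", "kid"))
  expect_equal(pc@apex, "dad")
  expect_equal(pc@marryIn, "mom")
})

test_that("the subgraph is invariant under carrier ordering", {
  tc <- threeCarrierPedigree()
  perms <- list(tc$carriers, rev(tc$carriers),
                tc$carriers[c(2, 1, 3)], tc$carriers[c(3, 1, 2)])
  subs <- lapply(perms, function(p) connectingSubgraph(tc$ped, p))
  for (s in subs[-1]) {
    expect_identical(s@nodes, subs[[1]]@nodes)
    expect_identical(s@meioses, subs[[1]]@meioses)
    expect_identical(s@apex, subs[[1]]@apex)
  }
})

test_that("kinship equals paths * (1/2)^(meioses+1) on loop-free pedigrees", {
  # on the generator's loop-free monogamous pedigrees every connected pair
  # of distinct lineage members has kinship c_apex * (1/2)^(meioses + 1)
  cfg <- simConfig(nGenerations = 5, seed = TEST_SEED, familyId = "KIN1")
  ped <- generatePedigree(cfg)
  lineage <- pedMetadata(ped)$truth$lineage
  set.seed(TEST_SEED)
  pairs <- t(replicate(25, sample(lineage, 2)))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    s <- tryCatch(connectingSubgraph(ped, c(a, b)),
                  famseg_disconnected_error = function(e) NULL)
    k <- kinshipCoeff(ped, a, b)
    if (is.null(s)) {
      expect_equal(k, 0)
    } else {
      nPaths <- length(s@apex)
      expect_equal(k, nPaths * 0.5^(s@meioses + 1),
                   tolerance = 1e-12,
                   label = sprintf("kinship(%s,%s)", a, b))
    }
  }
})

test_that("planted transmission paths are recovered as meioses", {
  cfg <- simConfig(nGenerations = 6, seed = TEST_SEED + 1, familyId = "PL1",
                   riskMultiplier = 20,
                   plantedVariant = list(penetrantTransmission = TRUE))
  ped <- assignAffection(generatePedigree(cfg), cfg)
  v <- plantVariant(ped, cfg)
  expect_gte(length(v$truth$forcedCarriers), 3)
  s <- connectingSubgraph(ped, v$truth$forcedCarriers)
  expect_equal(meioses(s), v$truth$pathMeioses)
})

test_that("disconnected carriers report the partition", {
  two <- newPedigree("two", data.frame(
    id = c("a", "b"), fatherId = c(NA, NA), motherId = c(NA, NA),
    sex = c("male", "male")))
  err <- tryCatch(connectingSubgraph(two, c("a", "b")),
                  famseg_disconnected_error = function(e) e)
  expect_s3_class(err, "famseg_disconnected_error")
  expect_setequal(unlist(err$partition), c("a", "b"))
  expect_length(err$partition, 2)
})
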