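# End-to-end pipeline on synthetic data: simulate -> aggregate -> filter ->
# segregate, with a machine-readable JSON report.

#' Segregation analysis for one carrier set, choosing the method by size
#'
#' Runs the closed form and exact peeling when the pruned pedigree is
#' within the exactness bound, and always a gene-drop estimate; for larger
#' problems the gene-drop estimate alone is returned.
#'
#' @param ped a [Pedigree].
#' @param carrierIds carrier ids.
#' @param q allele frequency.
#' @param seed base seed for the gene-drop stream.
#' @param nReps gene-drop replicates.
#' @param variantId label.
#' @return list with components `closedForm`, `exactPeeling` (either may be
#'   `NULL`), and `geneDrop`.
#' @export
segregateCarriers <- function(ped, carrierIds, q, seed, nReps = 1e5,
                              variantId = "variant") {
  cf <- tryCatch(closedFormSharing(ped, carrierIds, q, variantId = variantId),
                 famseg_disconnected_error = function(e) NULL)
  ep <- tryCatch(exactPeeling(ped, carrierIds, q, variantId = variantId),
                 famseg_use_genedrop = function(e) NULL)
  gd <- geneDrop(ped, carrierIds, q, nReps = nReps, seed = seed,
                 event = "all_carry", variantId = variantId)
  list(closedForm = cf, exactPeeling = ep, geneDrop = gd)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort of extended families (a fraction of them with
#' elevated familial risk), screens for high-risk families by the exact
#' Poisson test, plants a single rare functional variant in the top-ranked
#' high-risk family, filters the family's annotated variant table (the
#' planted variant among decoys), and computes segregation probabilities
#' for the realized carrier cases. All outputs (PED/VCF/TSV bundle, screen
#' table, filter report, JSON summary) are written under `outDir`; the
#' summary is byte-identical across runs with the same seed and
#' configuration.
#'
#' @param seed base seed for every stochastic stage.
#' @param outDir output directory.
#' @param nFamilies cohort size (default 20).
#' @param cfg a [simConfig()] template.
#' @param alpha familial significance threshold (default 0.01).
#' @param plantedFraction fraction of families with elevated risk
#'   (default 0.25).
#' @param plantedMultiplier lineage risk multiplier in those families
#'   (default 10).
#' @param q allele frequency of the planted variant (default 0.001).
#' @param nReps gene-drop replicates for the segregation stage.
#' @return the report list, invisibly; written to `<outDir>/report.json`.
#' @export
runPipeline <- function(seed, outDir, nFamilies = 20, cfg = simConfig(),
                        alpha = 0.01, plantedFraction = 0.25,
                        plantedMultiplier = 10, q = 0.001, nReps = 1e5) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nPlanted <- round(plantedFraction * nFamilies)

  cohort <- vector("list", nFamilies)
  for (i in seq_len(nFamilies)) {
    cfgi <- cfg
    cfgi$familyId <- sprintf("F%03d", i)
    cfgi$seed <- seed
    cfgi$riskMultiplier <- if (i <= nPlanted) plantedMultiplier else 1
    cohort[[i]] <- assignAffection(generatePedigree(cfgi), cfgi)
  }
  names(cohort) <- vapply(cohort, familyId, character(1))

  screen <- screenFamilies(cohort, cfg$baseRates, alpha = alpha)
  writeScreenResults(screen, file.path(outDir, "screen"))

  topFam <- screen$familyId[1]
  ped <- cohort[[topFam]]
  cfgTop <- cfg
  cfgTop$familyId <- topFam
  cfgTop$seed <- seed
  cfgTop$q <- q
  cfgTop$plantedVariant <- list(penetrantTransmission = TRUE)
  variant <- plantVariant(ped, cfgTop)
  writeSimulatedFamily(ped, variant, file.path(outDir, "family"))

  records <- rbind(variant$record, .decoyRecords(variant$record))
  records$controlAc_pop <- c(3L, 3L, 3L, 300L)
  records$controlAn_pop <- 20000L
  report <- familySharedFilter(records, sharedIn = variant$record$famCarriers)
  writeFilterReport(report, file.path(outDir, "filter"))

  segCarriers <- intersect(
    ped@members$id[ped@members$genotyped],
    variant$carrierIds)
  seg <- if (length(segCarriers) >= 1) {
    segregateCarriers(ped, segCarriers, q, seed = seed, nReps = nReps,
                      variantId = variant$record$id)
  } else NULL

  summary <- list(
    version = as.character(utils::packageVersion("famseg")),
    seed = seed,
    configHash = streamSeed(seed, nFamilies, alpha, plantedFraction,
                            plantedMultiplier, q, nReps, cfg$nGenerations,
                            cfg$meanOffspring),
    nFamilies = nFamilies,
    nHighRisk = sum(screen$highRisk),
    topFamily = topFam,
    topFamilyPValue = screen$pValue[1],
    filter = list(input = report@inputCount,
                  surviving = report@survivingCount),
    segregation = if (!is.null(seg)) list(
      carriers = sort(segCarriers),
      meioses = if (!is.null(seg$closedForm)) seg$closedForm@meioses else NA,
      pSingleIntroduction = if (!is.null(seg$closedForm))
        seg$closedForm@pSingleIntroduction else NA,
      pAnySharingClosedForm = if (!is.null(seg$closedForm))
        seg$closedForm@pAnySharing else NA,
      pAnySharingExact = if (!is.null(seg$exactPeeling))
        seg$exactPeeling@pAnySharing else NA,
      pAnySharingGeneDrop = seg$geneDrop@pHat
    ) else NULL
  )
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}

.decoyRecords <- function(template) {
  mk <- function(id, ...) {
    r <- template
    r$id <- id
    for (nm in names(list(...))) r[[nm]] <- list(...)[[nm]]
    r
  }
  rbind(
    mk("decoy_low_impact", impact = "LOW", consequence = "synonymous"),
    mk("decoy_not_shared", famCarriers = max(0L, template$famCarriers - 1L)),
    mk("decoy_common", impact = "MODERATE"))
}
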