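#' @import methods
NULL

# Pedigree ---------------------------------------------------------------------

#' Pedigree: a validated multi-generation family graph
#'
#' An S4 container for one extended family. The `members` slot is a
#' data.frame with one row per individual and columns `id`, `fatherId`,
#' `motherId` (`NA` = missing/founder), `sex` (`"male"`, `"female"`,
#' `"unknown"`), `affected` (`"affected"`, `"unaffected"`, `"unknown"`),
#' `genotyped` (logical), `birthYear` (integer or `NA`) and `stratum`
#' (character key into a [PopulationRates] table, or `NA`).
#'
#' Validity enforces the structural contract the downstream statistics rely
#' on: unique ids; parents either both present or both absent; parents are
#' members of the same family; fathers are male (or of unknown sex, permitted
#' for founders only, as deep genealogies often lack sex for apical
#' ancestors); the parent-to-child graph is acyclic; and the founder set is
#' non-empty.
#'
#' @slot familyId single character family identifier.
#' @slot members data.frame as described above.
#' @slot metadata free-form list (generator truth sidecars live here).
#' @seealso [newPedigree()], [readPed()], [founders()], [connectingSubgraph()]
#' @export
setClass("Pedigree", representation(
  familyId = "character",
  members = "data.frame",
  metadata = "list"
))

setValidity("Pedigree", function(object) {
  msgs <- .validateMembers(object@members)
  if (length(object@familyId) != 1L || is.na(object@familyId) ||
      !nzchar(object@familyId)) {
    msgs <- c(msgs, "familyId must be a single non-empty string")
  }
  if (length(msgs)) msgs else TRUE
})

# ConnectingSubgraph -----------------------------------------------------------

#' ConnectingSubgraph: minimal ancestral subgraph linking a carrier set
#'
#' The result of [connectingSubgraph()]: a minimum-meioses transmission tree
#' connecting all carriers through a common ancestral introduction point.
#' `nodes` holds the individuals on the transmission tree (one transmitting
#' parent per meiosis), `edges` the parent-to-child transmissions, and
#' `meioses` equals `nrow(edges)`. For every transmission the co-parent of
#' the child is recorded in `spouses`; co-parents that are pedigree founders
#' are the marry-in spouses, each an independent potential source of a
#' population allele. The apex introduction point is a founder couple
#' (2 individuals, either of whom may carry) or a single individual when the
#' apex is itself a carrier or has children by several partners.
#'
#' @slot familyId family the subgraph belongs to.
#' @slot carriers carrier ids the subgraph connects.
#' @slot nodes ids on the transmission tree.
#' @slot edges character matrix with columns `parent`, `child`.
#' @slot meioses integer transmission count (`nrow(edges)`).
#' @slot apex the designated introduction point (length 1 or 2).
#' @slot founderIntroducers same as `apex` (candidate single-introduction
#'   individuals).
#' @slot marryIn pedigree founders among the co-parents, excluding the apex.
#' @slot spouses named character: tree child id -> co-parent id.
#' @slot ties all apex candidates achieving the minimal meioses count.
#' @export
setClass("ConnectingSubgraph", representation(
  familyId = "character",
  carriers = "character",
  nodes = "character",
  edges = "matrix",
  meioses = "integer",
  apex = "character",
  founderIntroducers = "character",
  marryIn = "character",
  spouses = "character",
  ties = "character"
))

setValidity("ConnectingSubgraph", function(object) {
  msgs <- character()
  if (object@meioses != nrow(object@edges)) {
    msgs <- c(msgs, "meioses must equal the number of transmission edges")
  }
  if (!all(object@carriers %in% object@nodes)) {
    msgs <- c(msgs, "every carrier must be a node of the subgraph")
  }
  if (!length(object@apex) %in% 1:2) {
    msgs <- c(msgs, "apex must name one individual or one couple")
  }
  if (length(msgs)) msgs else TRUE
})

# PopulationRates --------------------------------------------------------------

#' PopulationRates: stratified population risk of the affected phenotype
#'
#' Maps stratum keys (for example sex by birth-cohort band) to either a
#' cumulative risk per person (probability, `mode = "cumulative"`) or a rate
#' per person-year (`mode = "person_year"`).
#'
#' @slot rates named numeric vector, one entry per stratum.
#' @slot mode `"cumulative"` or `"person_year"`.
#' @seealso [populationRates()], [expectedCount()]
#' @export
setClass("PopulationRates", representation(
  rates = "numeric",
  mode = "character"
))

setValidity("PopulationRates", function(object) {
  msgs <- character()
  if (length(object@mode) != 1L ||
      !object@mode %in% c("cumulative", "person_year")) {
    msgs <- c(msgs, "mode must be 'cumulative' or 'person_year'")
  }
  if (is.null(names(object@rates)) || anyNA(names(object@rates)) ||
      !all(nzchar(names(object@rates)))) {
    msgs <- c(msgs, "rates must be a named vector of stratum values")
  }
  if (anyNA(object@rates) || any(object@rates < 0)) {
    msgs <- c(msgs, "rates must be non-negative")
  }
  if (identical(object@mode, "cumulative") && any(object@rates > 1)) {
    msgs <- c(msgs, "cumulative risks must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

# SegregationResult ------------------------------------------------------------

#' SegregationResult: chance-sharing probabilities for a (variant, family) pair
#'
#' Probabilities that all observed carrier cases in a family carry a variant
#' of population allele frequency `q` under the null gene-drop model
#' (Hardy-Weinberg founders, fair Mendelian transmission).
#'
#' * `pSingleIntroduction`: the headline decomposition
#'   `(1 - (1-q)^(2 c_apex)) * (1/2)^meioses` — the chance the apex
#'   introduction point carries the allele times the chance it is transmitted
#'   through every connecting meiosis.
#' * `pAnySharing`: the exact unconditional probability that every carrier
#'   carries at least one copy (all introduction routes, including
#'   independent marry-in introductions).
#' * `pConditional`: `pAnySharing / P(index carrier carries)`, conditioning
#'   on the variant having been observed in the index case (the
#'   lexicographically smallest carrier id unless specified); exactly 1 for a
#'   single carrier.
#' * `pAtLeastOne`: probability at least one of the carriers carries.
#'
#' @slot variantId,familyId identifiers.
#' @slot q population allele frequency used for the null model.
#' @slot meioses transmissions in the minimal connecting subgraph
#'   (`NA` when carriers are disconnected).
#' @slot pSingleIntroduction,pAnySharing,pConditional,pAtLeastOne,pIndexCarrier
#'   probabilities as described above.
#' @slot method `"closed_form"` or `"exact_peeling"`.
#' @slot index the index carrier the conditional probability refers to.
#' @slot terms for the closed form, the per-configuration term table
#'   (which introduction sources carry, the configuration weight, the
#'   conditional sharing probability, and their product); empty otherwise.
#' @export
setClass("SegregationResult", representation(
  variantId = "character",
  familyId = "character",
  q = "numeric",
  meioses = "integer",
  pSingleIntroduction = "numeric",
  pAnySharing = "numeric",
  pConditional = "numeric",
  pAtLeastOne = "numeric",
  pIndexCarrier = "numeric",
  method = "character",
  carriers = "character",
  index = "character",
  terms = "data.frame"
))

setValidity("SegregationResult", function(object) {
  msgs <- character()
  ps <- c(object@pSingleIntroduction, object@pAnySharing,
          object@pConditional, object@pAtLeastOne, object@pIndexCarrier)
  if (anyNA(ps) || any(ps < -1e-12) || any(ps > 1 + 1e-12)) {
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  }
  if (object@pSingleIntroduction > object@pAnySharing + 1e-12) {
    msgs <- c(msgs, "pSingleIntroduction must not exceed pAnySharing")
  }
  if (object@pConditional < object@pAnySharing - 1e-12) {
    msgs <- c(msgs, "pConditional must be at least pAnySharing")
  }
  if (!object@method %in% c("closed_form", "exact_peeling")) {
    msgs <- c(msgs, "method must be 'closed_form' or 'exact_peeling'")
  }
  if (length(msgs)) msgs else TRUE
})

# GeneDropEstimate -------------------------------------------------------------

#' GeneDropEstimate: Monte Carlo estimate from gene-dropping
#'
#' @slot nReps replicates simulated.
#' @slot nSuccess replicates where the event occurred.
#' @slot nDenominator denominator replicates (`nReps` for unconditional
#'   events; for `"all_given_one"` the number of replicates where the index
#'   carrier carried, taken from the same replicate stream).
#' @slot pHat `nSuccess / nDenominator`.
#' @slot ciLow,ciHigh 95% Wilson score interval.
#' @slot seed the derived stream seed actually used.
#' @slot event `"all_carry"`, `"at_least_one"` or `"all_given_one"`.
#' @export
setClass("GeneDropEstimate", representation(
  nReps = "numeric",
  nSuccess = "numeric",
  nDenominator = "numeric",
  pHat = "numeric",
  ciLow = "numeric",
  ciHigh = "numeric",
  seed = "integer",
  event = "character"
))

setValidity("GeneDropEstimate", function(object) {
  msgs <- character()
  if (object@nDenominator > 0 &&
      abs(object@pHat - object@nSuccess / object@nDenominator) > 1e-12) {
    msgs <- c(msgs, "pHat must equal nSuccess / nDenominator")
  }
  if (object@nDenominator > 0 &&
      (object@ciLow > object@pHat + 1e-12 ||
       object@ciHigh < object@pHat - 1e-12)) {
    msgs <- c(msgs, "Wilson interval must bracket pHat")
  }
  if (!object@event %in% c("all_carry", "at_least_one", "all_given_one")) {
    msgs <- c(msgs, "unknown event type")
  }
  if (length(msgs)) msgs else TRUE
})

# FilterReport -----------------------------------------------------------------

#' FilterReport: outcome of a variant prioritization stage
#'
#' Elimination is attributed to the first failing rule in the documented
#' rule order, so `inputCount == survivingCount + sum(eliminated)`.
#'
#' @slot inputCount,survivingCount record counts.
#' @slot eliminated named integer tally, one entry per rule (plus
#'   `"unannotated"` for records missing a required annotation).
#' @slot surviving the surviving records (data.frame).
#' @slot rules the rule order used for attribution.
#' @export
setClass("FilterReport", representation(
  inputCount = "integer",
  survivingCount = "integer",
  eliminated = "integer",
  surviving = "data.frame",
  rules = "character"
))

setValidity("FilterReport", function(object) {
  if (object@inputCount != object@survivingCount + sum(object@eliminated)) {
    "inputCount must equal survivingCount + sum(eliminated)"
  } else TRUE
})
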