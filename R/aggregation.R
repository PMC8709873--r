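# High-risk family ascertainment: observed vs expected affected counts,
# standardized incidence ratio, exact Poisson significance.

#' Construct a stratified population rate table
#'
#' @param rates named numeric vector: stratum key -> cumulative risk per
#'   person (`mode = "cumulative"`, the default: no person-years needed) or
#'   rate per person-year (`mode = "person_year"`).
#' @param mode `"cumulative"` or `"person_year"`.
#' @return a [PopulationRates].
#' @examples
#' populationRates(c(male = 0.02, female = 0.005))
#' @export
populationRates <- function(rates, mode = c("cumulative", "person_year")) {
  new("PopulationRates", rates = rates, mode = match.arg(mode))
}

#' Read a rates table from a 3-column TSV (stratum, mode, value)
#'
#' @param path TSV file with columns `stratum`, `mode`, `value`; all rows
#'   must share one mode.
#' @return a [PopulationRates].
#' @export
readRates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("stratum", "mode", "value")
  if (!all(need %in% names(tab))) {
    .famsegError(sprintf("rates TSV must have columns %s",
                         paste(need, collapse = ", ")), "famseg_parse_error")
  }
  modes <- unique(tab$mode)
  if (length(modes) != 1L) {
    .famsegError("rates TSV mixes modes", "famseg_parse_error")
  }
  populationRates(stats::setNames(as.numeric(tab$value), tab$stratum),
                  mode = modes)
}

#' Write a rates table as TSV
#'
#' @param rates a [PopulationRates].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRates <- function(rates, path) {
  utils::write.table(
    data.frame(stratum = names(rates@rates), mode = rates@mode,
               value = unname(rates@rates)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected number of affected members under population rates
#'
#' Sums, over members with known affection status, the member's stratum
#' cumulative risk (or rate times years at risk in person-year mode).
#' Members with unknown affection are excluded from both the observed and
#' the expected count, so they cannot bias the standardized incidence ratio.
#'
#' @param ped a [Pedigree]; every member with known affection status must
#'   carry a resolvable `stratum`.
#' @param rates a [PopulationRates].
#' @param yearsAtRisk named numeric vector (id -> years), required in
#'   person-year mode.
#' @return a positive expected count (dimensionless).
#' @export
expectedCount <- function(ped, rates, yearsAtRisk = NULL) {
  stopifnot(is(rates, "PopulationRates"))
  m <- ped@members
  eligible <- m$affected %in% c("affected", "unaffected")
  if (!any(eligible)) {
    .famsegError(sprintf("family '%s' has no members with known affection status",
                         ped@familyId), "famseg_degenerate_error")
  }
  strata <- m$stratum[eligible]
  bad <- m$id[eligible][is.na(strata) | !strata %in% names(rates@rates)]
  if (length(bad)) {
    .famsegError(sprintf("unresolvable stratum for member(s): %s",
                         paste(bad, collapse = ", ")),
                 "famseg_config_error", ids = bad)
  }
  r <- unname(rates@rates[strata])
  if (rates@mode == "person_year") {
    if (is.null(yearsAtRisk)) {
      .famsegError("person_year mode requires yearsAtRisk",
                   "famseg_config_error")
    }
    yr <- yearsAtRisk[m$id[eligible]]
    if (anyNA(yr)) {
      .famsegError(sprintf("missing years at risk for member(s): %s",
                           paste(m$id[eligible][is.na(yr)], collapse = ", ")),
                   "famseg_config_error")
    }
    r <- r * unname(yr)
  }
  sum(r)
}

#' Standardized incidence ratio with exact Poisson upper-tail test
#'
#' `sir = observed / expected`; the p-value is the exact one-sided Poisson
#' upper tail `P(X >= observed | mean = expected)`. With per-family expected
#' counts well below 1, normal approximations to the SIR are invalid; the
#' exact tail is also conservative under discreteness, so a nominal
#' threshold never anti-conservatively over-flags.
#'
#' @param observed non-negative integer count of affected members.
#' @param expected positive real expected count.
#' @return list with `observed`, `expected`, `sir`, `pValue`.
#' @examples
#' sirTest(3, 0.5) # p ~ 0.0144
#' @export
sirTest <- function(observed, expected) {
  if (!is.numeric(observed) || observed < 0 || observed != round(observed)) {
    .domainError("observed must be a non-negative integer")
  }
  if (!is.numeric(expected) || !is.finite(expected) || expected <= 0) {
    .domainError("expected must be a positive real")
  }
  p <- if (observed == 0) 1 else
    stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  list(observed = as.integer(observed), expected = expected,
       sir = observed / expected, pValue = p)
}

#' Screen a cohort of families for familial aggregation
#'
#' One row per family: observed and expected affected counts, SIR, exact
#' Poisson p-value, and the high-risk flag `pValue < alpha` (the nominal
#' familial significance threshold; no multiple-testing correction is
#' applied to the flag, but a Bonferroni-adjusted flag is reported as
#' supplementary output). Families whose expected count cannot be computed
#' are reported in the `"failures"` attribute rather than aborting the
#' screen.
#'
#' @param cohort list of [Pedigree] objects.
#' @param rates a [PopulationRates].
#' @param alpha nominal significance threshold (default 0.01).
#' @param yearsAtRisk optional named list (family id -> named vector) for
#'   person-year mode.
#' @return data.frame sorted by ascending p-value.
#' @export
screenFamilies <- function(cohort, rates, alpha = 0.01, yearsAtRisk = NULL) {
  if (!length(cohort)) .domainError("empty cohort")
  .checkProb(alpha, "alpha")
  rows <- list()
  failures <- list()
  for (ped in cohort) {
    fid <- familyId(ped)
    res <- tryCatch({
      m <- ped@members
      obs <- sum(m$affected == "affected")
      expd <- expectedCount(ped, rates,
                            yearsAtRisk = yearsAtRisk[[fid]])
      st <- sirTest(obs, expd)
      data.frame(familyId = fid, observed = st$observed,
                 expected = st$expected, sir = st$sir, pValue = st$pValue,
                 stringsAsFactors = FALSE)
    }, famseg_error = function(e) e)
    if (inherits(res, "error")) failures[[fid]] <- conditionMessage(res)
    else rows[[fid]] <- res
  }
  if (!length(rows)) {
    .famsegError("no family could be screened", "famseg_degenerate_error")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pValue, out$familyId), , drop = FALSE]
  out$highRisk <- out$pValue < alpha
  out$highRiskBonferroni <- out$pValue < alpha / nrow(out)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "failures") <- failures
  out
}

#' Write screen results as TSV and JSON
#'
#' @param results data.frame from [screenFamilies()].
#' @param stem output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return character vector of the two paths, invisibly.
#' @export
writeScreenResults <- function(results, stem) {
  tsv <- paste0(stem, ".tsv")
  js <- paste0(stem, ".json")
  utils::write.table(results, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(results, js, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(c(tsv, js))
}
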