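# Variant prioritization: the two filter stages and the frequency /
# case-control arithmetic on annotated variant tables.
#
# Records are rows of a data.frame with columns: id, chrom, pos, ref, alt,
# rsid, impact (HIGH / MODERATE (or MEDIUM) / LOW / MODIFIER), sift
# (deleterious / tolerated / NA), polyphen (probably_damaging /
# possibly_damaging / benign / NA), consequence (missense / synonymous /
# other), caseHet, caseHom, caseN, famCarriers (carrier count among the
# family's sequenced cases, for the family-shared stage), and one or more
# control panels encoded as paired columns `controlAc_<panel>` /
# `controlAn_<panel>`. Coordinates are 1-based as in VCF.

#' Minor allele frequency from carrier counts
#'
#' `(het + 2 hom) / (2 n)` for a diploid cohort of `n` individuals.
#' Comparisons in the filters always use full precision; 4-decimal rounding
#' (see [displayFrequency()]) is a display convention only.
#'
#' @param het,hom heterozygous and homozygous carrier counts.
#' @param nIndividuals cohort size in individuals.
#' @return allele frequency at full precision (vectorized).
#' @examples
#' alleleFrequency(28, 0, 4376)                    # 28/8752
#' displayFrequency(alleleFrequency(28, 0, 4376))  # 0.0032
#' @export
alleleFrequency <- function(het, hom, nIndividuals) {
  if (any(het < 0) || any(hom < 0)) .domainError("counts must be non-negative")
  if (any(nIndividuals <= 0)) .domainError("cohort size must be positive")
  if (any(het + hom > nIndividuals)) {
    .domainError("carriers cannot exceed cohort size")
  }
  (het + 2 * hom) / (2 * nIndividuals)
}

#' Display rounding for allele frequencies
#'
#' @param freq numeric frequencies.
#' @param digits decimal places (default 4).
#' @return rounded frequencies.
#' @export
displayFrequency <- function(freq, digits = 4) round(freq, digits)

.normImpact <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("MED", "MEDIUM")] <- "MODERATE"
  x
}

.controlPanels <- function(records) {
  acs <- grep("^controlAc_", names(records), value = TRUE)
  if (!length(acs)) return(character())
  panels <- sub("^controlAc_", "", acs)
  ans <- paste0("controlAn_", panels)
  miss <- panels[!ans %in% names(records)]
  if (length(miss)) {
    .domainError(sprintf("control panel(s) missing allele-number column: %s",
                         paste(miss, collapse = ", ")))
  }
  panels
}

.controlFreqMatrix <- function(records) {
  panels <- .controlPanels(records)
  out <- matrix(NA_real_, nrow(records), length(panels),
                dimnames = list(NULL, panels))
  for (p in panels) {
    ac <- records[[paste0("controlAc_", p)]]
    an <- records[[paste0("controlAn_", p)]]
    out[, p] <- ifelse(is.na(ac) | is.na(an) | an <= 0, NA_real_, ac / an)
  }
  out
}

# Evaluate ordered rules; each rule returns TRUE / FALSE / NA per record.
# Attribution is first-fail in rule order; NA on a needed annotation counts
# under "unannotated".
.runFilter <- function(records, rules) {
  n <- nrow(records)
  ruleNames <- names(rules)
  fate <- rep(NA_character_, n)
  if (n) {
    verdicts <- vapply(rules, function(f) f(records), logical(n))
    if (n == 1L) verdicts <- matrix(verdicts, 1L, dimnames = list(NULL, ruleNames))
    for (i in seq_len(n)) {
      for (r in ruleNames) {
        v <- verdicts[i, r]
        if (is.na(v)) { fate[i] <- "unannotated"; break }
        if (!v) { fate[i] <- r; break }
      }
    }
  }
  surv <- is.na(fate)
  elim <- table(factor(fate, levels = c(ruleNames, "unannotated")))
  new("FilterReport",
      inputCount = n,
      survivingCount = sum(surv),
      eliminated = stats::setNames(as.integer(elim), names(elim)),
      surviving = records[surv, , drop = FALSE],
      rules = c(ruleNames, "unannotated"))
}

#' Family-shared variant filter
#'
#' The discovery-stage filter for variants shared within one sequenced
#' high-risk family: the minor allele must be carried by all `sharedIn`
#' sequenced cases, the minor allele frequency must be below
#' `controlMafMax` in every control panel (conjunctive: rare in local
#' controls AND every public panel), and the impact severity annotation
#' must be in `impacts` (MEDIUM and MODERATE are the same tier; both
#' spellings are accepted).
#'
#' @param records annotated variant data.frame (see file header).
#' @param sharedIn required carrier count among the family's sequenced
#'   cases (default 6).
#' @param controlMafMax control MAF threshold (default 0.01, strict `<`).
#' @param impacts retained impact tiers.
#' @return a [FilterReport]; elimination attribution order is
#'   shared -> control_frequency -> impact.
#' @export
familySharedFilter <- function(records, sharedIn = 6, controlMafMax = 0.01,
                               impacts = c("HIGH", "MODERATE")) {
  impacts <- .normImpact(impacts)
  cf <- .controlFreqMatrix(records)
  rules <- list(
    shared = function(r) {
      v <- r$famCarriers
      ifelse(is.na(v), NA, v == sharedIn)
    },
    control_frequency = function(r) {
      if (!ncol(cf)) return(rep(NA, nrow(r)))
      apply(cf, 1L, function(x) if (anyNA(x)) NA else all(x < controlMafMax))
    },
    impact = function(r) {
      v <- .normImpact(r$impact)
      ifelse(is.na(r$impact), NA, v %in% impacts)
    }
  )
  .runFilter(records, rules)
}

#' Cohort-wide functional variant filter
#'
#' The genotyping-stage filter for functional variants across the full case
#' cohort: non-synonymous (missense) consequence; both SIFT and PolyPhen
#' indicating likely functional effect (SIFT deleterious, PolyPhen probably
#' or possibly damaging); at least `minCarriers` carrier cases (a
#' homozygote counts once); case allele frequency at least `minCaseFreq`;
#' and allele frequency below `maxControlFreq` in every control panel.
#' Carrier-count and case-frequency rules are enforced independently (they
#' coincide at the default thresholds for a cohort of ~4000 cases).
#'
#' @param records annotated variant data.frame.
#' @param minCaseFreq minimum case allele frequency (default 0.001, `>=`).
#' @param maxControlFreq control frequency bound (default 0.01, strict `<`).
#' @param minCarriers minimum carrier cases (default 5, `>=`).
#' @return a [FilterReport]; attribution order is consequence ->
#'   annotations -> carriers -> case_frequency -> control_frequency.
#' @export
cohortFunctionalFilter <- function(records, minCaseFreq = 0.001,
                                   maxControlFreq = 0.01, minCarriers = 5) {
  cf <- .controlFreqMatrix(records)
  rules <- list(
    consequence = function(r) {
      ifelse(is.na(r$consequence), NA, r$consequence == "missense")
    },
    annotations = function(r) {
      s <- r$sift == "deleterious"
      pp <- r$polyphen %in% c("probably_damaging", "possibly_damaging")
      # a missing annotation is "unannotated", never a plain fail
      ifelse(is.na(r$sift) | is.na(r$polyphen), NA, s & pp)
    },
    carriers = function(r) {
      v <- r$caseHet + r$caseHom
      ifelse(is.na(v), NA, v >= minCarriers)
    },
    case_frequency = function(r) {
      ok <- !is.na(r$caseHet) & !is.na(r$caseHom) & !is.na(r$caseN)
      f <- rep(NA_real_, nrow(r))
      f[ok] <- alleleFrequency(r$caseHet[ok], r$caseHom[ok], r$caseN[ok])
      ifelse(is.na(f), NA, f >= minCaseFreq)
    },
    control_frequency = function(r) {
      if (!ncol(cf)) return(rep(NA, nrow(r)))
      apply(cf, 1L, function(x) if (anyNA(x)) NA else all(x < maxControlFreq))
    }
  )
  .runFilter(records, rules)
}

#' Case-control allele-count comparison
#'
#' Fisher's exact test on the 2x2 allele-count table (two-sided), with the
#' sample odds ratio; the Haldane-Anscombe 0.5 correction is applied to the
#' odds ratio when any cell is zero.
#'
#' @param caseAc,caseAn case allele count and allele number.
#' @param controlAc,controlAn control allele count and allele number.
#' @return list with `pValue`, `oddsRatio` and the 2x2 `table`.
#' @examples
#' caseControlTest(28, 8752, 29, 8758) # not significantly elevated
#' @export
caseControlTest <- function(caseAc, caseAn, controlAc, controlAn) {
  counts <- c(caseAc, caseAn, controlAc, controlAn)
  if (any(counts < 0) || caseAc > caseAn || controlAc > controlAn ||
      caseAn == 0 || controlAn == 0) {
    .domainError("inconsistent allele counts")
  }
  tab <- matrix(c(caseAc, caseAn - caseAc, controlAc, controlAn - controlAc),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("alt", "ref")))
  ft <- stats::fisher.test(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(pValue = unname(ft$p.value), oddsRatio = (a / b) / (c / d), table = tab)
}

# FilterReport accessors and I/O ----------------------------------------------

#' @rdname FilterReport-class
#' @export
setMethod("surviving", "FilterReport", function(x) x@surviving)

#' @rdname FilterReport-class
#' @export
setMethod("eliminated", "FilterReport", function(x) x@eliminated)

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d in, %d surviving\n",
              object@inputCount, object@survivingCount))
  el <- object@eliminated[object@eliminated > 0]
  for (r in names(el)) cat(sprintf("  eliminated by %s: %d\n", r, el[[r]]))
  invisible(object)
})

#' Read an annotated variant table from TSV
#'
#' @param path TSV with the columns described in [cohortFunctionalFilter()].
#' @return data.frame of records.
#' @export
readVariantTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
}

#' Write a filter report as TSV (surviving records) and JSON (tallies)
#'
#' @param report a [FilterReport].
#' @param stem output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return character vector of the two paths, invisibly.
#' @export
writeFilterReport <- function(report, stem) {
  tsv <- paste0(stem, ".tsv")
  js <- paste0(stem, ".json")
  utils::write.table(report@surviving, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(inputCount = report@inputCount,
         survivingCount = report@survivingCount,
         eliminated = as.list(report@eliminated),
         survivingIds = report@surviving$id),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
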