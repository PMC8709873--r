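# Closed-form segregation probabilities on the connecting subgraph.
#
# The chance that all observed carrier cases share a rare variant is
# decomposed by where the allele enters the family: a single introduction at
# the apex ancestral couple, transmitted through every connecting meiosis
# (the headline term, (1 - (1-q)^(2 c_apex)) * (1/2)^M), plus configurations
# in which one or more marry-in spouses independently introduce the
# population allele. The per-configuration terms are evaluated exactly on
# the transmission tree (apex couple and marry-in spouses Hardy-Weinberg at
# frequency q, fair Mendelian transmission), so their sum equals the exact
# peeling probability whenever the pedigree is loop-free and spouses are
# unrelated to the lineage.

#' Probability a marry-in founder introduces the allele
#'
#' The Hardy-Weinberg probability that a diploid individual drawn from a
#' population with allele frequency `q` carries at least one copy:
#' `1 - (1 - q)^2`.
#'
#' @param q allele frequency in \[0, 1\].
#' @return a probability.
#' @examples
#' introductionProbability(0.0032) # 0.00638976
#' @export
introductionProbability <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    .domainError("q must lie in [0, 1]")
  }
  1 - (1 - q)^2
}

.genotypePrior <- function(q, state = c("free", "carrier", "non")) {
  state <- match.arg(state)
  p <- 1 - q
  hw <- c(p^2, 2 * p * q, q^2)
  switch(state,
    free = hw,
    carrier = c(0, hw[2], hw[3]) / (1 - p^2),
    non = c(1, 0, 0))
}

.couplePrior <- function(q, state = c("free", "carrier", "non")) {
  state <- match.arg(state)
  hw <- .genotypePrior(q, "free")
  J <- outer(hw, hw)
  p <- 1 - q
  switch(state,
    free = J,
    carrier = { J[1, 1] <- 0; J / (1 - p^4) },
    non = { Z <- matrix(0, 3, 3); Z[1, 1] <- 1; Z })
}

# Exact evaluation of P(constraints hold) on the transmission tree.
# constraint: named character id -> "carry" | "zero"; unnamed ids are free.
# apexState: conditioning of the apex source; spouseStates: named vector of
# conditioning for each co-parent id.
.treeProbability <- function(sub, q, constraint,
                             apexState = "free",
                             spouseStates = character()) {
  tt <- .transTable()
  edges <- sub@edges
  treeKids <- split(edges[, "child"], edges[, "parent"])
  spouses <- sub@spouses
  apex <- sub@apex
  root <- if (length(apex) == 2L) {
    intersect(apex, edges[, "parent"])[1]
  } else apex
  partner <- if (length(apex) == 2L) setdiff(apex, root) else NA_character_

  allowed <- function(id) {
    cs <- constraint[id]
    if (is.na(cs)) 0:2 else if (cs == "carry") 1:2 else 0L
  }
  spousePrior <- function(s) {
    st <- spouseStates[s]
    .genotypePrior(q, if (is.na(st)) "free" else st)
  }
  rec <- function(id, g) {
    kids <- treeKids[[id]]
    if (is.null(kids)) return(1)
    out <- 1
    for (grp in split(kids, spouses[kids])) {
      s <- spouses[grp[1]]
      pr <- spousePrior(s)
      acc <- 0
      for (gs in 0:2) {
        if (pr[gs + 1] == 0) next
        prod <- 1
        for (ch in grp) prod <- prod * childSum(ch, g, gs)
        acc <- acc + pr[gs + 1] * prod
      }
      out <- out * acc
    }
    out
  }
  childSum <- function(ch, gp, gs) {
    acc <- 0
    for (gc in allowed(ch)) {
      w <- tt[gc + 1, gp + 1, gs + 1]
      if (w > 0) acc <- acc + w * rec(ch, gc)
    }
    acc
  }

  if (length(apex) == 2L) {
    J <- .couplePrior(q, apexState)
    kids <- treeKids[[root]]
    acc <- 0
    for (ga in 0:2) for (gb in 0:2) {
      w <- J[ga + 1, gb + 1]
      if (w == 0) next
      prod <- 1
      for (ch in kids) prod <- prod * childSum(ch, ga, gb)
      acc <- acc + w * prod
    }
    acc
  } else {
    pr <- .genotypePrior(q, apexState)
    acc <- 0
    for (ga in allowed(root)) {
      if (pr[ga + 1] == 0) next
      acc <- acc + pr[ga + 1] * rec(root, ga)
    }
    acc
  }
}

#' Closed-form sharing probability on the minimal connecting subgraph
#'
#' Computes the nominal probability that all carriers share the variant by
#' chance, decomposed over introduction configurations: the apex couple (one
#' introduction point, either spouse may carry) and every marry-in co-parent
#' along the transmission tree are independent potential sources at
#' Hardy-Weinberg frequency `q`. The headline single-introduction term uses
#' the verbal decomposition `(1 - (1-q)^(2 c_apex)) * (1/2)^meioses`; the
#' full `pAnySharing` sums the exact per-configuration terms (reported in
#' the `terms` slot), which matches [exactPeeling()] on loop-free pedigrees
#' whose marry-in spouses are unrelated to the lineage.
#'
#' @inheritParams exactPeeling
#' @param sub optionally, a precomputed [ConnectingSubgraph] for the same
#'   carriers.
#' @return a [SegregationResult] with `method = "closed_form"` and a
#'   populated per-configuration term table.
#' @examples
#' ped <- sibPairPedigree()
#' closedFormSharing(ped, c("sib1", "sib2"), q = 0.001)
#' @export
closedFormSharing <- function(ped, carrierIds, q, variantId = "variant",
                              index = NULL, sub = NULL) {
  carrierIds <- unique(as.character(carrierIds))
  if (!length(carrierIds)) .domainError("need at least one carrier")
  .checkProb(q, "q")
  if (q <= 0 || q >= 1) .domainError("q must lie strictly in (0, 1)")
  .checkMember(ped, carrierIds)
  if (is.null(sub)) sub <- connectingSubgraph(ped, carrierIds)
  if (is.null(index)) index <- sort(carrierIds)[1]
  stopifnot(index %in% carrierIds)

  cApex <- length(sub@apex)
  M <- sub@meioses
  p <- 1 - q
  pSingle <- (1 - p^(2 * cApex)) * 0.5^M

  carryAll <- stats::setNames(rep("carry", length(carrierIds)), carrierIds)
  zeroAll <- stats::setNames(rep("zero", length(carrierIds)), carrierIds)

  sources <- sort(unique(unname(sub@spouses[!sub@spouses %in% sub@apex])))
  nSrc <- length(sources)
  pApexCarry <- 1 - p^(2 * cApex)
  pSpouseCarry <- 1 - p^2
  evalConfig <- function(apexCarry, spCarry) {
    states <- stats::setNames(ifelse(spCarry, "carrier", "non"), sources)
    w <- (if (apexCarry) pApexCarry else 1 - pApexCarry) *
      prod(ifelse(spCarry, pSpouseCarry, 1 - pSpouseCarry))
    pr <- if (w == 0) 0 else {
      .treeProbability(sub, q, carryAll,
                       apexState = if (apexCarry) "carrier" else "non",
                       spouseStates = states)
    }
    lab <- c(if (apexCarry) "apex", sources[spCarry])
    data.frame(
      configuration = if (length(lab)) paste(lab, collapse = "+") else "none",
      weight = w, sharingProb = pr, term = w * pr, stringsAsFactors = FALSE)
  }
  pAllDirect <- .treeProbability(sub, q, carryAll)
  if (nSrc + 1L <= 12L) {
    # full enumeration over introduction configurations; sums to the exact
    # sharing probability by the law of total probability
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), nSrc + 1L))
    terms <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      evalConfig(combos[i, 1], as.logical(combos[i, -1, drop = FALSE]))
    }))
    pAll <- sum(terms$term)
    stopifnot(abs(pAll - pAllDirect) <= 1e-9 * pAllDirect + 1e-15)
  } else {
    # very deep subgraphs: list the single-source configurations and fold
    # multi-introduction configurations into one remainder term
    none <- rep(FALSE, nSrc)
    terms <- do.call(rbind, c(list(evalConfig(TRUE, none)),
                              lapply(seq_len(nSrc), function(j) {
                                sp <- none; sp[j] <- TRUE
                                evalConfig(FALSE, sp)
                              })))
    rest <- pAllDirect - sum(terms$term)
    terms <- rbind(terms, data.frame(
      configuration = "multiple introductions (folded)",
      weight = NA_real_, sharingProb = NA_real_, term = rest,
      stringsAsFactors = FALSE))
    pAll <- pAllDirect
  }

  pIndex <- .treeProbability(sub, q, stats::setNames("carry", index))
  pAtLeastOne <- 1 - .treeProbability(sub, q, zeroAll)

  new("SegregationResult",
      variantId = variantId, familyId = ped@familyId, q = q,
      meioses = M,
      pSingleIntroduction = min(pSingle, pAll),
      pAnySharing = pAll,
      pConditional = if (length(carrierIds) == 1L) 1 else pAll / pIndex,
      pAtLeastOne = pAtLeastOne,
      pIndexCarrier = pIndex,
      method = "closed_form",
      carriers = sort(carrierIds),
      index = index,
      terms = terms[order(-terms$term), ])
}

setMethod("show", "SegregationResult", function(object) {
  cat(sprintf("SegregationResult [%s] variant '%s', family '%s'\n",
              object@method, object@variantId, object@familyId))
  cat(sprintf("  q = %g, carriers = %d, meioses = %s\n", object@q,
              length(object@carriers),
              ifelse(is.na(object@meioses), "NA", object@meioses)))
  cat(sprintf("  p(single introduction) = %.4g\n", object@pSingleIntroduction))
  cat(sprintf("  p(all share)           = %.4g\n", object@pAnySharing))
  cat(sprintf("  p(all share | index '%s' carries) = %.4g\n",
              object@index, object@pConditional))
  invisible(object)
})

#' @rdname SegregationResult-class
#' @param x a [SegregationResult].
#' @export
setMethod("meioses", "SegregationResult", function(x) x@meioses)

#' @rdname SegregationResult-class
#' @export
setMethod("carriers", "SegregationResult", function(x) x@carriers)

#' Convert a SegregationResult to a one-row data.frame
#'
#' @param res a [SegregationResult].
#' @return data.frame with the identifying fields and probabilities.
#' @export
segregationAsData <- function(res) {
  data.frame(
    variantId = res@variantId, familyId = res@familyId, q = res@q,
    meioses = res@meioses, method = res@method,
    pSingleIntroduction = res@pSingleIntroduction,
    pAnySharing = res@pAnySharing,
    pConditional = res@pConditional,
    pAtLeastOne = res@pAtLeastOne,
    stringsAsFactors = FALSE
  )
}
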