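# Monte Carlo gene-dropping: the brute-force oracle for segregation
# probabilities and the engine for null genotype generation.
#
# Per replicate each founder receives two alleles i.i.d. Bernoulli(q) and
# each non-founder one uniformly chosen allele from each parent. Single
# biallelic variant, no linkage or mutation. The RNG stream is keyed per
# (family, variant, seed) so cohort simulations are order-independent and
# bit-exact reproducible.

.dropAlleleChunk <- function(idx, q, nChunk, founderOverride = list()) {
  n <- length(idx$ids)
  a1 <- vector("list", n)
  a2 <- vector("list", n)
  for (i in idx$order) {
    f <- idx$father[i]
    if (is.na(f)) {
      ov <- founderOverride[[idx$ids[i]]]
      if (is.null(ov)) {
        a1[[i]] <- stats::rbinom(nChunk, 1L, q)
        a2[[i]] <- stats::rbinom(nChunk, 1L, q)
      } else {
        a1[[i]] <- rep(as.integer(ov[1]), nChunk)
        a2[[i]] <- if (is.na(ov[2])) stats::rbinom(nChunk, 1L, q)
                   else rep(as.integer(ov[2]), nChunk)
      }
    } else {
      m <- idx$mother[i]
      pickF <- stats::rbinom(nChunk, 1L, 0.5)
      pickM <- stats::rbinom(nChunk, 1L, 0.5)
      a1[[i]] <- a1[[f]] * pickF + a2[[f]] * (1L - pickF)
      a2[[i]] <- a1[[m]] * pickM + a2[[m]] * (1L - pickM)
    }
  }
  list(a1 = a1, a2 = a2)
}

.dropIndex <- function(ped) {
  idx <- .pedIndex(ped)
  idx$order <- match(topoOrder(ped), idx$ids)
  idx
}

#' Gene-dropping Monte Carlo estimate of a sharing probability
#'
#' @param ped a [Pedigree].
#' @param carrierIds ids of the carriers defining the event.
#' @param q population allele frequency in \[0, 1\].
#' @param nReps number of replicates (>= 1).
#' @param seed base seed; the actual stream is keyed by
#'   `streamSeed(seed, familyId, variantId)`.
#' @param event `"all_carry"` (every carrier has >= 1 copy),
#'   `"at_least_one"`, or `"all_given_one"` (all carry, conditioned on the
#'   index carrier carrying; numerator and denominator are counted on the
#'   same replicate stream).
#' @param variantId label contributing to the RNG stream key.
#' @param index index carrier for `"all_given_one"`; defaults to the
#'   lexicographically smallest carrier id.
#' @param chunkSize replicates simulated per vectorized block.
#' @return a [GeneDropEstimate].
#' @examples
#' est <- geneDrop(sibPairPedigree(), c("sib1", "sib2"), q = 0.01,
#'                 nReps = 1e4, seed = 1)
#' est
#' @export
geneDrop <- function(ped, carrierIds, q, nReps, seed,
                     event = c("all_carry", "at_least_one", "all_given_one"),
                     variantId = "variant", index = NULL, chunkSize = 1e6) {
  event <- match.arg(event)
  carrierIds <- unique(as.character(carrierIds))
  if (!length(carrierIds)) .domainError("empty carrier set")
  .checkMember(ped, carrierIds)
  .checkProb(q, "q")
  stopifnot(nReps >= 1)
  if (is.null(index)) index <- sort(carrierIds)[1]
  stopifnot(index %in% carrierIds)

  idx <- .dropIndex(ped)
  ci <- match(carrierIds, idx$ids)
  ii <- match(index, idx$ids)
  usedSeed <- streamSeed(seed, ped@familyId, variantId)
  set.seed(usedSeed, kind = "Mersenne-Twister")

  nAll <- 0; nAny <- 0; nIndex <- 0
  left <- nReps
  while (left > 0) {
    nChunk <- min(left, chunkSize)
    al <- .dropAlleleChunk(idx, q, nChunk)
    carry <- lapply(ci, function(i) (al$a1[[i]] + al$a2[[i]]) > 0L)
    nAll <- nAll + sum(Reduce(`&`, carry))
    nAny <- nAny + sum(Reduce(`|`, carry))
    nIndex <- nIndex + sum((al$a1[[ii]] + al$a2[[ii]]) > 0L)
    left <- left - nChunk
  }

  succ <- switch(event, all_carry = nAll, at_least_one = nAny,
                 all_given_one = nAll)
  den <- switch(event, all_carry = nReps, at_least_one = nReps,
                all_given_one = nIndex)
  pHat <- if (den > 0) succ / den else NaN
  ci95 <- if (den > 0) wilsonInterval(succ, den) else c(NaN, NaN)
  new("GeneDropEstimate",
      nReps = as.numeric(nReps), nSuccess = as.numeric(succ),
      nDenominator = as.numeric(den), pHat = pHat,
      ciLow = unname(ci95[1]), ciHigh = unname(ci95[2]),
      seed = usedSeed, event = event)
}

setMethod("show", "GeneDropEstimate", function(object) {
  cat(sprintf(
    "GeneDropEstimate [%s]: p = %.4g (95%% CI %.4g-%.4g), %s/%s reps\n",
    object@event, object@pHat, object@ciLow, object@ciHigh,
    format(object@nSuccess, big.mark = ","),
    format(object@nDenominator, big.mark = ",")))
  invisible(object)
})

#' One full gene-drop genotype realization
#'
#' Drops a single biallelic variant through the pedigree: founders receive
#' two i.i.d. Bernoulli(q) alleles (unless overridden), children one random
#' allele from each parent, so Mendelian consistency holds by construction.
#'
#' @param ped a [Pedigree].
#' @param q allele frequency in \[0, 1\].
#' @param seed base seed (stream keyed by family id).
#' @param founderOverride named list id -> integer allele pair, e.g.
#'   `list(f1 = c(1L, 0L))` forces founder f1 heterozygous; an `NA` second
#'   allele is drawn Bernoulli(q).
#' @return named integer vector of copy numbers (0/1/2), in pedigree order.
#' @export
dropGenotypes <- function(ped, q, seed, founderOverride = list()) {
  .checkProb(q, "q")
  idx <- .dropIndex(ped)
  .setStream(seed, ped@familyId, "genedrop")
  al <- .dropAlleleChunk(idx, q, 1L, founderOverride)
  g <- vapply(seq_along(idx$ids), function(i) al$a1[[i]] + al$a2[[i]],
              integer(1))
  stats::setNames(as.integer(g), idx$ids)
}
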