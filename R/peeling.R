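# Exact genotype-configuration probabilities by pedigree peeling.
#
# The null model: each founder's genotype is Hardy-Weinberg(q); each
# non-founder receives one uniformly chosen allele from each parent. The
# probability of a carrier configuration is obtained by variable elimination
# over per-individual genotype variables (0/1/2 copies), which is the
# general-pedigree form of Elston-Stewart peeling and is exact, including
# through inbreeding loops.

.EXACT_PEELING_BOUND <- 25L

.transTable <- function() {
  # T[gc, gf, gm] = P(child genotype | father, mother genotypes)
  tt <- array(0, c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) {
    pf <- gf / 2 # probability the paternal gamete carries the allele
    pm <- gm / 2
    tt[1, gf + 1, gm + 1] <- (1 - pf) * (1 - pm)
    tt[2, gf + 1, gm + 1] <- pf * (1 - pm) + (1 - pf) * pm
    tt[3, gf + 1, gm + 1] <- pf * pm
  }
  tt
}

.digits3 <- function(k) {
  N <- 3L^k
  d <- matrix(0L, k, N)
  idx <- 0:(N - 1)
  for (i in seq_len(k)) {
    d[i, ] <- idx %% 3L
    idx <- idx %/% 3L
  }
  d
}

.factorLinearIndex <- function(vars, jointVars, dig) {
  pos <- match(vars, jointVars)
  1L + as.integer(colSums(dig[pos, , drop = FALSE] *
                            3L^(seq_along(pos) - 1L)))
}

# Eliminate (sum out) variable v from the factor list.
.eliminateVar <- function(factors, v) {
  has <- vapply(factors, function(f) v %in% f$vars, logical(1))
  fs <- factors[has]
  jointVars <- sort(unique(unlist(lapply(fs, `[[`, "vars"))))
  K <- length(jointVars)
  dig <- .digits3(K)
  val <- rep(1, 3L^K)
  for (f in fs) val <- val * f$tab[.factorLinearIndex(f$vars, jointVars, dig)]
  remaining <- setdiff(jointVars, v)
  if (!length(remaining)) {
    newf <- list(vars = integer(), tab = sum(val))
  } else {
    lin <- .factorLinearIndex(remaining, jointVars, dig)
    tab <- rep(0, 3L^length(remaining))
    agg <- rowsum(val, lin)
    tab[as.integer(rownames(agg))] <- agg[, 1]
    newf <- list(vars = remaining, tab = tab)
  }
  c(factors[!has], list(newf))
}

# P(genotype constraints hold) on a pedigree under the null gene-drop model.
# constraints: named character vector id -> "carry" (>= 1 copy) or "zero".
.peelProbability <- function(ped, q, constraints) {
  idx <- .pedIndex(ped)
  n <- length(idx$ids)
  p <- 1 - q
  hw <- c(p^2, 2 * p * q, q^2)
  tt <- .transTable()
  factors <- list()
  for (i in seq_len(n)) {
    if (is.na(idx$father[i])) {
      factors[[length(factors) + 1L]] <- list(vars = i, tab = hw)
    } else {
      vars <- c(i, idx$father[i], idx$mother[i])
      factors[[length(factors) + 1L]] <- list(vars = vars, tab = as.vector(tt))
    }
  }
  for (id in names(constraints)) {
    i <- match(id, idx$ids)
    tab <- if (constraints[[id]] == "carry") c(0, 1, 1) else c(1, 0, 0)
    factors[[length(factors) + 1L]] <- list(vars = i, tab = tab)
  }
  alive <- seq_len(n)
  while (length(alive)) {
    # greedy min-clique elimination order (pedigrees have small treewidth)
    cliqueSize <- vapply(alive, function(v) {
      vs <- unlist(lapply(factors, function(f) if (v %in% f$vars) f$vars))
      length(unique(vs))
    }, numeric(1))
    v <- alive[which.min(cliqueSize)]
    factors <- .eliminateVar(factors, v)
    alive <- setdiff(alive, v)
  }
  prod(vapply(factors, `[[`, numeric(1), "tab"))
}

#' Exact chance-sharing probabilities by pedigree peeling
#'
#' Computes, exactly, the probability under the null gene-drop model
#' (Hardy-Weinberg founders at allele frequency `q`, fair Mendelian
#' transmission) that every listed carrier has at least one copy of the
#' allele, together with the probability conditioned on the index carrier
#' and the probability that at least one carrier carries. The pedigree is
#' first pruned to the ancestral closure of the carriers; the exactness
#' bound of `r .EXACT_PEELING_BOUND` pruned individuals keeps the
#' elimination dense tables small — above it, use [geneDrop()].
#'
#' @param ped a [Pedigree].
#' @param carrierIds ids of the observed carriers.
#' @param q population allele frequency, in (0, 1).
#' @param variantId identifier stored in the result.
#' @param index id of the index carrier the conditional probability refers
#'   to; defaults to the lexicographically smallest carrier id.
#' @return a [SegregationResult] with `method = "exact_peeling"`.
#' @examples
#' ped <- sibPairPedigree()
#' exactPeeling(ped, c("sib1", "sib2"), q = 0.001)
#' @export
exactPeeling <- function(ped, carrierIds, q, variantId = "variant",
                         index = NULL) {
  carrierIds <- unique(as.character(carrierIds))
  if (!length(carrierIds)) .domainError("need at least one carrier")
  .checkProb(q, "q")
  if (q <= 0 || q >= 1) .domainError("q must lie strictly in (0, 1)")
  .checkMember(ped, carrierIds)
  if (is.null(index)) index <- sort(carrierIds)[1]
  stopifnot(index %in% carrierIds)

  closure <- ancestorClosure(ped, carrierIds)
  if (length(closure) > .EXACT_PEELING_BOUND) {
    .famsegError(sprintf(
      "pruned pedigree has %d members, above the exactness bound of %d: use genedrop",
      length(closure), .EXACT_PEELING_BOUND), "famseg_use_genedrop",
      bound = .EXACT_PEELING_BOUND, size = length(closure))
  }
  sub <- subPedigree(ped, closure)

  pAll <- .peelProbability(sub, q, stats::setNames(rep("carry", length(carrierIds)),
                                                   carrierIds))
  pNone <- .peelProbability(sub, q, stats::setNames(rep("zero", length(carrierIds)),
                                                    carrierIds))
  pIndex <- 1 - .peelProbability(sub, q, stats::setNames("zero", index))
  pAtLeastOne <- 1 - pNone

  meio <- tryCatch(meioses(connectingSubgraph(ped, carrierIds)),
                   famseg_disconnected_error = function(e) NA_integer_)

  new("SegregationResult",
      variantId = variantId, familyId = ped@familyId, q = q,
      meioses = meio,
      pSingleIntroduction = min(pAll, .singleIntroductionFormula(ped, carrierIds, q)),
      pAnySharing = pAll,
      pConditional = if (length(carrierIds) == 1L) 1 else pAll / pIndex,
      pAtLeastOne = pAtLeastOne,
      pIndexCarrier = pIndex,
      method = "exact_peeling",
      carriers = sort(carrierIds),
      index = index,
      terms = data.frame())
}

# The verbal closed-form decomposition for the single-introduction term;
# shared by exactPeeling (for reporting) and closedFormSharing.
.singleIntroductionFormula <- function(ped, carrierIds, q) {
  sub <- tryCatch(connectingSubgraph(ped, carrierIds),
                  famseg_disconnected_error = function(e) NULL)
  if (is.null(sub)) return(0)
  cApex <- length(sub@apex)
  (1 - (1 - q)^(2 * cApex)) * 0.5^sub@meioses
}
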