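# Recursive kinship coefficients.

#' Kinship coefficient between two pedigree members
#'
#' The standard recursive kinship coefficient phi(a, b): the probability that
#' one allele sampled at random from `a` and one from `b` are identical by
#' descent. Founders are assumed non-inbred and mutually unrelated, so
#' phi(f, f) = 1/2 for a founder f; phi(a, a) = 1/2 + phi(father, mother)/2
#' otherwise; and for a != b, phi(a, b) = (phi(father_a, b) +
#' phi(mother_a, b))/2, recursing on the member of greater generation depth
#' so the recursion always terminates.
#'
#' @param ped a [Pedigree].
#' @param a,b member ids.
#' @return a probability in [0, 1].
#' @examples
#' ped <- trioPedigree()
#' kinshipCoeff(ped, "dad", "kid") # parent-offspring: 0.25
#' @export
kinshipCoeff <- function(ped, a, b) {
  .checkMember(ped, c(a, b))
  idx <- .pedIndex(ped)
  depth <- unname(generationDepth(ped))
  memo <- new.env(parent = emptyenv())
  fa <- idx$father; mo <- idx$mother
  phi <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      if (is.na(fa[i])) 0.5
      else 0.5 + 0.5 * phi(fa[i], mo[i])
    } else {
      # recurse on the deeper individual; it cannot be an ancestor of the other
      deep <- if (depth[i] >= depth[j]) i else j
      other <- if (deep == i) j else i
      if (is.na(fa[deep])) 0
      else 0.5 * (phi(fa[deep], other) + phi(mo[deep], other))
    }
    memo[[key]] <- val
    val
  }
  phi(match(a, idx$ids), match(b, idx$ids))
}

#' Kinship matrix for a set of members
#'
#' @param ped a [Pedigree].
#' @param ids member ids (defaults to all members).
#' @return symmetric numeric matrix of kinship coefficients.
#' @export
kinshipMatrix <- function(ped, ids = members(ped)$id) {
  .checkMember(ped, ids)
  n <- length(ids)
  k <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    k[i, j] <- k[j, i] <- kinshipCoeff(ped, ids[i], ids[j])
  }
  k
}
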