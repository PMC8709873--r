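# Small deterministic pedigree builders, shared by examples and tests.

.fixtureMembers <- function(...) {
  do.call(rbind, lapply(list(...), function(r) {
    data.frame(id = r[[1]], fatherId = r[[2]], motherId = r[[3]],
               sex = r[[4]], affected = r[[5]], stringsAsFactors = FALSE)
  }))
}

#' Canonical trio pedigree (father, mother, affected child)
#' @return a [Pedigree].
#' @export
trioPedigree <- function() {
  newPedigree("trio", .fixtureMembers(
    list("dad", NA, NA, "male", "unaffected"),
    list("mom", NA, NA, "female", "unaffected"),
    list("kid", "dad", "mom", "female", "affected")))
}

#' Full-sibling pair pedigree
#' @return a [Pedigree] with members `dad`, `mom`, `sib1`, `sib2`.
#' @export
sibPairPedigree <- function() {
  newPedigree("sibs", .fixtureMembers(
    list("dad", NA, NA, "male", "unaffected"),
    list("mom", NA, NA, "female", "unaffected"),
    list("sib1", "dad", "mom", "male", "affected"),
    list("sib2", "dad", "mom", "female", "affected")))
}

#' Two-branch descent pedigree below an apex founder couple
#'
#' The apex couple has two children; each branch is a descent line with a
#' marry-in spouse at every generation. The leaves of the two branches
#' (`leaf1`, `leaf2`) are `d1 + d2` meioses apart: `branchPedigree(1, 1)`
#' gives full siblings, `branchPedigree(2, 2)` first cousins,
#' `branchPedigree(1, 2)` an avuncular pair.
#'
#' @param d1,d2 depth (meioses) of each branch below the apex couple.
#' @return a [Pedigree]; the two leaves are named `leaf1` and `leaf2`.
#' @export
branchPedigree <- function(d1, d2) {
  stopifnot(d1 >= 1, d2 >= 1)
  rows <- list(list("apexF", NA, NA, "male", "unknown"),
               list("apexM", NA, NA, "female", "unknown"))
  mkBranch <- function(b, d) {
    fa <- "apexF"; mo <- "apexM"
    for (k in seq_len(d)) {
      id <- if (k == d) paste0("leaf", b) else sprintf("b%d_%d", b, k)
      rows[[length(rows) + 1L]] <<- list(id, fa, mo, "male",
                                         if (k == d) "affected" else "unaffected")
      if (k < d) {
        sp <- sprintf("b%d_%dsp", b, k)
        rows[[length(rows) + 1L]] <<- list(sp, NA, NA, "female", "unaffected")
        fa <- id; mo <- sp
      }
    }
  }
  mkBranch(1, d1)
  mkBranch(2, d2)
  newPedigree(sprintf("branch_%d_%d", d1, d2), do.call(.fixtureMembers, rows))
}

#' First-cousin pair pedigree (8 members)
#' @return a [Pedigree]; the cousins are `leaf1` and `leaf2`.
#' @export
cousinPairPedigree <- function() branchPedigree(2, 2)

#' Direct descent line pedigree
#'
#' An apex ancestor (`anc`, a founder) with a single descent line of
#' `nMeioses` transmissions; every generation marries in a new founder
#' spouse. `anc` and the final descendant (`desc`) are `nMeioses` meioses
#' apart.
#'
#' @param nMeioses number of transmissions (>= 1).
#' @return a [Pedigree].
#' @export
directLinePedigree <- function(nMeioses) {
  stopifnot(nMeioses >= 1)
  rows <- list(list("anc", NA, NA, "male", "affected"),
               list("ancsp", NA, NA, "female", "unaffected"))
  fa <- "anc"; mo <- "ancsp"
  for (k in seq_len(nMeioses)) {
    id <- if (k == nMeioses) "desc" else sprintf("g%d", k)
    rows[[length(rows) + 1L]] <- list(id, fa, mo, "male",
                                      if (k == nMeioses) "affected" else "unaffected")
    if (k < nMeioses) {
      sp <- sprintf("g%dsp", k)
      rows[[length(rows) + 1L]] <- list(sp, NA, NA, "female", "unaffected")
      fa <- id; mo <- sp
    }
  }
  newPedigree(sprintf("line_%d", nMeioses), do.call(.fixtureMembers, rows))
}

#' Three-carrier pedigree (two cousins plus one connecting parent)
#'
#' `branchPedigree(2, 2)` with carriers `leaf1`, `leaf2` and the branch-2
#' parent `b2_1`; the minimal connecting subgraph still has 4 meioses.
#'
#' @return list with `ped` (a [Pedigree]) and `carriers`.
#' @export
threeCarrierPedigree <- function() {
  list(ped = branchPedigree(2, 2), carriers = c("leaf1", "leaf2", "b2_1"))
}
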