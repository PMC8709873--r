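# Minimal connecting subgraph (meioses counting) between carriers.
#
# The subgraph is the transmission tree of minimum total meioses that links
# all carriers through a common ancestral introduction point: a directed
# Steiner tree in the parent-to-child DAG, found exactly by the
# Dreyfus-Wagner dynamic programme over carrier subsets. Carrier sets in
# high-risk families are small (<= ~10), which keeps the 2^k subset table
# cheap; inbreeding loops are handled exactly because the programme is
# exhaustive over candidate apex ancestors.

.descentDistances <- function(ped) {
  idx <- .pedIndex(ped)
  n <- length(idx$ids)
  D <- matrix(Inf, n, n) # D[v, u]: min parent->child edges from v down to u
  for (u in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[u] <- 0
    frontier <- u
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      par <- unique(stats::na.omit(c(idx$father[frontier], idx$mother[frontier])))
      newp <- par[dist[par] > d]
      dist[newp] <- d
      frontier <- newp
    }
    D[, u] <- dist
  }
  D
}

#' Minimal ancestral subgraph connecting a set of carriers
#'
#' Finds the transmission tree of minimum meioses (parent-to-child
#' transmissions) linking all carriers through common ancestors. When
#' several ancestral subgraphs tie on meioses, the apex whose children
#' descend from a full couple is preferred and remaining ties are broken by
#' the lexicographically smallest apex id; all tied apex candidates are
#' reported in the `ties` slot. A founder couple at the apex counts as one
#' introduction point (either spouse may have introduced the allele); all
#' other pedigree founders contributing alleles along the tree are marry-in
#' spouses.
#'
#' @param ped a [Pedigree].
#' @param carrierIds ids of the (>= 1) carriers to connect.
#' @return a [ConnectingSubgraph].
#' @examples
#' ped <- trioPedigree()
#' meioses(connectingSubgraph(ped, c("dad", "kid"))) # 1
#' @export
connectingSubgraph <- function(ped, carrierIds) {
  carrierIds <- unique(as.character(carrierIds))
  if (length(carrierIds) < 1L) .domainError("need at least one carrier")
  .checkMember(ped, carrierIds)
  idx <- .pedIndex(ped)
  ids <- idx$ids
  n <- length(ids)
  lexOrder <- order(ids) # deterministic tie-breaking in id order
  D <- .descentDistances(ped)
  term <- match(sort(carrierIds), ids)
  k <- length(term)

  if (k == 1L) {
    return(.makeSubgraph(ped, carrierIds, nodes = carrierIds,
                         edges = matrix(character(), 0, 2,
                                        dimnames = list(NULL, c("parent", "child"))),
                         apexId = carrierIds, ties = carrierIds))
  }

  nS <- bitwShiftL(1L, k) - 1L
  f <- matrix(Inf, n, nS)       # final (relaxed) values
  g <- matrix(Inf, n, nS)       # merge-phase values
  choiceSplit <- matrix(0L, n, nS)
  choiceVia <- matrix(0L, n, nS)
  for (j in seq_len(k)) f[, bitwShiftL(1L, j - 1L)] <- D[, term[j]]

  masks <- seq_len(nS)
  pop <- vapply(masks, function(S) sum(bitwAnd(S, bitwShiftL(1L, 0:(k - 1))) > 0L),
                integer(1))
  for (S in masks[order(pop, masks)]) {
    if (pop[S] < 2L) next
    # merge phase: combine two sub-terminal trees at the same node
    Tsub <- bitwAnd(S - 1L, S) # iterate proper submasks of S
    while (Tsub > 0L) {
      if (Tsub < bitwAnd(S - Tsub, S)) { # each unordered split once
        cand <- f[, Tsub] + f[, S - Tsub]
        upd <- cand < g[, S]
        if (any(upd)) {
          g[upd, S] <- cand[upd]
          choiceSplit[upd, S] <- Tsub
        }
      }
      Tsub <- bitwAnd(Tsub - 1L, S)
    }
    # relax phase: allow the root to sit above the merge node
    gS <- g[, S]
    fin <- which(is.finite(gS))
    for (v in seq_len(n)) {
      reach <- fin[is.finite(D[v, fin])]
      if (!length(reach)) next
      vals <- D[v, reach] + gS[reach]
      best <- min(vals)
      if (best < f[v, S]) {
        hits <- reach[vals == best]
        u <- hits[which.min(match(hits, lexOrder))]
        f[v, S] <- best
        choiceVia[v, S] <- u
      }
    }
  }

  full <- nS
  if (!any(is.finite(f[, full]))) {
    .famsegError(
      sprintf("carriers have no common ancestor in family '%s'", ped@familyId),
      "famseg_disconnected_error",
      partition = .carrierPartition(ids, D, term))
  }
  best <- min(f[, full])
  roots <- which(f[, full] == best)
  rootsLex <- roots[order(match(roots, lexOrder))]

  buildTree <- function(root) {
    edges <- new.env(parent = emptyenv())
    addPath <- function(v, u) { # descend from v to u along a shortest path
      cur <- u
      while (cur != v) {
        par <- c(idx$father[cur], idx$mother[cur])
        par <- par[!is.na(par) & is.finite(D[v, par]) & D[v, par] == D[v, cur] - 1]
        p <- par[which.min(match(par, lexOrder))]
        edges[[paste0(ids[p], "\r", ids[cur])]] <- c(p, cur)
        cur <- p
      }
    }
    expand <- function(v, S) {
      if (pop[S] == 1L) {
        addPath(v, term[which(bitwAnd(S, bitwShiftL(1L, 0:(k - 1))) > 0L)])
        return()
      }
      u <- choiceVia[v, S]
      if (u != 0L && u != v) { addPath(v, u); v <- u }
      Tsub <- choiceSplit[v, S]
      expand(v, Tsub)
      expand(v, S - Tsub)
    }
    expand(root, full)
    em <- do.call(rbind, as.list(edges))
    if (is.null(em)) em <- matrix(integer(), 0, 2)
    em
  }

  pickApex <- function() {
    isCarrier <- seq_len(n) %in% term
    coupled <- function(r, em) {
      if (isCarrier[r]) return(NA_integer_)
      kids <- em[em[, 1] == r, 2]
      if (!length(kids)) return(NA_integer_)
      others <- ifelse(idx$father[kids] == r, idx$mother[kids], idx$father[kids])
      if (length(unique(others)) == 1L) others[1] else NA_integer_
    }
    trees <- lapply(rootsLex, buildTree)
    spouses <- vapply(seq_along(rootsLex),
                      function(i) coupled(rootsLex[i], trees[[i]]), integer(1))
    pick <- which(!is.na(spouses))[1]
    if (is.na(pick)) pick <- 1L
    list(root = rootsLex[pick], tree = trees[[pick]], spouse = spouses[pick])
  }

  sel <- pickApex()
  em <- sel$tree
  apexIds <- ids[sel$root]
  if (!is.na(sel$spouse)) apexIds <- sort(c(apexIds, ids[sel$spouse]))
  edgeIds <- matrix(ids[em], ncol = 2,
                    dimnames = list(NULL, c("parent", "child")))
  nodes <- unique(c(ids[sel$root], as.vector(edgeIds)))
  .makeSubgraph(ped, sort(carrierIds), nodes = nodes, edges = edgeIds,
                apexId = apexIds, ties = sort(ids[roots]))
}

.carrierPartition <- function(ids, D, term) {
  # connected components of carriers under "shares a common ancestor"
  k <- length(term)
  grp <- seq_len(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (any(is.finite(D[, term[i]]) & is.finite(D[, term[j]]))) {
      grp[grp == grp[j]] <- grp[i]
    }
  }
  unname(split(ids[term], grp))
}

.makeSubgraph <- function(ped, carrierIds, nodes, edges, apexId, ties) {
  m <- ped@members
  spouses <- character()
  if (nrow(edges)) {
    child <- edges[, "child"]
    ci <- match(child, m$id)
    other <- ifelse(m$fatherId[ci] == edges[, "parent"],
                    m$motherId[ci], m$fatherId[ci])
    spouses <- stats::setNames(other, child)
  }
  foundersIn <- m$id[is.na(m$fatherId)]
  marryIn <- setdiff(intersect(unique(unname(spouses)), foundersIn), apexId)
  new("ConnectingSubgraph",
      familyId = ped@familyId,
      carriers = carrierIds,
      nodes = nodes,
      edges = edges,
      meioses = nrow(edges),
      apex = apexId,
      founderIntroducers = apexId,
      marryIn = sort(marryIn),
      spouses = spouses,
      ties = ties)
}

#' @rdname ConnectingSubgraph-class
#' @export
setMethod("meioses", "ConnectingSubgraph", function(x) x@meioses)

#' @rdname ConnectingSubgraph-class
#' @export
setMethod("carriers", "ConnectingSubgraph", function(x) x@carriers)

#' @rdname ConnectingSubgraph-class
#' @export
setMethod("familyId", "ConnectingSubgraph", function(x) x@familyId)

setMethod("show", "ConnectingSubgraph", function(object) {
  cat(sprintf("ConnectingSubgraph (family '%s'): %d carriers, %d meioses\n",
              object@familyId, length(object@carriers), object@meioses))
  cat(sprintf("  apex: %s%s\n", paste(object@apex, collapse = " x "),
              if (length(object@apex) == 2) " (couple)" else ""))
  if (length(object@marryIn)) {
    cat(sprintf("  marry-in founders: %s\n",
                paste(object@marryIn, collapse = ", ")))
  }
  if (length(object@ties) > length(object@apex)) {
    cat(sprintf("  tied apex candidates: %s\n",
                paste(object@ties, collapse = ", ")))
  }
  invisible(object)
})
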