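# Pedigree construction, validation and graph queries.

.SEX_LEVELS <- c("male", "female", "unknown")
.AFF_LEVELS <- c("affected", "unaffected", "unknown")

.normalizeMembers <- function(members) {
  stopifnot(is.data.frame(members))
  need <- c("id", "fatherId", "motherId")
  miss <- setdiff(need, names(members))
  if (length(miss)) {
    .validationError(sprintf("members lacks required column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  m <- data.frame(
    id = as.character(members$id),
    fatherId = as.character(members$fatherId),
    motherId = as.character(members$motherId),
    stringsAsFactors = FALSE
  )
  m$fatherId[!is.na(m$fatherId) & m$fatherId == "0"] <- NA_character_
  m$motherId[!is.na(m$motherId) & m$motherId == "0"] <- NA_character_
  m$sex <- if ("sex" %in% names(members)) as.character(members$sex)
           else rep("unknown", nrow(m))
  m$affected <- if ("affected" %in% names(members))
    as.character(members$affected) else rep("unknown", nrow(m))
  m$genotyped <- if ("genotyped" %in% names(members))
    as.logical(members$genotyped) else rep(FALSE, nrow(m))
  m$genotyped[is.na(m$genotyped)] <- FALSE
  m$birthYear <- if ("birthYear" %in% names(members))
    as.integer(members$birthYear) else rep(NA_integer_, nrow(m))
  m$stratum <- if ("stratum" %in% names(members))
    as.character(members$stratum) else rep(NA_character_, nrow(m))
  m
}

.validateMembers <- function(m) {
  msgs <- character()
  if (nrow(m) == 0L) return("pedigree has no members")
  if (anyNA(m$id) || !all(nzchar(m$id))) msgs <- c(msgs, "empty member id")
  dup <- unique(m$id[duplicated(m$id)])
  if (length(dup)) {
    msgs <- c(msgs, sprintf("duplicated member id(s): %s",
                            paste(dup, collapse = ", ")))
  }
  bad <- m$id[!m$sex %in% .SEX_LEVELS]
  if (length(bad)) {
    msgs <- c(msgs, sprintf("invalid sex for: %s", paste(bad, collapse = ", ")))
  }
  bad <- m$id[!m$affected %in% .AFF_LEVELS]
  if (length(bad)) {
    msgs <- c(msgs, sprintf("invalid affection status for: %s",
                            paste(bad, collapse = ", ")))
  }
  half <- m$id[xor(is.na(m$fatherId), is.na(m$motherId))]
  if (length(half)) {
    msgs <- c(msgs, sprintf("half-specified parentage for: %s",
                            paste(half, collapse = ", ")))
  }
  self <- m$id[(!is.na(m$fatherId) & m$fatherId == m$id) |
               (!is.na(m$motherId) & m$motherId == m$id)]
  if (length(self)) {
    msgs <- c(msgs, sprintf("individual listed as own parent: %s",
                            paste(self, collapse = ", ")))
  }
  dangling <- unique(c(m$fatherId[!is.na(m$fatherId) & !m$fatherId %in% m$id],
                       m$motherId[!is.na(m$motherId) & !m$motherId %in% m$id]))
  if (length(dangling)) {
    msgs <- c(msgs, sprintf("parent(s) not members of the pedigree: %s",
                            paste(dangling, collapse = ", ")))
  }
  if (length(msgs)) return(msgs) # graph checks need a structurally sound table

  fi <- match(m$fatherId, m$id)
  mi <- match(m$motherId, m$id)
  badf <- m$id[!is.na(fi) & !m$sex[fi] %in% c("male", "unknown")]
  if (length(badf)) {
    msgs <- c(msgs, sprintf("father of %s is not male",
                            paste(unique(badf), collapse = ", ")))
  }
  badm <- m$id[!is.na(mi) & !m$sex[mi] %in% c("female", "unknown")]
  if (length(badm)) {
    msgs <- c(msgs, sprintf("mother of %s is not female",
                            paste(unique(badm), collapse = ", ")))
  }
  isFounder <- is.na(m$fatherId)
  if (!any(isFounder)) msgs <- c(msgs, "pedigree has no founders")
  badSex <- m$id[m$sex == "unknown" & !isFounder]
  if (length(badSex)) {
    msgs <- c(msgs, sprintf("unknown sex is allowed for founders only: %s",
                            paste(badSex, collapse = ", ")))
  }
  # acyclicity by Kahn's algorithm on parent -> child edges
  n <- nrow(m)
  indeg <- (!is.na(fi)) + (!is.na(mi))
  childrenOf <- split(rep(seq_len(n), 2L), factor(c(fi, mi), levels = seq_len(n)))
  frontier <- which(indeg == 0L)
  seen <- 0L
  while (length(frontier)) {
    seen <- seen + length(frontier)
    kids <- unlist(childrenOf[frontier], use.names = FALSE)
    if (length(kids)) {
      tab <- tabulate(kids, nbins = n)
      indeg <- indeg - tab
      frontier <- which(indeg == 0L & tab > 0L)
    } else frontier <- integer()
  }
  if (seen < n) {
    cyc <- m$id[indeg > 0L]
    msgs <- c(msgs, sprintf("ancestry cycle involving: %s",
                            paste(cyc, collapse = ", ")))
  }
  msgs
}

#' Construct a validated Pedigree
#'
#' @param familyId single family identifier.
#' @param members data.frame with at least `id`, `fatherId`, `motherId`;
#'   optional `sex`, `affected`, `genotyped`, `birthYear`, `stratum`.
#'   `"0"` and `NA` both denote a missing parent.
#' @param metadata optional list attached to the object.
#' @return a [Pedigree].
#' @examples
#' ped <- newPedigree("fam1", data.frame(
#'   id = c("f", "m", "c"), fatherId = c(NA, NA, "f"),
#'   motherId = c(NA, NA, "m"), sex = c("male", "female", "female"),
#'   affected = c("unaffected", "unaffected", "affected")))
#' founders(ped)
#' @export
newPedigree <- function(familyId, members, metadata = list()) {
  m <- .normalizeMembers(members)
  msgs <- .validateMembers(m)
  if (length(msgs)) {
    .validationError(sprintf("invalid pedigree '%s': %s", familyId,
                             paste(msgs, collapse = "; ")))
  }
  new("Pedigree", familyId = as.character(familyId), members = m,
      metadata = metadata)
}

#' @rdname Pedigree-class
#' @export
setMethod("familyId", "Pedigree", function(x) x@familyId)

#' @rdname Pedigree-class
#' @export
setMethod("members", "Pedigree", function(x) x@members)

#' @rdname founders
#' @export
setMethod("founders", "Pedigree", function(x) {
  x@members$id[is.na(x@members$fatherId)]
})

#' @rdname Pedigree-class
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@members))

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree '%s': %d members (%d founders, %d affected, %d genotyped)\n",
              object@familyId, nrow(m), sum(is.na(m$fatherId)),
              sum(m$affected == "affected"), sum(m$genotyped)))
  invisible(object)
})

#' Pedigree metadata
#'
#' @param ped a [Pedigree].
#' @return the metadata list (generator truth sidecars live here).
#' @export
pedMetadata <- function(ped) ped@metadata

# Graph queries ----------------------------------------------------------------

.pedIndex <- function(ped) {
  m <- ped@members
  list(ids = m$id,
       father = match(m$fatherId, m$id),
       mother = match(m$motherId, m$id))
}

.checkMember <- function(ped, ids) {
  bad <- setdiff(ids, ped@members$id)
  if (length(bad)) {
    .famsegError(sprintf("unknown member id(s) in family '%s': %s",
                         ped@familyId, paste(bad, collapse = ", ")),
                 "famseg_lookup_error", ids = bad)
  }
  invisible(ids)
}

#' Topological order of pedigree members (parents before children)
#'
#' @param ped a [Pedigree].
#' @return character vector of ids.
#' @export
topoOrder <- function(ped) {
  idx <- .pedIndex(ped)
  n <- length(idx$ids)
  depth <- rep(NA_integer_, n)
  depth[is.na(idx$father)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    d <- pmax(depth[idx$father[todo]], depth[idx$mother[todo]]) + 1L
    depth[todo] <- d # stays NA until both parents resolved
  }
  idx$ids[order(depth, seq_len(n))]
}

#' Generation depth of each member (founders are 0)
#'
#' @param ped a [Pedigree].
#' @return named integer vector.
#' @export
generationDepth <- function(ped) {
  idx <- .pedIndex(ped)
  depth <- rep(NA_integer_, length(idx$ids))
  depth[is.na(idx$father)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    depth[todo] <- pmax(depth[idx$father[todo]], depth[idx$mother[todo]]) + 1L
  }
  names(depth) <- idx$ids
  depth
}

#' Ancestral closure of a set of members
#'
#' The given ids together with all of their ancestors; the smallest
#' sub-pedigree on which genotype probabilities for the ids can be computed
#' exactly.
#'
#' @param ped a [Pedigree].
#' @param ids member ids.
#' @return character vector of ids (in pedigree row order).
#' @export
ancestorClosure <- function(ped, ids) {
  .checkMember(ped, ids)
  idx <- .pedIndex(ped)
  inset <- idx$ids %in% ids
  repeat {
    cur <- which(inset)
    par <- unique(stats::na.omit(c(idx$father[cur], idx$mother[cur])))
    newp <- par[!inset[par]]
    if (!length(newp)) break
    inset[newp] <- TRUE
  }
  idx$ids[inset]
}

#' Restrict a pedigree to a subset of members
#'
#' The subset must be closed under parentage (use [ancestorClosure()]);
#' members whose parents fall outside the subset become founders.
#'
#' @param ped a [Pedigree].
#' @param ids member ids to keep.
#' @return a [Pedigree].
#' @export
subPedigree <- function(ped, ids) {
  .checkMember(ped, ids)
  m <- ped@members[ped@members$id %in% ids, , drop = FALSE]
  # orphan references outside the subset: drop both parents together
  out <- !(m$fatherId %in% m$id) | !(m$motherId %in% m$id)
  m$fatherId[out] <- NA_character_
  m$motherId[out] <- NA_character_
  rownames(m) <- NULL
  newPedigree(ped@familyId, m, ped@metadata)
}

.childrenMap <- function(ped) {
  idx <- .pedIndex(ped)
  n <- length(idx$ids)
  kidOf <- vector("list", n)
  for (i in seq_len(n)) kidOf[[i]] <- integer()
  for (i in seq_len(n)) {
    f <- idx$father[i]; mo <- idx$mother[i]
    if (!is.na(f)) kidOf[[f]] <- c(kidOf[[f]], i)
    if (!is.na(mo)) kidOf[[mo]] <- c(kidOf[[mo]], i)
  }
  names(kidOf) <- idx$ids
  kidOf
}

#' Export a pedigree as Graphviz DOT
#'
#' Minimal drawing helper: one node per member (box = male, ellipse =
#' female), filled when affected, with parent-to-child edges.
#'
#' @param ped a [Pedigree].
#' @param path optional file to write to.
#' @return the DOT text, invisibly when written to `path`.
#' @export
pedToDot <- function(ped, path = NULL) {
  m <- ped@members
  shape <- c(male = "box", female = "ellipse", unknown = "diamond")[m$sex]
  fill <- ifelse(m$affected == "affected", ", style=filled, fillcolor=gray70", "")
  nodes <- sprintf("  \"%s\" [shape=%s%s];", m$id, shape, fill)
  kid <- m$id[!is.na(m$fatherId)]
  edges <- c(sprintf("  \"%s\" -> \"%s\";", m$fatherId[!is.na(m$fatherId)], kid),
             sprintf("  \"%s\" -> \"%s\";", m$motherId[!is.na(m$motherId)], kid))
  txt <- paste(c(sprintf("digraph \"%s\" {", ped@familyId), nodes, edges, "}"),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
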