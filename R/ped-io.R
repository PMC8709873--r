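# PED-format reader/writer.
#
# Dialect: whitespace-delimited, 6+ columns (family, id, father, mother, sex,
# phenotype); "0" marks a missing parent; sex 1 = male, 2 = female,
# 0 = unknown; phenotype 2 = affected, 1 = unaffected, 0 or -9 = unknown.
# Columns beyond 6 are mapped to member attributes through a JSON sidecar:
# {"columns": ["genotyped", "birth_year", "stratum"]}.

.SIDE_COLS <- c(genotyped = "genotyped", birth_year = "birthYear",
                stratum = "stratum")

.parsePedLines <- function(lines, path, extraCols = character()) {
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) .famsegError(sprintf("no records in '%s'", path),
                                  "famseg_parse_error")
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(toks)
  short <- nf < 6L
  if (any(short)) {
    .famsegError(sprintf("malformed PED line %d in '%s': expected >= 6 fields, got %d",
                         keep[which(short)[1]], path, nf[which(short)[1]]),
                 "famseg_parse_error")
  }
  tab <- t(vapply(toks, function(x) x[1:6], character(6)))
  sexCode <- tab[, 5]
  badSex <- !sexCode %in% c("0", "1", "2")
  if (any(badSex)) {
    .famsegError(sprintf("malformed PED line %d in '%s': bad sex code '%s'",
                         keep[which(badSex)[1]], path, sexCode[which(badSex)[1]]),
                 "famseg_parse_error")
  }
  phCode <- tab[, 6]
  badPh <- !phCode %in% c("0", "1", "2", "-9")
  if (any(badPh)) {
    .famsegError(sprintf("malformed PED line %d in '%s': bad phenotype code '%s'",
                         keep[which(badPh)[1]], path, phCode[which(badPh)[1]]),
                 "famseg_parse_error")
  }
  m <- data.frame(
    family = tab[, 1],
    id = tab[, 2],
    fatherId = ifelse(tab[, 3] == "0", NA_character_, tab[, 3]),
    motherId = ifelse(tab[, 4] == "0", NA_character_, tab[, 4]),
    sex = c(`0` = "unknown", `1` = "male", `2` = "female")[sexCode],
    affected = c(`0` = "unknown", `1` = "unaffected", `2` = "affected",
                 `-9` = "unknown")[phCode],
    stringsAsFactors = FALSE
  )
  for (j in seq_along(extraCols)) {
    col <- 6L + j
    vals <- vapply(toks, function(x) if (length(x) >= col) x[col] else NA_character_,
                   character(1))
    nm <- extraCols[j]
    target <- .SIDE_COLS[[nm]]
    if (is.null(target)) target <- nm
    m[[target]] <- switch(target,
      genotyped = vals %in% c("1", "TRUE", "true"),
      birthYear = suppressWarnings(as.integer(vals)),
      vals)
  }
  rownames(m) <- NULL
  m
}

.readSidecar <- function(sidecar) {
  if (is.null(sidecar)) return(character())
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  as.character(sc$columns %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a single-family PED file
#'
#' @param path PED file.
#' @param sidecar optional JSON sidecar naming the extra columns beyond the
#'   standard six, e.g. `{"columns": ["genotyped", "birth_year", "stratum"]}`.
#' @return a validated [Pedigree]. A file containing several families is an
#'   error here; use [readPedCohort()] for screens.
#' @examples
#' f <- tempfile(fileext = ".ped")
#' writeLines(c("fam1 dad 0 0 1 1", "fam1 mom 0 0 2 1", "fam1 kid dad mom 2 2"), f)
#' readPed(f)
#' @export
readPed <- function(path, sidecar = NULL) {
  peds <- readPedCohort(path, sidecar)
  if (length(peds) != 1L) {
    .famsegError(sprintf("'%s' contains %d families; readPed expects one",
                         path, length(peds)), "famseg_parse_error")
  }
  peds[[1L]]
}

#' Read a PED file possibly holding several families
#'
#' @inheritParams readPed
#' @return named list of [Pedigree] objects, in order of first appearance.
#' @export
readPedCohort <- function(path, sidecar = NULL) {
  if (!file.exists(path)) .famsegError(sprintf("no such file: '%s'", path),
                                       "famseg_parse_error")
  m <- .parsePedLines(readLines(path), path, .readSidecar(sidecar))
  fams <- unique(m$family)
  out <- lapply(fams, function(f) {
    newPedigree(f, m[m$family == f, setdiff(names(m), "family"), drop = FALSE])
  })
  names(out) <- fams
  out
}

#' Write a pedigree in PED format
#'
#' Columns 1-6 are written canonically so that read -> write -> read is the
#' identity on validated pedigrees; extra attribute columns are appended when
#' `extraCols` names them (in sidecar vocabulary: `"genotyped"`,
#' `"birth_year"`, `"stratum"`).
#'
#' @param ped a [Pedigree].
#' @param path output file.
#' @param extraCols character vector of extra columns to append.
#' @return `path`, invisibly.
#' @export
writePed <- function(ped, path, extraCols = character()) {
  m <- ped@members
  sexCode <- c(male = "1", female = "2", unknown = "0")[m$sex]
  phCode <- c(affected = "2", unaffected = "1", unknown = "0")[m$affected]
  fields <- cbind(ped@familyId, m$id,
                  ifelse(is.na(m$fatherId), "0", m$fatherId),
                  ifelse(is.na(m$motherId), "0", m$motherId),
                  sexCode, phCode)
  for (nm in extraCols) {
    target <- .SIDE_COLS[[nm]]
    if (is.null(target)) target <- nm
    v <- m[[target]]
    fields <- cbind(fields, switch(target,
      genotyped = ifelse(v %in% TRUE, "1", "0"),
      ifelse(is.na(v), "0", as.character(v))))
  }
  writeLines(apply(fields, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Write the JSON sidecar naming extra PED columns
#'
#' @param extraCols character vector of column names (sidecar vocabulary).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePedSidecar <- function(extraCols, path) {
  jsonlite::write_json(list(columns = extraCols), path, auto_unbox = FALSE)
  invisible(path)
}
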