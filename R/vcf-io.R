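# Minimal VCF and annotation-table emission for simulated genotypes.

#' Write a single-variant, GT-only VCFv4.2 file
#'
#' @param genotypes named integer vector of copy numbers (0/1/2), one per
#'   sample.
#' @param path output file.
#' @param chrom,pos,ref,alt,id variant fields.
#' @return `path`, invisibly.
#' @export
writeMinimalVcf <- function(genotypes, path, chrom = "2", pos = 50847195L,
                            ref = "G", alt = "A", id = ".") {
  gt <- c("0/0", "0/1", "1/1")[genotypes + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(genotypes)), collapse = "\t"))
  record <- paste(c(chrom, pos, id, ref, alt, ".", ".", ".", "GT", gt),
                  collapse = "\t")
  writeLines(c(header, record), path)
  invisible(path)
}

#' Read carrier genotypes back from a GT-only VCF
#'
#' Lightweight parser for the single-variant VCFs this package writes
#' (uncompressed, GT-only FORMAT).
#'
#' @param path VCF file.
#' @return named integer vector of copy numbers.
#' @export
readMinimalVcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) .famsegError("no #CHROM header line", "famseg_parse_error")
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  rec <- lines[!startsWith(lines, "#")][1]
  f <- strsplit(rec, "\t")[[1]]
  gtField <- f[-(1:9)]
  gt <- vapply(strsplit(sub(":.*", "", gtField), "[/|]"), function(a) {
    sum(a == "1")
  }, integer(1))
  stats::setNames(gt, samples)
}

#' Write an annotated variant table as TSV
#'
#' @param records variant data.frame (see [cohortFunctionalFilter()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a full simulated family bundle (PED, VCF, annotation TSV, truth)
#'
#' @param ped a [Pedigree] with affection assigned.
#' @param variant result of [plantVariant()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulatedFamily <- function(ped, variant, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fid <- familyId(ped)
  paths <- c(
    ped = file.path(dir, paste0(fid, ".ped")),
    sidecar = file.path(dir, paste0(fid, ".ped.json")),
    vcf = file.path(dir, paste0(fid, ".vcf")),
    annotation = file.path(dir, paste0(fid, ".annotation.tsv")),
    truth = file.path(dir, paste0(fid, ".truth.json")))
  writePed(ped, paths["ped"], extraCols = c("genotyped", "stratum"))
  writePedSidecar(c("genotyped", "stratum"), paths["sidecar"])
  writeMinimalVcf(variant$genotypes, paths["vcf"], id = variant$record$id)
  writeVariantTable(variant$record, paths["annotation"])
  truth <- pedMetadata(ped)$truth
  truth$config <- NULL # rate tables and closures do not serialize cleanly
  truth$variant <- variant$truth
  truth$variant$pathEdges <- apply(variant$truth$pathEdges, 1L, paste,
                                   collapse = ">")
  truth$carrierIds <- variant$carrierIds
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
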