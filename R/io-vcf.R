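# VCF input/output. Parsing is delegated to vcfR; serialization is done
# in-package so that INFO lists are emitted sorted and deduplicated and
# repeated runs are byte-identical.

# normalize one genotype string to an unordered, unphased allele-index pair;
# any missing allele collapses the call to "."
normalizeGenotype <- function(gt) {
  if (is.na(gt) || gt == "" || gt == ".") return(".")
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == "." | alleles == "")) return(".")
  paste(sort(as.integer(alleles)), collapse = "/")
}

# sorted, duplicate-free character vectors per tag; drops empty tags
normalizeInfo <- function(m) {
  m <- lapply(m, function(v) sort(unique(as.character(v))))
  m[lengths(m) > 0]
}

parseInfoString <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  out <- list()
  for (field in strsplit(s, ";", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", field, fixed = TRUE)
    if (eq > 0) {
      key <- substr(field, 1L, eq - 1L)
      val <- strsplit(substr(field, eq + 1L, nchar(field)), ",",
                      fixed = TRUE)[[1L]]
      out[[key]] <- c(out[[key]], val)
    } else if (nzchar(field)) {
      out[[field]] <- c(out[[field]], character(0))
    }
  }
  normalizeInfo(out)
}

# INFO definitions written to every VCF this package produces
ANNOTATION_INFO_HEADER <- c(
  EID = "Exon IDs of lifted exons containing the position",
  GID = "Gene IDs for the exons in EID",
  GIR = "Gene IDs for all lifted gene spans overlapping the position",
  GNM = "Gene names for the exons in EID",
  GNR = "Gene names for the gene spans in GIR",
  ENU = "1 if the REF>ALT change is an ENU-typical base change")

#' Read a multi-sample VCF
#'
#' Genotypes are normalized to unordered, unphased allele-index pairs (the
#' phase separator is ignored; \code{"1/0"} and \code{"0|1"} both become
#' \code{"0/1"}); missing calls are kept as \code{"."}. All INFO
#' \code{key=value} pairs are parsed into the record's info map with values
#' deduplicated and sorted.
#'
#' @param path VCF 4.x text file with a \code{#CHROM} header line.
#' @return a [VariantSet-class]; sample IDs via [vcfSamples()].
#' @export
readVcfFile <- function(path) {
  if (!file.exists(path)) formatError("VCF file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    formatError("%s: no #CHROM header line found", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (ln in body) {
    nf <- length(strsplit(lines[ln], "\t", fixed = TRUE)[[1L]])
    if (nf != length(cols))
      formatError("%s line %d: %d fields, expected %d", path, ln, nf,
                  length(cols))
  }
  if (length(body) == 0L) {
    return(variantSet(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = list(),
                      geno = matrix(character(0), nrow = 0,
                                    ncol = length(samples),
                                    dimnames = list(NULL, samples))))
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  n <- nrow(fix)
  alt <- lapply(fix[, "ALT"], function(a) {
    if (is.na(a) || a == ".") character(0)
    else strsplit(a, ",", fixed = TRUE)[[1L]]
  })
  info <- lapply(fix[, "INFO"], parseInfoString)
  if (length(samples) > 0) {
    gtRaw <- vcfR::extract.gt(v, element = "GT")
    geno <- matrix(".", nrow = n, ncol = length(samples),
                   dimnames = list(NULL, samples))
    for (s in samples)
      geno[, s] <- vapply(gtRaw[, s], normalizeGenotype, "",
                          USE.NAMES = FALSE)
  } else {
    geno <- matrix(character(0), nrow = n, ncol = 0)
  }
  qual <- fix[, "QUAL"]
  qual[is.na(qual)] <- "."
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  idc <- fix[, "ID"]
  idc[is.na(idc)] <- "."
  new("VariantSet", chrom = unname(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]), id = unname(idc),
      ref = unname(fix[, "REF"]), alt = unname(alt), qual = unname(qual),
      filter = unname(filt), info = unname(info), geno = geno)
}

serializeInfo <- function(m) {
  m <- normalizeInfo(m)
  if (length(m) == 0L) return(".")
  keys <- sort(names(m))
  paste(vapply(keys, function(k) paste0(k, "=", paste(m[[k]], collapse = ",")),
               ""), collapse = ";")
}

#' Write a multi-sample VCF
#'
#' Output is byte-stable: INFO values are serialized comma-separated in
#' sorted, deduplicated order under sorted tags, genotypes unphased with
#' \code{"/"} and ascending allele order, and \code{##INFO} definition lines
#' for the lift-over annotation tags (EID, GID, GIR, GNM, GNR and ENU) are
#' always emitted.
#'
#' @param x a [VariantSet-class].
#' @param path output file.
#' @param headerExtra optional additional header lines (written verbatim
#'   after the INFO definitions).
#' @return invisibly, \code{path}.
#' @export
writeVcfFile <- function(x, path, headerExtra = character(0)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf('##INFO=<ID=%s,Number=.,Type=String,Description="%s">',
                   names(ANNOTATION_INFO_HEADER), ANNOTATION_INFO_HEADER),
           headerExtra,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vcfSamples(x)), collapse = "\t"))
  n <- length(x)
  recs <- character(n)
  for (r in seq_len(n)) {
    alt <- if (length(x@alt[[r]]) == 0L) "." else paste(x@alt[[r]],
                                                        collapse = ",")
    recs[r] <- paste(c(x@chrom[r], x@pos[r], x@id[r], x@ref[r], alt,
                       x@qual[r], x@filter[r], serializeInfo(x@info[[r]]),
                       "GT", x@geno[r, ]), collapse = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
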