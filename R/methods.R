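# accessors, subsetting and show methods for the central classes

#' @rdname ExonCatalog-class
#' @export
setMethod("exonIds", "ExonCatalog", function(x) names(x@sequences))
#' @rdname ExonCatalog-class
#' @export
setMethod("geneIds", "ExonCatalog", function(x) x@geneId)
#' @rdname ExonCatalog-class
#' @export
setMethod("geneNames", "ExonCatalog", function(x) x@geneName)
#' @rdname ExonCatalog-class
#' @export
setMethod("exonSequences", "ExonCatalog", function(x) x@sequences)
#' @rdname ExonCatalog-class
#' @export
setMethod("sourceChromosomes", "ExonCatalog", function(x) x@chromosome)
#' @rdname ExonCatalog-class
#' @export
setMethod("geneStrands", "ExonCatalog", function(x) x@strand)

#' @rdname ExonCatalog-class
#' @export
setMethod("length", "ExonCatalog", function(x) length(x@sequences))

#' @rdname ExonCatalog-class
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "ExonCatalog", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, exonIds(x))
  new("ExonCatalog", sequences = x@sequences[i], geneId = x@geneId[i],
      geneName = x@geneName[i], chromosome = x@chromosome[i],
      strand = x@strand[i])
})

setMethod("show", "ExonCatalog", function(object) {
  cat(sprintf("ExonCatalog with %d exons from %d genes on %d chromosomes\n",
              length(object), length(unique(object@geneId)),
              length(unique(object@chromosome))))
  if (length(object) > 0)
    cat(sprintf("  widths %d..%d\n", min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences))))
})

#' @rdname VariantSet-class
#' @export
setMethod("vcfSamples", "VariantSet", function(x) colnames(x@geno))
#' @rdname VariantSet-class
#' @export
setMethod("genotypes", "VariantSet", function(x) x@geno)
#' @rdname VariantSet-class
#' @export
setMethod("variantInfo", "VariantSet", function(x) x@info)
#' @rdname VariantSet-class
#' @export
setMethod("refAlleles", "VariantSet", function(x) x@ref)
#' @rdname VariantSet-class
#' @export
setMethod("altAlleles", "VariantSet", function(x) x@alt)

#' @rdname VariantSet-class
#' @export
setMethod("variantPositions", "VariantSet", function(x) {
  GenomicRanges::GRanges(x@chrom, IRanges::IRanges(x@pos, width = 1L))
})

#' @rdname VariantSet-class
#' @export
setMethod("length", "VariantSet", function(x) length(x@pos))

#' @rdname VariantSet-class
#' @param i record index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = TRUE) {
  new("VariantSet", chrom = x@chrom[i], pos = x@pos[i], id = x@id[i],
      ref = x@ref[i], alt = x@alt[i], qual = x@qual[i],
      filter = x@filter[i], info = x@info[i],
      geno = x@geno[i, , drop = FALSE])
})

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet with %d records and %d samples\n", length(object),
              ncol(object@geno)))
  if (length(object) > 0) {
    n <- min(3L, length(object))
    for (r in seq_len(n))
      cat(sprintf("  %s:%d %s>%s\n", object@chrom[r], object@pos[r],
                  object@ref[r], paste(object@alt[[r]], collapse = ",")))
    if (length(object) > n) cat("  ...\n")
  }
})

#' Single INFO tag values across records
#'
#' @param x a [VariantSet-class].
#' @param tag INFO tag name.
#' @return a list (one element per record) of character vectors; records
#'   without the tag yield \code{character(0)}.
#' @export
infoTag <- function(x, tag) {
  lapply(x@info, function(m) {
    v <- m[[tag]]
    if (is.null(v)) character(0) else v
  })
}

#' Merge per-line variant sets over identical sites
#'
#' Supports cohorts delivered as one VCF per line: all sets must contain the
#' same sites in the same order (chromosome, position, REF, ALT); samples are
#' concatenated.
#'
#' @param sets a list of [VariantSet-class] objects.
#' @return a single [VariantSet-class].
#' @export
mergeVariantSets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  key <- function(v) paste(v@chrom, v@pos, v@ref,
                           vapply(v@alt, paste, "", collapse = ","))
  for (s in sets[-1L]) {
    if (length(s) != length(ref) || !identical(key(s), key(ref)))
      formatError("variant sets to merge must contain identical sites")
  }
  geno <- do.call(cbind, lapply(sets, genotypes))
  if (anyDuplicated(colnames(geno)))
    formatError("duplicate sample IDs across merged variant sets: %s",
                paste(unique(colnames(geno)[duplicated(colnames(geno))]),
                      collapse = ", "))
  new("VariantSet", chrom = ref@chrom, pos = ref@pos, id = ref@id,
      ref = ref@ref, alt = ref@alt, qual = ref@qual, filter = ref@filter,
      info = ref@info, geno = geno)
}

#' @rdname LineSpec-class
#' @export
setMethod("lineId", "LineSpec", function(x) x@lineId)
#' @rdname LineSpec-class
#' @export
setMethod("lineSamples", "LineSpec", function(x) x@samples)
#' @rdname LineSpec-class
#' @export
setMethod("inheritanceModel", "LineSpec", function(x) x@inheritance)
#' @rdname LineSpec-class
#' @export
setMethod("linkageRegions", "LineSpec", function(x) x@regions)

setMethod("show", "LineSpec", function(object) {
  cat(sprintf("LineSpec %s: %d samples, %s, %s\n", object@lineId,
              length(object@samples), object@inheritance,
              if (is.null(object@regions)) "no linkage region"
              else sprintf("%d linkage region(s)", length(object@regions))))
})

setMethod("show", "FeatureIndex", function(object) {
  cat(sprintf("FeatureIndex: %d exon features, %d gene spans\n",
              length(object@exons), length(object@genes)))
})
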