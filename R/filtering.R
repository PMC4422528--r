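# Multi-line variant filtration cascade:
#   privacy (expected genotype in the target line, homozygous reference in
#   every other line) -> exon/gene containment -> one-variant-per-gene ->
#   linkage-region restriction -> ENU-type base-change flagging.

#' Expected VCF genotype for an inheritance model
#'
#' Homozygous alternative for recessive lines, heterozygous for dominant
#' lines.
#'
#' @param inheritance \code{"dominant"} or \code{"recessive"}.
#' @return the normalized genotype string (\code{"0/1"} or \code{"1/1"}).
#' @examples
#' expectedGenotype("recessive")  # "1/1"
#' expectedGenotype("dominant")   # "0/1"
#' @export
expectedGenotype <- function(inheritance) {
  switch(inheritance,
         recessive = "1/1",
         dominant = "0/1",
         stop(sprintf("unknown inheritance model: '%s'", inheritance)))
}

checkLineSamples <- function(x, lines) {
  wanted <- unlist(lapply(lines, lineSamples))
  missing <- setdiff(wanted, vcfSamples(x))
  if (length(missing))
    stop(sprintf("sample(s) named in line config but absent from the VCF: %s",
                 paste(missing, collapse = ", ")))
}

#' Private-variant filter for one line
#'
#' Keeps exactly the records where every sample of the target line has the
#' line's expected genotype and every sample of every other line is
#' homozygous reference. Under the strict missing-data policy any missing
#' genotype among the tested samples excludes the record; the lenient policy
#' treats missing calls in \emph{other} lines as compatible with homozygous
#' reference (a missing call in the target line always excludes).
#'
#' @param x a [VariantSet-class].
#' @param lines named list of [LineSpec-class] for the whole cohort.
#' @param targetLine line ID to filter for.
#' @param missing \code{"strict"} (default) or \code{"lenient"}.
#' @return the filtered [VariantSet-class].
#' @export
privateLineFilter <- function(x, lines, targetLine,
                              missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  checkLineSamples(x, lines)
  target <- lines[[targetLine]]
  if (is.null(target)) stop(sprintf("unknown line: '%s'", targetLine))
  expected <- expectedGenotype(inheritanceModel(target))
  otherSamples <- unlist(lapply(lines[names(lines) != targetLine],
                                lineSamples))
  g <- genotypes(x)
  if (length(x) == 0L) return(x)
  keepTarget <- rowSums(g[, lineSamples(target), drop = FALSE] != expected) == 0L
  refOk <- if (missing == "strict") "0/0" else c("0/0", ".")
  if (length(otherSamples) == 0L) {
    keepOthers <- rep(TRUE, nrow(g))
  } else {
    others <- g[, otherSamples, drop = FALSE]
    bad <- array(!(others %in% refOk), dim = dim(others))
    keepOthers <- rowSums(bad) == 0L
  }
  x[keepTarget & keepOthers]
}

#' Exon/gene containment filter
#'
#' At \code{level = "exon"} keeps records inside a lifted exon (non-empty
#' EID tag); at \code{level = "gene"} keeps records inside any lifted gene
#' span (non-empty GIR tag).
#'
#' @param x an annotated [VariantSet-class] (see [annotateVariants()]).
#' @param level \code{"exon"} or \code{"gene"}.
#' @return the filtered [VariantSet-class].
#' @export
exonicFilter <- function(x, level = c("exon", "gene")) {
  level <- match.arg(level)
  tag <- if (level == "exon") "EID" else "GIR"
  x[lengths(infoTag(x, tag)) > 0L]
}

#' One-variant-per-gene exclusion
#'
#' A record is excluded iff any gene span containing it (its GIR tag) holds
#' two or more records of the input set: ENU mutagenesis is highly unlikely
#' to hit the same gene twice, so multi-hit genes indicate strain artifacts.
#' Exclusion is evaluated against the input set once, not iteratively.
#'
#' @param x the post-privacy record set for one line, annotated.
#' @return the filtered [VariantSet-class].
#' @export
onePerGeneFilter <- function(x) {
  genes <- infoTag(x, "GIR")
  counts <- table(unlist(genes))
  multi <- names(counts)[counts >= 2L]
  keep <- !vapply(genes, function(g) any(g %in% multi), TRUE)
  x[keep]
}

#' ENU-typical base change test
#'
#' The predominant ENU-induced changes in phenotype-based screens are T>C,
#' A>G, T>A and A>T. Any allele longer than one base (indel) is not flagged.
#'
#' @param ref,alt REF and ALT allele strings (vectorized).
#' @return logical vector.
#' @examples
#' enuTypeFlag("T", "C")   # TRUE
#' enuTypeFlag("C", "G")   # FALSE
#' enuTypeFlag("T", "TA")  # FALSE
#' @export
enuTypeFlag <- function(ref, alt) {
  pairs <- c("T>C", "A>G", "T>A", "A>T")
  nchar(ref) == 1L & nchar(alt) == 1L & paste0(ref, ">", alt) %in% pairs
}

#' Restrict records to linkage regions
#'
#' Keeps records whose POS base lies in any region. When the line has no
#' linkage region the operation is the identity and the returned set carries
#' attribute \code{linkage_applied = FALSE} so the summary can mark the
#' stage not applicable.
#'
#' @param x a [VariantSet-class].
#' @param regions a \link[GenomicRanges]{GRanges} of regions, or \code{NULL}.
#' @return the filtered [VariantSet-class] with attribute
#'   \code{linkage_applied}.
#' @export
linkageRestrict <- function(x, regions) {
  if (is.null(regions) || length(regions) == 0L) {
    attr(x, "linkage_applied") <- FALSE
    return(x)
  }
  pos <- variantPositions(x)
  lvls <- union(GenomeInfoDb::seqlevels(pos),
                GenomeInfoDb::seqlevels(regions))
  GenomeInfoDb::seqlevels(pos) <- lvls
  GenomeInfoDb::seqlevels(regions) <- lvls
  keep <- IRanges::overlapsAny(pos, regions, ignore.strand = TRUE)
  out <- x[keep]
  attr(out, "linkage_applied") <- TRUE
  out
}

# ENU typing is evaluated for the alt allele the target line actually
# carries; both expected genotypes ("0/1", "1/1") carry allele index 1.
carriedAltAllele <- function(x) {
  vapply(x@alt, function(a) if (length(a) >= 1L) a[[1L]] else "", "")
}

#' Run the full filtering cascade over all lines
#'
#' Applies, per line, [privateLineFilter()], [exonicFilter()],
#' [onePerGeneFilter()] and [linkageRestrict()], then flags ENU-typical
#' records (INFO tag \code{ENU=1}); with \code{enuOnly = TRUE} the flag
#' becomes a filter. Counts after each stage are collected in a summary
#' table whose columns are non-increasing along the cascade.
#'
#' @param x an annotated multi-sample [VariantSet-class].
#' @param lines named list of [LineSpec-class].
#' @param level exon/gene containment level, see [exonicFilter()].
#' @param missing missing-genotype policy, see [privateLineFilter()].
#' @param enuOnly drop records without an ENU-typical base change.
#' @return a list with \code{candidates} (named list of per-line
#'   [VariantSet-class]) and \code{summary} (data.frame with columns
#'   line_id, inheritance, genotype, n_samples, n_private, n_exonic,
#'   n_one_per_gene, n_in_linkage (NA when no region is available),
#'   n_enu_type, n_candidates).
#' @export
runCascade <- function(x, lines, level = c("exon", "gene"),
                       missing = c("strict", "lenient"), enuOnly = FALSE) {
  level <- match.arg(level)
  missing <- match.arg(missing)
  checkLineSamples(x, lines)
  candidates <- list()
  rows <- list()
  for (ln in names(lines)) {
    spec <- lines[[ln]]
    s1 <- privateLineFilter(x, lines, ln, missing = missing)
    s2 <- exonicFilter(s1, level = level)
    s3 <- onePerGeneFilter(s2)
    s4 <- linkageRestrict(s3, linkageRegions(spec))
    applied <- attr(s4, "linkage_applied")
    flag <- enuTypeFlag(refAlleles(s4), carriedAltAllele(s4))
    info <- variantInfo(s4)
    for (r in which(flag)) info[[r]][["ENU"]] <- "1"
    s4@info <- info
    cand <- if (enuOnly) s4[flag] else s4
    candidates[[ln]] <- cand
    rows[[ln]] <- data.frame(
      line_id = ln, inheritance = inheritanceModel(spec),
      genotype = expectedGenotype(inheritanceModel(spec)),
      n_samples = length(lineSamples(spec)), n_private = length(s1),
      n_exonic = length(s2), n_one_per_gene = length(s3),
      n_in_linkage = if (applied) length(s4) else NA_integer_,
      n_enu_type = sum(flag), n_candidates = length(cand))
  }
  summary <- do.call(rbind, unname(rows))
  rownames(summary) <- NULL
  list(candidates = candidates, summary = summary)
}
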