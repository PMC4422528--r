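# Attach lifted exon and gene-span features to variant records as INFO tags:
#   EID  exon IDs of lifted exons containing the position
#   GID  gene IDs for the exons in EID
#   GIR  gene IDs for all lifted gene spans overlapping the position
#   GNM  gene names for the exons in EID
#   GNR  gene names for the gene spans in GIR
# Overlap is tested at the variant's POS base only; empty tags are omitted.

#' Build a stabbing-query index over lifted features
#'
#' @param features a \link[GenomicRanges]{GRanges} of lifted features with a
#'   \code{kind} column (\code{"exon"}/\code{"gene"}), e.g. the
#'   concatenation of [liftExons()] and [deriveGeneSpans()] output, or the
#'   two BED files read back with [readFeatureBed()].
#' @return a [FeatureIndex-class].
#' @export
buildFeatureIndex <- function(features) {
  new("FeatureIndex",
      exons = features[features$kind == "exon"],
      genes = features[features$kind == "gene"])
}

#' Features containing a position
#'
#' @param index a [FeatureIndex-class].
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param kind \code{"exon"} or \code{"gene"}.
#' @return the subset of features whose interval contains the position.
#' @export
queryFeatures <- function(index, chrom, pos, kind = c("exon", "gene")) {
  kind <- match.arg(kind)
  feats <- if (kind == "exon") index@exons else index@genes
  p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  lvls <- union(GenomeInfoDb::seqlevels(p), GenomeInfoDb::seqlevels(feats))
  GenomeInfoDb::seqlevels(p) <- lvls
  GenomeInfoDb::seqlevels(feats) <- lvls
  feats[S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(p, feats, ignore.strand = TRUE))]
}

#' Annotate variant records with lifted features
#'
#' For each record the single reference base at POS is tested for
#' containment in lifted exon features and gene spans, and the EID, GID,
#' GIR, GNM, GNR INFO tags are set (replaced, so annotation is idempotent).
#' Tags whose value list is empty are omitted; lists are deduplicated and
#' sorted. Empty gene names are dropped from GNM/GNR.
#'
#' @param x a [VariantSet-class] with target-assembly chromosome names.
#' @param index a [FeatureIndex-class].
#' @return the annotated [VariantSet-class] (same records, same order).
#' @export
annotateVariants <- function(x, index) {
  if (length(x) == 0L) return(x)
  featChroms <- union(as.character(GenomeInfoDb::seqnames(index@exons)),
                      as.character(GenomeInfoDb::seqnames(index@genes)))
  unknown <- setdiff(unique(x@chrom), featChroms)
  for (ch in unknown)
    liftLog("WARN", "chromosome %s carries no lifted features", ch)

  pos <- variantPositions(x)
  exons <- index@exons
  genes <- index@genes
  lvls <- union(GenomeInfoDb::seqlevels(pos), featChroms)
  GenomeInfoDb::seqlevels(pos) <- lvls
  GenomeInfoDb::seqlevels(exons) <- lvls
  GenomeInfoDb::seqlevels(genes) <- lvls
  exonHits <- GenomicRanges::findOverlaps(pos, exons,
                                          ignore.strand = TRUE)
  geneHits <- GenomicRanges::findOverlaps(pos, genes,
                                          ignore.strand = TRUE)
  exonBy <- split(S4Vectors::subjectHits(exonHits),
                  factor(S4Vectors::queryHits(exonHits),
                         levels = seq_along(x@pos)))
  geneBy <- split(S4Vectors::subjectHits(geneHits),
                  factor(S4Vectors::queryHits(geneHits),
                         levels = seq_along(x@pos)))
  info <- x@info
  for (r in seq_along(info)) {
    ex <- exons[exonBy[[r]]]
    gn <- genes[geneBy[[r]]]
    m <- info[[r]]
    m$EID <- ex$exon_id
    m$GID <- ex$gene_id
    m$GIR <- gn$gene_id
    m$GNM <- ex$gene_name[nzchar(ex$gene_name)]
    m$GNR <- gn$gene_name[nzchar(gn$gene_name)]
    info[[r]] <- normalizeInfo(m)
  }
  new("VariantSet", chrom = x@chrom, pos = x@pos, id = x@id, ref = x@ref,
      alt = x@alt, qual = x@qual, filter = x@filter, info = info,
      geno = x@geno)
}
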