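# Exon lift-over: best single-hit alignment of each catalog exon onto the
# target assembly, then strand-aware exon features and gene spans.

#' Seed index over a target genome
#'
#' @slot xp external pointer to the native index.
#' @slot k seed length.
#' @slot genomeNames target sequence names.
#' @seealso [buildKmerIndex()]
#' @export
setClass("KmerIndex",
  representation(xp = "ANY", k = "integer", genomeNames = "character"))

setMethod("show", "KmerIndex", function(object) {
  info <- .seed_index_info(object@xp)
  cat(sprintf("KmerIndex: k=%d over %d sequence(s), %.0f seeds\n", object@k,
              length(object@genomeNames), info$n_seeds))
})

#' Build a k-mer seed index of a genome
#'
#' Indexes every k-mer position of the genome (k-mers containing N are
#' skipped). Reverse-complement seeds are resolved at query time, so minus-
#' strand hits need no second index.
#'
#' @param genome a named \link[Biostrings]{DNAStringSet} or named character
#'   vector of target sequences.
#' @param k seed length in bases (>= 8, <= 31).
#' @return a [KmerIndex-class].
#' @examples
#' idx <- buildKmerIndex(c(chr1 = "ACGTACGTACGT"), k = 8)
#' kmerPositions(idx, "ACGTACGT")
#' @export
buildKmerIndex <- function(genome, k = 16L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named")
  xp <- .seed_index_build(genome, k)
  new("KmerIndex", xp = xp, k = k, genomeNames = names(genome))
}

#' Positions of an exact k-mer in an indexed genome
#'
#' @param index a [KmerIndex-class].
#' @param kmer a k-length DNA string.
#' @param strand \code{"+"} looks up the k-mer itself, \code{"-"} its
#'   reverse complement.
#' @return a data.frame with columns \code{chrom} and 1-based \code{pos}.
#' @export
kmerPositions <- function(index, kmer, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  res <- .seed_index_lookup(index@xp, as.character(kmer), strand)
  data.frame(chrom = index@genomeNames[unlist(res$chrom) + 1L],
             pos = as.integer(unlist(res$pos)) + 1L)
}

hitFromList <- function(res, queryId, seqlevels) {
  gr <- GenomicRanges::GRanges(factor(res$chrom, levels = seqlevels),
                               IRanges::IRanges(res$start, res$end),
                               strand = res$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    query_id = queryId,
    percent_identity = round(res$percent_identity, 2L),
    alignment_length = as.integer(res$columns),
    mismatches = as.integer(res$mismatches),
    gap_opens = as.integer(res$gap_opens),
    score = res$score)
  gr
}

#' Best single alignment of one sequence against an indexed genome
#'
#' Exact k-mer seeds are clustered by diagonal on both strands and each
#' candidate locus is extended by a windowed local alignment (match +1,
#' mismatch -2, gap open -4, gap extend -1). The single highest-scoring
#' alignment is returned; ties break by percent identity, alignment length,
#' then lowest (chromosome name, start). Percent identity is
#' 100 x matches / alignment columns, reported to 2 decimals.
#'
#' @param sequence DNA string (or single-element DNAStringSet) to place.
#' @param index a [KmerIndex-class] of the target genome.
#' @param minCoverage minimum fraction of the query that the best alignment
#'   must cover; hits below it are discarded.
#' @param band diagonal band width for seed clustering and extension.
#' @param queryId identifier recorded in the returned hit.
#' @return a single-hit \link[GenomicRanges]{GRanges} (as [readTabularHits()]
#'   emits), or a zero-length one when no acceptable hit exists.
#' @export
findBestHit <- function(sequence, index, minCoverage = 0.7, band = 16L,
                        queryId = "query") {
  sequence <- as.character(sequence)
  res <- .seed_align_query(index@xp, sequence, minCoverage,
                           as.integer(band), 32L, 256L, 1L, -2L, -4L, -1L)
  if (length(res) == 0L) return(emptyHits())
  hitFromList(res, queryId, index@genomeNames)
}

#' Select the single best hit per query from a hit list
#'
#' Used for externally computed tabular hits where the aligner emitted more
#' than one hit per query. Maximizes (score, percent identity, alignment
#' length); remaining ties break by lowest (chromosome name, start). The
#' result is independent of the input order.
#'
#' @param hits a hit \link[GenomicRanges]{GRanges} (see [readTabularHits()]).
#' @return one hit per distinct \code{query_id}.
#' @export
selectBest <- function(hits) {
  if (length(hits) == 0L) stop("empty hit list")
  ord <- order(hits$query_id, -hits$score, -hits$percent_identity,
               -hits$alignment_length,
               as.character(GenomeInfoDb::seqnames(hits)),
               GenomicRanges::start(hits),
               as.character(GenomicRanges::strand(hits)))
  hits <- hits[ord]
  hits[!duplicated(hits$query_id)]
}

composeStrand <- function(a, b) ifelse(a == b, "+", "-")

#' Lift catalog exons onto the target assembly
#'
#' One exon feature per best hit. The feature strand is the composition of
#' the exon's source gene strand with the hit strand (two minuses give plus),
#' which orients the gene on the target assembly given catalog sequences in
#' forward-genome orientation. Exons without hits are absent from the result
#' and reported.
#'
#' @param catalog an [ExonCatalog-class].
#' @param hits best hits, one per exon (\link[GenomicRanges]{GRanges} with a
#'   \code{query_id} column naming catalog exons).
#' @return a \link[GenomicRanges]{GRanges} of exon features with metadata
#'   columns \code{kind} (\code{"exon"}), \code{exon_id}, \code{gene_id},
#'   \code{gene_name}, \code{percent_identity}.
#' @export
liftExons <- function(catalog, hits) {
  idx <- match(hits$query_id, exonIds(catalog))
  if (anyNA(idx))
    stop(sprintf("hit(s) reference unknown exon ID(s): %s",
                 paste(unique(hits$query_id[is.na(idx)]), collapse = ", ")))
  features <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(hits), IRanges::ranges(hits),
    strand = composeStrand(geneStrands(catalog)[idx],
                           as.character(GenomicRanges::strand(hits))))
  S4Vectors::mcols(features) <- S4Vectors::DataFrame(
    kind = rep("exon", length(hits)), exon_id = hits$query_id,
    gene_id = geneIds(catalog)[idx], gene_name = geneNames(catalog)[idx],
    percent_identity = hits$percent_identity)
  nUnmapped <- length(catalog) - length(features)
  liftLog("INFO", "lifted %d/%d exons (%d unmapped)", length(features),
          length(catalog), nUnmapped)
  features
}

#' Derive gene spans from lifted exon features
#'
#' One gene feature per gene: the interval from the outermost exon start to
#' the outermost exon end on the gene's majority chromosome; exons of the
#' gene lifted to other chromosomes are excluded from the span and logged.
#' The gene strand is the majority exon strand (ties resolve to \code{"+"}).
#'
#' @param exonFeatures exon features from [liftExons()].
#' @return a \link[GenomicRanges]{GRanges} of gene features (\code{kind}
#'   \code{"gene"}, empty \code{exon_id}, \code{percent_identity} NA).
#' @export
deriveGeneSpans <- function(exonFeatures) {
  stopifnot(all(exonFeatures$kind == "exon"))
  geneIds <- unique(exonFeatures$gene_id)
  chromOut <- character(0); startOut <- integer(0); endOut <- integer(0)
  strandOut <- character(0); nameOut <- character(0)
  for (g in geneIds) {
    ex <- exonFeatures[exonFeatures$gene_id == g]
    chroms <- as.character(GenomeInfoDb::seqnames(ex))
    tab <- table(chroms)
    major <- names(tab)[tab == max(tab)][1L]  # lexicographically smallest
    dropped <- sum(chroms != major)
    if (dropped > 0)
      liftLog("WARN",
              "gene %s: %d exon(s) lifted off chromosome %s excluded from its span",
              g, dropped, major)
    ex <- ex[chroms == major]
    strands <- as.character(GenomicRanges::strand(ex))
    chromOut <- c(chromOut, major)
    startOut <- c(startOut, min(GenomicRanges::start(ex)))
    endOut <- c(endOut, max(GenomicRanges::end(ex)))
    strandOut <- c(strandOut,
                   if (sum(strands == "-") > length(strands) / 2) "-" else "+")
    nameOut <- c(nameOut, ex$gene_name[1L])
  }
  gr <- GenomicRanges::GRanges(
    factor(chromOut, levels = GenomeInfoDb::seqlevels(exonFeatures)),
    IRanges::IRanges(startOut, endOut), strand = strandOut)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = rep("gene", length(geneIds)),
    exon_id = rep("", length(geneIds)), gene_id = geneIds,
    gene_name = nameOut, percent_identity = rep(NA_real_, length(geneIds)))
  gr
}

#' Lift a whole exon catalog with the built-in aligner
#'
#' Convenience wrapper: builds the seed index, finds the best hit per exon,
#' and derives exon features and gene spans.
#'
#' @param catalog an [ExonCatalog-class].
#' @param genome target genome (named \link[Biostrings]{DNAStringSet} or
#'   named character vector).
#' @param k seed length.
#' @param minCoverage minimum query coverage of an acceptable hit.
#' @return a list with \code{hits} (best hit per mapped exon),
#'   \code{exons} and \code{genes} (lifted features), and \code{unmapped}
#'   (IDs of exons without an acceptable hit).
#' @export
liftoverExons <- function(catalog, genome, k = 16L, minCoverage = 0.7) {
  index <- buildKmerIndex(genome, k = k)
  hitList <- vector("list", length(catalog))
  seqs <- as.character(exonSequences(catalog))
  ids <- exonIds(catalog)
  for (i in seq_along(seqs))
    hitList[[i]] <- findBestHit(seqs[i], index, minCoverage = minCoverage,
                                queryId = ids[i])
  hitList <- hitList[vapply(hitList, length, 0L) > 0L]
  hits <- if (length(hitList)) unname(do.call(c, hitList)) else emptyHits()
  unmapped <- setdiff(ids, hits$query_id)
  if (length(unmapped))
    liftLog("INFO", "%d exon(s) had no acceptable hit", length(unmapped))
  exons <- liftExons(catalog, hits)
  genes <- deriveGeneSpans(exons)
  list(hits = hits, exons = exons, genes = genes, unmapped = unmapped)
}

#' Per-source-chromosome identity summary of lift-over hits
#'
#' @param hits best-hit \link[GenomicRanges]{GRanges} with
#'   \code{percent_identity} and \code{query_id} columns.
#' @param catalog the [ExonCatalog-class] supplying each exon's source
#'   chromosome.
#' @return a list with \code{per_chromosome} (data.frame: chromosome, n,
#'   min_identity, mean_identity) and \code{overall_mean} (NA with a message
#'   when there are no hits).
#' @export
identitySummary <- function(hits, catalog) {
  if (length(hits) == 0L) {
    liftLog("WARN", "identity summary over zero hits; overall mean undefined")
    return(list(per_chromosome = data.frame(
      chromosome = character(0), n = integer(0), min_identity = numeric(0),
      mean_identity = numeric(0)), overall_mean = NA_real_))
  }
  chrom <- sourceChromosomes(catalog)[match(hits$query_id, exonIds(catalog))]
  ident <- hits$percent_identity
  per <- do.call(rbind, lapply(sort(unique(chrom)), function(ch) {
    v <- ident[chrom == ch]
    data.frame(chromosome = ch, n = length(v), min_identity = min(v),
               mean_identity = mean(v))
  }))
  rownames(per) <- NULL
  list(per_chromosome = per, overall_mean = mean(ident))
}
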