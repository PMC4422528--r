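setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Exon catalog of the annotated source assembly
#'
#' One record per exon of the source (annotated) assembly: identifiers, gene
#' membership, source chromosome, gene strand, and the exon DNA sequence.
#' Sequences are stored in forward-genome orientation (the orientation of the
#' source chromosome's plus strand), with the \code{strand} column recording
#' the direction of the gene; the lift-over composes the gene strand with the
#' alignment hit strand to orient lifted features.
#'
#' @slot sequences a \link[Biostrings]{DNAStringSet}, names are exon IDs
#'   (unique, non-empty).
#' @slot geneId,geneName,chromosome,strand character vectors parallel to
#'   \code{sequences}; \code{geneName} may be empty; \code{strand} is
#'   \code{"+"} or \code{"-"}.
#'
#' @seealso [readExonTable()], [exonCatalog()]
#' @export
setClass("ExonCatalog",
  representation(sequences = "DNAStringSet", geneId = "character",
                 geneName = "character", chromosome = "character",
                 strand = "character"))

setValidity("ExonCatalog", function(object) {
  n <- length(object@sequences)
  msgs <- character()
  if (length(object@geneId) != n || length(object@geneName) != n ||
      length(object@chromosome) != n || length(object@strand) != n)
    msgs <- c(msgs, "annotation vectors must parallel 'sequences'")
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || any(!nzchar(ids))))
    msgs <- c(msgs, "every exon needs a non-empty exon ID")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicated exon IDs: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (n > 0 && any(Biostrings::width(object@sequences) < 1L))
    msgs <- c(msgs, "exon sequences must have length >= 1")
  if (n > 0 && !all(object@strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an exon catalog
#'
#' @param exonId,geneId,geneName,chromosome,strand,sequence parallel vectors
#'   describing one exon each; \code{sequence} is forward-genome oriented DNA.
#' @return an [ExonCatalog-class] object.
#' @examples
#' exonCatalog(exonId = "E1", geneId = "G1", geneName = "Abc",
#'             chromosome = "chr1", strand = "+", sequence = "ACGTACGT")
#' @export
exonCatalog <- function(exonId, geneId, geneName, chromosome, strand,
                        sequence) {
  seqs <- Biostrings::DNAStringSet(as.character(sequence))
  names(seqs) <- as.character(exonId)
  new("ExonCatalog", sequences = seqs, geneId = as.character(geneId),
      geneName = as.character(geneName),
      chromosome = as.character(chromosome), strand = as.character(strand))
}

#' Multi-sample variant set
#'
#' A light text-level model of a multi-sample VCF: one row per site with
#' per-sample genotypes normalized to unordered, unphased allele-index pairs
#' (\code{"0/1"}; missing is \code{"."}) and an INFO map of tag to a sorted,
#' duplicate-free character vector of values.
#'
#' @slot chrom,id,ref,qual,filter character vectors, one element per record.
#' @slot pos integer vector of 1-based positions.
#' @slot alt list of character vectors (ALT alleles per record).
#' @slot info list of named lists; each element maps an INFO tag to a sorted
#'   character vector of values.
#' @slot geno character matrix, records x samples, normalized genotypes.
#'
#' @seealso [readVcfFile()], [writeVcfFile()], [variantSet()]
#' @export
setClass("VariantSet",
  representation(chrom = "character", pos = "integer", id = "character",
                 ref = "character", alt = "list", qual = "character",
                 filter = "character", info = "list", geno = "matrix"))

setValidity("VariantSet", function(object) {
  n <- length(object@pos)
  msgs <- character()
  lens <- c(length(object@chrom), length(object@id), length(object@ref),
            length(object@alt), length(object@qual), length(object@filter),
            length(object@info))
  if (any(lens != n)) msgs <- c(msgs, "all record slots must have equal length")
  if (nrow(object@geno) != n)
    msgs <- c(msgs, "genotype matrix must have one row per record")
  if (ncol(object@geno) > 0 && is.null(colnames(object@geno)))
    msgs <- c(msgs, "genotype matrix needs sample names as colnames")
  if (n > 0 && any(object@pos < 1L)) msgs <- c(msgs, "positions must be >= 1")
  if (n > 0 && any(!nzchar(object@ref)))
    msgs <- c(msgs, "REF alleles must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct a variant set
#'
#' @param chrom,pos,ref core site fields (parallel vectors).
#' @param alt ALT alleles: a character vector (one allele per record) or a
#'   list of character vectors.
#' @param geno character matrix of genotypes (records x samples, colnames =
#'   sample IDs); genotypes are normalized on construction.
#' @param id,qual,filter,info optional per-record fields.
#' @return a [VariantSet-class] object.
#' @export
variantSet <- function(chrom, pos, ref, alt, geno,
                       id = NULL, qual = NULL, filter = NULL, info = NULL) {
  n <- length(pos)
  if (!is.list(alt)) alt <- as.list(as.character(alt))
  if (is.null(id)) id <- rep(".", n)
  if (is.null(qual)) qual <- rep(".", n)
  if (is.null(filter)) filter <- rep(".", n)
  if (is.null(info)) info <- rep(list(list()), n)
  geno <- as.matrix(geno)
  if (n > 0 && nrow(geno) != n) stop("geno must have one row per record")
  norm <- apply(geno, c(1, 2), normalizeGenotype)
  if (n == 0) norm <- geno
  new("VariantSet", chrom = as.character(chrom), pos = as.integer(pos),
      id = as.character(id), ref = as.character(ref), alt = alt,
      qual = as.character(qual), filter = as.character(filter),
      info = lapply(info, normalizeInfo), geno = norm)
}

#' Mutant line specification
#'
#' One mutagenized line: its sequenced animals (VCF sample IDs), the expected
#' mode of inheritance, and optional linkage regions confining the causative
#' locus.
#'
#' @slot lineId single identifier.
#' @slot samples non-empty character vector of VCF sample IDs.
#' @slot inheritance \code{"dominant"} or \code{"recessive"}.
#' @slot regions a \link[GenomicRanges]{GRanges} of linkage regions, or
#'   \code{NULL} when no region is available.
#'
#' @seealso [lineSpec()], [readLineConfig()]
#' @export
setClass("LineSpec",
  representation(lineId = "character", samples = "character",
                 inheritance = "character", regions = "GRangesOrNULL"))

setValidity("LineSpec", function(object) {
  msgs <- character()
  if (length(object@lineId) != 1L || !nzchar(object@lineId))
    msgs <- c(msgs, "lineId must be a single non-empty string")
  if (length(object@samples) < 1L)
    msgs <- c(msgs, "a line needs at least one sample")
  if (length(object@inheritance) != 1L ||
      !object@inheritance %in% c("dominant", "recessive"))
    msgs <- c(msgs, "inheritance must be 'dominant' or 'recessive'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LineSpec-class
#' @param lineId,samples,inheritance,regions see the class slots.
#' @export
lineSpec <- function(lineId, samples, inheritance, regions = NULL) {
  new("LineSpec", lineId = as.character(lineId),
      samples = as.character(samples),
      inheritance = match.arg(inheritance, c("dominant", "recessive")),
      regions = regions)
}

#' Stabbing-query index over lifted features
#'
#' Lifted exon and gene-span features held separately so that a position
#' query returns exactly the features whose interval contains it.
#'
#' @slot exons,genes \link[GenomicRanges]{GRanges} of lifted features of the
#'   respective kind, carrying \code{exon_id}, \code{gene_id},
#'   \code{gene_name} metadata columns.
#' @seealso [buildFeatureIndex()], [annotateVariants()]
#' @export
setClass("FeatureIndex",
  representation(exons = "GRanges", genes = "GRanges"))

#' Simulation configuration
#'
#' Parameters of the synthetic study: a diverged genome pair emulating an
#' annotated source assembly and an un-annotated target strain assembly, an
#' exon catalog, and a multi-line cohort with one planted causative exonic
#' ENU-type variant per line. Defaults mirror the study design the package
#' targets: 8 lines with 4,4,4,4,2,2,2,2 sequenced animals, inheritance
#' recessive/dominant/dominant/recessive then dominant, linkage regions
#' available for two lines only, 5000 shared strain variants, 200 private
#' noise variants per line, and 1\% source-to-target divergence.
#'
#' @slot nChromosomes,chromosomeLength,nGenes integer genome layout.
#' @slot exonsPerGene,exonLength,intronLength integer ranges (min, max).
#' @slot divergence per-base substitution rate source to target (< 0.1).
#' @slot nIndels number of small indels (0 keeps coordinates aligned).
#' @slot indelLength integer range of indel lengths.
#' @slot nLines number of mutant lines.
#' @slot samplesPerLine integer vector, animals sequenced per line (2-4).
#' @slot inheritance character vector of inheritance modes per line.
#' @slot nSharedVariants strain background variants present in all samples.
#' @slot nNoisePerLine private noise variants per line.
#' @slot noiseFractions named numeric: fractions of noise placed
#'   \code{intergenic}, \code{intronic}, and in \code{multiGene} exon pairs.
#' @slot linkageLines indices of lines with a linkage region.
#' @slot linkageWidth linkage region width as a fraction of the chromosome.
#' @slot seed integer RNG seed; all outputs are pure functions of the config.
#' @seealso [simConfig()], [simulateGenomePair()], [simulateCohort()]
#' @export
setClass("SimConfig",
  representation(nChromosomes = "integer", chromosomeLength = "integer",
                 nGenes = "integer", exonsPerGene = "integer",
                 exonLength = "integer", intronLength = "integer",
                 divergence = "numeric", nIndels = "integer",
                 indelLength = "integer", nLines = "integer",
                 samplesPerLine = "integer", inheritance = "character",
                 nSharedVariants = "integer", nNoisePerLine = "integer",
                 noiseFractions = "numeric", linkageLines = "integer",
                 linkageWidth = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  pos1 <- c(nChromosomes = object@nChromosomes,
            chromosomeLength = object@chromosomeLength,
            nGenes = object@nGenes, nLines = object@nLines)
  bad <- names(pos1)[pos1 < 1L]
  if (length(bad)) msgs <- c(msgs, paste("must be positive:",
                                         paste(bad, collapse = ", ")))
  if (object@divergence < 0 || object@divergence >= 0.1)
    msgs <- c(msgs, "divergence must lie in [0, 0.1)")
  if (length(object@samplesPerLine) != object@nLines)
    msgs <- c(msgs, "samplesPerLine must have one entry per line")
  else if (any(object@samplesPerLine < 2L | object@samplesPerLine > 4L))
    msgs <- c(msgs, "samplesPerLine entries must be in 2..4")
  if (length(object@inheritance) != object@nLines ||
      !all(object@inheritance %in% c("dominant", "recessive")))
    msgs <- c(msgs, "inheritance must name a valid mode per line")
  if (abs(sum(object@noiseFractions) - 1) > 1e-8 ||
      !all(c("intergenic", "intronic", "multiGene") %in%
           names(object@noiseFractions)))
    msgs <- c(msgs, "noiseFractions must be named and sum to 1")
  if (any(object@linkageLines < 1L | object@linkageLines > object@nLines))
    msgs <- c(msgs, "linkageLines out of range")
  if (length(msgs)) msgs else TRUE
})
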