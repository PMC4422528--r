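# tab-separated exon catalog (Biomart-style export) and 12-column tabular
# alignment hits

EXON_TABLE_COLUMNS <- c("exon_id", "gene_id", "gene_name", "chromosome",
                        "strand", "sequence")

#' Read an exon catalog table
#'
#' Tab-separated with a header row naming at least \code{exon_id},
#' \code{gene_id}, \code{gene_name}, \code{chromosome}, \code{strand} and
#' \code{sequence}. Rows with an empty sequence are skipped with a warning.
#' Sequences are expected in forward-genome orientation (see
#' [ExonCatalog-class]).
#'
#' @param path TSV file.
#' @return an [ExonCatalog-class].
#' @export
readExonTable <- function(path) {
  if (!file.exists(path)) formatError("exon table not found: %s", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  missing <- setdiff(EXON_TABLE_COLUMNS, colnames(tab))
  if (length(missing))
    formatError("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  empty <- !nzchar(tab$sequence) | is.na(tab$sequence)
  if (any(empty)) {
    liftLog("WARN", "%s: skipping %d row(s) with empty sequence", path,
            sum(empty))
    tab <- tab[!empty, , drop = FALSE]
  }
  exonCatalog(exonId = tab$exon_id, geneId = tab$gene_id,
              geneName = tab$gene_name, chromosome = tab$chromosome,
              strand = tab$strand, sequence = tab$sequence)
}

#' Write an exon catalog table
#'
#' @param catalog an [ExonCatalog-class].
#' @param path output TSV file.
#' @return invisibly, \code{path}.
#' @export
writeExonTable <- function(catalog, path) {
  tab <- data.frame(exon_id = exonIds(catalog), gene_id = geneIds(catalog),
                    gene_name = geneNames(catalog),
                    chromosome = sourceChromosomes(catalog),
                    strand = geneStrands(catalog),
                    sequence = as.character(exonSequences(catalog)),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read precomputed alignment hits in 12-column tabular format
#'
#' The standard tabular dialect: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start, query end, subject start,
#' subject end, e-value, bit score (1-based inclusive coordinates). A subject
#' start greater than subject end marks a minus-strand hit; coordinates are
#' normalized to ascending with the strand recorded.
#'
#' @param path whitespace-delimited 12-column file.
#' @return a \link[GenomicRanges]{GRanges} of hits with metadata columns
#'   \code{query_id}, \code{percent_identity}, \code{alignment_length},
#'   \code{mismatches}, \code{gap_opens}, \code{score}.
#' @export
readTabularHits <- function(path) {
  if (!file.exists(path)) formatError("hits file not found: %s", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(emptyHits())
  qid <- character(length(keep)); sid <- character(length(keep))
  num <- matrix(NA_real_, nrow = length(keep), ncol = 10L)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
    if (length(f) != 12L)
      formatError("%s line %d: %d fields, expected 12", path, ln, length(f))
    vals <- suppressWarnings(as.numeric(f[3:12]))
    if (anyNA(vals))
      formatError("%s line %d: non-numeric coordinate or score field", path,
                  ln)
    qid[i] <- f[1L]; sid[i] <- f[2L]; num[i, ] <- vals
  }
  sstart <- num[, 7L]; send <- num[, 8L]
  strand <- ifelse(sstart <= send, "+", "-")
  lo <- pmin(sstart, send); hi <- pmax(sstart, send)
  gr <- GenomicRanges::GRanges(sid, IRanges::IRanges(lo, hi),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    query_id = qid, percent_identity = num[, 1L],
    alignment_length = as.integer(num[, 2L]),
    mismatches = as.integer(num[, 3L]), gap_opens = as.integer(num[, 4L]),
    score = num[, 10L])
  gr
}

emptyHits <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    query_id = character(0), percent_identity = numeric(0),
    alignment_length = integer(0), mismatches = integer(0),
    gap_opens = integer(0), score = numeric(0))
  gr
}
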