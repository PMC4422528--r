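# BED6 I/O for lifted features. The BED name field encodes
# "kind|exon_id|gene_id|gene_name" with kind in {exon, gene} and an empty
# exon_id segment for gene spans. On disk BED is 0-based half-open; in
# memory features are GRanges (1-based closed); rtracklayer performs the
# conversion at the boundary.

featureName <- function(kind, exon_id, gene_id, gene_name) {
  paste(kind, exon_id, gene_id, gene_name, sep = "|")
}

#' Write lifted features as BED6
#'
#' @param features a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{kind}, \code{exon_id}, \code{gene_id}, \code{gene_name} (see
#'   [liftExons()], [deriveGeneSpans()]).
#' @param path output BED file.
#' @return invisibly, \code{path}.
#' @export
writeFeatureBed <- function(features, path) {
  m <- S4Vectors::mcols(features)
  out <- features
  S4Vectors::mcols(out) <- NULL
  names(out) <- NULL
  out$name <- featureName(m$kind, m$exon_id, m$gene_id, m$gene_name)
  out$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read lifted features from BED6
#'
#' @param path BED file written by [writeFeatureBed()] (or any BED6 whose
#'   name field follows the \code{kind|exon_id|gene_id|gene_name} encoding).
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{kind}, \code{exon_id}, \code{gene_id}, \code{gene_name}.
#' @export
readFeatureBed <- function(path) {
  if (!file.exists(path)) formatError("BED file not found: %s", path)
  lines <- readLines(path)
  body <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L)
      formatError("%s line %d: expected BED6 (6 columns), found %d", path,
                  ln, length(f))
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      formatError("%s line %d: non-numeric coordinates", path, ln)
    if (s >= e)
      formatError("%s line %d: start (%s) must be < end (%s)", path, ln,
                  f[2L], f[3L])
  }
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  getf <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[[i]] else ""
  }, "")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = getf(1L), exon_id = getf(2L), gene_id = getf(3L),
    gene_name = getf(4L))
  gr
}
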