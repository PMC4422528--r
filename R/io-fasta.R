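#' Read a genome FASTA
#'
#' Sequence names are the first whitespace-delimited token of each header
#' and must be unique.
#'
#' @param path FASTA file.
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) formatError("FASTA file not found: %s", path)
  lines <- readLines(path, n = 1000L)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first))
    formatError("%s line 1: empty FASTA file", path)
  if (!startsWith(lines[first], ">"))
    formatError("%s line %d: expected a '>' FASTA header", path, first)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    formatError("%s: duplicate sequence name(s): %s", path,
                paste(dup, collapse = ", "))
  seqs
}

#' Write a genome FASTA
#'
#' @param seqs a named \link[Biostrings]{DNAStringSet} or named character
#'   vector.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
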